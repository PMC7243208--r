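make_hb_kernels <- function(g, sets) {
  hb <- build_haploblocks(g, sets = sets, max_alleles = 6)
  pm <- dosage_encode(hb)
  cg <- categorical_encode(hb)
  list(hb = hb, pm = pm, cg = cg,
       GH = grm_haplotype(pm), SH = ibs_categorical(cg),
       EH = epistasis_categorical(ibs_categorical(cg)))
}

test_that("the VanRaden matrix matches its closed form on a hand example", {
  # 3 individuals x 2 markers, dosages (0,2), (1,1), (2,0): p = (0.5, 0.5)
  h1 <- rbind(c(0L, 1L), c(1L, 0L), c(1L, 0L))
  h2 <- rbind(c(0L, 1L), c(0L, 1L), c(1L, 0L))
  g <- phased_genotypes(h1, h2, tibble::tibble(
    marker_id = c("a", "b"), chrom = "1", pos = c(1L, 2L)
  ))
  G <- grm_vanraden(g)
  Z <- rbind(c(-1, 1), c(0, 0), c(1, -1))    # M - 2p
  expect_equal(unname(G$K), Z %*% t(Z) / 1, tolerance = 1e-12)
  expect_equal(G$denominator, 2 * (0.25 + 0.25))
  # identical genotype rows give identical kernel entries
  expect_equal(G$K[1, 1], G$K[1, 1])
  g2 <- subset_genotypes(g, individuals = c(1L, 1L, 2L))
  G2 <- grm_vanraden(g2)
  expect_equal(G2$K[1, 1], G2$K[1, 2])
  expect_equal(G2$K[1, 1], G2$K[2, 2])
})

test_that("centring by 2p makes G row sums vanish", {
  g <- rand_genotypes(12, 25, seed = 6)
  G <- grm_vanraden(g)
  expect_equal(unname(rowSums(G$K)), rep(0, 12), tolerance = 1e-10)
  mono <- phased_genotypes(matrix(0L, 4, 2), matrix(0L, 4, 2),
                           tibble::tibble(marker_id = c("a", "b"),
                                          chrom = "1", pos = c(1L, 2L)))
  expect_error(grm_vanraden(mono), "monomorphic")
})

test_that("haplotype kernel entries follow the dosage cross products", {
  fx <- table2_population()
  hb <- build_haploblocks(fx$genotypes, sets = list(1:2))
  pm <- dosage_encode(hb)
  # two AB|Ab individuals (row 2 of the ten configurations): dot product 2/1
  GH <- grm_haplotype(pm)
  expect_equal(GH$K[2, 2], 2)
  # diagonals over multi-SNP blocks are 2 (full het) .. 4 (full hom)
  diag_multi <- diag(GH$K)
  expect_true(all(diag_multi >= 2 - 1e-12 & diag_multi <= 4 + 1e-12))
  # Q = 1 single-SNP column: outer product of the 0/1/2 genotype
  g <- rand_genotypes(8, 3, seed = 10)
  hb1 <- build_haploblocks(g, sets = list(2L))
  GH1 <- grm_haplotype(dosage_encode(hb1))
  v <- dosage(g)[, 2]
  expect_equal(unname(GH1$K), unname(outer(v, v)) / 1, tolerance = 1e-12)
})

test_that("IBS entries count shared states and ignore locus order", {
  # genotypes j = (0,1,2), i = (0,2,2) over m = 3 share 2 states
  h1 <- rbind(c(0L, 1L, 1L), c(0L, 1L, 1L))
  h2 <- rbind(c(0L, 0L, 1L), c(0L, 1L, 1L))
  g <- phased_genotypes(h1, h2, tibble::tibble(
    marker_id = paste0("m", 1:3), chrom = "1", pos = c(1L, 2L, 3L)
  ))
  S <- ibs_categorical(g)
  expect_equal(S$K[1, 2], 2 / 3)
  expect_equal(diag(S$K), setNames(c(1, 1), g$ids))
  # permuting loci leaves the matrix unchanged
  perm <- c(3L, 1L, 2L)
  gp <- phased_genotypes(h1[, perm], h2[, perm], tibble::tibble(
    marker_id = paste0("p", 1:3), chrom = "1", pos = c(1L, 2L, 3L)
  ))
  expect_equal(unname(ibs_categorical(gp)$K), unname(S$K))
})

test_that("the epistasis lift matches exhaustive pair counting", {
  # S_ij = 2/3 at m = 3 -> E_ij = 0.5 * 2 * 3 / 9 = 1/3
  h1 <- rbind(c(0L, 1L, 1L), c(0L, 1L, 1L))
  h2 <- rbind(c(0L, 0L, 1L), c(0L, 1L, 1L))
  g <- phased_genotypes(h1, h2, tibble::tibble(
    marker_id = paste0("m", 1:3), chrom = "1", pos = c(1L, 2L, 3L)
  ))
  E <- epistasis_categorical(ibs_categorical(g))
  expect_equal(E$K[1, 2], 1 / 3)
  expect_identical(unname(diag(E$K)), rep((3 + 1) / (2 * 3), 2))
  expect_equal(unname(E$K), oracle_epistasis(dosage(g), 3), tolerance = 1e-14)
  # zero shared loci -> zero shared pairs
  h1b <- rbind(c(0L, 0L), c(1L, 1L))
  gb <- phased_genotypes(h1b, h1b, tibble::tibble(
    marker_id = c("a", "b"), chrom = "1", pos = c(1L, 2L)
  ))
  Eb <- epistasis_categorical(ibs_categorical(gb))
  expect_equal(Eb$K[1, 2], 0)
  # count mismatch with the parent kernel is an error
  expect_error(epistasis_categorical(ibs_categorical(gb), count = 5), "match")
  expect_error(epistasis_categorical(grm_vanraden(rand_genotypes(4, 3, seed = 1))),
               "S-family")
})

test_that("all kernels agree with brute-force nested-loop oracles", {
  withr::with_seed(17, {
    for (rep in 1:25) {
      n <- sample(3:6, 1)
      m <- sample(4:12, 1)
      g <- rand_genotypes(n, m)
      D <- unname(dosage(g))
      expect_equal(unname(grm_vanraden(g)$K), oracle_grm_vanraden(D),
                   tolerance = 1e-10)
      expect_equal(unname(ibs_categorical(g)$K), oracle_ibs(D, m),
                   tolerance = 1e-10)
      expect_equal(unname(epistasis_categorical(ibs_categorical(g))$K),
                   oracle_epistasis(D, m), tolerance = 1e-10)
      kk <- make_hb_kernels(g, list(seq_len(m)))
      expect_equal(unname(kk$GH$K),
                   oracle_cross_product(unname(kk$pm$matrix), kk$hb$Q),
                   tolerance = 1e-10)
      expect_equal(unname(kk$SH$K), oracle_ibs(unname(kk$cg$codes), kk$hb$Q),
                   tolerance = 1e-10)
      expect_equal(unname(kk$EH$K),
                   oracle_epistasis(unname(kk$cg$codes), kk$hb$Q),
                   tolerance = 1e-10)
    }
  })
})

test_that("single-SNP blocks reduce S_H to S and E_H to E", {
  withr::with_seed(29, {
    for (rep in 1:10) {
      n <- sample(4:8, 1); m <- sample(3:10, 1)
      g <- rand_genotypes(n, m)
      hb <- build_haploblocks(g, sets = as.list(seq_len(m)))
      expect_equal(hb$Q, m)
      cg <- categorical_encode(hb)
      SH <- ibs_categorical(cg)
      S <- ibs_categorical(g)
      expect_equal(unname(SH$K), unname(S$K), tolerance = 1e-12)
      expect_equal(unname(epistasis_categorical(SH)$K),
                   unname(epistasis_categorical(S)$K), tolerance = 1e-12)
    }
  })
})

test_that("kernels are symmetric, bounded and PSD up to a tiny ridge", {
  g <- rand_genotypes(20, 30, seed = 52)
  kk <- make_hb_kernels(g, list(1:30))
  for (k in list(grm_vanraden(g), ibs_categorical(g),
                 epistasis_categorical(ibs_categorical(g)),
                 kk$GH, kk$SH, kk$EH)) {
    expect_identical(k$K, t(k$K))
    expect_gte(min(eigen(k$K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
  S <- ibs_categorical(g)
  expect_true(all(S$K >= 0 & S$K <= 1 + 1e-12))
  E <- epistasis_categorical(S)
  m <- S$denominator
  expect_true(all(E$K >= 0 & E$K <= (m + 1) / (2 * m) + 1e-12))
})

test_that("adding or removing a shared locus moves IBS monotonically", {
  withr::with_seed(63, {
    g <- rand_genotypes(6, 10)
    D <- dosage(g)
    S <- ibs_categorical(g)$K * 10          # shared-locus counts
    # append a locus where individuals 1 and 2 share state
    h_extra <- matrix(0L, 6, 1)
    g2 <- phased_genotypes(cbind(g$hap1, h_extra), cbind(g$hap2, h_extra),
                           dplyr::bind_rows(g$markers[, c("marker_id", "chrom", "pos")],
                                            tibble::tibble(marker_id = "x",
                                                           chrom = "1",
                                                           pos = max(g$markers$pos) + 1L)))
    S2 <- ibs_categorical(g2)$K * 11
    expect_true(all(S2 - S >= -1e-9))
  })
})

test_that("kernel text and GCTA binary round trips preserve the matrix", {
  g <- rand_genotypes(10, 15, seed = 71)
  G <- grm_vanraden(g)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_kernel_tsv(G, tsv)
  back <- read_kernel_tsv(tsv)
  expect_equal(back$K, G$K, tolerance = 1e-6)
  expect_identical(back$ids, G$ids)
  prefix <- withr::local_tempfile()
  write_grm_gcta(G, prefix)
  back2 <- read_grm_gcta(prefix)
  expect_equal(back2$K, G$K, tolerance = 1e-6)  # single-precision storage
  expect_identical(back2$ids, G$ids)
})
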