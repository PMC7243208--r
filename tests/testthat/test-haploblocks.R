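test_that("a one-marker SNP set is retained as a 0/1/2 single-SNP column", {
  g <- rand_genotypes(12, 5, seed = 2)
  hb <- build_haploblocks(g, sets = list(3L))
  expect_equal(hb$Q, 1L)
  expect_equal(hb$blocks[[1]]$type, "single")
  expect_equal(hb$blocks[[1]]$geno, unname(dosage(g)[, 3]))
  pm <- dosage_encode(hb)
  expect_equal(ncol(pm$matrix), 1L)
  expect_equal(unname(pm$matrix[, 1]), unname(dosage(g)[, 3]))
  cg <- categorical_encode(hb)
  expect_equal(unname(cg$codes[, 1]), unname(dosage(g)[, 3]))
})

test_that("the allele catalog enumerates the distinct observed haplotypes", {
  # 4 individuals / 8 haplotypes over 3 SNPs drawn from {000, 010, 100};
  # all indicator frequencies stay at or below 0.5, so orientation is kept
  hs <- c("000", "010", "100", "000", "010", "100", "000", "100")
  tomat <- function(s) t(vapply(strsplit(s, ""), as.integer, integer(3)))
  H <- tomat(hs)
  g <- phased_genotypes(H[1:4, ], H[5:8, ], tibble::tibble(
    marker_id = paste0("m", 1:3), chrom = "1", pos = c(5L, 10L, 15L)
  ))
  hb <- build_haploblocks(g, sets = list(1:3))
  expect_equal(hb$Q, 1L)
  expect_equal(hb$blocks[[1]]$alleles, c("000", "010", "100"))
  # per-individual catalog indices recover the input haplotypes
  expect_equal(hb$blocks[[1]]$alleles[hb$blocks[[1]]$a1], hs[1:4])
  expect_equal(hb$blocks[[1]]$alleles[hb$blocks[[1]]$a2], hs[5:8])
})

test_that("the greedy scan closes a block exactly where the limit breaks", {
  # population crafted so the first 4 SNPs show <= 10 distinct haplotypes
  # but all 5 show 12: boundary must fall after SNP 4
  withr::with_seed(33, {
    repeat {
      H <- matrix(rbinom(16 * 5, 1, 0.5), 16, 5)
      n4 <- length(unique(apply(H[, 1:4], 1, paste, collapse = "")))
      n5 <- length(unique(apply(H, 1, paste, collapse = "")))
      if (n4 <= 10 && n5 == 12) break
    }
    g <- phased_genotypes(H[1:8, ], H[9:16, ], tibble::tibble(
      marker_id = paste0("m", 1:5), chrom = "1", pos = as.integer(1:5 * 10)
    ))
    hb <- build_haploblocks(g, sets = list(1:5))
    expect_equal(hb$block_table$n_snps[1], 4L)
    expect_equal(hb$blocks[[1]]$markers, 1:4)
    expect_equal(hb$blocks[[2]]$markers, 5L)
  })
})

test_that("emitted blocks are greedily maximal with 2..max_alleles alleles", {
  withr::with_seed(91, {
    for (rep in 1:8) {
      g <- rand_genotypes(20, 30)
      hb <- build_haploblocks(g, sets = list(1:30), max_alleles = 10)
      blocks <- hb$blocks
      for (b in seq_along(blocks)) {
        idx <- blocks[[b]]$markers
        if (blocks[[b]]$type == "multi") {
          k <- oracle_n_alleles(g, idx)
          expect_gte(k, 2)
          expect_lte(k, 10)
          expect_equal(length(blocks[[b]]$alleles), k)
        }
        # maximality: extending by the next in-set marker must overflow
        nxt <- idx[length(idx)] + 1L
        if (nxt <= 30) {
          expect_gt(oracle_n_alleles(g, c(idx, nxt)), 10)
        }
      }
      # concatenated blocks reproduce the SNP set without gap or overlap
      expect_equal(unlist(lapply(blocks, `[[`, "markers")), 1:30)
      expect_equal(hb$Q, length(blocks))
    }
  })
})

test_that("dosage encoding reproduces the two-SNP worked example", {
  fx <- table2_population()
  hb <- build_haploblocks(fx$genotypes, sets = list(1:2))
  expect_equal(hb$blocks[[1]]$alleles, c("00", "01", "10", "11"))
  pm <- dosage_encode(hb)
  expected <- rbind(
    c(2, 0, 0, 0), c(1, 1, 0, 0), c(1, 0, 1, 0), c(1, 0, 0, 1),
    c(0, 2, 0, 0), c(0, 1, 1, 0), c(0, 1, 0, 1),
    c(0, 0, 2, 0), c(0, 0, 1, 1), c(0, 0, 0, 2)
  )
  expect_equal(unname(pm$matrix), expected)
  expect_equal(unname(rowSums(pm$matrix)), rep(2, 10))
})

test_that("categorical codes identify unordered allele pairs", {
  fx <- table2_population()
  hb <- build_haploblocks(fx$genotypes, sets = list(1:2))
  cg <- categorical_encode(hb)
  expect_equal(length(unique(cg$codes[, 1])), 10L)  # all ten configurations

  # swapping the haplotypes of an individual leaves the code unchanged
  g_swapped <- phased_genotypes(fx$genotypes$hap2, fx$genotypes$hap1,
                                fx$genotypes$markers[, 1:3])
  cg2 <- categorical_encode(build_haploblocks(g_swapped, sets = list(1:2)))
  expect_equal(unname(cg$codes), unname(cg2$codes))
})

test_that("code equality matches brute-force string-pair comparison", {
  withr::with_seed(14, {
    for (rep in 1:5) {
      g <- rand_genotypes(10, 8)
      hb <- build_haploblocks(g, sets = list(1:8), max_alleles = 6)
      cg <- categorical_encode(hb)
      H <- rbind(g$hap1, g$hap2)
      for (b in seq_along(hb$blocks)) {
        idx <- hb$blocks[[b]]$markers
        s <- apply(H[, idx, drop = FALSE], 1, paste, collapse = "")
        pair <- vapply(1:10, function(i) {
          paste(sort(c(s[i], s[10 + i])), collapse = "|")
        }, character(1))
        same_code <- outer(unname(cg$codes[, b]), unname(cg$codes[, b]), "==")
        same_pair <- outer(pair, pair, "==")
        expect_identical(same_code, same_pair)
      }
    }
  })
})

test_that("dosage and categorical encodings are mutually consistent", {
  withr::with_seed(58, {
    g <- rand_genotypes(15, 12)
    hb <- build_haploblocks(g, sets = list(1:12), max_alleles = 8)
    pm <- dosage_encode(hb)
    cg <- categorical_encode(hb)
    for (b in seq_along(hb$blocks)) {
      off <- pm$offsets[pm$offsets$block_id == b, ]
      cols <- off$first_col:(off$first_col + off$n_cols - 1L)
      rows <- pm$matrix[, cols, drop = FALSE]
      same_dosage <- outer(seq_len(15), seq_len(15), Vectorize(function(i, j) {
        all(rows[i, ] == rows[j, ])
      }))
      expect_identical(outer(unname(cg$codes[, b]), unname(cg$codes[, b]), "=="),
                       same_dosage)
    }
    # per-block row sums are 2 for multi-SNP blocks
    for (b in which(hb$block_table$type == "multi")) {
      off <- pm$offsets[pm$offsets$block_id == b, ]
      cols <- off$first_col:(off$first_col + off$n_cols - 1L)
      expect_equal(unname(rowSums(pm$matrix[, cols, drop = FALSE])), rep(2, 15))
    }
  })
})

test_that("whole-genome mode scans each chromosome with the same rule", {
  g <- rand_genotypes(18, 20, n_chrom = 2, seed = 44)
  whole <- build_haploblocks(g)
  manual <- build_haploblocks(g, sets = split(seq_len(40), g$markers$chrom))
  expect_equal(whole$block_table, manual$block_table)
  # no block straddles a chromosome boundary
  expect_equal(
    g$markers$chrom[whole$block_table$first_marker],
    g$markers$chrom[whole$block_table$last_marker]
  )
})
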