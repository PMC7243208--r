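# Small fixture builders shared across test files.

# Two-SNP population carrying all ten genotype configurations of a
# four-allele haploblock. Haplotype alleles map to strings as
# AB = "00", Ab = "01", aB = "10", ab = "11", so the lexicographic catalog
# is exactly (AB, Ab, aB, ab).
table2_population <- function() {
  alleles <- list(AB = c(0L, 0L), Ab = c(0L, 1L), aB = c(1L, 0L), ab = c(1L, 1L))
  pairs <- t(combn(4L, 2L))
  pairs <- rbind(cbind(1:4, 1:4), pairs)   # 4 homozygotes + 6 heterozygotes
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), ]
  h1 <- t(vapply(pairs[, 1L], function(a) alleles[[a]], integer(2)))
  h2 <- t(vapply(pairs[, 2L], function(a) alleles[[a]], integer(2)))
  g <- phased_genotypes(
    h1, h2,
    tibble::tibble(marker_id = c("s1", "s2"), chrom = "chr1", pos = c(100L, 200L))
  )
  list(genotypes = g, pairs = pairs, allele_names = names(alleles))
}

# write a phased genotypes object to VCF text and return the path
tmp_vcf <- function(g, ...) {
  path <- withr::local_tempfile(fileext = ".vcf", .local_envir = parent.frame())
  write_phased_vcf(g, path, ...)
  path
}

small_sim <- function(n = 80, m = 120, seed = 42, ...) {
  cfg <- sim_config(n_individuals = n, n_chromosomes = 2,
                    markers_per_chrom = m %/% 2, chrom_length = 5e5,
                    n_genes = 12, n_qtl = min(20L, m %/% 6), seed = seed, ...)
  simulate_dataset(cfg)
}

# minimal kernel wrapper for hand-built matrices
new_kernel_for_test <- function(K, ids, model = "G") {
  dimnames(K) <- list(ids, ids)
  structure(list(K = K, model = model, denominator = NA_real_,
                 class_tag = "all", ids = ids),
            class = "gp_kernel")
}
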