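# Independent brute-force implementations used as oracles. These are written
# as plain nested loops over individuals and loci so they share no code path
# with the package's vectorised kernels.

oracle_grm_vanraden <- function(D) {
  n <- nrow(D); m <- ncol(D)
  p <- colSums(D) / (2 * n)
  denom <- 2 * sum(p * (1 - p))
  K <- matrix(0, n, n)
  for (j in seq_len(n)) for (i in seq_len(n)) {
    s <- 0
    for (k in seq_len(m)) s <- s + (D[j, k] - 2 * p[k]) * (D[i, k] - 2 * p[k])
    K[j, i] <- s / denom
  }
  K
}

oracle_cross_product <- function(M, q) {
  n <- nrow(M)
  K <- matrix(0, n, n)
  for (j in seq_len(n)) for (i in seq_len(n)) {
    K[j, i] <- sum(M[j, ] * M[i, ]) / q
  }
  K
}

oracle_ibs <- function(codes, count) {
  n <- nrow(codes)
  K <- matrix(0, n, n)
  for (j in seq_len(n)) for (i in seq_len(n)) {
    s <- 0L
    for (k in seq_len(ncol(codes))) s <- s + (codes[j, k] == codes[i, k])
    K[j, i] <- s / count
  }
  K
}

# proportion of unordered locus pairs (self-pairs included) whose joint state
# is identical between two individuals, scaled by count^2
oracle_epistasis <- function(codes, count) {
  n <- nrow(codes)
  m <- ncol(codes)
  K <- matrix(0, n, n)
  for (j in seq_len(n)) for (i in seq_len(n)) {
    s <- 0L
    for (k1 in seq_len(m)) for (k2 in k1:m) {
      if (codes[j, k1] == codes[i, k1] && codes[j, k2] == codes[i, k2]) {
        s <- s + 1L
      }
    }
    K[j, i] <- s / count^2
  }
  K
}

# distinct haplotype strings observed over a marker index set
oracle_n_alleles <- function(g, idx) {
  H <- rbind(g$hap1, g$hap2)
  length(unique(apply(H[, idx, drop = FALSE], 1L, paste, collapse = "")))
}

# random complete phased genotypes on one or more chromosomes
rand_genotypes <- function(n, m, n_chrom = 1, seed = NULL) {
  draw <- function() {
    pos <- sort(sample.int(m * 1000L, m))
    freq <- runif(m, 0.1, 0.5)
    h <- function() matrix(rbinom(n * m, 1L, rep(freq, each = n)), nrow = n)
    list(h1 = h(), h2 = h(), pos = pos)
  }
  go <- function() {
    parts <- lapply(seq_len(n_chrom), function(cc) draw())
    mk <- dplyr::bind_rows(lapply(seq_len(n_chrom), function(cc) {
      tibble::tibble(marker_id = paste0("c", cc, "_", parts[[cc]]$pos),
                     chrom = paste0("c", cc), pos = parts[[cc]]$pos)
    }))
    phased_genotypes(do.call(cbind, lapply(parts, `[[`, "h1")),
                     do.call(cbind, lapply(parts, `[[`, "h2")),
                     mk)
  }
  if (is.null(seed)) go() else withr::with_seed(seed, go())
}
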