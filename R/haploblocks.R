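#' Build haploblocks under the maximum-allele-count rule
#'
#' Within each SNP set (or each chromosome when `sets = NULL`), markers are
#' scanned left to right in physical order. The current block is extended by
#' the next marker unless the number of distinct haplotype strings observed
#' in the population (over all 2n haplotypes) would exceed `max_alleles`; in
#' that case the block is closed and a new one starts at that marker. A SNP
#' set with a single marker, or a trailing singleton, is retained as a
#' single-SNP column keeping its 0/1/2 genotype.
#'
#' @param g A [phased_genotypes] object with no missing cells.
#' @param sets `NULL` (whole-genome mode: one SNP set per chromosome), a
#'   `snp_partition` from [assign_snps()], or a list of marker index vectors.
#' @param max_alleles Maximum number of distinct haplotype alleles per block
#'   (default 10).
#' @return An object of class `haploblock_set`: list with `blocks` (each a
#'   list with `markers`, `type` = "multi"/"single", and for multi-SNP blocks
#'   the lexicographically ordered `alleles` catalog plus per-individual
#'   catalog indices `a1`, `a2`; for single-SNP columns the 0/1/2 `geno`),
#'   `Q` (total number of blocks including single-SNP columns), `n`
#'   individuals, `ids`, and a `block_table` tibble.
#' @export
build_haploblocks <- function(g, sets = NULL, max_alleles = 10) {
  stopifnot(inherits(g, "phased_genotypes"))
  if (anyNA(g$hap1)) {
    stop("haploblock construction requires complete phased genotypes",
         call. = FALSE)
  }
  stopifnot(max_alleles >= 2)
  if (is.null(sets)) {
    sets <- split(seq_len(nrow(g$markers)), g$markers$chrom)
    sets <- sets[unique(g$markers$chrom)]  # genomic order
  } else if (inherits(sets, "snp_partition")) {
    sets <- sets$sets
  }
  n <- length(g$ids)
  # haplotypes as rows: 2n x m (individual i occupies rows i and n + i)
  H <- rbind(g$hap1, g$hap2)
  blocks <- list()
  for (s in seq_along(sets)) {
    idx <- sets[[s]]
    if (length(idx) == 0L) next
    start <- 1L
    grp <- rep(1L, 2L * n)       # distinct-prefix group ids within block
    n_grp <- 1L
    j <- 1L
    while (j <= length(idx)) {
      col <- H[, idx[j]]
      key <- grp * 2L + col
      new_grp <- match(key, unique(key))
      k <- max(new_grp)
      if (j > start && k > max_alleles) {
        blocks[[length(blocks) + 1L]] <-
          close_block(H, idx[start:(j - 1L)], n)
        start <- j
        grp <- rep(1L, 2L * n)
        n_grp <- 1L
        # do not advance j: re-scan this marker as the head of a new block
      } else {
        grp <- new_grp
        n_grp <- k
        j <- j + 1L
      }
    }
    blocks[[length(blocks) + 1L]] <- close_block(H, idx[start:length(idx)], n)
  }
  block_table <- tibble::tibble(
    block_id = seq_along(blocks),
    chrom = vapply(blocks, function(b) g$markers$chrom[b$markers[1]], character(1)),
    first_marker = vapply(blocks, function(b) b$markers[1], integer(1)),
    last_marker = vapply(blocks, function(b) b$markers[length(b$markers)], integer(1)),
    n_snps = vapply(blocks, function(b) length(b$markers), integer(1)),
    n_alleles = vapply(blocks, function(b) {
      if (b$type == "multi") length(b$alleles) else NA_integer_
    }, integer(1)),
    type = vapply(blocks, function(b) b$type, character(1))
  )
  structure(
    list(blocks = blocks, Q = length(blocks), n = n, ids = g$ids,
         block_table = block_table),
    class = "haploblock_set"
  )
}

close_block <- function(H, idx, n) {
  if (length(idx) == 1L) {
    geno <- H[seq_len(n), idx] + H[n + seq_len(n), idx]
    return(list(type = "single", markers = idx, geno = as.integer(geno)))
  }
  strings <- apply(H[, idx, drop = FALSE], 1L, paste, collapse = "")
  catalog <- sort(unique(strings))   # lexicographic over 0/1 strings
  a <- match(strings, catalog)
  list(type = "multi", markers = idx, alleles = catalog,
       a1 = a[seq_len(n)], a2 = a[n + seq_len(n)])
}

#' @export
print.haploblock_set <- function(x, ...) {
  nm <- sum(x$block_table$type == "multi")
  cat("<haploblock_set> Q = ", x$Q, " blocks (", nm, " multi-SNP, ",
      x$Q - nm, " single-SNP) over ", x$n, " individuals\n", sep = "")
  invisible(x)
}

#' Numerical dosage encoding of haploblocks
#'
#' Each multi-SNP block contributes one pseudo-marker column per catalog
#' allele, holding the number of copies (0/1/2) of that allele the
#' individual carries; an individual's entries over a block therefore sum
#' to 2. Single-SNP columns pass through the original 0/1/2 genotype.
#'
#' @param h A `haploblock_set` from [build_haploblocks()].
#' @return An object of class `pseudo_markers`: list with `matrix`
#'   (individuals x pseudo-markers), `offsets` (per-block column ranges as a
#'   tibble), and `Q` (block count, the kernel denominator).
#' @export
dosage_encode <- function(h) {
  stopifnot(inherits(h, "haploblock_set"))
  cols <- list()
  off <- integer(length(h$blocks))
  width <- integer(length(h$blocks))
  p <- 0L
  for (b in seq_along(h$blocks)) {
    blk <- h$blocks[[b]]
    if (blk$type == "single") {
      m <- matrix(blk$geno, ncol = 1L,
                  dimnames = list(NULL, paste0("b", b, "_snp")))
    } else {
      k <- length(blk$alleles)
      m <- matrix(0L, nrow = h$n, ncol = k,
                  dimnames = list(NULL, paste0("b", b, "_", blk$alleles)))
      m[cbind(seq_len(h$n), blk$a1)] <- m[cbind(seq_len(h$n), blk$a1)] + 1L
      m[cbind(seq_len(h$n), blk$a2)] <- m[cbind(seq_len(h$n), blk$a2)] + 1L
    }
    cols[[b]] <- m
    off[b] <- p + 1L
    width[b] <- ncol(m)
    p <- p + ncol(m)
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- h$ids
  structure(
    list(matrix = mat,
         offsets = tibble::tibble(block_id = seq_along(h$blocks),
                                  first_col = off,
                                  n_cols = width),
         Q = h$Q, ids = h$ids),
    class = "pseudo_markers"
  )
}

#' Categorical encoding of haploblocks
#'
#' Per block, every unordered pair of catalog alleles (a genotype
#' configuration) maps to a stable integer code; two individuals share a
#' code at a block iff they carry the same unordered allele pair. Single-SNP
#' columns use the 0/1/2 genotype as the code.
#'
#' @param h A `haploblock_set` from [build_haploblocks()].
#' @return An object of class `categorical_genotypes`: list with `codes`
#'   (integer matrix, individuals x blocks) and `Q`.
#' @export
categorical_encode <- function(h) {
  stopifnot(inherits(h, "haploblock_set"))
  codes <- matrix(0L, nrow = h$n, ncol = h$Q)
  for (b in seq_along(h$blocks)) {
    blk <- h$blocks[[b]]
    if (blk$type == "single") {
      codes[, b] <- blk$geno
    } else {
      k <- length(blk$alleles)
      lo <- pmin(blk$a1, blk$a2)
      hi <- pmax(blk$a1, blk$a2)
      codes[, b] <- (lo - 1L) * k + hi   # stable over unordered pairs
    }
  }
  rownames(codes) <- h$ids
  structure(list(codes = codes, Q = h$Q, ids = h$ids),
            class = "categorical_genotypes")
}
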