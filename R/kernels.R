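new_kernel <- function(K, model, denominator, class_tag = "all", ids = NULL) {
  K <- (K + t(K)) / 2           # enforce exact symmetry against FP noise
  if (!is.null(ids)) dimnames(K) <- list(ids, ids)
  structure(
    list(K = K, model = model, denominator = denominator,
         class_tag = class_tag, ids = ids %||% rownames(K)),
    class = "gp_kernel"
  )
}

#' @export
print.gp_kernel <- function(x, ...) {
  cat("<gp_kernel> model ", x$model,
      if (!identical(x$class_tag, "all")) paste0(" | ", x$class_tag),
      ": ", nrow(x$K), " x ", ncol(x$K),
      ", denominator = ", format(x$denominator), "\n", sep = "")
  invisible(x)
}

#' VanRaden genomic relationship matrix
#'
#' `G = (M - P)(M - P)' / (2 * sum(p_i (1 - p_i)))`, where `M` is the 0/1/2
#' minor-allele dosage matrix, `p_i` the minor-allele frequency of marker
#' `i` computed from the sample, and the columns of `P` equal `2 p_i`.
#'
#' @param g A [phased_genotypes] object (complete, QC-passed).
#' @return A `gp_kernel` with model tag `"G"`.
#' @export
grm_vanraden <- function(g) {
  stopifnot(inherits(g, "phased_genotypes"))
  M <- dosage(g)
  if (anyNA(M)) stop("genotypes must be complete", call. = FALSE)
  p <- colMeans(M) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) {
    stop("all markers are monomorphic: zero denominator", call. = FALSE)
  }
  Z <- sweep(M, 2L, 2 * p)
  new_kernel(tcrossprod(Z) / denom, "G", denom, "all", g$ids)
}

#' Haplotype-dosage genomic relationship matrix
#'
#' `G_H = M_H M_H' / Q`, the uncentered cross-product of the pseudo-marker
#' dosage matrix scaled by the number of haploblocks: `Q_H` for a
#' whole-genome block set (model `G_H`), `Q_H^GA` for a class-restricted
#' one (model `G_H|GA`).
#'
#' @param mh A `pseudo_markers` object from [dosage_encode()].
#' @param class_tag Genomic class label, `"all"` for whole-genome blocks.
#' @return A `gp_kernel` with model tag `"GH"` (or `"GH_GA"` when a class
#'   is given).
#' @export
grm_haplotype <- function(mh, class_tag = "all") {
  stopifnot(inherits(mh, "pseudo_markers"), mh$Q >= 1)
  model <- if (identical(class_tag, "all")) "GH" else "GH_GA"
  new_kernel(tcrossprod(mh$matrix) / mh$Q, model, mh$Q, class_tag, mh$ids)
}

#' Identity-by-state (categorical) relatedness matrix
#'
#' Entry (j, i) is the proportion of loci at which individuals j and i carry
#' an identical state: SNP genotypes over `m` markers for the SNP-level
#' matrix `S`, haploblock genotype configurations over `Q` blocks for the
#' haplotype versions `S_H` (whole genome) and the class-restricted variant.
#'
#' @param states A [phased_genotypes] object (states are the 0/1/2
#'   genotypes) or a `categorical_genotypes` object from
#'   [categorical_encode()].
#' @param class_tag Genomic class label, `"all"` for whole-genome input.
#' @return A `gp_kernel` with model tag `"S"`, `"SH"` or `"S_GA"`; entries
#'   lie in `[0, 1]` with unit diagonal.
#' @export
ibs_categorical <- function(states, class_tag = "all") {
  if (inherits(states, "phased_genotypes")) {
    codes <- dosage(states)
    if (anyNA(codes)) stop("genotypes must be complete", call. = FALSE)
    count <- ncol(codes)
    model <- "S"
    ids <- states$ids
  } else if (inherits(states, "categorical_genotypes")) {
    codes <- states$codes
    count <- states$Q
    model <- if (identical(class_tag, "all")) "SH" else "S_GA"
    ids <- states$ids
  } else {
    stop("`states` must be phased_genotypes or categorical_genotypes",
         call. = FALSE)
  }
  n <- nrow(codes)
  # one-hot expansion per locus, then a single cross-product
  nlev <- integer(ncol(codes))
  jj <- vector("list", ncol(codes))
  for (q in seq_len(ncol(codes))) {
    f <- match(codes[, q], unique(codes[, q]))
    nlev[q] <- max(f)
    jj[[q]] <- f
  }
  offs <- cumsum(c(0L, nlev[-length(nlev)]))
  Z <- matrix(0L, nrow = n, ncol = sum(nlev))
  for (q in seq_len(ncol(codes))) {
    Z[cbind(seq_len(n), offs[q] + jj[[q]])] <- 1L
  }
  new_kernel(tcrossprod(Z) / count, model, count, class_tag, ids)
}

#' Categorical first-order epistasis kernel
#'
#' Lifts an identity-by-state matrix to locus pairs:
#' `E = 0.5 * (cS) # (cS + 1) / c^2`, `#` the Hadamard product and `c` the
#' number of loci (markers `m` or haploblocks `Q`). Entry (j, i) equals the
#' proportion, among all unordered locus pairs including self-pairs, whose
#' joint state is identical in the two individuals. The diagonal is exactly
#' `(c + 1) / (2c)`.
#'
#' @param s A `gp_kernel` of the S family ([ibs_categorical()]).
#' @param count The locus count; defaults to (and must match) the
#'   denominator stored in `s`.
#' @return A `gp_kernel` with model tag `"E"`, `"EH"` or `"E_GA"`.
#' @export
epistasis_categorical <- function(s, count = s$denominator) {
  stopifnot(inherits(s, "gp_kernel"))
  if (!s$model %in% c("S", "SH", "S_GA")) {
    stop("`s` must be an S-family kernel", call. = FALSE)
  }
  if (!isTRUE(all.equal(count, s$denominator))) {
    stop("`count` (", count, ") does not match the kernel denominator (",
         s$denominator, ")", call. = FALSE)
  }
  cs <- count * s$K
  E <- 0.5 * cs * (cs + 1) / count^2
  model <- c(S = "E", SH = "EH", S_GA = "E_GA")[[s$model]]
  new_kernel(E, model, count, s$class_tag, s$ids)
}

#' Export a kernel as tab-separated text
#'
#' Writes the full symmetric matrix with a header row and first column of
#' individual ids.
#'
#' @param k A `gp_kernel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kernel_tsv <- function(k, path) {
  stopifnot(inherits(k, "gp_kernel"))
  df <- data.frame(id = k$ids, k$K, check.names = FALSE)
  colnames(df) <- c("id", k$ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a kernel written by [write_kernel_tsv()]
#'
#' @param path Input path.
#' @param model,denominator,class_tag Metadata to attach (the text format
#'   stores only the matrix).
#' @return A `gp_kernel`.
#' @export
read_kernel_tsv <- function(path, model = "G", denominator = NA_real_,
                            class_tag = "all") {
  df <- utils::read.delim(path, check.names = FALSE)
  ids <- as.character(df[[1]])
  K <- as.matrix(df[, -1, drop = FALSE])
  dimnames(K) <- list(ids, ids)
  new_kernel(K, model, denominator, class_tag, ids)
}

#' Export a kernel in GCTA binary GRM format
#'
#' Writes the `.grm.bin` (lower triangle, single-precision), `.grm.N.bin`
#' (marker count per pair) and `.grm.id` files used by GCTA.
#'
#' @param k A `gp_kernel`.
#' @param prefix Output path prefix.
#' @param n_markers Marker count recorded per pair (defaults to the kernel
#'   denominator rounded to an integer, or 1 if unknown).
#' @return `prefix`, invisibly.
#' @export
write_grm_gcta <- function(k, prefix, n_markers = NULL) {
  stopifnot(inherits(k, "gp_kernel"))
  n <- nrow(k$K)
  if (is.null(n_markers)) {
    n_markers <- if (is.finite(k$denominator)) max(1L, round(k$denominator)) else 1L
  }
  lower <- k$K[upper.tri(k$K, diag = TRUE)]  # column-major upper == row-major lower
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lower), con, size = 4L)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(n_markers), length(lower)), con, size = 4L)
  close(con)
  utils::write.table(data.frame(fid = k$ids, iid = k$ids),
                     paste0(prefix, ".grm.id"),
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a GCTA binary GRM
#'
#' @param prefix Path prefix of the `.grm.bin` / `.grm.id` pair.
#' @param model,class_tag Metadata to attach.
#' @return A `gp_kernel` (denominator taken from `.grm.N.bin` if present).
#' @export
read_grm_gcta <- function(prefix, model = "G", class_tag = "all") {
  ids <- utils::read.table(paste0(prefix, ".grm.id"))[[2]]
  n <- length(ids)
  m <- n * (n + 1) / 2
  con <- file(paste0(prefix, ".grm.bin"), "rb")
  v <- readBin(con, "numeric", n = m, size = 4L)
  close(con)
  K <- matrix(0, n, n)
  K[upper.tri(K, diag = TRUE)] <- v
  K <- K + t(K) - diag(diag(K))
  denom <- NA_real_
  nbin <- paste0(prefix, ".grm.N.bin")
  if (file.exists(nbin)) {
    con <- file(nbin, "rb")
    denom <- readBin(con, "numeric", n = 1L, size = 4L)
    close(con)
  }
  new_kernel(K, model, denom, class_tag, as.character(ids))
}
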