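#' Phased genotype container
#'
#' Stores per-individual, per-marker pairs of minor-allele indicators for
#' phased biallelic genotypes, together with marker metadata. The dosage view
#' (0/1/2 copies of the minor allele) is always the sum of the two haplotype
#' indicators.
#'
#' @param hap1,hap2 Integer matrices (individuals x markers) of 0/1 allele
#'   indicators for the two haplotypes. `NA` marks a missing genotype and must
#'   occur in both matrices at the same cell.
#' @param markers A data frame with one row per marker and columns
#'   `marker_id`, `chrom`, `pos` (1-based bp), and optionally `ref`, `alt`,
#'   `minor_is_alt`. Positions must be strictly increasing within a
#'   chromosome. The minor-allele frequency is recomputed from the matrices.
#' @param ids Character vector of individual identifiers (row order).
#'
#' @return An object of class `phased_genotypes`: a list with elements
#'   `hap1`, `hap2`, `markers` (tibble, including a `maf` column computed from
#'   the data) and `ids`.
#' @export
phased_genotypes <- function(hap1, hap2, markers, ids = NULL) {
  hap1 <- as.matrix(hap1)
  hap2 <- as.matrix(hap2)
  storage.mode(hap1) <- "integer"
  storage.mode(hap2) <- "integer"
  if (!identical(dim(hap1), dim(hap2))) {
    stop("`hap1` and `hap2` must have identical dimensions", call. = FALSE)
  }
  if (!identical(is.na(hap1), is.na(hap2))) {
    stop("missing cells must be missing on both haplotypes", call. = FALSE)
  }
  ok <- is.na(hap1) | hap1 %in% c(0L, 1L)
  ok2 <- is.na(hap2) | hap2 %in% c(0L, 1L)
  if (!all(ok) || !all(ok2)) {
    stop("haplotype indicators must be 0, 1 or NA", call. = FALSE)
  }
  markers <- tibble::as_tibble(markers)
  stopifnot(all(c("marker_id", "chrom", "pos") %in% names(markers)))
  if (nrow(markers) != ncol(hap1)) {
    stop("`markers` must have one row per genotype column", call. = FALSE)
  }
  bad <- markers |>
    dplyr::mutate(.i = dplyr::row_number()) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::filter(dplyr::row_number() > 1L & diff(c(-Inf, .data$pos)) <= 0) |>
    dplyr::ungroup()
  if (nrow(bad) > 0) {
    stop("marker positions must be strictly increasing within a chromosome ",
         "(first offender: ", bad$marker_id[1], ")", call. = FALSE)
  }
  if (is.null(ids)) ids <- paste0("ind_", seq_len(nrow(hap1)))
  if (length(ids) != nrow(hap1)) {
    stop("`ids` length must equal the number of individuals", call. = FALSE)
  }
  if (!("ref" %in% names(markers))) markers$ref <- "A"
  if (!("alt" %in% names(markers))) markers$alt <- "C"
  if (!("minor_is_alt" %in% names(markers))) markers$minor_is_alt <- TRUE
  # enforce the minor-allele orientation invariant: flip any column whose
  # indicator frequency exceeds 0.5 (ties keep the given orientation)
  f <- colMeans(hap1 + hap2, na.rm = TRUE) / 2
  flip <- which(!is.nan(f) & f > 0.5)
  if (length(flip) > 0) {
    hap1[, flip] <- 1L - hap1[, flip]
    hap2[, flip] <- 1L - hap2[, flip]
    markers$minor_is_alt[flip] <- !markers$minor_is_alt[flip]
  }
  rownames(hap1) <- rownames(hap2) <- ids
  colnames(hap1) <- colnames(hap2) <- markers$marker_id
  g <- structure(
    list(hap1 = hap1, hap2 = hap2, markers = markers, ids = ids),
    class = "phased_genotypes"
  )
  g$markers$maf <- marker_maf(g)
  g
}

#' Minor-allele dosage view
#'
#' @param g A [phased_genotypes] object.
#' @return Integer matrix (individuals x markers) with entries 0/1/2, the
#'   number of copies of the minor allele; `NA` where the genotype is missing.
#' @export
dosage <- function(g) {
  stopifnot(inherits(g, "phased_genotypes"))
  g$hap1 + g$hap2
}

marker_maf <- function(g) {
  d <- g$hap1 + g$hap2
  f <- unname(colMeans(d, na.rm = TRUE)) / 2
  f[is.nan(f)] <- NA_real_
  pmin(f, 1 - f)
}

#' @export
print.phased_genotypes <- function(x, ...) {
  cat("<phased_genotypes> ", length(x$ids), " individuals x ",
      nrow(x$markers), " markers on ",
      length(unique(x$markers$chrom)), " chromosome(s)\n", sep = "")
  n_na <- sum(is.na(x$hap1))
  if (n_na > 0) cat("  missing genotype cells: ", n_na, "\n", sep = "")
  invisible(x)
}

#' Subset a phased genotype object
#'
#' @param g A [phased_genotypes] object.
#' @param individuals,markers Integer or logical index vectors (default: keep
#'   all). Marker metadata and minor-allele frequencies are updated.
#' @return A [phased_genotypes] object.
#' @export
subset_genotypes <- function(g, individuals = NULL, markers = NULL) {
  stopifnot(inherits(g, "phased_genotypes"))
  i <- if (is.null(individuals)) seq_along(g$ids) else individuals
  j <- if (is.null(markers)) seq_len(nrow(g$markers)) else markers
  phased_genotypes(
    g$hap1[i, j, drop = FALSE], g$hap2[i, j, drop = FALSE],
    g$markers[j, setdiff(names(g$markers), "maf")],
    ids = g$ids[i]
  )
}
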