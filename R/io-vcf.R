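#' Read phased genotypes from a VCF file
#'
#' Reads a VCF with phased `GT` fields and orients every marker to its minor
#' allele: the returned indicators count copies of whichever allele is rarer
#' in the sample (ties go to the ALT allele). Only biallelic records with
#' complete, phased genotypes are accepted; imputation and phasing are out of
#' scope, so violations are errors, not warnings.
#'
#' @param path Path to a VCF (v4.x) file, plain text or bgzipped.
#' @return A [phased_genotypes] object.
#' @export
read_phased_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  rec <- paste0(fix$CHROM, ":", fix$POS)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    stop("multiallelic record at ", rec[which(multi)[1]],
         "; only biallelic markers are supported", call. = FALSE)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  miss <- is.na(gt) | gt == "." | gt == ".|." | gt == "./."
  if (any(miss)) {
    idx <- which(miss, arr.ind = TRUE)[1, ]
    stop("missing genotype at ", rec[idx[1]], " for sample ",
         colnames(gt)[idx[2]], "; input must be complete (no imputation)",
         call. = FALSE)
  }
  unphased <- matrix(grepl("/", gt, fixed = TRUE), nrow = nrow(gt))
  if (any(unphased)) {
    idx <- which(unphased, arr.ind = TRUE)[1, ]
    stop("unphased genotype at ", rec[idx[1]], " for sample ",
         colnames(gt)[idx[2]], "; all GT fields must use '|'", call. = FALSE)
  }
  a1 <- matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(gt))
  a2 <- matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt))
  alt_freq <- rowMeans(a1 + a2) / 2
  minor_is_alt <- alt_freq <= 0.5
  # orient indicators to the minor allele; markers are rows here
  h1 <- matrix(ifelse(rep(minor_is_alt, ncol(a1)), a1, 1L - a1), nrow = nrow(a1))
  h2 <- matrix(ifelse(rep(minor_is_alt, ncol(a2)), a2, 1L - a2), nrow = nrow(a2))
  ids <- colnames(gt)
  mid <- fix$ID
  if (is.null(mid) || all(is.na(mid)) || any(mid == "." | is.na(mid))) {
    mid <- paste0(fix$CHROM, "_", fix$POS)
  }
  markers <- tibble::tibble(
    marker_id = mid,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    minor_is_alt = minor_is_alt
  )
  phased_genotypes(t(h1), t(h2), markers, ids = ids)
}

#' Write phased genotypes to a VCF file
#'
#' Emits a minimal VCFv4.2 with phased `GT` fields. Alleles are written in
#' REF/ALT orientation (indicators are flipped back where the minor allele is
#' the reference), so a write-then-read round trip reproduces the dosage
#' matrix exactly.
#'
#' @param g A [phased_genotypes] object.
#' @param path Output file path.
#' @param chrom_lengths Optional named vector of chromosome lengths for
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(g, path, chrom_lengths = NULL) {
  stopifnot(inherits(g, "phased_genotypes"))
  if (anyNA(g$hap1)) {
    stop("cannot write genotypes containing missing cells", call. = FALSE)
  }
  mk <- g$markers
  flip <- !mk$minor_is_alt
  # back to ALT-allele orientation, markers in columns
  a1 <- sweep(g$hap1, 2L, as.integer(flip), function(x, f) ifelse(f == 1L, 1L - x, x))
  a2 <- sweep(g$hap2, 2L, as.integer(flip), function(x, f) ifelse(f == 1L, 1L - x, x))
  gt <- matrix(paste0(t(a1), "|", t(a2)), nrow = nrow(mk))
  header <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(chrom_lengths)) {
      paste0("##contig=<ID=", names(chrom_lengths), ",length=",
             as.integer(chrom_lengths), ">")
    },
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$ids), collapse = "\t")
  )
  body <- paste(mk$chrom, mk$pos, mk$marker_id, mk$ref, mk$alt, ".", "PASS",
                ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a phenotype table
#'
#' @param path Tab-separated file with header; expected columns `id`, a trait
#'   column, `sex`, `year`, `entry_weight`, `fattening_days`.
#' @return A tibble with `sex` and `year` as factors.
#' @export
read_phenotypes <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  p <- tibble::as_tibble(p)
  for (col in intersect(c("sex", "year"), names(p))) {
    p[[col]] <- factor(p[[col]])
  }
  p
}

#' Write a phenotype table
#'
#' @param pheno A data frame of phenotypes.
#' @param path Output path (tab-separated, header, no quotes).
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
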