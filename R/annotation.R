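GENOMIC_CLASSES <- c("IGR", "gene", "exon", "CDS", "UTR")

features_to_granges <- function(features, chrom_lengths = NULL) {
  sl <- NULL
  if (!is.null(chrom_lengths)) sl <- chrom_lengths
  GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    feature_id = features$feature_id,
    seqlengths = sl
  )
}

#' Read genome features from a GFF3 file
#'
#' Keeps `gene`, `exon`, `CDS` and UTR records; `three_prime_UTR` and
#' `five_prime_UTR` types are merged into a single `UTR` class. Coordinates
#' are 1-based inclusive and strand is ignored.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `feature_id`, `class`, `chrom`, `start`,
#'   `end`.
#' @export
read_gff3 <- function(path) {
  # cheap validation pass so coordinate errors carry a line number
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  for (i in which(body)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) >= 5) {
      s <- suppressWarnings(as.numeric(f[4]))
      e <- suppressWarnings(as.numeric(f[5]))
      if (!is.na(s) && !is.na(e) && s > e) {
        stop("malformed feature at line ", i, ": start (", f[4],
             ") exceeds end (", f[5], ")", call. = FALSE)
      }
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in%
    c("gene", "exon", "CDS", "three_prime_UTR", "five_prime_UTR", "UTR")
  gr <- gr[keep]
  cls <- as.character(gr$type)
  cls[cls %in% c("three_prime_UTR", "five_prime_UTR")] <- "UTR"
  fid <- gr$ID
  if (is.null(fid)) fid <- rep(NA_character_, length(gr))
  fid <- ifelse(is.na(fid) | fid == "",
                paste0(cls, ":", as.character(GenomicRanges::seqnames(gr)),
                       ":", GenomicRanges::start(gr), "-",
                       GenomicRanges::end(gr)),
                fid)
  tibble::tibble(
    feature_id = fid,
    class = cls,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  )
}

#' Derive intergenic regions from gene features
#'
#' Genes are merged into union intervals per chromosome; the intergenic
#' regions (IGR) are the complement within `[1, chrom_length]`: the interval
#' before the first merged gene, the gaps between adjacent merged genes, and
#' the interval after the last one. Empty gaps (adjacent or overlapping
#' genes) are dropped.
#'
#' @param genes A features tibble (only rows with `class == "gene"` are
#'   used; a tibble of genes alone also works).
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @return A features tibble of `IGR` intervals.
#' @export
derive_igr <- function(genes, chrom_lengths) {
  genes <- tibble::as_tibble(genes)
  if ("class" %in% names(genes)) genes <- genes[genes$class == "gene", ]
  stopifnot(!is.null(names(chrom_lengths)))
  bad <- genes$end > chrom_lengths[genes$chrom]
  if (any(bad, na.rm = TRUE)) {
    stop("gene ", genes$feature_id[which(bad)[1]],
         " extends beyond its chromosome length", call. = FALSE)
  }
  gr <- GenomicRanges::reduce(features_to_granges(genes, chrom_lengths))
  whole <- GenomicRanges::GRanges(
    seqnames = names(chrom_lengths),
    ranges = IRanges::IRanges(1L, as.integer(chrom_lengths)),
    seqlengths = chrom_lengths
  )
  igr <- GenomicRanges::setdiff(whole, gr)
  igr <- sort(igr)
  tibble::tibble(
    feature_id = paste0("igr:", as.character(GenomicRanges::seqnames(igr)),
                        ":", GenomicRanges::start(igr), "-",
                        GenomicRanges::end(igr)),
    class = "IGR",
    chrom = as.character(GenomicRanges::seqnames(igr)),
    start = GenomicRanges::start(igr),
    end = GenomicRanges::end(igr)
  )
}

#' Assign markers to per-feature SNP sets of each genomic class
#'
#' A marker joins the SNP set of every feature whose interval contains its
#' position (boundaries inclusive). Overlapping features of the same class
#' are first merged into union intervals so a marker occurs in at most one
#' SNP set per class; `merge_overlaps = FALSE` preserves per-feature
#' duplication instead.
#'
#' @param markers A marker tibble (`marker_id`, `chrom`, `pos`) or a
#'   [phased_genotypes] object.
#' @param features A features tibble as from [read_gff3()] /
#'   [derive_igr()]; may mix classes.
#' @param merge_overlaps Merge overlapping same-class features before
#'   assignment (default `TRUE`).
#' @return A named list with one `snp_partition` per class present in
#'   `features`. Each partition is a list with elements `class`, `sets`
#'   (named list of strictly increasing marker index vectors, empty sets
#'   dropped), `n_snps` (distinct markers in the class) and
#'   `n_represented_features`.
#' @export
assign_snps <- function(markers, features, merge_overlaps = TRUE) {
  if (inherits(markers, "phased_genotypes")) markers <- markers$markers
  markers <- tibble::as_tibble(markers)
  features <- tibble::as_tibble(features)
  mpos <- GenomicRanges::GRanges(
    seqnames = markers$chrom,
    ranges = IRanges::IRanges(markers$pos, width = 1L)
  )
  out <- list()
  for (cls in intersect(GENOMIC_CLASSES, unique(features$class))) {
    fc <- features[features$class == cls, ]
    fgr <- features_to_granges(fc)
    if (merge_overlaps) {
      red <- GenomicRanges::reduce(fgr, with.revmap = TRUE)
      ids <- vapply(red$revmap, function(ii) {
        if (length(ii) == 1L) fc$feature_id[ii]
        else paste(fc$feature_id[ii], collapse = "+")
      }, character(1))
      fgr <- red
      fgr$feature_id <- ids
    }
    hits <- GenomicRanges::findOverlaps(mpos, fgr)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    sets <- split(qh, fgr$feature_id[sh])
    sets <- lapply(sets, function(ii) sort(unique(ii)))
    # keep genomic (feature) order for determinism
    ord <- order(vapply(sets, min, numeric(1)))
    sets <- sets[ord]
    out[[cls]] <- structure(
      list(class = cls,
           sets = sets,
           n_snps = length(unique(qh)),
           n_represented_features = length(sets)),
      class = "snp_partition"
    )
  }
  out
}

#' @export
print.snp_partition <- function(x, ...) {
  cat("<snp_partition> class ", x$class, ": ", x$n_snps, " SNPs in ",
      x$n_represented_features, " represented feature(s)\n", sep = "")
  invisible(x)
}

#' Partition markers into the five genomic classes
#'
#' Convenience wrapper: derives the intergenic complement of the gene
#' features and assigns markers to all five classes (IGR, gene, exon, CDS,
#' UTR). Gene and IGR tile the genome, so every marker belongs to exactly
#' one of the two.
#'
#' @inheritParams assign_snps
#' @param chrom_lengths Named chromosome lengths (bp) for the IGR complement.
#' @return Named list of `snp_partition` objects (classes with no features
#'   are absent).
#' @export
annotate_markers <- function(markers, features, chrom_lengths,
                             merge_overlaps = TRUE) {
  igr <- derive_igr(features, chrom_lengths)
  assign_snps(markers, dplyr::bind_rows(features, igr), merge_overlaps)
}
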