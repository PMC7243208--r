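#' Export a haploblock table
#'
#' @param h A `haploblock_set`.
#' @param path Tab-separated output path.
#' @return `path`, invisibly.
#' @export
write_block_table <- function(h, path) {
  stopifnot(inherits(h, "haploblock_set"))
  utils::write.table(h$block_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export an encoded pseudo-marker matrix
#'
#' Writes the dense dosage matrix as tab-separated text plus a JSON sidecar
#' mapping each block to its column range.
#'
#' @param pm A `pseudo_markers` object from [dosage_encode()].
#' @param prefix Output prefix; writes `<prefix>.tsv` and `<prefix>.json`.
#' @return `prefix`, invisibly.
#' @export
write_pseudo_markers <- function(pm, prefix) {
  stopifnot(inherits(pm, "pseudo_markers"))
  df <- data.frame(id = pm$ids, pm$matrix, check.names = FALSE)
  utils::write.table(df, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(Q = pm$Q, offsets = pm$offsets),
    paste0(prefix, ".json"),
    dataframe = "columns", auto_unbox = TRUE
  )
  invisible(prefix)
}
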