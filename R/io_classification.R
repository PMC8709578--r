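# Classification table output: one row per (gene, mode, region) with the
# region coordinates, evidence flags and signed distance to the TSS.

CLASSIFICATION_HEADER <- c(
  "gene_id", "mode", "region_id", "chrom", "start", "end", "source",
  "er_present", "hsf1_present", "ere_present", "hse_present",
  "anchor_present", "distance")

#' Write a gene-mode classification table as TSV
#'
#' Fixed header (`gene_id mode region_id chrom start end source
#' er_present hsf1_present ere_present hse_present anchor_present
#' distance`); logical flags are written as 0/1. An empty table produces
#' a header-only file.
#'
#' @param gene_table output of [aggregate_by_gene()] (flag columns are
#'   filled with `NA` when missing).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_classification <- function(gene_table, path) {
  df <- gene_table
  for (col in CLASSIFICATION_HEADER)
    if (is.null(df[[col]])) df[[col]] <- rep(NA, nrow(df))
  df <- df[, CLASSIFICATION_HEADER, drop = FALSE]
  for (col in c("er_present", "hsf1_present", "ere_present",
                "hse_present", "anchor_present"))
    df[[col]] <- as.integer(df[[col]])
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) user_error(sprintf("cannot write classification to: %s", path))
  invisible(path)
}

#' Read a classification table written by [write_classification()]
#' @param path path to the TSV.
#' @return a `data.frame` with the fixed columns; flags as logicals.
#' @export
read_classification <- function(path) {
  if (!file.exists(path)) user_error(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!identical(names(df), CLASSIFICATION_HEADER))
    user_error("unexpected classification table header")
  for (col in c("er_present", "hsf1_present", "ere_present",
                "hse_present", "anchor_present"))
    df[[col]] <- as.logical(df[[col]])
  df
}
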