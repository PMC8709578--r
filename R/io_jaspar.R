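# JASPAR PFM text I/O.
#
# Format: ">ID NAME" header followed by four rows, one per base, e.g.
#   A [ 4 19  0 ]
# Row labels are honored regardless of their order in the file; bare rows
# without brackets or labels are also accepted (A,C,G,T order assumed).

#' Construct a motif count matrix
#'
#' @param motif_id motif identifier (e.g. `"ERE"`, `"HSE"`).
#' @param counts a 4 x L numeric matrix of non-negative base counts, rows
#'   in A,C,G,T order.
#' @return an object of class `motif_counts`: a list with `motif_id` and
#'   the `counts` matrix (rownames `A`,`C`,`G`,`T`).
#' @export
motif_counts <- function(motif_id, counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L)
    user_error("counts must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 1L)
    user_error("motif must have at least one position")
  if (any(counts < 0) || any(!is.finite(counts)))
    user_error("counts must be finite and non-negative")
  if (any(colSums(counts) <= 0))
    user_error("every motif column needs at least one positive count")
  rownames(counts) <- DNA_BASES4
  structure(list(motif_id = as.character(motif_id), counts = counts),
            class = "motif_counts")
}

#' Read motif count matrices from JASPAR PFM text
#'
#' @param path path to a JASPAR 2016+ PFM file (one or more motifs).
#' @return a list of [motif_counts()] objects, in file order.
#' @export
read_jaspar <- function(path) {
  if (!file.exists(path)) user_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) user_error("no '>' header found in JASPAR file")
  ends <- c(hdr[-1] - 1L, length(lines))
  out <- vector("list", length(hdr))
  for (k in seq_along(hdr)) {
    id <- sub("^>\\s*", "", lines[hdr[k]])
    id <- strsplit(id, "\\s+")[[1]][1]
    body <- lines[(hdr[k] + 1L):ends[k]]
    if (length(body) != 4L)
      user_error(sprintf("motif '%s': expected 4 count rows, got %d",
                         id, length(body)))
    labs <- toupper(sub("^\\s*([ACGTacgt])\\b.*$", "\\1", body))
    labeled <- labs %in% DNA_BASES4 & grepl("^\\s*[ACGTacgt][\\s\\[]", body, perl = TRUE)
    rows <- lapply(body, function(b) {
      b <- sub("^\\s*[ACGTacgt]", "", b)
      b <- gsub("\\[|\\]", " ", b)
      v <- suppressWarnings(as.numeric(strsplit(trimws(b), "\\s+")[[1]]))
      if (anyNA(v)) user_error(sprintf("motif '%s': non-numeric count row", id))
      v
    })
    if (length(unique(lengths(rows))) != 1L)
      user_error(sprintf("motif '%s': rows of unequal length", id))
    m <- do.call(rbind, rows)
    if (all(labeled)) m <- m[match(DNA_BASES4, labs), , drop = FALSE]
    out[[k]] <- motif_counts(id, m)
  }
  out
}

#' Write motif count matrices as JASPAR PFM text
#' @param motifs a [motif_counts()] object or a list of them.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_jaspar <- function(motifs, path) {
  if (inherits(motifs, "motif_counts")) motifs <- list(motifs)
  lines <- unlist(lapply(motifs, function(m) {
    c(sprintf(">%s %s", m$motif_id, m$motif_id),
      vapply(DNA_BASES4, function(b) {
        sprintf("%s [ %s ]", b,
                paste(formatC(m$counts[b, ], format = "fg", digits = 10),
                      collapse = " "))
      }, character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}
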