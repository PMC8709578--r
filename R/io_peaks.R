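# Peak, anchor-pair and TSS table I/O.
#
# All internal coordinates are 0-based half-open [start, end), the BED
# convention. 1-based formats (GFF/GTF) are converted at the boundary.
# Chromosome names are kept verbatim; no "chr" normalization is applied.

#' Construct a peak table
#'
#' The common currency of the package: a `data.frame` with one row per
#' called peak. Coordinates are 0-based half-open. `summit_offset` is the
#' offset of the read-pileup summit from `start` (as in ENCODE narrowPeak
#' column 10); `tags` is the per-peak sequencing tag count and
#' `fold_enrichment` the caller's signal value, both optional.
#'
#' @param chrom character vector of chromosome names (kept verbatim).
#' @param start,end integer vectors, 0-based half-open span; `start < end`.
#' @param name peak identifiers; autogenerated when omitted.
#' @param score numeric display score (BED column 5).
#' @param summit_offset integer offset of the summit from `start`, or `NA`.
#' @param tags integer tag count per peak, or `NA`.
#' @param fold_enrichment numeric signal value, or `NA`.
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `summit_offset`, `tags`, `fold_enrichment`.
#' @export
#' @examples
#' peak_records("chr1", 100, 200, summit_offset = 30)
peak_records <- function(chrom, start, end, name = NULL, score = 0,
                         summit_offset = NA_integer_, tags = NA_integer_,
                         fold_enrichment = NA_real_) {
  n <- max(length(chrom), length(start), length(end))
  if (length(chrom) == 0L || length(start) == 0L || length(end) == 0L) n <- 0L
  chrom <- rep_len(chrom, n)
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  if (any(start < 0) || any(start >= end))
    user_error("peaks must satisfy 0 <= start < end")
  name <- if (is.null(name)) sprintf("peak_%d", seq_len(n)) else as.character(name)
  df <- data.frame(
    chrom = as.character(chrom), start = start, end = end,
    name = rep_len(name, n), score = rep_len(as.numeric(score), n),
    summit_offset = rep_len(as.numeric(summit_offset), n),
    tags = rep_len(as.numeric(tags), n),
    fold_enrichment = rep_len(as.numeric(fold_enrichment), n),
    stringsAsFactors = FALSE
  )
  bad <- !is.na(df$summit_offset) &
    (df$summit_offset < 0 | df$summit_offset >= df$end - df$start)
  if (any(bad))
    user_error(sprintf("summit_offset outside peak for: %s",
                       paste(df$name[bad], collapse = ", ")))
  df
}

read_tabular_lines <- function(path) {
  if (!file.exists(path)) user_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$|^#|^track|^browser", lines)
  list(lines = lines[keep], lineno = which(keep))
}

split_fields <- function(lines) {
  strsplit(lines, "[\t ]+")
}

num_or_fail <- function(x, what, lineno) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) & !is.na(x)
  if (any(bad))
    user_error(sprintf("malformed %s at line %d: '%s'",
                       what, lineno[which(bad)[1]], x[which(bad)[1]]))
  v
}

#' Read ChIP-seq peak calls from BED or narrowPeak files
#'
#' `dialect = "bed"` accepts BED3+ (name and score used when present).
#' `dialect = "narrowPeak"` expects the 10-column ENCODE format; column 10
#' is the summit offset (`-1` means no summit). Some MACS dialects emit an
#' absolute summit coordinate instead of an offset; a column-10 value
#' greater than or equal to the peak start is detected as absolute and
#' converted to an offset. Track, browser and `#` comment lines are
#' skipped. narrowPeak `signalValue` (column 7) is mapped to
#' `fold_enrichment`.
#'
#' @param path path to the file.
#' @param dialect `"bed"` or `"narrowPeak"`.
#' @return a peak `data.frame`; see [peak_records()].
#' @export
read_peaks <- function(path, dialect = c("narrowPeak", "bed")) {
  dialect <- match.arg(dialect)
  tl <- read_tabular_lines(path)
  if (length(tl$lines) == 0L)
    return(peak_records(character(0), numeric(0), numeric(0)))
  f <- split_fields(tl$lines)
  need <- if (dialect == "narrowPeak") 10L else 3L
  nf <- lengths(f)
  if (any(nf < need))
    user_error(sprintf("malformed %s line %d: expected >= %d columns, got %d",
                       dialect, tl$lineno[which(nf < need)[1]], need,
                       nf[which(nf < need)[1]]))
  col <- function(i) vapply(f, function(x) if (length(x) >= i) x[i] else NA_character_,
                            character(1))
  start <- num_or_fail(col(2), "start", tl$lineno)
  end <- num_or_fail(col(3), "end", tl$lineno)
  bad <- start >= end | start < 0
  if (any(bad))
    user_error(sprintf("invalid interval (start >= end) at line %d",
                       tl$lineno[which(bad)[1]]))
  nm <- if (max(nf) >= 4L) col(4) else NA_character_
  nm[is.na(nm) | nm == "."] <- sprintf("peak_%d", which(is.na(nm) | nm == "."))
  sc <- if (max(nf) >= 5L) suppressWarnings(as.numeric(col(5))) else 0
  sc[is.na(sc)] <- 0
  fe <- NA_real_; summit <- NA_real_
  if (dialect == "narrowPeak") {
    fe <- num_or_fail(col(7), "signalValue", tl$lineno)
    s10 <- num_or_fail(col(10), "summit", tl$lineno)
    summit <- ifelse(s10 < 0, NA_real_,
                     ifelse(s10 >= start, s10 - start, s10))
    bad_s <- !is.na(summit) & (summit < 0 | summit >= end - start)
    if (any(bad_s))
      user_error(sprintf("summit outside peak at line %d",
                         tl$lineno[which(bad_s)[1]]))
  }
  peak_records(col(1), start, end, name = nm, score = sc,
               summit_offset = summit, fold_enrichment = fe)
}

#' Write peaks to BED or narrowPeak
#'
#' The narrowPeak writer emits `fold_enrichment` as `signalValue` (0 when
#' absent), `-1` for the unused p/q columns, and the summit offset (or
#' `-1`) in column 10, so that reading the file back reproduces the fields
#' the dialect can carry.
#'
#' @param peaks a peak `data.frame` ([peak_records()]).
#' @param path output path.
#' @param dialect `"bed"` or `"narrowPeak"`.
#' @return invisibly, `path`.
#' @export
write_peaks <- function(peaks, path, dialect = c("narrowPeak", "bed")) {
  dialect <- match.arg(dialect)
  fmtnum <- function(x) formatC(x, format = "fg", digits = 15)
  if (dialect == "bed") {
    lines <- paste(peaks$chrom, fmtnum(peaks$start), fmtnum(peaks$end),
                   peaks$name, fmtnum(peaks$score), ".", sep = "\t")
  } else {
    fe <- ifelse(is.na(peaks$fold_enrichment), 0, peaks$fold_enrichment)
    sm <- ifelse(is.na(peaks$summit_offset), -1, peaks$summit_offset)
    lines <- paste(peaks$chrom, fmtnum(peaks$start), fmtnum(peaks$end),
                   peaks$name, fmtnum(peaks$score), ".",
                   fmtnum(fe), -1, -1, fmtnum(sm), sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Construct an anchor-pair table from two interval sets
#'
#' One row per ChIA-PET interaction: two genomic intervals (the loop
#' anchors) and a paired-end-tag count. Pairs are normalized so that the
#' left anchor precedes the right by (chromosome, start).
#'
#' @param chrom1,start1,end1 left interval (before normalization).
#' @param chrom2,start2,end2 right interval.
#' @param pet_count integer PET support per interaction (default 1).
#' @return a `data.frame` with columns `chrom1`, `start1`, `end1`,
#'   `chrom2`, `start2`, `end2`, `pet_count`.
#' @export
anchor_pairs <- function(chrom1, start1, end1, chrom2, start2, end2,
                         pet_count = 1L) {
  n <- length(chrom1)
  df <- data.frame(
    chrom1 = as.character(chrom1), start1 = as.numeric(start1),
    end1 = as.numeric(end1), chrom2 = as.character(chrom2),
    start2 = as.numeric(start2), end2 = as.numeric(end2),
    pet_count = rep_len(as.numeric(pet_count), n),
    stringsAsFactors = FALSE
  )
  if (any(df$start1 >= df$end1) || any(df$start2 >= df$end2))
    user_error("anchor intervals must satisfy start < end")
  if (any(df$pet_count < 1))
    user_error("pet_count must be >= 1")
  swap <- df$chrom2 < df$chrom1 |
    (df$chrom2 == df$chrom1 & df$start2 < df$start1)
  if (any(swap)) {
    tmp <- df[swap, c("chrom1", "start1", "end1")]
    df[swap, c("chrom1", "start1", "end1")] <-
      df[swap, c("chrom2", "start2", "end2")]
    df[swap, c("chrom2", "start2", "end2")] <- tmp
  }
  df
}

#' Read ChIA-PET interactions from a BEDPE-like file
#'
#' Expects at least six columns (`chrom1 start1 end1 chrom2 start2 end2`);
#' column 8 (BEDPE score), when present and numeric, is taken as the PET
#' count. Both intra- and inter-chromosomal pairs are retained and each
#' pair is normalized left-before-right by (chromosome, start).
#'
#' @param path path to the file.
#' @return an anchor-pair `data.frame`; see [anchor_pairs()].
#' @export
read_anchor_pairs <- function(path) {
  tl <- read_tabular_lines(path)
  if (length(tl$lines) == 0L)
    return(anchor_pairs(character(0), numeric(0), numeric(0),
                        character(0), numeric(0), numeric(0)))
  f <- split_fields(tl$lines)
  nf <- lengths(f)
  if (any(nf < 6L))
    user_error(sprintf("malformed BEDPE line %d: expected >= 6 columns",
                       tl$lineno[which(nf < 6L)[1]]))
  col <- function(i) vapply(f, function(x) if (length(x) >= i) x[i] else NA_character_,
                            character(1))
  ints <- lapply(c(2, 3, 5, 6), function(i) {
    v <- num_or_fail(col(i), "coordinate", tl$lineno)
    if (any(v != floor(v)))
      user_error(sprintf("non-integer coordinate at line %d",
                         tl$lineno[which(v != floor(v))[1]]))
    v
  })
  pet <- if (max(nf) >= 8L) suppressWarnings(as.numeric(col(8))) else NA_real_
  pet[is.na(pet) | pet < 1] <- 1
  anchor_pairs(col(1), ints[[1]], ints[[2]], col(4), ints[[3]], ints[[4]],
               pet_count = pet)
}

#' Write anchor pairs as 8-column BEDPE
#' @param pairs an anchor-pair `data.frame`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_anchor_pairs <- function(pairs, path) {
  fmtnum <- function(x) formatC(x, format = "fg", digits = 15)
  lines <- paste(pairs$chrom1, fmtnum(pairs$start1), fmtnum(pairs$end1),
                 pairs$chrom2, fmtnum(pairs$start2), fmtnum(pairs$end2),
                 sprintf("pair_%d", seq_len(nrow(pairs))),
                 fmtnum(pairs$pet_count), sep = "\t")
  if (nrow(pairs) == 0L) lines <- character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Construct a TSS table
#'
#' @param gene_id unique gene identifiers.
#' @param chrom chromosome names.
#' @param strand `"+"` or `"-"` per gene.
#' @param tss 0-based TSS position.
#' @return a `data.frame` with columns `gene_id`, `chrom`, `strand`, `tss`.
#' @export
tss_records <- function(gene_id, chrom, strand, tss) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id))
    user_error("gene_id must be unique within a TSS table")
  if (!all(strand %in% c("+", "-")))
    user_error("strand must be '+' or '-'")
  data.frame(gene_id = gene_id, chrom = as.character(chrom),
             strand = as.character(strand), tss = as.numeric(tss),
             stringsAsFactors = FALSE)
}

#' Read gene TSS positions
#'
#' Accepts either a 4-column TSV (`gene_id chrom strand tss`, header
#' required, TSS already 0-based) or a GFF3/GTF file, in which case gene
#' features are imported with rtracklayer, 1-based starts are converted to
#' 0-based, and for minus-strand genes the TSS is the feature end.
#'
#' @param path path to the file; format chosen by extension
#'   (`.gff`/`.gff3`/`.gtf` versus anything else).
#' @return a TSS `data.frame`; see [tss_records()].
#' @export
read_tss <- function(path) {
  if (!file.exists(path)) user_error(sprintf("file not found: %s", path))
  if (grepl("\\.(gff3?|gtf)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      user_error("rtracklayer is required to read GFF/GTF TSS input")
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "gene"]
    ids <- gr$gene_id %||% gr$ID
    if (is.null(ids)) ids <- gr$Name
    if (is.null(ids)) user_error("no gene_id/ID attribute in GFF/GTF")
    minus <- as.character(BiocGenerics::strand(gr)) == "-"
    tss <- ifelse(minus, BiocGenerics::end(gr) - 1,
                  BiocGenerics::start(gr) - 1)
    strand <- ifelse(minus, "-", "+")
    return(tss_records(as.character(ids),
                       as.character(GenomeInfoDb::seqnames(gr)), strand, tss))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss")
  if (!all(need %in% names(df)))
    user_error(sprintf("TSS TSV must have columns: %s",
                       paste(need, collapse = ", ")))
  tss_records(df$gene_id, df$chrom, df$strand, df$tss)
}

#' Write a TSS table as TSV
#' @param tss a TSS `data.frame`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_tss <- function(tss, path) {
  utils::write.table(tss[, c("gene_id", "chrom", "strand", "tss")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
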