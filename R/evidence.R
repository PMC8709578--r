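# Building RegionEvidence: anchors x two ChIP peak sets -> one region
# stream with presence flags for each factor.

# Minimal union-find for grouping mutually-overlapping peak pairs.
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Combine reduced anchors with two ChIP-seq peak sets
#'
#' For every reduced anchor, a factor is flagged present when some peak of
#' that factor and the anchor satisfy the each-center rule (the peak
#' center lies in the anchor and the anchor midpoint lies in the peak).
#' Peaks not attached to any anchor are emitted as peak-only regions:
#' ER/HSF1 peaks that mutually overlap (each-center rule by default,
#' one-center behind `overlap_rule = "one"`) are merged into one region
#' spanning both; remaining peaks become single-factor regions.
#'
#' @param anchors a `data.frame` of reduced anchor intervals (`chrom`,
#'   `start`, `end`); must be disjoint (run [reduce_merge()] first).
#' @param er_peaks,hsf1_peaks peak `data.frame`s for the two factors.
#' @param overlap_rule `"each"` (default, the classification convention)
#'   or `"one"` for the permissive common-site rule, applied to peak-only
#'   ER/HSF1 pairing.
#' @return a `data.frame` of region evidence: `region_id`, `chrom`,
#'   `start`, `end`, `source` (`"anchor"`, `"peak_pair"`, `"peak"`),
#'   `anchor_present`, `er_present`, `hsf1_present`, plus the contributing
#'   peak names `er_peak` and `hsf1_peak` (comma-separated, `NA` if none).
#' @export
three_way_overlap <- function(anchors, er_peaks, hsf1_peaks,
                              overlap_rule = c("each", "one")) {
  overlap_rule <- match.arg(overlap_rule)
  if (nrow(anchors) > 0L) {
    o <- order(anchors$chrom, anchors$start)
    a2 <- anchors[o, ]
    same <- a2$chrom[-1] == a2$chrom[-nrow(a2)]
    if (any(same & a2$start[-1] < a2$end[-nrow(a2)]))
      stop("internal error: anchors overlap; reduce_merge them first")
  }

  amid <- floor((anchors$start + anchors$end) / 2)
  attach_hits <- function(peaks) {
    # each-center between peak and anchor
    h <- point_in_ranges(peaks$chrom, peak_center(peaks),
                         anchors$chrom, anchors$start, anchors$end)
    if (nrow(h) == 0L) return(h)
    keep <- peaks$start[h$p] <= amid[h$r] & amid[h$r] < peaks$end[h$p]
    h[keep, , drop = FALSE]
  }
  er_h <- attach_hits(er_peaks)
  hs_h <- attach_hits(hsf1_peaks)

  n_anchor <- nrow(anchors)
  join_names <- function(x) if (length(x)) paste(sort(unique(x)), collapse = ",") else NA_character_
  anchor_rows <- data.frame(
    chrom = anchors$chrom, start = anchors$start, end = anchors$end,
    source = rep("anchor", n_anchor),
    anchor_present = rep(TRUE, n_anchor),
    er_present = seq_len(n_anchor) %in% er_h$r,
    hsf1_present = seq_len(n_anchor) %in% hs_h$r,
    er_peak = vapply(seq_len(n_anchor), function(i)
      join_names(er_peaks$name[er_h$p[er_h$r == i]]), character(1)),
    hsf1_peak = vapply(seq_len(n_anchor), function(i)
      join_names(hsf1_peaks$name[hs_h$p[hs_h$r == i]]), character(1)),
    stringsAsFactors = FALSE
  )

  er_free <- setdiff(seq_len(nrow(er_peaks)), er_h$p)
  hs_free <- setdiff(seq_len(nrow(hsf1_peaks)), hs_h$p)
  era <- er_peaks[er_free, , drop = FALSE]
  hsa <- hsf1_peaks[hs_free, , drop = FALSE]
  pairs <- if (overlap_rule == "each") common_pairs_each(era, hsa)
           else common_sites_one(era, hsa)

  # connected components over the bipartite pair graph
  n_e <- nrow(era); n_h <- nrow(hsa)
  parent <- seq_len(n_e + n_h)
  if (nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      ra <- uf_find(parent, pairs$a[i])
      rb <- uf_find(parent, n_e + pairs$b[i])
      if (ra != rb) parent[rb] <- ra
    }
  }
  root <- vapply(seq_len(n_e + n_h), function(i) uf_find(parent, i), integer(1))
  comp_rows <- lapply(unique(root), function(r) {
    ei <- which(root[seq_len(n_e)] == r)
    hi <- which(root[n_e + seq_len(n_h)] == r)
    sub <- rbind(era[ei, c("chrom", "start", "end")],
                 hsa[hi, c("chrom", "start", "end")])
    data.frame(
      chrom = sub$chrom[1], start = min(sub$start), end = max(sub$end),
      source = if (length(ei) && length(hi)) "peak_pair" else "peak",
      anchor_present = FALSE,
      er_present = length(ei) > 0L, hsf1_present = length(hi) > 0L,
      er_peak = join_names(era$name[ei]),
      hsf1_peak = join_names(hsa$name[hi]),
      stringsAsFactors = FALSE
    )
  })
  out <- rbind(anchor_rows, do.call(rbind, comp_rows))
  if (is.null(out) || nrow(out) == 0L) {
    out <- anchor_rows
  }
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  cbind(region_id = sprintf("region_%04d", seq_len(nrow(out))), out,
        stringsAsFactors = FALSE)
}

#' Extract region sequences from a genome
#'
#' @param genome_seq named character vector (or `DNAStringSet`) of
#'   chromosome sequences.
#' @param regions a `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return character vector of region sequences, named by `region_id` when
#'   present.
#' @export
extract_region_seqs <- function(genome_seq, regions) {
  if (inherits(genome_seq, "DNAStringSet"))
    genome_seq <- setNames(as.character(genome_seq), names(genome_seq))
  miss <- setdiff(unique(regions$chrom), names(genome_seq))
  if (length(miss))
    user_error(sprintf("chromosome missing from genome FASTA: %s",
                       paste(miss, collapse = ", ")))
  seqs <- substr(genome_seq[regions$chrom], regions$start + 1, regions$end)
  names(seqs) <- if (!is.null(regions$region_id)) regions$region_id
                 else sprintf("%s:%d-%d", regions$chrom,
                              as.integer(regions$start), as.integer(regions$end))
  seqs
}
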