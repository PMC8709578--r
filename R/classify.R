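# The decision table mapping region evidence flags to binding modes, gene
# aggregation by nearest TSS, and gene-set summaries.

#' Binding mode labels
#'
#' The seven possible labels, in reporting order. `tethering_HSF1_by_ER`
#' means both factors occupy the region but only the ERE is present, so
#' ER alpha contacts DNA and HSF1 is tethered through protein-protein
#' interaction; `tethering_ER_by_HSF1` is the converse (HSE only).
#'
#' @return character vector of mode labels.
#' @export
binding_modes <- function() {
  c("canonical_ER", "canonical_HSF1", "cobinding",
    "tethering_HSF1_by_ER", "tethering_ER_by_HSF1",
    "indirect", "unclassified")
}

TETHERING_MODES <- c("tethering_HSF1_by_ER", "tethering_ER_by_HSF1")

#' Classify regions from evidence flags
#'
#' Total, deterministic decision table over the flag space:
#' * both factors, both motifs -> `cobinding`
#' * both factors, ERE only -> `tethering_HSF1_by_ER`
#' * both factors, HSE only -> `tethering_ER_by_HSF1`
#' * both factors, no motif -> `indirect`
#' * ER only with ERE -> `canonical_ER`; HSF1 only with HSE ->
#'   `canonical_HSF1`
#' * a single factor without its own motif, or no factor at all ->
#'   `unclassified`
#'
#' The anchor flag does not enter the table (anchors determine which
#' interval the evidence was collected on, not the mode).
#'
#' @param er,hsf1 logical vectors: factor occupancy per region.
#' @param ere,hse logical vectors: motif presence per region.
#' @return character vector of modes (see [binding_modes()]).
#' @export
classify_region <- function(er, hsf1, ere, hse) {
  n <- length(er)
  stopifnot(length(hsf1) == n, length(ere) == n, length(hse) == n)
  mode <- rep("unclassified", n)
  both <- er & hsf1
  mode[both & ere & hse] <- "cobinding"
  mode[both & ere & !hse] <- "tethering_HSF1_by_ER"
  mode[both & !ere & hse] <- "tethering_ER_by_HSF1"
  mode[both & !ere & !hse] <- "indirect"
  mode[er & !hsf1 & ere] <- "canonical_ER"
  mode[!er & hsf1 & hse] <- "canonical_HSF1"
  mode
}

#' Aggregate classified regions to genes by nearest TSS
#'
#' Each region with a mode other than `unclassified` contributes one row
#' under its nearest-TSS gene. A gene may carry several modes (one per
#' region). Regions on chromosomes absent from the TSS table are dropped
#' with a warning.
#'
#' @param evidence a region evidence `data.frame` carrying at least
#'   `region_id`, `chrom`, `start`, `end` and `mode` (plus any flag
#'   columns, which are carried through).
#' @param tss a TSS `data.frame` ([tss_records()]).
#' @return a gene-mode table: one row per (gene, mode, region) with
#'   `gene_id`, `mode`, `region_id`, `distance` (signed bp to TSS) and
#'   the region columns.
#' @export
aggregate_by_gene <- function(evidence, tss) {
  keep <- evidence$mode != "unclassified"
  ev <- evidence[keep, , drop = FALSE]
  if (nrow(ev) == 0L) {
    out <- cbind(gene_id = character(0), ev, distance = numeric(0))
    return(out)
  }
  nt <- nearest_tss(ev, tss)
  drop <- is.na(nt$gene_id)
  if (any(drop)) {
    warning(sprintf("%d region(s) without a same-chromosome TSS dropped",
                    sum(drop)))
    ev <- ev[!drop, , drop = FALSE]
    nt <- nt[!drop, , drop = FALSE]
  }
  out <- cbind(gene_id = nt$gene_id, ev, distance = nt$distance,
               stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$gene_id, out$mode, out$region_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-level mode summary
#'
#' Counts genes by regulation mode: canonical per factor, canonically
#' co-regulated genes (at least one canonical region of each factor,
#' possibly far apart), cobinding genes, tethering genes (either
#' direction) and direct cooperation (union of cobinding and tethering
#' genes).
#'
#' @param gene_table output of [aggregate_by_gene()].
#' @return list with `counts` (named integer vector) and `genes` (named
#'   list of gene-id sets).
#' @export
summarize_modes <- function(gene_table) {
  gmode <- function(modes) unique(gene_table$gene_id[gene_table$mode %in% modes])
  g_can_er <- gmode("canonical_ER")
  g_can_hs <- gmode("canonical_HSF1")
  g_cob <- gmode("cobinding")
  g_tet <- gmode(TETHERING_MODES)
  g_ind <- gmode("indirect")
  g_coreg <- intersect(g_can_er, g_can_hs)
  g_direct <- union(g_cob, g_tet)
  genes <- list(canonical_ER = g_can_er, canonical_HSF1 = g_can_hs,
                canonical_coregulated = g_coreg, cobinding = g_cob,
                tethering = g_tet, direct_cooperation = g_direct,
                indirect = g_ind)
  list(counts = vapply(genes, length, integer(1)), genes = genes)
}

#' Three-set Venn region counts
#'
#' @param set_a,set_b,set_c character vectors (gene-id sets).
#' @return named integer vector of the 7 Venn region counts
#'   (`a_only`, `b_only`, `c_only`, `ab_only`, `ac_only`, `bc_only`,
#'   `abc`); the counts sum to `|A union B union C|`.
#' @export
compare_gene_sets <- function(set_a, set_b, set_c) {
  a <- unique(set_a); b <- unique(set_b); c <- unique(set_c)
  u <- union(union(a, b), c)
  in_a <- u %in% a; in_b <- u %in% b; in_c <- u %in% c
  c(a_only = sum(in_a & !in_b & !in_c),
    b_only = sum(!in_a & in_b & !in_c),
    c_only = sum(!in_a & !in_b & in_c),
    ab_only = sum(in_a & in_b & !in_c),
    ac_only = sum(in_a & !in_b & in_c),
    bc_only = sum(!in_a & in_b & in_c),
    abc = sum(in_a & in_b & in_c))
}

#' Run the full classification pipeline
#'
#' Reduces the ChIA-PET anchors, builds region evidence against the two
#' peak sets ([three_way_overlap()]), calls ERE and HSE motif presence on
#' each region's sequence, applies the decision table
#' ([classify_region()]), aggregates to genes by nearest TSS and
#' summarizes gene counts. Optionally reports loop-mediated pairings
#' (ER alpha and HSF1 occupying two different anchors of one
#' interaction) as a separate table; these are not folded into tethering.
#'
#' @param er_peaks,hsf1_peaks peak `data.frame`s.
#' @param pairs anchor-pair `data.frame` ([anchor_pairs()]), or `NULL`
#'   for a peaks-only analysis.
#' @param genome_seq named character vector or `DNAStringSet` of
#'   chromosome sequences.
#' @param pwm_ere,pwm_hse [build_pwm()] objects for the two motifs.
#' @param tss TSS `data.frame`.
#' @param p_threshold per-window motif p-value cutoff (default `1e-4`).
#' @param overlap_rule `"each"` or `"one"`, for peak-only ER/HSF1 pairing.
#' @return list with `evidence` (flags, motif calls and `mode` per
#'   region), `gene_table`, `summary` ([summarize_modes()]), `anchors`
#'   (reduced), and `loop_pairs` (regions of one interaction carrying the
#'   two factors on opposite anchors).
#' @export
classify_pipeline <- function(er_peaks, hsf1_peaks, pairs, genome_seq,
                              pwm_ere, pwm_hse, tss,
                              p_threshold = 1e-4,
                              overlap_rule = c("each", "one")) {
  overlap_rule <- match.arg(overlap_rule)
  anchors <- if (is.null(pairs) || nrow(pairs) == 0L) {
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  } else {
    reduce_merge(data.frame(
      chrom = c(pairs$chrom1, pairs$chrom2),
      start = c(pairs$start1, pairs$start2),
      end = c(pairs$end1, pairs$end2), stringsAsFactors = FALSE))
  }
  ev <- three_way_overlap(anchors, er_peaks, hsf1_peaks,
                          overlap_rule = overlap_rule)
  seqs <- extract_region_seqs(genome_seq, ev)
  np_ere <- null_pmf(pwm_ere)
  np_hse <- null_pmf(pwm_hse)
  call_one <- function(pwm, npmf) vapply(seqs, function(s)
    motif_present(pwm, s, p_threshold = p_threshold, npmf = npmf)$present,
    logical(1), USE.NAMES = FALSE)
  ev$ere_present <- call_one(pwm_ere, np_ere)
  ev$hse_present <- call_one(pwm_hse, np_hse)
  ev$mode <- classify_region(ev$er_present, ev$hsf1_present,
                             ev$ere_present, ev$hse_present)
  gene_table <- aggregate_by_gene(ev, tss)
  loop_pairs <- loop_mediated_pairs(pairs, anchors, ev)
  list(evidence = ev, gene_table = gene_table,
       summary = summarize_modes(gene_table), anchors = anchors,
       loop_pairs = loop_pairs,
       params = list(p_threshold = p_threshold, overlap_rule = overlap_rule))
}

# Interactions whose two (reduced) anchors carry the two different
# factors: candidate loop-mediated cooperation, reported separately.
loop_mediated_pairs <- function(pairs, anchors, evidence) {
  empty <- data.frame(pair = integer(0), left_region = character(0),
                      right_region = character(0), stringsAsFactors = FALSE)
  if (is.null(pairs) || nrow(pairs) == 0L || nrow(anchors) == 0L) return(empty)
  anchor_ev <- evidence[evidence$source == "anchor", , drop = FALSE]
  find_region <- function(chrom, start, end) {
    mid <- floor((start + end) / 2)
    h <- point_in_ranges(chrom, mid, anchor_ev$chrom,
                         anchor_ev$start, anchor_ev$end)
    out <- rep(NA_integer_, length(chrom))
    out[h$p] <- h$r
    out
  }
  li <- find_region(pairs$chrom1, pairs$start1, pairs$end1)
  ri <- find_region(pairs$chrom2, pairs$start2, pairs$end2)
  ok <- !is.na(li) & !is.na(ri) & li != ri
  cross <- ok &
    ((anchor_ev$er_present[li] & !anchor_ev$hsf1_present[li] &
        anchor_ev$hsf1_present[ri] & !anchor_ev$er_present[ri]) |
       (anchor_ev$hsf1_present[li] & !anchor_ev$er_present[li] &
          anchor_ev$er_present[ri] & !anchor_ev$hsf1_present[ri]))
  cross[is.na(cross)] <- FALSE
  data.frame(pair = which(cross),
             left_region = anchor_ev$region_id[li[cross]],
             right_region = anchor_ev$region_id[ri[cross]],
             stringsAsFactors = FALSE)
}
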