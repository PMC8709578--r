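# Interval algebra: the overlap conventions used throughout the pipeline,
# anchor reduction, nearest-TSS annotation and randomized placement.
#
# Two overlap rules appear in TF ChIP-seq practice and both are
# implemented: the permissive "one-center" rule (peaks are common if at
# least one peak's center lies inside the other) used for genome-wide
# common-site counting, and the strict "each-center" rule (each center
# inside the other peak) used for region classification.

#' Genome specification
#'
#' @param chrom unique chromosome names.
#' @param length chromosome lengths in bp (> 0).
#' @return a `data.frame` with columns `chrom` and `length`.
#' @export
genome_spec <- function(chrom, length) {
  chrom <- as.character(chrom)
  if (anyDuplicated(chrom)) user_error("chromosome names must be unique")
  length <- as.numeric(length)
  if (length(chrom) != base::length(length))
    user_error("chrom and length must have equal length")
  if (any(length <= 0)) user_error("chromosome lengths must be > 0")
  data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE)
}

#' Peak center
#'
#' The summit position (`start + summit_offset`) when a summit is present,
#' otherwise the floored midpoint `floor((start + end) / 2)`.
#'
#' @param peaks a peak `data.frame` (or any data.frame with `start`, `end`
#'   and optionally `summit_offset`).
#' @return integer-valued vector of center positions (0-based).
#' @export
peak_center <- function(peaks) {
  ctr <- floor((peaks$start + peaks$end) / 2)
  so <- peaks$summit_offset
  if (!is.null(so)) {
    has <- !is.na(so)
    ctr[has] <- peaks$start[has] + so[has]
  }
  ctr
}

#' Is the center of `a` inside interval `b`?
#'
#' Half-open convention: true iff the chromosomes match and
#' `b$start <= center(a) < b$end`. Vectorized row-wise over equal-length
#' inputs.
#'
#' @param a a peak `data.frame` (centers taken with [peak_center()]).
#' @param b a `data.frame` with `chrom`, `start`, `end`.
#' @return logical vector.
#' @export
center_in <- function(a, b) {
  ctr <- peak_center(a)
  a$chrom == b$chrom & b$start <= ctr & ctr < b$end
}

# Point-in-interval hits across chromosomes. Returns data.frame(p, r):
# indices of points and of the (possibly overlapping) intervals that
# contain them under the half-open convention.
point_in_ranges <- function(p_chrom, p_pos, r_chrom, r_start, r_end) {
  out_p <- integer(0); out_r <- integer(0)
  if (length(p_pos) && length(r_start)) {
    for (ch in intersect(unique(p_chrom), unique(r_chrom))) {
      pi <- which(p_chrom == ch); ri <- which(r_chrom == ch)
      # 0-based point c in [start, end)  <=>  1-based point c+1 in [start+1, end]
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(p_pos[pi] + 1L, p_pos[pi] + 1L),
        IRanges::IRanges(r_start[ri] + 1L, r_end[ri]))
      out_p <- c(out_p, pi[S4Vectors::queryHits(hits)])
      out_r <- c(out_r, ri[S4Vectors::subjectHits(hits)])
    }
  }
  data.frame(p = out_p, r = out_r)
}

#' Common binding sites under the one-center rule
#'
#' A pair (A_i, B_j) qualifies when the center of A_i lies in B_j or the
#' center of B_j lies in A_i; each qualifying pair is emitted once.
#'
#' @param set_a,set_b peak `data.frame`s.
#' @return a `data.frame` with columns `a` and `b`: row indices into
#'   `set_a` and `set_b`, ordered by (a, b).
#' @export
common_sites_one <- function(set_a, set_b) {
  h1 <- point_in_ranges(set_a$chrom, peak_center(set_a),
                        set_b$chrom, set_b$start, set_b$end)
  h2 <- point_in_ranges(set_b$chrom, peak_center(set_b),
                        set_a$chrom, set_a$start, set_a$end)
  pairs <- rbind(data.frame(a = h1$p, b = h1$r),
                 data.frame(a = h2$r, b = h2$p))
  pairs <- unique(pairs)
  pairs[order(pairs$a, pairs$b), , drop = FALSE]
}

#' Mutual overlap under the each-center rule
#'
#' True iff the center of `a` is inside `b` and the center of `b` is
#' inside `a` (strictly stronger than the one-center rule). Vectorized
#' row-wise.
#'
#' @param a,b peak `data.frame`s of equal length.
#' @return logical vector.
#' @export
common_sites_each <- function(a, b) {
  center_in(a, b) & center_in(b, a)
}

# All (i, j) index pairs satisfying the each-center rule between two sets.
common_pairs_each <- function(set_a, set_b) {
  h1 <- point_in_ranges(set_a$chrom, peak_center(set_a),
                        set_b$chrom, set_b$start, set_b$end)
  if (nrow(h1) == 0L) return(data.frame(a = integer(0), b = integer(0)))
  ctr_b <- peak_center(set_b)
  keep <- set_a$start[h1$p] <= ctr_b[h1$r] & ctr_b[h1$r] < set_a$end[h1$p]
  pairs <- data.frame(a = h1$p[keep], b = h1$r[keep])
  pairs[order(pairs$a, pairs$b), , drop = FALSE]
}

#' Merge overlapping and adjacent intervals
#'
#' Sort-and-sweep reduction: the output is sorted, pairwise disjoint, and
#' covers exactly the union of the input; book-ended intervals
#' (`end == start`) are merged, matching `IRanges::reduce` semantics on
#' integer ranges.
#'
#' @param intervals a `data.frame` with `chrom`, `start`, `end`.
#' @return a `data.frame` with `chrom`, `start`, `end`, sorted by
#'   (chrom, start).
#' @export
reduce_merge <- function(intervals) {
  if (nrow(intervals) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  o <- order(intervals$chrom, intervals$start, intervals$end)
  ch <- intervals$chrom[o]; s <- intervals$start[o]; e <- intervals$end[o]
  oc <- character(0); os <- numeric(0); oe <- numeric(0)
  cur_c <- ch[1]; cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (ch[i] == cur_c && s[i] <= cur_e) {
      cur_e <- max(cur_e, e[i])
    } else {
      oc <- c(oc, cur_c); os <- c(os, cur_s); oe <- c(oe, cur_e)
      cur_c <- ch[i]; cur_s <- s[i]; cur_e <- e[i]
    }
  }
  oc <- c(oc, cur_c); os <- c(os, cur_s); oe <- c(oe, cur_e)
  data.frame(chrom = oc, start = os, end = oe, stringsAsFactors = FALSE)
}

#' Nearest TSS annotation
#'
#' Assigns each region to the gene minimizing the distance between the
#' region midpoint and the gene TSS on the same chromosome. Ties (equal
#' absolute distance) are broken by lexicographically smaller `gene_id`.
#' The returned distance is signed by gene strand so that negative values
#' lie upstream of the TSS: `midpoint - tss` for `+` genes, `tss -
#' midpoint` for `-` genes.
#'
#' @param regions a `data.frame` with `chrom`, `start`, `end`.
#' @param tss a TSS `data.frame` ([tss_records()]); must be non-empty.
#' @return a `data.frame` with columns `gene_id`, `distance`, `tss`,
#'   `strand`; `NA` row where the region's chromosome has no TSS.
#' @export
nearest_tss <- function(regions, tss) {
  if (nrow(tss) == 0L) user_error("TSS table is empty")
  n <- nrow(regions)
  out <- data.frame(gene_id = rep(NA_character_, n),
                    distance = rep(NA_real_, n),
                    tss = rep(NA_real_, n),
                    strand = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  mid <- floor((regions$start + regions$end) / 2)
  for (ch in unique(regions$chrom)) {
    ti <- which(tss$chrom == ch)
    ri <- which(regions$chrom == ch)
    if (length(ti) == 0L) next
    # order genes by (position, gene_id); per unique position keep the
    # lexicographically smallest gene so the tie rule is local to a lookup
    o <- ti[order(tss$tss[ti], tss$gene_id[ti])]
    pos <- tss$tss[o]
    first <- !duplicated(pos)
    upos <- pos[first]; ugene <- o[first]
    k <- length(upos)
    idx <- findInterval(mid[ri], upos)
    for (jj in seq_along(ri)) {
      i <- idx[jj]; m <- mid[ri[jj]]
      dl <- if (i >= 1L) m - upos[i] else Inf
      dr <- if (i < k) upos[i + 1L] - m else Inf
      pick <- if (dl < dr) ugene[i]
      else if (dr < dl) ugene[i + 1L]
      else { # equidistant: lexicographic gene_id across both positions
        cand <- c(ugene[i], ugene[i + 1L])
        cand[order(tss$gene_id[cand])][1]
      }
      out$gene_id[ri[jj]] <- tss$gene_id[pick]
      out$tss[ri[jj]] <- tss$tss[pick]
      out$strand[ri[jj]] <- tss$strand[pick]
      out$distance[ri[jj]] <- if (tss$strand[pick] == "+")
        m - tss$tss[pick] else tss$tss[pick] - m
    }
  }
  out
}

#' Randomize peak positions, preserving chromosome and length
#'
#' Each peak is repositioned uniformly on its own chromosome with its
#' width preserved; summit offsets (relative to start) travel with the
#' peak. Deterministic given `seed`.
#'
#' @param peaks a peak `data.frame`.
#' @param genome a [genome_spec()].
#' @param seed integer seed.
#' @return a peak `data.frame` with new `start`/`end`.
#' @export
randomize_peaks <- function(peaks, genome, seed) {
  len <- genome$length[match(peaks$chrom, genome$chrom)]
  if (anyNA(len))
    user_error(sprintf("chromosome not in genome spec: %s",
                       peaks$chrom[which(is.na(len))[1]]))
  w <- peaks$end - peaks$start
  if (any(w > len))
    user_error("peak longer than its chromosome; cannot randomize")
  new_start <- withr::with_seed(as.integer(seed),
    floor(stats::runif(nrow(peaks)) * (len - w + 1)))
  out <- peaks
  out$start <- new_start
  out$end <- new_start + w
  out
}
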