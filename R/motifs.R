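# PWM construction, both-strand log-odds scanning, exact null score
# distribution by convolution, MAST-style presence calls and a
# central-enrichment statistic.
#
# Scores are in bits (log2). The null model draws each position
# independently from the background; the exact window-score distribution
# is obtained by convolving per-position score distributions on a
# discretized grid, so per-window p-values carry no sampling error beyond
# the bin width.

#' Build a position weight matrix from base counts
#'
#' Log-odds per position:
#' `log2((counts + pseudocount * bg) / (column_total + pseudocount) / bg)`,
#' i.e. a total pseudocount of `pseudocount` per column distributed
#' according to the background (MEME convention).
#'
#' @param counts a [motif_counts()] object, or a bare 4 x L matrix
#'   (A,C,G,T rows).
#' @param background length-4 probabilities (A,C,G,T), summing to 1.
#' @param pseudocount total pseudocount per column (> 0 unless every
#'   column already has all-positive counts).
#' @param motif_id identifier; defaults to the one carried by `counts`.
#' @return an object of class `pwm`: list with `motif_id`, `counts`,
#'   `log_odds` (4 x L, bits), `background`, `pseudocount`, `length`.
#' @export
build_pwm <- function(counts, background = rep(0.25, 4), pseudocount = 1,
                      motif_id = NULL) {
  if (inherits(counts, "motif_counts")) {
    motif_id <- motif_id %||% counts$motif_id
    counts <- counts$counts
  }
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) user_error("counts must be a 4 x L matrix")
  if (abs(sum(background) - 1) > 1e-8)
    user_error("background must sum to 1")
  if (any(background <= 0))
    user_error("background probabilities must all be > 0")
  tot <- colSums(counts)
  if (pseudocount <= 0 && any(counts == 0))
    user_error("zero counts require a positive pseudocount")
  L <- ncol(counts)
  lo <- matrix(0, 4, L, dimnames = list(DNA_BASES4, NULL))
  for (j in 1:4) {
    lo[j, ] <- log2((counts[j, ] + pseudocount * background[j]) /
                      (tot + pseudocount) / background[j])
  }
  structure(list(motif_id = motif_id %||% "motif", counts = counts,
                 log_odds = lo, background = background,
                 pseudocount = pseudocount, length = L),
            class = "pwm")
}

#' Maximum-likelihood consensus of a PWM
#'
#' Per position, the base(s) with the highest count. With
#' `collapse = TRUE`, ties are resolved to the first base in A,C,G,T
#' order and a single string is returned; otherwise a list of tied base
#' sets is returned (used by the simulator to sample degenerate
#' positions).
#'
#' @param pwm a [build_pwm()] object.
#' @param collapse return a single consensus string (default) or a list
#'   of per-position tied base sets.
#' @return character string or list of character vectors.
#' @export
pwm_consensus <- function(pwm, collapse = TRUE) {
  sets <- lapply(seq_len(pwm$length), function(i) {
    cnt <- pwm$counts[, i]
    DNA_BASES4[cnt == max(cnt)]
  })
  if (collapse) paste(vapply(sets, `[`, character(1), 1L), collapse = "")
  else sets
}

#' Exact null score distribution of a PWM
#'
#' Distribution of the window score when each position is drawn
#' independently from the background, computed by exact convolution of
#' per-position score distributions on a discrete grid. The internal
#' grid step is `bin_width / (L + 1)` so that the rounding error
#' accumulated over all L positions stays below the nominal `bin_width`:
#' tail probabilities agree with exhaustive enumeration to within one
#' bin.
#'
#' @param pwm a [build_pwm()] object.
#' @param bin_width nominal score resolution in bits (default 0.01).
#' @return an object of class `null_pmf`: list with `bin_width`, `step`
#'   (internal grid), `min_bin`, `mass` (probability per grid point) and
#'   `tail` (`tail[k] = P(score >= grid point k)`).
#' @export
null_pmf <- function(pwm, bin_width = 0.01) {
  if (bin_width <= 0) user_error("bin_width must be > 0")
  bg <- pwm$background
  step <- bin_width / (pwm$length + 1)
  pm_min <- 0L
  pm_mass <- 1
  for (i in seq_len(pwm$length)) {
    k <- as.integer(round(pwm$log_odds[, i] / step))
    kmin <- min(k)
    m <- numeric(max(k) - kmin + 1L)
    for (j in 1:4) m[k[j] - kmin + 1L] <- m[k[j] - kmin + 1L] + bg[j]
    conv <- numeric(length(pm_mass) + length(m) - 1L)
    for (t in which(m > 0)) {
      span <- t:(t + length(pm_mass) - 1L)
      conv[span] <- conv[span] + pm_mass * m[t]
    }
    pm_min <- pm_min + kmin
    pm_mass <- conv
  }
  structure(list(motif_id = pwm$motif_id, bin_width = bin_width,
                 step = step, min_bin = pm_min, mass = pm_mass,
                 tail = rev(cumsum(rev(pm_mass)))),
            class = "null_pmf")
}

#' Null tail probability of a score
#'
#' `P(window score >= score)` under the background model, read off the
#' discretized exact distribution. Vectorized over `score`.
#'
#' @param npmf a [null_pmf()] object.
#' @param score score(s) in bits.
#' @return numeric vector of tail probabilities in (0, 1].
#' @export
score_pvalue <- function(npmf, score) {
  k <- as.integer(round(score / npmf$step)) - npmf$min_bin + 1L
  k <- pmax(1L, pmin(k, length(npmf$tail)))
  npmf$tail[k]
}

#' Scan a sequence with a PWM on both strands
#'
#' Every window is scored on the forward strand and against the
#' reverse-complement motif (reported as strand `-` at the same forward
#' offset). Windows containing non-ACGT characters are skipped.
#'
#' @param pwm a [build_pwm()] object.
#' @param seq a DNA string (ACGTN).
#' @param npmf optional precomputed [null_pmf()] for p-values (computed on
#'   the fly when `NULL`).
#' @return a `data.frame` of scored windows, sorted by `position` (0-based
#'   window start) then strand: columns `position`, `strand`, `score`,
#'   `p_value`. Empty when the sequence is shorter than the motif.
#' @export
scan_sequence <- function(pwm, seq, npmf = NULL) {
  L <- pwm$length
  code <- encode_dna(seq)
  nw <- length(code) - L + 1L
  empty <- data.frame(position = integer(0), strand = character(0),
                      score = numeric(0), p_value = numeric(0),
                      stringsAsFactors = FALSE)
  if (nw < 1L) return(empty)
  score_with <- function(lo) {
    s <- numeric(nw)
    for (i in seq_len(L)) s <- s + lo[, i][code[seq_len(nw) + i - 1L]]
    s
  }
  lo_rc <- pwm$log_odds[4:1, L:1, drop = FALSE]
  s_f <- score_with(pwm$log_odds)
  s_r <- score_with(lo_rc)
  hits <- data.frame(
    position = rep(0:(nw - 1L), 2L),
    strand = rep(c("+", "-"), each = nw),
    score = c(s_f, s_r), stringsAsFactors = FALSE)
  hits <- hits[!is.na(hits$score), , drop = FALSE]
  if (nrow(hits)) {
    if (is.null(npmf)) npmf <- null_pmf(pwm)
    hits$p_value <- score_pvalue(npmf, hits$score)
  } else hits$p_value <- numeric(0)
  hits <- hits[order(hits$position, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' MAST-style motif presence call
#'
#' Scans the sequence and calls the motif present when the best window's
#' exact null p-value is below `p_threshold`. With `p_threshold = 1` the
#' call is present whenever at least one scorable window exists (every
#' p-value is <= 1).
#'
#' @param pwm a [build_pwm()] object.
#' @param seq DNA string.
#' @param p_threshold per-window p-value cutoff in (0, 1]; default `1e-4`,
#'   the conventional MAST hit threshold.
#' @param npmf optional precomputed [null_pmf()].
#' @return list with `present` (logical) and `best` (one-row hit
#'   `data.frame`, or `NULL` when no window was scorable).
#' @export
motif_present <- function(pwm, seq, p_threshold = 1e-4, npmf = NULL) {
  if (p_threshold <= 0 || p_threshold > 1)
    user_error("p_threshold must be in (0, 1]")
  hits <- scan_sequence(pwm, seq, npmf = npmf)
  if (nrow(hits) == 0L) return(list(present = FALSE, best = NULL))
  best <- hits[order(hits$p_value, -hits$score, hits$strand, hits$position), ][1, ]
  rownames(best) <- NULL
  present <- if (p_threshold >= 1) TRUE else best$p_value < p_threshold
  list(present = present, best = best)
}

#' Central enrichment of motif hits within fixed-width regions
#'
#' Given the best-hit motif midpoints (bp offsets) in a set of regions of
#' common width, computes the ratio of the observed fraction of midpoints
#' falling inside the central window (of width `central_fraction *
#' region_width`, centered) to `central_fraction`, with a one-sided exact
#' binomial p-value. A simplified stand-in for CentriMo-style local
#' enrichment.
#'
#' @param offsets numeric vector of best-hit midpoints, one per region,
#'   in `[0, region_width)`.
#' @param region_width common region width in bp (e.g. 150 for
#'   summit-centered windows).
#' @param central_fraction proportion of the region considered central
#'   (default 0.2).
#' @return list with `ratio` (NA when no hits), `p_value`, `n_central`,
#'   `n`.
#' @export
central_enrichment <- function(offsets, region_width, central_fraction = 0.2) {
  if (central_fraction <= 0 || central_fraction >= 1)
    user_error("central_fraction must be in (0, 1)")
  n <- length(offsets)
  if (n == 0L)
    return(list(ratio = NA_real_, p_value = NA_real_, n_central = 0L, n = 0L))
  centre <- region_width / 2
  half <- central_fraction * region_width / 2
  inwin <- offsets >= centre - half & offsets < centre + half
  x <- sum(inwin)
  list(ratio = (x / n) / central_fraction,
       p_value = stats::binom.test(x, n, central_fraction,
                                   alternative = "greater")$p.value,
       n_central = x, n = n)
}
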