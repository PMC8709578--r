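# Peak-level statistics: tags-per-peak summaries, treatment-vs-control
# fold enrichment on counts normalized to 1 million reads, and a
# chromosome- and length-preserving permutation test for peak-set
# overlap.

#' Summarize a peak set
#'
#' Tag-count quartiles (linear-interpolation quantiles) and mean, width
#' quartiles, and the peak count.
#'
#' @param peaks a peak `data.frame` with non-missing `tags`.
#' @return an object of class `peak_summary`: list with `n_peaks`,
#'   `tags` (named quantile vector `min/q25/median/q75/max` plus `mean`)
#'   and `width` quartiles.
#' @export
summarize_peaks <- function(peaks) {
  if (nrow(peaks) == 0L) user_error("cannot summarize an empty peak set")
  if (is.null(peaks$tags) || anyNA(peaks$tags))
    user_error("tags are required on every peak for summarize_peaks")
  qn <- function(x) setNames(
    stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7),
    c("min", "q25", "median", "q75", "max"))
  structure(list(n_peaks = nrow(peaks),
                 tags = c(qn(peaks$tags), mean = mean(peaks$tags)),
                 width = qn(peaks$end - peaks$start)),
            class = "peak_summary")
}

#' @export
print.peak_summary <- function(x, ...) {
  cat(sprintf("Peak set: %d peaks\n", x$n_peaks))
  cat("  tags/peak: ", paste(sprintf("%s=%.6g", names(x$tags), x$tags),
                             collapse = " "), "\n")
  cat("  width bp : ", paste(sprintf("%s=%.6g", names(x$width), x$width),
                             collapse = " "), "\n")
  invisible(x)
}

#' Fold enrichment of treatment over control tag counts
#'
#' Both counts are scaled to counts per million (`tags / libsize * 1e6`)
#' and a pseudocount (in CPM units, default 1) guards against division by
#' zero: `(treat_cpm + pseudocount) / (ctrl_cpm + pseudocount)`.
#' Vectorized over tag counts.
#'
#' @param treat_tags,ctrl_tags tag counts in treated and control
#'   conditions.
#' @param treat_libsize,ctrl_libsize library sizes (> 0).
#' @param pseudocount CPM pseudocount (default 1).
#' @return numeric fold-enrichment ratio(s).
#' @export
fold_enrichment <- function(treat_tags, ctrl_tags, treat_libsize,
                            ctrl_libsize, pseudocount = 1) {
  if (any(treat_libsize <= 0) || any(ctrl_libsize <= 0))
    user_error("library sizes must be > 0")
  (treat_tags / treat_libsize * 1e6 + pseudocount) /
    (ctrl_tags / ctrl_libsize * 1e6 + pseudocount)
}

#' Permutation test for peak-set overlap
#'
#' The observed statistic is the number of distinct peaks of `set_a` that
#' share a common site with `set_b` under the one-center rule. Each of
#' `n_perm` permutations repositions `set_b` uniformly
#' (chromosome- and length-preserving, [randomize_peaks()]) with a
#' substream seed derived from `seed`, and the add-one estimator
#' `p = (1 + #\{perm >= observed\}) / (1 + n_perm)` is reported, so `p`
#' is never 0 and is bounded below by `1 / (1 + n_perm)`.
#'
#' @param set_a,set_b peak `data.frame`s.
#' @param genome a [genome_spec()] bounding the randomization.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer master seed.
#' @return an object of class `overlap_test`: list with
#'   `observed_overlap`, `perm_overlaps`, `p_value`, `n_perm`, `seed`.
#' @export
overlap_permutation_test <- function(set_a, set_b, genome, n_perm = 1000,
                                     seed = 1) {
  if (!is_count(n_perm) || n_perm < 1) user_error("n_perm must be >= 1")
  observed <- length(unique(common_sites_one(set_a, set_b)$a))
  sub_seeds <- derive_seeds(seed, n_perm)
  perm <- vapply(sub_seeds, function(s) {
    b <- randomize_peaks(set_b, genome, seed = s)
    length(unique(common_sites_one(set_a, b)$a))
  }, numeric(1))
  structure(list(observed_overlap = observed,
                 perm_overlaps = as.integer(perm),
                 p_value = (1 + sum(perm >= observed)) / (1 + n_perm),
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "Peak overlap permutation test\n  observed: %d common A-peaks\n  permutations: %d (mean %.2f, max %d)\n  p-value: %.4g\n",
    x$observed_overlap, x$n_perm, mean(x$perm_overlaps),
    max(x$perm_overlaps), x$p_value))
  invisible(x)
}
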