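# Independent brute-force oracles. These deliberately share no code with
# the package internals: centers, overlaps and scores are recomputed from
# first principles, O(n*m) or by exhaustive enumeration.

oracle_center_one <- function(start, end, summit_offset) {
  if (!is.na(summit_offset)) start + summit_offset
  else floor((start + end) / 2)
}

oracle_common_one <- function(a, b) {
  out <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ca <- oracle_center_one(a$start[i], a$end[i], a$summit_offset[i])
    cb <- oracle_center_one(b$start[j], b$end[j], b$summit_offset[j])
    hit <- (b$start[j] <= ca && ca < b$end[j]) ||
      (a$start[i] <= cb && cb < a$end[i])
    if (hit) out <- rbind(out, c(i, j))
  }
  if (is.null(out)) data.frame(a = integer(0), b = integer(0))
  else data.frame(a = out[, 1], b = out[, 2])
}

oracle_common_each_one <- function(a_row, b_row) {
  if (a_row$chrom != b_row$chrom) return(FALSE)
  ca <- oracle_center_one(a_row$start, a_row$end, a_row$summit_offset)
  cb <- oracle_center_one(b_row$start, b_row$end, b_row$summit_offset)
  (b_row$start <= ca && ca < b_row$end) &&
    (a_row$start <= cb && cb < a_row$end)
}

oracle_nearest_tss <- function(regions, tss) {
  n <- nrow(regions)
  gene <- rep(NA_character_, n); dist <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    mid <- floor((regions$start[i] + regions$end[i]) / 2)
    cand <- tss[tss$chrom == regions$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0L) next
    d <- abs(mid - cand$tss)
    best <- cand[order(d, cand$gene_id), ][1, ]
    gene[i] <- best$gene_id
    dist[i] <- if (best$strand == "+") mid - best$tss else best$tss - mid
  }
  data.frame(gene_id = gene, distance = dist, stringsAsFactors = FALSE)
}

# Independent log-odds: recomputed from counts with the stated formula.
oracle_log_odds <- function(counts, bg, pc) {
  L <- ncol(counts)
  lo <- matrix(0, 4, L)
  for (i in seq_len(L)) {
    tot <- sum(counts[, i])
    for (j in 1:4)
      lo[j, i] <- log2((counts[j, i] + pc * bg[j]) / (tot + pc) / bg[j])
  }
  rownames(lo) <- c("A", "C", "G", "T")
  lo
}

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# Per-window naive scoring of both strands.
oracle_scan <- function(counts, bg, pc, seq) {
  lo <- oracle_log_odds(counts, bg, pc)
  L <- ncol(counts)
  n <- nchar(seq)
  score_word <- function(word) {
    b <- strsplit(word, "")[[1]]
    if (any(!b %in% c("A", "C", "G", "T"))) return(NA_real_)
    sum(vapply(seq_len(L), function(i) lo[b[i], i], numeric(1)))
  }
  out <- NULL
  for (pos in seq_len(max(0, n - L + 1)) - 1L) {
    w <- substr(seq, pos + 1, pos + L)
    sf <- score_word(w)
    sr <- score_word(oracle_revcomp(w))
    if (!is.na(sf)) out <- rbind(out, data.frame(position = pos, strand = "+", score = sf))
    if (!is.na(sr)) out <- rbind(out, data.frame(position = pos, strand = "-", score = sr))
  }
  if (is.null(out)) data.frame(position = integer(0), strand = character(0),
                               score = numeric(0))
  else out[order(out$position, out$strand), , drop = FALSE]
}

# Exact tail P(score >= s) by enumerating all 4^L words under background.
oracle_null_tail <- function(counts, bg, pc, scores) {
  lo <- oracle_log_odds(counts, bg, pc)
  L <- ncol(counts)
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  word_scores <- apply(grid, 1, function(ix)
    sum(lo[cbind(ix, seq_len(L))]))
  word_probs <- apply(grid, 1, function(ix) prod(bg[ix]))
  vapply(scores, function(s) sum(word_probs[word_scores >= s]), numeric(1))
}

oracle_venn <- function(a, b, c) {
  a <- unique(a); b <- unique(b); c <- unique(c)
  n <- function(x) length(x)
  c(a_only = n(setdiff(setdiff(a, b), c)),
    b_only = n(setdiff(setdiff(b, a), c)),
    c_only = n(setdiff(setdiff(c, a), b)),
    ab_only = n(setdiff(intersect(a, b), c)),
    ac_only = n(setdiff(intersect(a, c), b)),
    bc_only = n(setdiff(intersect(b, c), a)),
    abc = n(intersect(intersect(a, b), c)))
}
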