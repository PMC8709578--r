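# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Signal a user-level error (bad input, missing file).
#' CLI maps these to exit status 1; everything else to 2.
#' @noRd
user_error <- function(msg, call. = FALSE) {
  stop(structure(
    class = c("tetherscan_user_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

# Derive k reproducible 31-bit substream seeds from one master seed.
# Used so that independent stages (placement, sequence, tags, permutations)
# consume disjoint random streams.
derive_seeds <- function(seed, k, labels = NULL) {
  s <- withr::with_seed(as.integer(seed), sample.int(2147483646L, k))
  if (!is.null(labels)) names(s) <- labels
  s
}

# Complement/reverse-complement for plain ACGTN character strings.
revcomp <- function(seq) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         vapply(seq, function(s) {
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
         }, character(1), USE.NAMES = FALSE))
}

DNA_BASES4 <- c("A", "C", "G", "T")

# Map sequence characters to 1..4 (A,C,G,T); anything else becomes NA.
encode_dna <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], DNA_BASES4)
}
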