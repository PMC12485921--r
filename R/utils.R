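#' @noRd
AA_ALPHABET20 <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

#' Derive a reproducible child seed for a named pipeline stage
#'
#' Child seeds keep independent stages decoupled: re-running one stage with
#' the same master seed reproduces its stream regardless of what ran before.
#' The derivation is a small deterministic hash of the stage name folded into
#' the master seed, kept below 2^31 so it is always a valid R integer seed.
#'
#' @param seed Master seed (integer).
#' @param stage Stage name (character scalar).
#' @return An integer seed in `[0, 2^31)`.
#' @export
#' @examples
#' derive_seed(1, "cohort")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (code in utf8ToInt(stage)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer((abs(seed) * 7919 + h) %% 2147483647)
}

#' Run code with a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Check that a character vector holds amino-acid sequences (20 letters + X)
#' @noRd
assert_aa <- function(x, what = "sequence") {
  if (any(!nzchar(x))) {
    abort(sprintf("empty %s is not allowed", what))
  }
  bad <- grepl(sprintf("[^%sX]", paste(AA_ALPHABET20, collapse = "")), x)
  if (any(bad)) {
    abort(sprintf(
      "%s contains characters outside the 20-letter amino-acid alphabet plus X (first offender: %s)",
      what, x[which(bad)[1L]]
    ))
  }
  invisible(x)
}

#' Split sequences into one-character vectors
#' @noRd
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)

#' Shannon entropy (bits) of a residue vector
#' @noRd
entropy_bits <- function(chars) {
  tab <- table(chars)
  p <- tab / sum(tab)
  -sum(p * log2(p))
}

#' @noRd
`%or%` <- function(a, b) if (length(a) == 0 || (length(a) == 1 && is.na(a))) b else a
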