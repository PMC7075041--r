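`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random DNA sequence
#'
#' Uniform i.i.d. bases; draws from the caller's RNG stream.
#'
#' @param n Number of bases.
#' @return A single character string of length `n` over A/C/G/T.
#' @export
random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Hamming distance of `flank_int` (utf8 codes) against `read_int` at each
# 0-based offset in `offsets`; offsets must keep the window inside the read.
hamming_at_offsets <- function(read_int, flank_int, offsets) {
  m <- length(flank_int)
  if (!length(offsets)) return(integer(0))
  idx <- outer(offsets, seq_len(m), `+`)
  win <- matrix(read_int[idx], nrow = length(offsets))
  rowSums(win != matrix(flank_int, nrow = length(offsets), ncol = m, byrow = TRUE))
}

# data.frame constructor without deparse/coercion overhead; columns must
# be equal-length atomic vectors (used on per-read hot paths).
fast_df <- function(...) {
  x <- list(...)
  structure(x, class = "data.frame",
            row.names = c(NA_integer_, -length(x[[1]])))
}

phred_to_string <- function(q) intToUtf8(pmin(q, 93L) + 33L)

string_to_phred <- function(s) utf8ToInt(s) - 33L

is_dna <- function(x, allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  !is.na(x) & grepl(pat, x)
}
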