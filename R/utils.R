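## Small sequence utilities shared across modules. All coordinates in this
## package are 0-based half-open internally; 1-based only in human-facing
## report helpers.

#' Reverse complement of character sequences
#'
#' Vectorized reverse complement over plain character DNA strings
#' (alphabet A/C/G/T/N).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Circular substring
#'
#' Extract `len` bases starting at 0-based position `start` from a circular
#' sequence, wrapping past the end if needed.
#'
#' @param seq single character string (the circular reference).
#' @param start 0-based start position(s), each in `[0, nchar(seq))`.
#' @param len substring length(s).
#' @return character vector of substrings.
#' @export
circular_substr <- function(seq, start, len) {
  L <- nchar(seq)
  stopifnot(L > 0L, all(start >= 0L), all(start < L), all(len >= 0L),
            all(len <= L))
  n <- max(length(start), length(len))
  start <- rep_len(start, n)
  len <- rep_len(len, n)
  end <- start + len            # exclusive, may exceed L
  out <- substr(rep(seq, n), start + 1L, pmin(end, L))
  wraps <- end > L
  if (any(wraps)) {
    out[wraps] <- paste0(out[wraps],
                         substr(rep(seq, sum(wraps)), 1L, end[wraps] - L))
  }
  out
}

#' Generate a random DNA sequence
#'
#' Uniform i.i.d. bases; uses the current RNG state.
#'
#' @param n length in bases.
#' @return a single character string of length `n`.
#' @export
random_dna <- function(n) {
  stopifnot(n >= 0)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Hamming distance between two equal-length strings (N never matches
## anything but itself is irrelevant here: callers treat N as mismatch by
## comparing raw characters, which makes N != A/C/G/T a mismatch and
## N == N a match; pattern sequences never contain N).
hamming_chr <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(charToRaw(a) != charToRaw(b))
}

## Phred+33 helpers -----------------------------------------------------

#' Convert a Phred+33 quality string to integer scores
#' @param qual character vector of quality strings.
#' @return list of integer vectors (one per input string).
#' @export
phred_to_int <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

#' Convert integer Phred scores to a Phred+33 quality string
#' @param q integer vector of Phred scores (0-93).
#' @return single quality string.
#' @export
int_to_phred <- function(q) {
  stopifnot(all(q >= 0), all(q <= 93))
  rawToChar(as.raw(q + 33L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
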