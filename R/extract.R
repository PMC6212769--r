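## Spacer extraction and identity deduplication. Candidate spacers are the
## sequences strictly between consecutive CRISPR repeat matches; statistics
## downstream use the distinct sequence set ("every spacer counts once"),
## with read support retained for reporting only.

#' Extract inter-repeat spacer candidates from one read
#'
#' For each consecutive pair of (resolved, non-overlapping) repeat matches,
#' returns the substring strictly between the end of the first repeat and
#' the start of the next. Candidates outside the length bounds, containing
#' `N`, or with zero gap are dropped and counted.
#'
#' @param seq read sequence (array orientation).
#' @param matches resolved repeat matches from [find_repeats()].
#' @param repeat_length repeat length in nt.
#' @param min_len,max_len spacer length bounds (defaults 20 and 50 nt;
#'   out-of-bounds gaps are PCR/sequencing artifacts).
#' @return list with `spacers` (character vector, 5' to 3' order) and drop
#'   counts `n_short_long`, `n_with_n`, `n_zero_gap`.
#' @export
extract_spacers <- function(seq, matches, repeat_length,
                            min_len = 20L, max_len = 50L) {
  out <- list(spacers = character(0), n_short_long = 0L, n_with_n = 0L,
              n_zero_gap = 0L)
  if (nrow(matches) < 2L) return(out)
  st <- sort(matches$start)
  gap_start <- st[-length(st)] + repeat_length   # 0-based, inclusive
  gap_end <- st[-1L]                             # 0-based, exclusive
  len <- gap_end - gap_start
  out$n_zero_gap <- sum(len == 0L)
  ok <- len > 0L
  if (!any(ok)) return(out)
  s <- substring(seq, gap_start[ok] + 1L, gap_end[ok])
  bad_len <- nchar(s) < min_len | nchar(s) > max_len
  out$n_short_long <- sum(bad_len)
  s <- s[!bad_len]
  has_n <- grepl("N", s, fixed = TRUE)
  out$n_with_n <- sum(has_n)
  out$spacers <- s[!has_n]
  out
}

#' Extract spacers from a preprocessed library
#'
#' Applies [extract_spacers()] to every retained read.
#'
#' @param prep a `preprocessed_reads` object from [preprocess_reads()].
#' @param repeat_length repeat length in nt.
#' @param min_len,max_len spacer length bounds.
#' @return list with `spacers` (all extracted sequences, with repeats) and
#'   aggregated drop counts.
#' @export
extract_all_spacers <- function(prep, repeat_length,
                                min_len = 20L, max_len = 50L) {
  per_read <- mapply(function(s, m)
    extract_spacers(s, m, repeat_length, min_len, max_len),
    prep$reads$seq, prep$matches, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  list(spacers = unlist(lapply(per_read, `[[`, "spacers")) %||% character(0),
       n_short_long = sum(vapply(per_read, `[[`, integer(1), "n_short_long")),
       n_with_n = sum(vapply(per_read, `[[`, integer(1), "n_with_n")),
       n_zero_gap = sum(vapply(per_read, `[[`, integer(1), "n_zero_gap")))
}

#' Deduplicate spacer sequences
#'
#' Collapses extracted sequences to one record per distinct string.
#' Deduplication is identity-based and orientation-naive: a spacer and its
#' reverse complement are distinct records, because reads have already been
#' normalized to array orientation and strand is recovered at mapping time.
#'
#' @param seqs character vector of extracted spacer sequences.
#' @return data frame of class `spacer_table` with columns `sequence`,
#'   `length` and `support` (occurrence count), ordered by decreasing
#'   support then sequence.
#' @export
dedupe_spacers <- function(seqs) {
  if (length(seqs) == 0L) {
    out <- data.frame(sequence = character(0), length = integer(0),
                      support = integer(0), stringsAsFactors = FALSE)
  } else {
    tab <- table(seqs)
    out <- data.frame(sequence = names(tab), length = nchar(names(tab)),
                      support = as.integer(tab), stringsAsFactors = FALSE)
    out <- out[order(-out$support, out$sequence), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("spacer_table", "data.frame")
  out
}
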