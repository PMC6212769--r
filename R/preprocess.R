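## Read preprocessing: Phred-threshold 3' trimming, approximate CRISPR
## repeat detection (Hamming distance, both orientations), orientation
## normalization, and selection of reads carrying >= 2 repeats.

#' Quality-trim a read at its 3' end
#'
#' Two deterministic rules are available. `"first_low"` (default) scans
#' 5' to 3' and truncates at the first base with quality below
#' `q_threshold`, so every retained base has quality at or above the
#' threshold. `"sliding"` truncates before the first complete window of
#' `window` bases whose mean quality falls below the threshold; windows
#' shorter than `window` at the 3' end are not evaluated. Both rules are
#' idempotent.
#'
#' @param seq read sequence (single string).
#' @param qual Phred+33 quality string of the same length.
#' @param q_threshold minimum acceptable Phred score (default 20).
#' @param rule trimming rule, `"first_low"` or `"sliding"`.
#' @param window window size for the sliding rule.
#' @return list with elements `seq` and `qual` (possibly empty strings).
#' @export
trim_read <- function(seq, qual, q_threshold = 20,
                      rule = c("first_low", "sliding"), window = 4L) {
  rule <- match.arg(rule)
  stopifnot(nchar(seq) == nchar(qual))
  q <- as.integer(charToRaw(qual)) - 33L
  n <- length(q)
  cut <- n + 1L
  if (rule == "first_low") {
    low <- which(q < q_threshold)
    if (length(low)) cut <- low[1L]
  } else if (n >= window) {
    cs <- cumsum(c(0L, q))
    means <- (cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]) / window
    low <- which(means < q_threshold)
    if (length(low)) cut <- low[1L]
  }
  list(seq = substr(seq, 1L, cut - 1L), qual = substr(qual, 1L, cut - 1L))
}

## Vectorized trimming over a reads data frame.
trim_reads <- function(reads, q_threshold = 20, rule = "first_low",
                       window = 4L) {
  for (i in seq_len(nrow(reads))) {
    t <- trim_read(reads$seq[i], reads$qual[i], q_threshold, rule, window)
    reads$seq[i] <- t$seq
    reads$qual[i] <- t$qual
  }
  reads
}

#' Find approximate CRISPR repeat occurrences in a read
#'
#' Reports every offset, on both the forward and reverse-complement
#' orientation, at which the Hamming distance between the repeat and the
#' read window is at most `max_mismatch` (default 2, the standard
#' two-mismatch allowance). `N` bases count as mismatches. With
#' `resolve = TRUE` overlapping matches are reduced to a non-overlapping
#' set by repeatedly keeping the match with the fewest mismatches
#' (ties broken leftmost) and discarding matches overlapping it, since
#' repeats in a physical array never overlap.
#'
#' @param seq read sequence (single string).
#' @param repeat_seq CRISPR repeat sequence.
#' @param max_mismatch maximum Hamming distance (default 2).
#' @param resolve resolve overlapping matches (default `TRUE`).
#' @return data frame with columns `start` (0-based), `orientation`
#'   (`"F"` forward, `"R"` reverse-complement) and `mismatches`,
#'   sorted by `start`.
#' @export
find_repeats <- function(seq, repeat_seq, max_mismatch = 2L,
                         resolve = TRUE) {
  out <- find_repeats_batch(seq, repeat_seq, max_mismatch)[[1L]]
  if (resolve) out <- resolve_repeat_overlaps(out, nchar(repeat_seq))
  out
}

## Batch repeat search over many reads via Biostrings::vmatchPattern.
## Returns a list of unresolved match data frames (one per read).
find_repeats_batch <- function(seqs, repeat_seq, max_mismatch = 2L) {
  stopifnot(max_mismatch >= 0L)
  m <- nchar(repeat_seq)
  subj <- Biostrings::DNAStringSet(seqs)
  w <- Biostrings::width(subj)
  starts <- function(pattern) {
    mi <- Biostrings::vmatchPattern(pattern, subj,
                                    max.mismatch = max_mismatch,
                                    fixed = TRUE)
    BiocGenerics::start(mi)
  }
  sf <- starts(repeat_seq)
  sr <- starts(revcomp(repeat_seq))
  rc_rep <- revcomp(repeat_seq)
  lapply(seq_along(seqs), function(i) {
    ## drop matches hanging over the read ends (possible at max_mismatch>0)
    f <- sf[[i]]; f <- f[f >= 1L & f + m - 1L <= w[i]]
    r <- sr[[i]]; r <- r[r >= 1L & r + m - 1L <= w[i]]
    df <- data.frame(
      start = c(f, r) - 1L,
      orientation = rep(c("F", "R"), c(length(f), length(r))),
      stringsAsFactors = FALSE)
    if (nrow(df)) {
      win <- substring(seqs[i], df$start + 1L, df$start + m)
      pat <- ifelse(df$orientation == "F", repeat_seq, rc_rep)
      df$mismatches <- mapply(hamming_chr, win, pat, USE.NAMES = FALSE)
      df <- df[df$mismatches <= max_mismatch, , drop = FALSE]
      df <- df[order(df$start, df$orientation), , drop = FALSE]
      rownames(df) <- NULL
    } else df$mismatches <- integer(0)
    df
  })
}

#' Resolve overlapping repeat matches
#'
#' Best-first selection: repeatedly accept the remaining match with the
#' fewest mismatches (ties broken by leftmost start), then discard all
#' matches overlapping the accepted one.
#'
#' @param matches match data frame from [find_repeats()].
#' @param repeat_length repeat length in nt.
#' @return non-overlapping subset, sorted by `start`.
#' @export
resolve_repeat_overlaps <- function(matches, repeat_length) {
  if (nrow(matches) <= 1L) return(matches)
  cand <- matches[order(matches$mismatches, matches$start), , drop = FALSE]
  kept <- matches[0L, , drop = FALSE]
  while (nrow(cand)) {
    top <- cand[1L, , drop = FALSE]
    kept <- rbind(kept, top)
    ov <- cand$start < top$start + repeat_length &
          cand$start + repeat_length > top$start
    cand <- cand[!ov, , drop = FALSE]
  }
  kept <- kept[order(kept$start), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

## Mirror matches onto the reverse-complemented read.
flip_matches <- function(matches, read_length, repeat_length) {
  matches$start <- read_length - matches$start - repeat_length
  matches$orientation <- ifelse(matches$orientation == "F", "R", "F")
  matches[order(matches$start), , drop = FALSE]
}

#' Select reads carrying at least two CRISPR repeats
#'
#' @param matches_list list of resolved match data frames, one per read.
#' @param min_matches minimum repeat count to retain a read (default 2,
#'   the two flanking repeats needed to delimit a spacer).
#' @return logical vector marking retained reads.
#' @export
select_spacer_reads <- function(matches_list, min_matches = 2L) {
  vapply(matches_list, nrow, integer(1)) >= min_matches
}

#' Preprocess an amplicon sequencing library
#'
#' Runs the full preprocessing stage: quality trimming, approximate repeat
#' detection on both orientations, wholesale reverse-complementation of
#' reads whose repeat matches are predominantly in reverse-complement
#' orientation (so spacers are always reported in array orientation),
#' overlap resolution, and retention of reads with at least `min_matches`
#' repeats. Paired mates are processed independently.
#'
#' @param reads reads data frame (columns `id`, `mate`, `seq`, `qual`),
#'   e.g. from [read_fastq()] or [simulate_reads()].
#' @param repeat_seq CRISPR repeat sequence.
#' @param max_mismatch Hamming mismatch allowance (default 2).
#' @param q_threshold Phred trimming threshold (default 20).
#' @param trim_rule `"first_low"` or `"sliding"` (see [trim_read()]).
#' @param window window size for the sliding rule.
#' @param min_matches minimum repeat count to retain a read.
#' @return list of class `preprocessed_reads` with elements `reads` (the
#'   retained, oriented reads, with a logical `flipped` column), `matches`
#'   (resolved repeat matches per retained read) and `stats` (counts of
#'   input, trimmed-empty, flipped, retained and discarded reads).
#' @export
preprocess_reads <- function(reads, repeat_seq, max_mismatch = 2L,
                             q_threshold = 20, trim_rule = "first_low",
                             window = 4L, min_matches = 2L) {
  n_input <- nrow(reads)
  reads <- trim_reads(reads, q_threshold, trim_rule, window)
  n_empty <- sum(nchar(reads$seq) == 0L)
  reads <- reads[nchar(reads$seq) >= nchar(repeat_seq), , drop = FALSE]
  m <- nchar(repeat_seq)
  raw <- find_repeats_batch(reads$seq, repeat_seq, max_mismatch)
  n_rev <- vapply(raw, function(d) sum(d$orientation == "R"), integer(1))
  n_fwd <- vapply(raw, function(d) sum(d$orientation == "F"), integer(1))
  flip <- n_rev > n_fwd
  if (any(flip)) {
    reads$seq[flip] <- revcomp(reads$seq[flip])
    reads$qual[flip] <- vapply(reads$qual[flip], function(q)
      paste(rev(strsplit(q, "")[[1L]]), collapse = ""), character(1),
      USE.NAMES = FALSE)
    rl <- nchar(reads$seq)
    raw[flip] <- lapply(which(flip), function(i)
      flip_matches(raw[[i]], rl[i], m))
  }
  resolved <- lapply(raw, resolve_repeat_overlaps, repeat_length = m)
  keep <- select_spacer_reads(resolved, min_matches)
  reads$flipped <- flip
  out <- list(reads = reads[keep, , drop = FALSE],
              matches = resolved[keep],
              stats = list(n_input = n_input,
                           n_empty_after_trim = n_empty,
                           n_flipped = sum(flip),
                           n_retained = sum(keep),
                           n_discarded = n_input - sum(keep)))
  class(out) <- "preprocessed_reads"
  out
}

#' @export
print.preprocessed_reads <- function(x, ...) {
  s <- x$stats
  cat("Preprocessed reads\n")
  cat(sprintf("  input %d, retained with >=2 repeats %d, discarded %d\n",
              s$n_input, s$n_retained, s$n_discarded))
  cat(sprintf("  empty after trimming %d, reverse-complemented %d\n",
              s$n_empty_after_trim, s$n_flipped))
  invisible(x)
}
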