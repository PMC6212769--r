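# Independent brute-force oracles, deliberately written against the problem
# statement rather than the package internals: plain all-offset scans over
# character vectors.

# All offsets (both orientations) where the Hamming distance between
# `pattern` and the read window is <= max_mm. N counts as a mismatch.
# Returns a data frame like find_repeats(..., resolve = FALSE).
brute_repeat_scan <- function(seq, pattern, max_mm) {
  n <- nchar(seq)
  m <- nchar(pattern)
  scan_one <- function(pat, orientation) {
    if (m > n) return(NULL)
    s <- strsplit(seq, "")[[1L]]
    p <- strsplit(pat, "")[[1L]]
    mm <- integer(n - m + 1L)
    for (j in seq_len(m))
      mm <- mm + (s[j:(n - m + j)] != p[j])
    hit <- which(mm <= max_mm)
    if (!length(hit)) return(NULL)
    data.frame(start = hit - 1L, orientation = orientation,
               mismatches = mm[hit], stringsAsFactors = FALSE)
  }
  rc <- function(x) {
    paste(rev(chartr("ACGTN", "TGCAN", strsplit(x, "")[[1L]])), collapse = "")
  }
  out <- rbind(scan_one(pattern, "F"), scan_one(rc(pattern), "R"))
  if (is.null(out))
    return(data.frame(start = integer(0), orientation = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  out <- out[order(out$start, out$orientation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# All exact occurrences of `spacer` on both strands of the circular
# reference, by scanning the doubled sequence with substring comparison.
brute_circular_hits <- function(spacer, reference) {
  L <- nchar(reference)
  k <- nchar(spacer)
  ext <- paste0(reference, substr(reference, 1L, k - 1L))
  rc <- function(x) {
    paste(rev(chartr("ACGTN", "TGCAN", strsplit(x, "")[[1L]])), collapse = "")
  }
  scan_one <- function(pat, strand) {
    wins <- substring(ext, 1:L, 1:L + k - 1L)
    hit <- which(wins == pat)
    if (!length(hit)) return(NULL)
    data.frame(position = hit - 1L, strand = strand,
               stringsAsFactors = FALSE)
  }
  out <- rbind(scan_one(spacer, "+"), scan_one(rc(spacer), "-"))
  if (is.null(out))
    return(data.frame(position = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random DNA string helper independent of the package's generator.
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# Build a reads data frame from plain sequences at uniform quality q.
make_reads <- function(seqs, q = 37L, mate = 1L) {
  data.frame(id = sprintf("r%03d", seq_along(seqs)),
             mate = rep(mate, length(seqs)),
             seq = seqs,
             qual = vapply(nchar(seqs),
                           function(n) paste(rep(rawToChar(as.raw(q + 33L)), n),
                                             collapse = ""),
                           character(1)),
             stringsAsFactors = FALSE)
}

# Small simulation config used across tests (50 kb chromosome keeps
# everything fast while leaving random 33-mers effectively unique).
small_config <- function(...) {
  args <- list(...)
  defaults <- list(chromosome_length = 50000, plasmid_length = 4000,
                   n_events = 40, per_base_error_rate = 0, seed = 42)
  do.call(sim_config, utils::modifyList(defaults, args))
}
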