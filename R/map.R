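## Hierarchical spacer mapping: exact search on both strands of circular
## references, plasmid first; spacers absent from the plasmid are mapped to
## the chromosome and non-unique chromosomal matches are discarded.
## Positions are 0-based leftmost forward-strand coordinates.

#' Find all occurrences of a spacer on a circular reference
#'
#' Searches both strands, including occurrences spanning the circular
#' origin (the reference is scanned with its first `length(spacer) - 1`
#' bases appended, and positions reported modulo the reference length).
#' Matching is exact by default; a Hamming mismatch tolerance is available
#' for robustness studies.
#'
#' @param spacer spacer sequence (>= 15 nt recommended; shorter sequences
#'   risk spurious multi-hits).
#' @param reference circular reference sequence (single string).
#' @param max_mismatch Hamming tolerance (default 0, exact).
#' @return data frame with columns `position` (0-based leftmost coordinate
#'   on the forward strand) and `strand` (`"+"` or `"-"`), sorted by
#'   position.
#' @export
find_hits <- function(spacer, reference, max_mismatch = 0L) {
  k <- nchar(spacer)
  L <- nchar(reference)
  stopifnot(k >= 1L, k <= L)
  ext <- Biostrings::DNAString(paste0(reference, substr(reference, 1L, k - 1L)))
  scan <- function(pat) {
    m <- Biostrings::matchPattern(pat, ext, max.mismatch = max_mismatch,
                                  fixed = TRUE)
    s <- BiocGenerics::start(m)
    s <- s[s >= 1L & s + k - 1L <= length(ext)]
    s0 <- s - 1L
    s0[s0 < L]
  }
  fwd <- scan(spacer)
  rev <- scan(revcomp(spacer))
  out <- data.frame(position = c(fwd, rev),
                    strand = rep(c("+", "-"), c(length(fwd), length(rev))),
                    stringsAsFactors = FALSE)
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Exact hits for many spacers against one circular reference, batched by
## spacer width through a PDict (fast enough for Mb-scale chromosomes).
## Returns a list (one element per spacer) of hit data frames as in
## find_hits().
hits_batch_exact <- function(spacers, reference) {
  L <- nchar(reference)
  out <- vector("list", length(spacers))
  widths <- nchar(spacers)
  for (w in unique(widths)) {
    idx <- which(widths == w)
    ext <- Biostrings::DNAString(paste0(reference,
                                        substr(reference, 1L, w - 1L)))
    collect <- function(seqs) {
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs))
      mi <- Biostrings::matchPDict(pd, ext)
      lapply(BiocGenerics::start(mi), function(s) {
        s0 <- s - 1L
        s0[s0 < L]
      })
    }
    fwd <- collect(spacers[idx])
    rev <- collect(revcomp(spacers[idx]))
    for (j in seq_along(idx)) {
      df <- data.frame(position = c(fwd[[j]], rev[[j]]),
                       strand = rep(c("+", "-"),
                                    c(length(fwd[[j]]), length(rev[[j]]))),
                       stringsAsFactors = FALSE)
      df <- df[order(df$position, df$strand), , drop = FALSE]
      rownames(df) <- NULL
      out[[idx[j]]] <- df
    }
  }
  out
}

#' Map unique spacers hierarchically (plasmid first, then chromosome)
#'
#' Each spacer is first searched against the plasmid: any plasmid hit
#' assigns `target = "plasmid"` (a position is reported only when the
#' plasmid hit is unique; multi-hit plasmid spacers keep the plasmid
#' assignment with the position withheld). Spacers without a plasmid hit
#' are searched against the chromosome: exactly one hit assigns
#' `target = "chromosome"` with position and strand; more than one hit is
#' `"ambiguous"` (discarded from downstream statistics); no hit is
#' `"unmapped"`. Both references are treated as circular.
#'
#' @param spacers a `spacer_table` from [dedupe_spacers()], or a character
#'   vector of spacer sequences.
#' @param plasmid,chromosome circular reference sequences.
#' @param max_mismatch Hamming tolerance (default 0, exact matching).
#' @return data frame of class `mapping_results` with columns `sequence`,
#'   `support`, `target`, `position`, `strand`, `n_hits`.
#' @export
map_spacers <- function(spacers, plasmid, chromosome, max_mismatch = 0L) {
  if (is.character(spacers))
    spacers <- data.frame(sequence = spacers,
                          support = rep(1L, length(spacers)),
                          stringsAsFactors = FALSE)
  seqs <- spacers$sequence
  if (max_mismatch == 0L) {
    p_hits <- hits_batch_exact(seqs, plasmid)
    c_hits <- hits_batch_exact(seqs, chromosome)
  } else {
    p_hits <- lapply(seqs, find_hits, reference = plasmid,
                     max_mismatch = max_mismatch)
    c_hits <- lapply(seqs, find_hits, reference = chromosome,
                     max_mismatch = max_mismatch)
  }
  n <- length(seqs)
  target <- character(n)
  position <- rep(NA_integer_, n)
  strand <- rep(NA_character_, n)
  n_hits <- integer(n)
  for (i in seq_len(n)) {
    np <- nrow(p_hits[[i]])
    nc <- nrow(c_hits[[i]])
    if (np >= 1L) {
      target[i] <- "plasmid"
      n_hits[i] <- np
      if (np == 1L) {       # position reported only for unique plasmid hits
        position[i] <- p_hits[[i]]$position
        strand[i] <- p_hits[[i]]$strand
      }
    } else if (nc == 1L) {
      target[i] <- "chromosome"
      n_hits[i] <- 1L
      position[i] <- c_hits[[i]]$position
      strand[i] <- c_hits[[i]]$strand
    } else if (nc > 1L) {
      target[i] <- "ambiguous"
      n_hits[i] <- nc
    } else {
      target[i] <- "unmapped"
      n_hits[i] <- 0L
    }
  }
  out <- data.frame(sequence = seqs,
                    support = spacers$support %||% rep(1L, n),
                    target = target, position = position, strand = strand,
                    n_hits = n_hits, stringsAsFactors = FALSE)
  class(out) <- c("mapping_results", "data.frame")
  out
}

#' Chromosome vs plasmid origin fractions
#'
#' Fractions are computed over mapped unique spacers; ambiguous and
#' unmapped spacers are excluded from the denominator and reported.
#'
#' @param results a `mapping_results` data frame from [map_spacers()].
#' @return list with `fraction_chromosome`, `fraction_plasmid`, `n_mapped`,
#'   `n_excluded` and the per-category counts.
#' @export
origin_fractions <- function(results) {
  counts <- table(factor(results$target,
                         levels = c("plasmid", "chromosome", "ambiguous",
                                    "unmapped")))
  n_mapped <- counts[["plasmid"]] + counts[["chromosome"]]
  if (n_mapped == 0L)
    stop("no spacers mapped to plasmid or chromosome; cannot compute ",
         "origin fractions")
  list(fraction_chromosome = counts[["chromosome"]] / n_mapped,
       fraction_plasmid = counts[["plasmid"]] / n_mapped,
       n_mapped = n_mapped,
       n_excluded = counts[["ambiguous"]] + counts[["unmapped"]],
       counts = as.list(counts))
}

#' Strand balance of chromosome-mapped spacers
#'
#' Forward-strand fraction among uniquely chromosome-mapped spacers, with a
#' two-sided exact binomial test against 0.5 (naive adaptation is expected
#' to show no strand bias).
#'
#' @param results a `mapping_results` data frame from [map_spacers()].
#' @return list with `fraction_forward`, `p_value`, `n_forward`,
#'   `n_reverse`.
#' @export
strand_balance <- function(results) {
  chr <- results[results$target == "chromosome", , drop = FALSE]
  if (nrow(chr) == 0L)
    stop("no chromosome-mapped spacers; cannot test strand balance")
  n_f <- sum(chr$strand == "+")
  n <- nrow(chr)
  bt <- stats::binom.test(n_f, n, p = 0.5, alternative = "two.sided")
  list(fraction_forward = n_f / n, p_value = bt$p.value,
       n_forward = n_f, n_reverse = n - n_f)
}
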