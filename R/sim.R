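## Synthetic-data module: references, acquisition events, expanded-array
## amplicons and paired-end reads with known ground truth. Emulates the
## inputs of a naive-adaptation amplicon sequencing experiment (2 x 150
## paired-end reads of PCR products spanning the leader-proximal end of an
## expanded CRISPR array).

## Default fixtures. The repeat is the canonical 29-nt E. coli type I-E
## CRISPR repeat; leader and ancestral spacer are arbitrary fixed strings.
## These are configuration defaults, not claims about any particular strain.
DEFAULT_REPEAT <- "GTGTTCCCCGCGCCAGCGGGGATAAACCG"
DEFAULT_LEADER <- paste0("ATTTAGGTAGATTGTGACTGGCTTAAAAAATCATTAATTAATAATAGGTT",
                         "ATGGTACTAT")
DEFAULT_OLD_SPACER <- "TGCCGATAACGGTCTGCATAAGGCTCAGATTGC"

#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic amplicon
#' sequencing library generator. Defaults describe an \emph{E. coli}-scale
#' experiment: a 4.64-Mb circular chromosome, a small expression plasmid,
#' a 29-nt CRISPR repeat, 33-nt spacers, 2 x 150 paired-end reads, and the
#' regime reported for naive adaptation (most spacers chromosomal, origin
#' and terminus regions several-fold enriched, no strand bias).
#'
#' @param chromosome_length circular chromosome length in bp.
#' @param plasmid_length circular plasmid length in bp (Cas1-Cas2 expression
#'   vector scale).
#' @param repeat_seq CRISPR repeat sequence (character).
#' @param leader_seq leader sequence placed 5' of the first repeat.
#' @param amplicon_leader_len how many 3'-terminal bases of the leader the
#'   PCR amplicon retains (the forward primer anneals inside the leader;
#'   default 20 nt, which lets mate 1 span leader-repeat-spacer-repeat at
#'   the default geometry).
#' @param old_spacer ancestral spacer present in the unexpanded array.
#' @param spacer_len_min,spacer_len_max bounds on new-spacer length (nt);
#'   lengths are drawn uniformly from this range.
#' @param n_events number of acquisition events to simulate.
#' @param region_weights named numeric vector of relative sampling weights
#'   for named chromosomal regions (e.g. `c(Ori = 4, Ter = 4)`); positions
#'   outside any named region get `baseline_weight`. Only used when a
#'   region set is supplied to [sample_events()].
#' @param baseline_weight sampling weight outside named regions.
#' @param plasmid_fraction proportion of events drawn from the plasmid.
#' @param strand_balance proportion of events taken from the forward strand.
#' @param read_length read length in nt (both mates).
#' @param per_base_error_rate substitution error probability per base.
#' @param quality_high,quality_low Phred scores assigned to correct and
#'   errored bases respectively (two-valued quality model).
#' @param n_read_pairs number of read pairs; `NULL` (default) sequences each
#'   amplicon exactly once, guaranteeing every event is covered.
#' @param seed integer seed; all generator functions derive their RNG state
#'   from it, so a fixed seed gives byte-identical output.
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(chromosome_length = 50000, n_events = 10, seed = 1)
#' @export
sim_config <- function(chromosome_length = 4641652,
                       plasmid_length = 6600,
                       repeat_seq = DEFAULT_REPEAT,
                       leader_seq = DEFAULT_LEADER,
                       amplicon_leader_len = 20,
                       old_spacer = DEFAULT_OLD_SPACER,
                       spacer_len_min = 33,
                       spacer_len_max = 33,
                       n_events = 1000,
                       region_weights = c(Ori = 4, Ter = 4, Cr = 1),
                       baseline_weight = 1,
                       plasmid_fraction = 0.15,
                       strand_balance = 0.5,
                       read_length = 150,
                       per_base_error_rate = 0.001,
                       quality_high = 37,
                       quality_low = 11,
                       n_read_pairs = NULL,
                       seed = 1L) {
  cfg <- list(chromosome_length = as.integer(chromosome_length),
              plasmid_length = as.integer(plasmid_length),
              repeat_seq = toupper(repeat_seq),
              leader_seq = toupper(leader_seq),
              amplicon_leader_len = as.integer(amplicon_leader_len),
              old_spacer = toupper(old_spacer),
              spacer_len_min = as.integer(spacer_len_min),
              spacer_len_max = as.integer(spacer_len_max),
              n_events = as.integer(n_events),
              region_weights = region_weights,
              baseline_weight = baseline_weight,
              plasmid_fraction = plasmid_fraction,
              strand_balance = strand_balance,
              read_length = as.integer(read_length),
              per_base_error_rate = per_base_error_rate,
              quality_high = as.integer(quality_high),
              quality_low = as.integer(quality_low),
              n_read_pairs = if (is.null(n_read_pairs)) NULL
                             else as.integer(n_read_pairs),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$chromosome_length > 0, cfg$plasmid_length > 0,
            nchar(cfg$repeat_seq) > 0, nchar(cfg$leader_seq) > 0,
            cfg$spacer_len_min > 0,
            cfg$spacer_len_max >= cfg$spacer_len_min,
            cfg$n_events >= 0,
            cfg$plasmid_fraction >= 0, cfg$plasmid_fraction <= 1,
            cfg$strand_balance >= 0, cfg$strand_balance <= 1,
            cfg$read_length > 0,
            cfg$per_base_error_rate >= 0, cfg$per_base_error_rate < 1,
            cfg$quality_high >= 0, cfg$quality_high <= 93,
            cfg$quality_low >= 0, cfg$quality_low <= 93,
            length(cfg$seed) == 1L, !is.na(cfg$seed))
  if (length(cfg$region_weights)) {
    if (any(cfg$region_weights < 0) || all(c(cfg$region_weights, cfg$baseline_weight) == 0))
      stop("region weights must be >= 0 with at least one weight > 0")
  }
  stopifnot(cfg$amplicon_leader_len >= 0,
            cfg$amplicon_leader_len <= nchar(cfg$leader_seq))
  if (2L * nchar(cfg$repeat_seq) + cfg$spacer_len_max > cfg$read_length)
    warning("repeat-spacer-repeat unit (", 2L * nchar(cfg$repeat_seq) +
            cfg$spacer_len_max, " nt) exceeds read_length (",
            cfg$read_length, " nt); single reads cannot span a spacer ",
            "with both flanking repeats")
  else if (cfg$amplicon_leader_len + 2L * nchar(cfg$repeat_seq) +
           cfg$spacer_len_max > cfg$read_length)
    warning("retained leader plus repeat-spacer-repeat exceeds read_length;",
            " mate 1 cannot span a new spacer with both flanking repeats")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  chromosome %d bp (circular), plasmid %d bp (circular)\n",
              x$chromosome_length, x$plasmid_length))
  cat(sprintf("  repeat %d nt, leader %d nt, spacers %d-%d nt\n",
              nchar(x$repeat_seq), nchar(x$leader_seq),
              x$spacer_len_min, x$spacer_len_max))
  cat(sprintf("  %d events, plasmid fraction %.2f, forward-strand %.2f\n",
              x$n_events, x$plasmid_fraction, x$strand_balance))
  cat(sprintf("  reads 2 x %d nt, error rate %.4g, seed %d\n",
              x$read_length, x$per_base_error_rate, x$seed))
  invisible(x)
}

## Replace every exact occurrence of `pattern` (either strand, circular) by
## point mutation until none remains. Occurrences are vanishingly rare in
## random sequence; this enforces the contract that repeat detection cannot
## fire on reference-derived sequence.
scrub_pattern <- function(seq, pattern) {
  k <- nchar(pattern)
  pats <- unique(c(pattern, revcomp(pattern)))
  repeat {
    ext <- paste0(seq, substr(seq, 1L, k - 1L))
    hits <- integer(0)
    subj <- Biostrings::DNAString(ext)
    for (p in pats) {
      m <- Biostrings::matchPattern(p, subj, fixed = TRUE)
      hits <- c(hits, BiocGenerics::start(m))
    }
    if (!length(hits)) return(seq)
    for (h in hits) {
      pos <- ((h - 1L + sample.int(k, 1L) - 1L) %% nchar(seq)) + 1L
      old <- substr(seq, pos, pos)
      substr(seq, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    }
  }
}

#' Generate circular reference sequences
#'
#' Draws pseudo-random chromosome and plasmid sequences of the configured
#' lengths. Any window exactly matching the CRISPR repeat (either strand,
#' including across the circular junction) is mutated away, so repeat
#' detection can never fire on reference-derived spacer sequence.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `chromosome` and `plasmid` (character strings).
#' @export
make_references <- function(config) {
  min_len <- 10L * config$spacer_len_max
  if (config$chromosome_length < min_len || config$plasmid_length < min_len)
    stop("reference lengths must be at least 10 x the maximum spacer ",
         "length (", min_len, " bp) to host distinct spacers")
  set.seed(config$seed)
  chromosome <- scrub_pattern(random_dna(config$chromosome_length),
                              config$repeat_seq)
  plasmid <- scrub_pattern(random_dna(config$plasmid_length),
                           config$repeat_seq)
  list(chromosome = chromosome, plasmid = plasmid)
}

## Piecewise-constant position sampler on the circular chromosome:
## weight w(name) inside each named region interval, baseline elsewhere.
sample_chromosome_positions <- function(n, L, regions, region_weights,
                                        baseline_weight) {
  if (n == 0L) return(integer(0))
  if (is.null(regions)) return(sample.int(L, n, replace = TRUE) - 1L)
  iv <- regions$intervals
  w <- region_weights[iv$name]
  w[is.na(w)] <- baseline_weight
  segs <- data.frame(start = iv$start, end = iv$end, w = as.numeric(w))
  ## complement segments (gaps between sorted intervals, circular)
  o <- order(segs$start)
  segs <- segs[o, , drop = FALSE]
  gaps_start <- c(if (nrow(segs)) segs$end else 0L)
  gaps_end <- c(if (nrow(segs)) c(segs$start[-1L], segs$start[1L] + L) else L)
  gaps <- data.frame(start = gaps_start, end = gaps_end,
                     w = baseline_weight)
  gaps <- gaps[gaps$end > gaps$start, , drop = FALSE]
  segs <- rbind(segs, gaps)
  len <- segs$end - segs$start
  stopifnot(sum(len) == L)
  idx <- sample.int(nrow(segs), n, replace = TRUE, prob = segs$w * len)
  pos <- segs$start[idx] + floor(runif(n) * len[idx])
  as.integer(pos %% L)
}

#' Sample spacer acquisition events
#'
#' Draws `n_events` protospacer positions: plasmid events uniformly, and
#' chromosome events with probability proportional to the configured region
#' weights inside named regions of `regions` and the baseline weight
#' elsewhere, so an origin/terminus enrichment of any factor can be planted
#' by construction. The recorded position is the leftmost (forward-strand)
#' coordinate of the protospacer; minus-strand spacer sequences are reverse
#' complemented, as stored in the array.
#'
#' @param config a [sim_config()] object.
#' @param chromosome,plasmid reference sequences from [make_references()].
#' @param regions optional [region_set()] on the chromosome; `NULL` samples
#'   chromosome positions uniformly.
#' @return a `ground_truth` data frame with columns `source`
#'   (chromosome|plasmid), `position` (0-based), `strand` (+|-), `length`
#'   and `sequence`.
#' @export
sample_events <- function(config, chromosome, plasmid, regions = NULL) {
  stopifnot(nchar(chromosome) == config$chromosome_length,
            nchar(plasmid) == config$plasmid_length)
  if (!is.null(regions))
    stopifnot(inherits(regions, "region_set"),
              regions$chromosome_length == config$chromosome_length)
  set.seed(config$seed + 1L)
  n <- config$n_events
  src <- ifelse(runif(n) < config$plasmid_fraction, "plasmid", "chromosome")
  strand <- ifelse(runif(n) < config$strand_balance, "+", "-")
  len <- if (config$spacer_len_min == config$spacer_len_max)
    rep.int(config$spacer_len_min, n)
  else
    sample(seq.int(config$spacer_len_min, config$spacer_len_max), n,
           replace = TRUE)
  pos <- integer(n)
  is_chr <- src == "chromosome"
  pos[is_chr] <- sample_chromosome_positions(sum(is_chr),
                                             config$chromosome_length,
                                             regions, config$region_weights,
                                             config$baseline_weight)
  pos[!is_chr] <- sample.int(config$plasmid_length, sum(!is_chr),
                             replace = TRUE) - 1L
  seqs <- character(n)
  seqs[is_chr] <- circular_substr(chromosome, pos[is_chr], len[is_chr])
  seqs[!is_chr] <- circular_substr(plasmid, pos[!is_chr], len[!is_chr])
  minus <- strand == "-"
  seqs[minus] <- revcomp(seqs[minus])
  truth <- data.frame(source = src, position = pos, strand = strand,
                      length = len, sequence = seqs,
                      stringsAsFactors = FALSE)
  class(truth) <- c("ground_truth", "data.frame")
  truth
}

#' Build expanded CRISPR-array amplicons
#'
#' Constructs one amplicon per acquisition event with the structure
#' leader - repeat - new spacer - repeat - ancestral spacer - repeat, i.e.
#' the PCR product of an array that integrated one new spacer-plus-repeat
#' unit at the leader end. The amplicon starts at the forward primer, so
#' only the 3'-terminal `amplicon_leader_len` bases of the leader are
#' present. With zero events the unexpanded parental array
#' (leader - repeat - ancestral spacer - repeat) is returned.
#'
#' @param truth a `ground_truth` data frame from [sample_events()].
#' @param config a [sim_config()] object.
#' @return data frame with columns `event` (row index into `truth`, `NA`
#'   for the unexpanded array), `sequence`, and `spacer_start` (0-based
#'   offset of the new spacer within the amplicon).
#' @export
build_amplicons <- function(truth, config) {
  R <- config$repeat_seq
  lead <- substr(config$leader_seq,
                 nchar(config$leader_seq) - config$amplicon_leader_len + 1L,
                 nchar(config$leader_seq))
  unexpanded <- paste0(lead, R, config$old_spacer, R)
  if (nrow(truth) == 0L)
    return(data.frame(event = NA_integer_, sequence = unexpanded,
                      spacer_start = NA_integer_, stringsAsFactors = FALSE))
  offset <- nchar(lead) + nchar(R)
  data.frame(event = seq_len(nrow(truth)),
             sequence = paste0(lead, R, truth$sequence, R,
                               config$old_spacer, R),
             spacer_start = offset,
             stringsAsFactors = FALSE)
}

#' Simulate paired-end reads from amplicons
#'
#' Emulates 2 x `read_length` paired-end amplicon sequencing. The sequenced
#' fragment is the whole amplicon when it is at most twice the read length
#' (the usual case for CRISPR-array PCR products), otherwise a uniformly
#' placed fragment of twice the read length. Mate 1 is the fragment 5' end,
#' mate 2 the reverse complement of its 3' end. Substitution errors are
#' injected per base at `per_base_error_rate`; errored bases carry
#' `quality_low`, all others `quality_high`.
#'
#' @param amplicons data frame from [build_amplicons()].
#' @param config a [sim_config()] object.
#' @param n_pairs number of read pairs; defaults to `config$n_read_pairs`,
#'   and when that is `NULL` each amplicon is sequenced exactly once.
#' @return a reads data frame (columns `id`, `mate`, `seq`, `qual`,
#'   `amplicon`) as consumed by [preprocess_reads()]; write it to FASTQ
#'   with [write_fastq()].
#' @export
simulate_reads <- function(amplicons, config, n_pairs = config$n_read_pairs) {
  RL <- config$read_length
  if (any(nchar(amplicons$sequence) < RL))
    stop("amplicon shorter than read_length (", RL, " nt)")
  set.seed(config$seed + 2L)
  n_amp <- nrow(amplicons)
  amp_idx <- if (is.null(n_pairs)) seq_len(n_amp)
             else sample.int(n_amp, n_pairs, replace = TRUE)
  n <- length(amp_idx)
  aseq <- amplicons$sequence[amp_idx]
  alen <- nchar(aseq)
  frag <- aseq
  long <- alen > 2L * RL
  if (any(long)) {
    fstart <- floor(runif(sum(long)) * (alen[long] - 2L * RL + 1L))
    frag[long] <- substr(aseq[long], fstart + 1L, fstart + 2L * RL)
  }
  flen <- nchar(frag)
  r1 <- substr(frag, 1L, RL)
  r2 <- revcomp(substr(frag, flen - RL + 1L, flen))
  seqs <- c(r1, r2)
  quals <- rep.int(strrep(int_to_phred(config$quality_high), RL), 2L * n)
  e <- config$per_base_error_rate
  if (e > 0) {
    bases <- c("A", "C", "G", "T")
    qlow <- int_to_phred(config$quality_low)
    for (i in seq_along(seqs)) {
      hit <- which(runif(RL) < e)
      if (!length(hit)) next
      s <- seqs[i]; q <- quals[i]
      for (p in hit) {
        substr(s, p, p) <- sample(setdiff(bases, substr(s, p, p)), 1L)
        substr(q, p, p) <- qlow
      }
      seqs[i] <- s; quals[i] <- q
    }
  }
  data.frame(id = rep(sprintf("pair%06d", seq_len(n)), 2L),
             mate = rep(c(1L, 2L), each = n),
             seq = seqs, qual = quals,
             amplicon = rep(amp_idx, 2L),
             stringsAsFactors = FALSE)
}

#' Simulate a complete sequencing library
#'
#' Convenience wrapper running [make_references()], [sample_events()],
#' [build_amplicons()] and [simulate_reads()], optionally writing all
#' outputs (FASTA references, paired FASTQ, BED regions, ground-truth TSV)
#' to a directory.
#'
#' @param config a [sim_config()] object.
#' @param regions optional [region_set()] controlling regional enrichment.
#' @param dir optional output directory.
#' @return list of class `sim_library` with elements `config`, `chromosome`,
#'   `plasmid`, `truth`, `amplicons`, `reads` and `regions`.
#' @export
simulate_library <- function(config, regions = NULL, dir = NULL) {
  refs <- make_references(config)
  truth <- sample_events(config, refs$chromosome, refs$plasmid, regions)
  amplicons <- build_amplicons(truth, config)
  reads <- simulate_reads(amplicons, config)
  lib <- list(config = config, chromosome = refs$chromosome,
              plasmid = refs$plasmid, truth = truth,
              amplicons = amplicons, reads = reads, regions = regions)
  class(lib) <- "sim_library"
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(c(chromosome = refs$chromosome), file.path(dir, "chromosome.fa"))
    write_fasta(c(plasmid = refs$plasmid), file.path(dir, "plasmid.fa"))
    write_fastq(reads[reads$mate == 1L, ], file.path(dir, "reads_R1.fastq"))
    write_fastq(reads[reads$mate == 2L, ], file.path(dir, "reads_R2.fastq"))
    write.table(truth, file.path(dir, "ground_truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(regions))
      write_regions_bed(regions, file.path(dir, "regions.bed"))
  }
  lib
}

#' @export
print.sim_library <- function(x, ...) {
  cat("Simulated CRISPR adaptation library\n")
  cat(sprintf("  %d events (%d plasmid, %d chromosome), %d read pairs\n",
              nrow(x$truth), sum(x$truth$source == "plasmid"),
              sum(x$truth$source == "chromosome"),
              sum(x$reads$mate == 1L)))
  invisible(x)
}
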