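## End-to-end pipeline: preprocess -> extract -> dedupe -> map -> summarize.

#' Run the full spacer acquisition pipeline
#'
#' Chains [preprocess_reads()], [extract_all_spacers()],
#' [dedupe_spacers()], [map_spacers()], [origin_fractions()],
#' [strand_balance()] and, when a region set is supplied,
#' [enrichment()].
#'
#' @param reads reads data frame ([read_fastq()] output, or rbind of both
#'   mates; mates are processed independently).
#' @param plasmid,chromosome circular reference sequences (character), e.g.
#'   from [read_fasta()].
#' @param repeat_seq CRISPR repeat sequence.
#' @param regions optional [region_set()] for regional enrichment.
#' @param max_mismatch repeat-detection Hamming allowance (default 2).
#' @param q_threshold Phred trimming threshold (default 20).
#' @param min_len,max_len spacer length bounds (defaults 20 and 50 nt).
#' @param map_mismatch mapping Hamming tolerance (default 0, exact).
#' @param ... further arguments passed to [preprocess_reads()].
#' @return object of class `spacer_analysis`: list with elements
#'   `preprocess` (stats), `spacers` (deduplicated `spacer_table`),
#'   `mapping` (`mapping_results`), `origin`, `strand`, `enrichment`
#'   (or `NULL`) and `extraction` (drop counts).
#' @export
run_spacer_pipeline <- function(reads, plasmid, chromosome, repeat_seq,
                                regions = NULL, max_mismatch = 2L,
                                q_threshold = 20, min_len = 20L,
                                max_len = 50L, map_mismatch = 0L, ...) {
  prep <- preprocess_reads(reads, repeat_seq, max_mismatch = max_mismatch,
                           q_threshold = q_threshold, ...)
  extracted <- extract_all_spacers(prep, nchar(repeat_seq),
                                   min_len = min_len, max_len = max_len)
  spacers <- dedupe_spacers(extracted$spacers)
  mapping <- map_spacers(spacers, plasmid, chromosome,
                         max_mismatch = map_mismatch)
  origin <- if (any(mapping$target %in% c("plasmid", "chromosome")))
    origin_fractions(mapping) else NULL
  strand <- if (any(mapping$target == "chromosome"))
    strand_balance(mapping) else NULL
  enrich <- if (!is.null(regions) && any(mapping$target == "chromosome"))
    enrichment(mapping, regions) else NULL
  out <- list(preprocess = prep$stats, extraction = extracted[-1L],
              spacers = spacers, mapping = mapping, origin = origin,
              strand = strand, enrichment = enrich)
  class(out) <- "spacer_analysis"
  out
}

#' @export
print.spacer_analysis <- function(x, ...) {
  cat("CRISPR spacer acquisition analysis\n")
  cat(sprintf("  reads: %d in, %d retained with >=2 repeats\n",
              x$preprocess$n_input, x$preprocess$n_retained))
  cat(sprintf("  unique spacers: %d (from %d extracted sequences)\n",
              nrow(x$spacers), sum(x$spacers$support)))
  tab <- table(x$mapping$target)
  cat("  mapping: ",
      paste(sprintf("%s %d", names(tab), as.integer(tab)), collapse = ", "),
      "\n", sep = "")
  if (!is.null(x$origin))
    cat(sprintf("  origin: %.1f%% chromosome / %.1f%% plasmid (n = %d)\n",
                100 * x$origin$fraction_chromosome,
                100 * x$origin$fraction_plasmid, x$origin$n_mapped))
  if (!is.null(x$strand))
    cat(sprintf("  strand: %.1f%% forward (exact binomial p = %.3g)\n",
                100 * x$strand$fraction_forward, x$strand$p_value))
  if (!is.null(x$enrichment)) {
    cat("  enrichment:\n")
    print.data.frame(x$enrichment, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
summary.spacer_analysis <- function(object, ...) print(object, ...)

#' @export
plot.spacer_analysis <- function(x, ...) {
  if (is.null(x$enrichment))
    stop("no enrichment table in this analysis (no region set supplied)")
  plot(x$enrichment, ...)
}
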