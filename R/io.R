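## File formats: FASTA/FASTQ through Biostrings; BED and TSV as plain text.
## Reads are carried internally as a data frame with columns id, mate, seq,
## qual (Phred+33 string); coordinates written to BED are 0-based half-open.

#' Write sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file
#' @param path input file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write reads to FASTQ (Phred+33)
#' @param reads reads data frame (columns `id`, `seq`, `qual`).
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' Sanger/Illumina-1.8 encoding is assumed; files that look Phred+64
#' encoded (no quality character below ASCII 59 and some at or above 75)
#' are rejected with an explanatory error.
#'
#' @param path input FASTQ.
#' @param mate mate number recorded on every read (1 or 2; `NA` if unknown).
#' @return reads data frame with columns `id`, `mate`, `seq`, `qual`.
#' @export
read_fastq <- function(path, mate = NA_integer_) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  qual <- as.character(S4Vectors::mcols(x)$qualities)
  if (length(qual)) {
    qr <- as.integer(charToRaw(paste(qual, collapse = "")))
    if (length(qr) && min(qr) >= 59L && max(qr) >= 75L)
      stop("FASTQ qualities look Phred+64 encoded; this pipeline requires ",
           "Phred+33 (Sanger) encoding")
  }
  data.frame(id = sub("\\s.*$", "", names(x)),
             mate = rep(as.integer(mate), length(x)),
             seq = as.character(x), qual = qual,
             stringsAsFactors = FALSE)
}

#' Write a region set to BED
#'
#' Intervals are written 0-based half-open with the region name in column 4.
#'
#' @param regions a [region_set()].
#' @param path output file.
#' @param chrom chromosome name for column 1.
#' @export
write_regions_bed <- function(regions, path, chrom = "chromosome") {
  iv <- regions$intervals
  write.table(data.frame(chrom = chrom, start = iv$start, end = iv$end,
                         name = iv$name),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a region set from BED
#'
#' @param path BED file (0-based half-open; column 4 holds the region name).
#' @param chromosome_length circular chromosome length.
#' @param window_width required total span of every named region.
#' @return a [region_set()].
#' @export
read_regions_bed <- function(path, chromosome_length, window_width = 670000) {
  bed <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(bed) < 4L) stop("BED file must have at least 4 columns ",
                           "(chrom, start, end, name)")
  region_set_from_intervals(data.frame(name = bed[[4L]], start = bed[[2L]],
                                       end = bed[[3L]]),
                            chromosome_length = chromosome_length,
                            window_width = window_width)
}

#' Read gel band intensities from TSV
#'
#' Expects columns `strain`, `plasmid`, `passage`, `intensity_C`
#' (unexpanded band) and `intensity_C1` (expanded band).
#'
#' @param path TSV file with a header row.
#' @return validated data frame of gel lanes.
#' @export
read_gel_tsv <- function(path) {
  x <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  validate_gel_lanes(x)
}
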