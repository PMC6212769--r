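test_that("reference generation is reproducible, length-exact and repeat-free", {
  cfg <- small_config(seed = 1)
  r1 <- make_references(cfg)
  r2 <- make_references(cfg)
  expect_identical(r1, r2)
  expect_equal(nchar(r1$chromosome), 50000)
  expect_equal(nchar(r1$plasmid), 4000)

  # a short repeat occurs by chance in random sequence, so the scrubbing
  # step must actually fire; brute scan of the doubled sequence finds none
  cfg5 <- sim_config(chromosome_length = 5000, plasmid_length = 2000,
                     repeat_seq = "ACGTA", spacer_len_min = 5,
                     spacer_len_max = 5, read_length = 40, seed = 3)
  refs <- make_references(cfg5)
  for (s in c(refs$chromosome, refs$plasmid)) {
    expect_equal(nrow(brute_circular_hits("ACGTA", s)), 0)
  }

  expect_error(make_references(small_config(chromosome_length = 100)),
               "10 x")
})

test_that("event sampling follows the configured composition and weights", {
  cfg <- small_config(n_events = 10000, plasmid_fraction = 0.15)
  refs <- make_references(cfg)
  truth <- sample_events(cfg, refs$chromosome, refs$plasmid)
  expect_equal(nrow(truth), 10000)
  expect_true(all(truth$position >= 0))
  expect_true(all(truth$position[truth$source == "chromosome"] < 50000))
  expect_true(all(truth$position[truth$source == "plasmid"] < 4000))

  # plasmid fraction within 3 binomial standard errors
  p_hat <- mean(truth$source == "plasmid")
  se <- sqrt(0.15 * 0.85 / 10000)
  expect_lt(abs(p_hat - 0.15), 3 * se)

  # spacer sequences equal the (possibly reverse-complemented) reference
  # substring at the recorded position
  i <- which(truth$source == "chromosome")[1:50]
  expected <- circular_substr(refs$chromosome, truth$position[i],
                              truth$length[i])
  minus <- truth$strand[i] == "-"
  expected[minus] <- revcomp(expected[minus])
  expect_identical(truth$sequence[i], expected)

  # boundary: no plasmid events at plasmid_fraction = 0
  cfg0 <- small_config(plasmid_fraction = 0, n_events = 500)
  t0 <- sample_events(cfg0, refs$chromosome, refs$plasmid)
  expect_true(all(t0$source == "chromosome"))
})

test_that("planted regional enrichment is recovered in the raw event counts", {
  cfg <- small_config(n_events = 10000, plasmid_fraction = 0,
                      region_weights = c(Ori = 4), baseline_weight = 1)
  refs <- make_references(cfg)
  regs <- region_set(50000, centers = c(Ori = 20000), window_width = 4000)
  truth <- sample_events(cfg, refs$chromosome, refs$plasmid, regs)
  counts <- count_in_regions(truth$position, regs)
  # expected ratio Ori/Ref = 4 (equal widths, baseline weight in Ref);
  # compare on the Ori proportion of the two-window total, 3 SE bound
  n2 <- counts[["Ori"]] + counts[["Ref"]]
  p_hat <- counts[["Ori"]] / n2
  se <- sqrt(0.8 * 0.2 / n2)
  expect_lt(abs(p_hat - 0.8), 3 * se)

  # uniform null: equal weights give near-equal window counts
  cfg_u <- small_config(n_events = 10000, plasmid_fraction = 0,
                        region_weights = c(Ori = 1), baseline_weight = 1)
  t_u <- sample_events(cfg_u, refs$chromosome, refs$plasmid, regs)
  c_u <- count_in_regions(t_u$position, regs)
  exp_n <- 10000 * 4000 / 50000
  se_n <- sqrt(10000 * (4000 / 50000) * (1 - 4000 / 50000))
  for (nm in c("Ori", "Ref"))
    expect_lt(abs(c_u[[nm]] - exp_n), 3 * se_n)
})

test_that("amplicons have the leader-repeat-spacer-repeat-spacer-repeat structure", {
  cfg <- small_config(n_events = 3)
  refs <- make_references(cfg)
  truth <- sample_events(cfg, refs$chromosome, refs$plasmid)
  amp <- build_amplicons(truth, cfg)
  expect_equal(nrow(amp), 3)
  m <- nchar(cfg$repeat_seq)
  for (i in 1:3) {
    hits <- find_repeats(amp$sequence[i], cfg$repeat_seq, max_mismatch = 0)
    expect_gte(nrow(hits), 2)
    planted <- substr(amp$sequence[i], amp$spacer_start[i] + 1,
                      amp$spacer_start[i] + truth$length[i])
    expect_identical(planted, truth$sequence[i])
  }

  # zero events: the unexpanded parental array
  empty <- truth[0, , drop = FALSE]
  amp0 <- build_amplicons(empty, cfg)
  expect_equal(nrow(amp0), 1)
  expect_true(is.na(amp0$event))
  # expansion adds exactly repeat + spacer length
  expect_equal(nchar(amp$sequence[1]) - nchar(amp0$sequence),
               m + truth$length[1])
})

test_that("simulated reads are faithful fragments with a calibrated error rate", {
  cfg <- small_config(n_events = 30, per_base_error_rate = 0)
  refs <- make_references(cfg)
  truth <- sample_events(cfg, refs$chromosome, refs$plasmid)
  amp <- build_amplicons(truth, cfg)
  reads <- simulate_reads(amp, cfg)
  expect_equal(nrow(reads), 60)
  # error-free reads are exact substrings of their amplicon (mate 1) or of
  # its reverse complement (mate 2)
  for (i in seq_len(nrow(reads))) {
    a <- amp$sequence[reads$amplicon[i]]
    target <- if (reads$mate[i] == 1L) a else revcomp(a)
    expect_true(grepl(reads$seq[i], target, fixed = TRUE))
  }

  # substitution rate calibration: >= 100 kb simulated, 3 SE bound
  cfg_e <- small_config(n_events = 400, per_base_error_rate = 0.01, seed = 9)
  refs_e <- make_references(cfg_e)
  truth_e <- sample_events(cfg_e, refs_e$chromosome, refs_e$plasmid)
  amp_e <- build_amplicons(truth_e, cfg_e)
  reads_e <- simulate_reads(amp_e, cfg_e)
  reads_0 <- simulate_reads(amp_e, small_config(n_events = 400,
                                                per_base_error_rate = 0,
                                                seed = 9))
  n_bases <- sum(nchar(reads_e$seq))
  expect_gte(n_bases, 100000)
  mism <- sum(mapply(function(a, b)
    sum(charToRaw(a) != charToRaw(b)), reads_e$seq, reads_0$seq))
  se <- sqrt(0.01 * 0.99 / n_bases)
  expect_lt(abs(mism / n_bases - 0.01), 3 * se)
  # errored bases get quality_low, clean bases quality_high
  qerr <- unlist(phred_to_int(reads_e$qual))
  err_pos <- unlist(mapply(function(a, b) charToRaw(a) != charToRaw(b),
                           reads_e$seq, reads_0$seq))
  expect_true(all(qerr[err_pos] == cfg_e$quality_low))
  expect_true(all(qerr[!err_pos] == cfg_e$quality_high))

  # amplicon shorter than the read length is an error
  short_amp <- data.frame(event = 1L, sequence = "ACGTACGT",
                          spacer_start = NA_integer_)
  expect_error(simulate_reads(short_amp, cfg), "shorter than read_length")
})

test_that("a fixed seed gives byte-identical FASTQ output", {
  cfg <- small_config(n_events = 20, per_base_error_rate = 0.01, seed = 11)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  lib1 <- simulate_library(cfg)
  lib2 <- simulate_library(cfg)
  write_fastq(lib1$reads[lib1$reads$mate == 1, ], f1)
  write_fastq(lib2$reads[lib2$reads$mate == 1, ], f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  # FASTQ round-trip preserves sequences and qualities
  back <- read_fastq(f1, mate = 1)
  r1 <- lib1$reads[lib1$reads$mate == 1, ]
  expect_identical(back$seq, r1$seq)
  expect_identical(back$qual, r1$qual)
})
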