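REP20 <- "GTGTTCCCCGCGCCAGCGGG"   # 20-nt test repeat

test_that("quality trimming follows the stated rules and is idempotent", {
  # identity at uniformly high quality
  t1 <- trim_read("ACGTACGT", int_to_phred(rep(40L, 8)))
  expect_equal(t1$seq, "ACGTACGT")
  # full trim at uniformly low quality
  t2 <- trim_read("ACGTACGT", int_to_phred(rep(10L, 8)))
  expect_equal(t2$seq, "")
  # cut at the first low-quality base: [40,40,15,40] keeps 2 bases
  t3 <- trim_read("ACGT", int_to_phred(c(40L, 40L, 15L, 40L)))
  expect_equal(nchar(t3$seq), 2)
  expect_equal(t3$seq, "AC")
  # cross-check against a position-by-position oracle on random reads
  set.seed(101)
  for (i in 1:50) {
    n <- sample(5:80, 1)
    q <- sample(0:42, n, replace = TRUE)
    s <- rand_seq(n)
    keep <- which(cumsum(q < 20) > 0)  # first low base and everything after
    exp_len <- if (length(keep)) keep[1] - 1L else n
    tr <- trim_read(s, int_to_phred(q))
    expect_equal(nchar(tr$seq), exp_len)
    # idempotence for both rules
    for (rule in c("first_low", "sliding")) {
      a <- trim_read(s, int_to_phred(q), rule = rule)
      b <- trim_read(a$seq, a$qual, rule = rule)
      expect_identical(a, b)
    }
  }
})

test_that("repeat detection matches the brute-force Hamming oracle", {
  # self-match
  hits <- find_repeats(REP20, REP20)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 0)
  expect_equal(hits$mismatches, 0)
  expect_equal(hits$orientation, "F")
  # three substitutions exceed the two-mismatch allowance
  mut <- REP20
  substr(mut, 1, 1) <- "A"; substr(mut, 5, 5) <- "A"; substr(mut, 9, 9) <- "T"
  expect_equal(nrow(find_repeats(mut, REP20, max_mismatch = 2)), 0)
  expect_equal(nrow(find_repeats(mut, REP20, max_mismatch = 3)), 1)

  # randomized equivalence with the all-offset scan, both orientations,
  # with planted near-repeats so matches actually occur
  set.seed(202)
  for (i in 1:120) {
    n <- sample(60:500, 1)
    read <- rand_seq(n)
    for (k in seq_len(sample(0:3, 1))) {
      r <- REP20
      for (p in sample(20, sample(0:3, 1)))
        substr(r, p, p) <- sample(c("A", "C", "G", "T"), 1)
      if (runif(1) < 0.5)
        r <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
      pos <- sample(n - 20 + 1, 1)
      substr(read, pos, pos + 19) <- r
    }
    got <- find_repeats(read, REP20, max_mismatch = 2, resolve = FALSE)
    want <- brute_repeat_scan(read, REP20, 2)
    expect_identical(got, want)
  }
})

test_that("reverse-complementing a read mirrors its repeat matches", {
  set.seed(303)
  for (i in 1:30) {
    read <- rand_seq(200)
    pos <- sample(180, 2)
    substr(read, pos[1], pos[1] + 19) <- REP20
    a <- find_repeats(read, REP20, resolve = FALSE)
    b <- find_repeats(revcomp(read), REP20, resolve = FALSE)
    expect_equal(nrow(a), nrow(b))
    if (nrow(a)) {
      mirrored <- data.frame(start = as.integer(200 - a$start - 20),
                             orientation = ifelse(a$orientation == "F",
                                                  "R", "F"),
                             mismatches = a$mismatches)
      mirrored <- mirrored[order(mirrored$start, mirrored$orientation), ]
      rownames(mirrored) <- NULL
      expect_identical(b, mirrored)
    }
  }
})

test_that("overlapping matches resolve to the fewest-mismatch non-overlapping set", {
  m <- data.frame(start = c(0L, 5L, 30L),
                  orientation = c("F", "F", "F"),
                  mismatches = c(2L, 0L, 1L))
  res <- resolve_repeat_overlaps(m, repeat_length = 20L)
  expect_equal(res$start, c(5L, 30L))
  # tie broken leftmost
  m2 <- data.frame(start = c(0L, 5L), orientation = c("F", "F"),
                   mismatches = c(1L, 1L))
  expect_equal(resolve_repeat_overlaps(m2, 20L)$start, 0L)
})

test_that("reads are kept only with two or more repeats, per ground truth", {
  reads <- make_reads(c(
    rand_seq(120),                                        # 0 repeats
    paste0(rand_seq(20), REP20, rand_seq(60)),            # 1 repeat
    paste0(rand_seq(10), REP20, rand_seq(33), REP20)      # 2 repeats
  ))
  set.seed(404)
  prep <- preprocess_reads(reads, REP20)
  expect_equal(prep$reads$id, "r003")
  expect_equal(prep$stats$n_retained, 1)
  expect_equal(prep$stats$n_discarded, 2)

  # simulated library: retained set equals reads with >= 2 planted repeats
  cfg <- small_config(n_events = 30)
  lib <- simulate_library(cfg)
  planted <- vapply(lib$reads$seq, function(s)
    nrow(brute_repeat_scan(s, cfg$repeat_seq, 0)), integer(1),
    USE.NAMES = FALSE)
  prep2 <- preprocess_reads(lib$reads, cfg$repeat_seq)
  expect_setequal(prep2$reads$id[prep2$reads$mate == 1],
                  lib$reads$id[lib$reads$mate == 1][planted[lib$reads$mate == 1] >= 2])
})

test_that("reads in reverse orientation are flipped into array orientation", {
  spacer <- rand_seq(33)
  fwd <- paste0(rand_seq(8), REP20, spacer, REP20, rand_seq(8))
  reads <- make_reads(c(fwd, revcomp(fwd)))
  prep <- preprocess_reads(reads, REP20)
  expect_equal(prep$stats$n_flipped, 1)
  expect_equal(prep$stats$n_retained, 2)
  # both reads now present the spacer in array orientation
  for (i in 1:2) {
    sp <- extract_spacers(prep$reads$seq[i], prep$matches[[i]], 20L)
    expect_identical(sp$spacers, spacer)
  }
})

test_that("Phred+64-looking FASTQ is rejected", {
  f <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGTACGT", "+", "hhhhhhhh"), f)  # Phred+64 Q40
  expect_error(read_fastq(f), "Phred\\+64")
})
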