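test_that("generation is deterministic and respects the empty case", {
  cfg <- small_synth(seed = 1, n_hairpins = 0)
  synth <- generate_genome_and_truth(cfg)
  expect_equal(nrow(synth$truth), 0L)

  cfg7 <- small_synth(seed = 7, n_hairpins = 3)
  a <- generate_genome_and_truth(cfg7)
  b <- generate_genome_and_truth(cfg7)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth, b$truth)
  fa <- tempfile(fileext = ".fa")
  fb <- tempfile(fileext = ".fa")
  write_genome_fasta(a, fa); write_genome_fasta(b, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("planted hairpins satisfy the stated structural invariants", {
  synth <- generate_genome_and_truth(small_synth(seed = 3, n_hairpins = 6))
  tr <- synth$truth
  cfg <- synth$config
  for (i in seq_len(nrow(tr))) {
    # precursor length window
    expect_gte(nchar(tr$precursor[i]), cfg$precursor_length_range[1])
    expect_lte(nchar(tr$precursor[i]), cfg$precursor_length_range[2])
    expect_equal(tr$end[i] - tr$start[i] + 1L, nchar(tr$precursor[i]))
    # mature and star are substrings on opposite sides of the loop
    m_at <- regexpr(tr$mature[i], tr$precursor[i], fixed = TRUE)
    s_at <- regexpr(tr$star[i], tr$precursor[i], fixed = TRUE)
    expect_gt(m_at, 0); expect_gt(s_at, 0)
    expect_true(tr$mature_arm[i] != tr$star_arm[i])
    if (tr$mature_arm[i] == "5p") expect_lt(m_at, s_at) else expect_gt(m_at, s_at)
    # the genomic slice reproduces the planted precursor
    gseq <- as.character(Biostrings::subseq(
      synth$genome[[tr$chrom[i]]], tr$start[i], tr$end[i]))
    if (tr$strand[i] == "-") gseq <- revcomp_dna(gseq)
    expect_equal(as_rna(gseq), tr$precursor[i])
  }
})

test_that("the star carries a 2-nt 3' overhang past the mature 5' pairing position", {
  synth <- generate_genome_and_truth(small_synth(seed = 11, n_hairpins = 5))
  tr <- synth$truth
  for (i in seq_len(nrow(tr))) {
    fold <- fold_hairpin(tr$precursor[i])
    m_iv <- c(tr$mature_offset[i], tr$mature_offset[i] + nchar(tr$mature[i]) - 1L)
    s_at <- tr$star_offset[i]
    s_iv <- c(s_at, s_at + nchar(tr$star[i]) - 1L)
    # the star 3' end lies two positions beyond the mature 5' base's
    # pairing partner
    p <- fold$partner[m_iv[1]]
    expect_false(is.na(p))
    expect_equal(abs(s_iv[2] - p), 2L)
  }
})

test_that("zero-mismatch duplexes are exactly reverse-complementary", {
  cfg <- small_synth(seed = 2, n_hairpins = 5,
                     duplex_mismatch_range = c(0, 0), bulge_max_count = 0)
  synth <- generate_genome_and_truth(cfg)
  for (i in seq_len(nrow(synth$truth))) {
    tr <- synth$truth[i, ]
    m <- nchar(tr$mature)
    # dropping the star 2-nt 3' overhang leaves the exact reverse
    # complement of the mature's first m-2 bases
    core <- substr(tr$star, 1, nchar(tr$star) - 2L)
    expect_equal(core, revcomp_rna(substr(tr$mature, 1, m - 2L)))
  }
})

test_that("simulated counts equal the configured expectation when noise is off", {
  cfg <- small_synth(seed = 5, n_hairpins = 3, isomir_shift_prob = 0)
  synth <- generate_genome_and_truth(cfg)
  reads <- simulate_libraries(synth)
  expected <- attr(reads, "expected")
  # with no isomiR shifts every planted read is the mature or the star
  expect_true(all(expected$role %in% c("mature", "star")))
  for (i in seq_len(nrow(synth$truth))) {
    tr <- synth$truth[i, ]
    for (lib in cfg$library_labels) {
      got <- reads$count[reads$sequence == tr$mature & reads$library == lib]
      expect_equal(got, tr$base_count, info = paste(tr$hairpin_id, lib))
    }
  }
})

test_that("fold-change maps scale per-library counts exactly", {
  cfg <- small_synth(seed = 6, n_hairpins = 2, isomir_shift_prob = 0)
  synth <- generate_genome_and_truth(cfg)
  fcm <- matrix(1, nrow = 2, ncol = 8,
                dimnames = list(synth$truth$hairpin_id, cfg$library_labels))
  fcm["hp01", "DSRT"] <- 2
  synth$config$fold_change_map <- fcm
  reads <- simulate_libraries(synth)
  m1 <- synth$truth$mature[1]
  c_ctrl <- reads$count[reads$sequence == m1 & reads$library == "DSRC"]
  c_trt <- reads$count[reads$sequence == m1 & reads$library == "DSRT"]
  expect_equal(c_trt / c_ctrl, 2)
})

test_that("isomiR emission respects the shift probability and length window", {
  cfg <- small_synth(seed = 8, n_hairpins = 4, isomir_shift_prob = 0.3)
  synth <- generate_genome_and_truth(cfg)
  reads <- simulate_libraries(synth)
  expected <- attr(reads, "expected")
  iso <- expected[expected$role == "isomir", ]
  expect_gt(nrow(iso), 0)
  expect_true(all(nchar(iso$sequence) >= 19 & nchar(iso$sequence) <= 24))
  # isomiR share of each hairpin/library equals the configured fraction
  for (h in unique(iso$hairpin)) {
    e <- expected[expected$hairpin == h & expected$library == "DSRC", ]
    expect_equal(sum(e$expected[e$role == "isomir"]) /
                   sum(e$expected[e$role %in% c("mature", "isomir")]), 0.3)
    # every isomiR is a substring of the precursor
    prec <- synth$truth$precursor[synth$truth$hairpin_id == h]
    for (s in e$sequence[e$role == "isomir"]) {
      expect_true(grepl(s, prec, fixed = TRUE))
    }
  }
  # all emitted tags are inside the length window
  expect_true(all(nchar(reads$sequence) >= 19 & nchar(reads$sequence) <= 24))
})

test_that("background tags never match the genome on either strand", {
  synth <- generate_genome_and_truth(small_synth(seed = 9, n_hairpins = 2))
  reads <- simulate_libraries(synth)
  planted <- attr(reads, "expected")$sequence
  bg <- setdiff(unique(reads$sequence), planted)
  expect_gt(length(bg), 0)
  gs <- as.character(synth$genome)
  for (s in bg) {
    d <- as_dna(s)
    expect_false(any(grepl(d, gs, fixed = TRUE) |
                       grepl(revcomp_dna(d), gs, fixed = TRUE)))
  }
})

test_that("planted matures carry the configured 5'-U bias", {
  cfg <- synthetic_config(seed = 13, n_hairpins = 40, n_chromosomes = 4,
                          chrom_length = 40000, u5_bias = 0.7,
                          background_tag_count = 0)
  synth <- generate_genome_and_truth(cfg)
  frac_u <- mean(substr(synth$truth$mature, 1, 1) == "U")
  # binomial 3-sigma band around 0.7 with n = 40
  expect_gt(frac_u, 0.7 - 3 * sqrt(0.7 * 0.3 / 40))
  expect_lt(frac_u, 0.7 + 3 * sqrt(0.7 * 0.3 / 40))
})
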