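# A deterministic hand-built hairpin used in several tests: 21-nt mature
# on the 5' arm, perfect duplex, spacer before the loop.
perfect_hairpin <- function(mature = "UGGACGUAAUCGCUAGCAAGU",
                            e5 = "AUGGCUAG", sp = "ACGG",
                            loop = "AAACAAACAAACAAA") {
  left <- paste0(e5, mature, sp)
  precursor <- paste0(left, loop, revcomp_rna(left))
  list(precursor = precursor,
       mature_iv = c(nchar(e5) + 1L, nchar(e5) + nchar(mature)),
       mature = mature,
       left_len = nchar(left), loop_len = nchar(loop))
}

test_that("flank windows have the expected extent and truncation flags", {
  set.seed(50)
  chrom <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                 collapse = "")
  idx <- build_index(c(chr1 = chrom))

  mid <- data.frame(chrom = "chr1", start = 1000L, end = 1020L, strand = "+")
  w <- extract_flanks(mid, idx, 200L)
  expect_equal(nchar(w$seq), 421L)
  expect_equal(c(w$tag_start, w$tag_end), c(201L, 221L))
  expect_false(w$trunc5 || w$trunc3)
  expect_equal(substr(w$seq, 201, 221), as_rna(substr(chrom, 1000, 1020)))

  first <- data.frame(chrom = "chr1", start = 1L, end = 21L, strand = "+")
  w0 <- extract_flanks(first, idx, 200L)
  expect_true(w0$trunc5)
  expect_equal(w0$tag_start, 1L)

  minus <- data.frame(chrom = "chr1", start = 500L, end = 520L, strand = "-")
  wm <- extract_flanks(minus, idx, 200L)
  expect_equal(substr(wm$seq, wm$tag_start, wm$tag_end),
               as_rna(revcomp_dna(substr(chrom, 500, 520))))
  # coordinate map round-trips
  expect_equal(window_to_genome(wm, wm$tag_start), 520L)
  expect_equal(window_to_genome(wm, wm$tag_end), 500L)
})

test_that("the star arm is located for a planted duplex and not in noise", {
  hp <- perfect_hairpin()
  set.seed(60)
  flank <- random_rna(150)
  window <- structure(list(
    seq = paste0(flank, hp$precursor, random_rna(150)),
    tag_start = 150L + hp$mature_iv[1],
    tag_end = 150L + hp$mature_iv[2],
    chrom = "chr1", strand = "+", g_start = 1L,
    g_end = 300L + nchar(hp$precursor), trunc5 = FALSE, trunc3 = FALSE),
    class = "flank_window")
  star <- locate_star(window, hp$mature)
  expect_false(is.null(star))
  # rc-mature sits right after the loop spacer in the 3' arm
  rc_start <- 150L + hp$left_len + hp$loop_len + 4L + 1L  # revcomp(sp) first
  expect_equal(star$s_start, rc_start)
  expect_equal(star$score, nchar(hp$mature))

  # pure noise on both sides: nothing reaches the floor
  noise <- structure(list(
    seq = paste0(random_rna(180), hp$mature, random_rna(180)),
    tag_start = 181L, tag_end = 180L + nchar(hp$mature),
    chrom = "chr1", strand = "+", g_start = 1L, g_end = 381L,
    trunc5 = FALSE, trunc3 = FALSE), class = "flank_window")
  expect_null(locate_star(noise, hp$mature))
})

test_that("duplex criteria accept perfect stems and reject excess defects", {
  hp <- perfect_hairpin()
  fold <- fold_hairpin(hp$precursor)
  star_iv <- c(hp$left_len + hp$loop_len + 5L,
               hp$left_len + hp$loop_len + 4L + 21L)
  ev <- evaluate_duplex(fold, hp$mature_iv, star_iv)
  expect_true(ev$criterion_i && ev$criterion_ii && ev$criterion_iii)
  expect_true(ev$accepted)
  expect_equal(ev$n_mismatches, 0L)
  expect_equal(nrow(ev$bulges), 0L)

  # swapping mature and star labels leaves the verdict unchanged
  ev_sw <- evaluate_duplex(fold, star_iv, hp$mature_iv)
  expect_equal(ev_sw$accepted, ev$accepted)
  expect_equal(ev_sw$n_mismatches, ev$n_mismatches)

  # five unpaired mature positions violate criterion ii: build the duplex
  # structure explicitly (a stem 1..33 / 49..81 with mature 9..29, star
  # 53..73, and five mature bases 9..13 left unpaired)
  n <- nchar(hp$precursor)
  partner <- rep(NA_integer_, n)
  for (i in 1:33) {
    if (i %in% 9:13) next
    partner[i] <- n + 1L - i
    partner[n + 1L - i] <- i
  }
  pr <- which(!is.na(partner) & seq_len(n) < partner)
  fold_bad <- structure(list(sequence = hp$precursor,
                             pairs = cbind(i = pr, j = partner[pr]),
                             partner = partner,
                             n_pairs = length(pr), score = 0,
                             dotbracket = ""),
                        class = "fold_structure")
  ev_bad <- evaluate_duplex(fold_bad, hp$mature_iv, star_iv)
  expect_equal(ev_bad$n_mismatches, 5L)
  expect_false(ev_bad$criterion_ii)
  expect_false(ev_bad$accepted)

  # a 3-nt asymmetric bulge violates criterion iii (size limit 2)
  left <- paste0("AUGGCUAG", hp$mature, "ACGG")
  star_side <- revcomp_rna(left)
  bulged <- paste0(substr(star_side, 1, 12), "GGG",
                   substr(star_side, 13, nchar(star_side)))
  prec_bulge <- paste0(left, "AAACAAACAAACAAA", bulged)
  fold_bu <- fold_hairpin(prec_bulge)
  star_iv_bu <- c(hp$left_len + hp$loop_len + 5L,
                  hp$left_len + hp$loop_len + 4L + 24L)
  ev_bu <- evaluate_duplex(fold_bu, hp$mature_iv, star_iv_bu)
  expect_false(ev_bu$criterion_iii)
  expect_false(ev_bu$accepted)
})

test_that("mature and star intervals outside the precursor are an error", {
  hp <- perfect_hairpin()
  fold <- fold_hairpin(hp$precursor)
  expect_error(evaluate_duplex(fold, c(1L, 500L), c(2L, 3L)), "outside")
})

test_that("discovery recovers planted minus-strand hairpins", {
  synth <- generate_genome_and_truth(small_synth(seed = 23, n_hairpins = 6))
  minus <- synth$truth[synth$truth$strand == "-", , drop = FALSE]
  expect_gt(nrow(minus), 0)    # this seed plants minus-strand hairpins
  res <- run_discovery_chain(synth)
  for (i in seq_len(nrow(minus))) {
    hit <- res$candidates$chrom == minus$chrom[i] &
      res$candidates$strand == "-" &
      res$candidates$start <= minus$end[i] &
      res$candidates$end >= minus$start[i]
    expect_true(any(hit), info = minus$hairpin_id[i])
    expect_true(minus$mature[i] %in%
                  unlist(res$candidates$members[which(hit)]))
  }
})
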