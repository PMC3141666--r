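# Toy catalogs for classification tests. The known hairpin embeds its
# recorded mature on the 5' arm and a distinct star-side sequence on the
# 3' arm.
toy_catalogs <- function() {
  mature_gma <- "UGACAGAAGAGAGUGAGCACA"
  star_gma <- revcomp_rna(substr(mature_gma, 1, 19))
  hairpin <- paste0("GGAUG", mature_gma, "GAAUACAUACAUU", star_gma, "CAUCC")
  list(
    mature = data.frame(
      id = c("gma-miR156j", "ath-miR9999"),
      species = c("gma", "ath"),
      description = "",
      sequence = c(mature_gma, "UAUUGGCCUGGUUCACUCAGA"),
      stringsAsFactors = FALSE),
    hairpin = data.frame(
      id = "gma-MIR156j", species = "gma", description = "",
      sequence = hairpin, stringsAsFactors = FALSE),
    mature_seq = mature_gma, star_seq = star_gma, hairpin_seq = hairpin)
}

fake_candidate <- function(mature, precursor, chrom = "Gm01", start = 1000L,
                           arm = "5p", arms = "5p") {
  df <- data.frame(chrom = chrom, start = start,
                   end = start + nchar(precursor) - 1L,
                   length = nchar(precursor), strand = "+",
                   precursor = precursor, dotbracket = "",
                   mature = mature, mature_arm = arm,
                   star = "", star_arm = if (arm == "5p") "3p" else "5p",
                   n_mismatches = 0L, n_bulges = 0L,
                   arms_observed = arms, n_members = 1L,
                   stringsAsFactors = FALSE)
  df$members <- list(mature)
  df$context <- NA_character_
  df
}

test_that("classification follows the five-class priority", {
  cat <- toy_catalogs()

  known <- fake_candidate(cat$mature_seq, cat$hairpin_seq)
  anti <- fake_candidate(cat$star_seq, cat$hairpin_seq, arm = "3p")
  new_member <- fake_candidate(cat$mature_seq,
                               paste0("GGGUU", cat$mature_seq, "AACAAACAAA",
                                      revcomp_rna(substr(cat$mature_seq, 1, 19)),
                                      "AACCC"))
  conserved <- fake_candidate("UAUUGGCCUGGUUCACUCAGA",
                              paste0("AAGGC", "UAUUGGCCUGGUUCACUCAGA",
                                     "CAAACAAAC",
                                     revcomp_rna("UAUUGGCCUGGUUCACUCA"),
                                     "GCCUU"))
  novel <- fake_candidate("UUGUUCGAUAAAACUGUUGUG",
                          paste0("AAGGC", "UUGUUCGAUAAAACUGUUGUG",
                                 "CAAACAAAC",
                                 revcomp_rna("UUGUUCGAUAAAACUGUUG"), "GCCUU"))
  cands <- rbind(known, anti, new_member, conserved, novel)

  out <- classify_mirnas(cands, species_mature = cat$mature,
                         species_hairpin = cat$hairpin,
                         other_mature = cat$mature)
  expect_equal(out$class,
               c("KNOWN", "ANTISENSE_ARM_OF_KNOWN", "NEW_MEMBER_KNOWN_FAMILY",
                 "CONSERVED_OTHER_SPECIES", "NOVEL_FAMILY"))
  # a partition: re-running is idempotent and single-class
  out2 <- classify_mirnas(out, species_mature = cat$mature,
                          species_hairpin = cat$hairpin,
                          other_mature = cat$mature)
  expect_equal(out2$class, out$class)
})

test_that("isoforms of a recorded mature on its own hairpin are flagged", {
  cat <- toy_catalogs()
  shifted <- paste0("G", substr(cat$mature_seq, 1, 20))  # 5' -1 / 3' -1 shift
  # ensure the shifted variant really occurs in the hairpin
  expect_true(grepl(shifted, cat$hairpin_seq, fixed = TRUE))
  iso <- fake_candidate(shifted, cat$hairpin_seq)
  out <- classify_mirnas(iso, species_mature = cat$mature,
                         species_hairpin = cat$hairpin)
  expect_equal(out$class, "ISOFORM")
})

test_that("novel families are named by coordinate with letter and arm suffixes", {
  m1 <- "UUGUUCGAUAAAACUGUUGUG"
  m2 <- "AAAUGACUUGAGAGGUGUAG"
  m2b <- "CAUCUGAAGGAUAGAACACAUA"
  prec <- function(m) paste0("GG", m, "AAACAAAC", revcomp_rna(m), "CC")
  two_loci_a <- fake_candidate(m1, prec(m1), chrom = "Gm08", start = 100L)
  two_loci_b <- fake_candidate(m1, prec(m1), chrom = "Gm18", start = 900L)
  single <- fake_candidate(m2, prec(m2), chrom = "Gm09", start = 500L)
  both_arms_1 <- fake_candidate(m2b, prec(m2b), chrom = "Gm15", start = 700L,
                                arm = "5p")
  both_arms_2 <- fake_candidate(revcomp_rna(m2b), prec(m2b), chrom = "Gm15",
                                start = 700L, arm = "3p")
  records <- rbind(two_loci_a, two_loci_b, single, both_arms_1, both_arms_2)
  records$class <- "NOVEL_FAMILY"
  records$matched_id <- NA_character_

  named <- assign_names(records)
  expect_equal(named$id[1], "gma-MIR-Seq01a")   # Gm08 before Gm18
  expect_equal(named$id[2], "gma-MIR-Seq01b")
  expect_equal(named$id[3], "gma-MIR-Seq02")    # single locus: bare id
  expect_setequal(named$id[4:5], c("gma-MIR-Seq03-5p", "gma-MIR-Seq03-3p"))

  # stability: adding a second locus of family 1 does not rename others
  extra <- fake_candidate(m1, prec(m1), chrom = "Gm20", start = 50L)
  extra$class <- "NOVEL_FAMILY"; extra$matched_id <- NA_character_
  renamed <- assign_names(rbind(records, extra))
  expect_equal(renamed$id[3], "gma-MIR-Seq02")
  expect_setequal(renamed$id[4:5], c("gma-MIR-Seq03-5p", "gma-MIR-Seq03-3p"))
})

test_that("isomiR groups summarise end variation as +n/CORE/+n patterns", {
  prec <- paste0("GGAUC", "AAAUGACUUGAGAGGUGUAG", "CCAAACAAACC",
                 revcomp_rna("AAAUGACUUGAGAGGUGUAG"), "GAUCC")
  ref <- "AAAUGACUUGAGAGGUGUAG"

  single <- group_isomirs(character(0), prec, reference = ref)
  expect_equal(single$pattern, ref)
  expect_equal(c(single$n5, single$n3), c(0L, 0L))
  expect_equal(single$n_isoforms, 1L)

  # shifted members: one 2-nt 5' extension, one 1-nt 3' extension
  mem <- c(paste0("UC", substr(ref, 1, 19)),    # +2 at 5', trimmed 3'
           paste0(substr(ref, 3, 20), "C"))     # trimmed 5', +1 at 3'
  expect_true(all(vapply(mem, grepl, TRUE, x = prec, fixed = TRUE)))
  g <- group_isomirs(mem, prec, reference = ref)
  expect_equal(g$n_isoforms, 3L)
  expect_equal(g$core, substr(ref, 3, 19))
  expect_equal(g$n5, 4L)   # ref extends 2 before core, member adds 2 more
  expect_equal(g$n3, 2L)
  expect_equal(g$pattern, paste0("+4/", substr(ref, 3, 19), "/+2"))

  # members absent from the precursor are rejected with a warning
  expect_warning(group_isomirs(c("GGGGGGGGGGGGGGGGGGG", mem), prec, ref),
                 "dropped")
})

test_that("simulated isomiR truth counts are recovered by grouping", {
  cfg <- small_synth(seed = 8, n_hairpins = 3, isomir_shift_prob = 0.4)
  synth <- generate_genome_and_truth(cfg)
  reads <- simulate_libraries(synth)
  expected <- attr(reads, "expected")
  for (h in unique(expected$hairpin)) {
    tr <- synth$truth[synth$truth$hairpin_id == h, ]
    members <- unique(expected$sequence[expected$hairpin == h &
                                          expected$role %in% c("mature", "isomir")])
    g <- group_isomirs(members, tr$precursor, reference = tr$mature)
    expect_equal(g$n_isoforms, length(members))
  }
})
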