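test_that("primer sets follow the stem-loop construction rules", {
  p <- design_primers("UGACAGAAGAGAGAGAGCACA")
  expect_equal(p$forward, "TGACAGAAGAGAGAGAGCACA")
  expect_equal(nchar(p$backbone), 44L)
  expect_false(grepl("N", p$backbone, fixed = TRUE))
  expect_equal(nchar(p$tail), 6L)
  expect_true(grepl(p$universal_reverse, p$backbone, fixed = TRUE))
  expect_equal(p$stemloop_rt, paste0(p$backbone, p$tail))

  # the tail is the DNA reverse complement of the mature's last six bases
  p2 <- design_primers("UUGUUCGAUAAAACUGUUGUG")   # ends ...UGUUGUG
  expect_equal(p2$tail, "CACAAC")
  expect_error(design_primers("ACGU"), "at least 6")
})

flat_ct <- function(dct_a, dct_b, ref_ct = 20) {
  # two conditions, one target gene, one reference; ct = ref + dct
  rows <- rbind(
    data.frame(gene = "tgt", condition = "A", replicate = seq_along(dct_a),
               ct = ref_ct + dct_a),
    data.frame(gene = "tgt", condition = "B", replicate = seq_along(dct_b),
               ct = ref_ct + dct_b),
    data.frame(gene = "ref", condition = "A", replicate = seq_along(dct_a),
               ct = ref_ct),
    data.frame(gene = "ref", condition = "B", replicate = seq_along(dct_b),
               ct = ref_ct))
  attr(rows, "ref_genes") <- "ref"
  class(rows) <- c("ct_table", "data.frame")
  rows
}

test_that("ddCt identities hold in closed form", {
  same <- flat_ct(c(2, 2, 2), c(2, 2, 2))
  r0 <- suppressWarnings(relative_expression(same, "tgt", "A", "B"))
  expect_equal(r0$ddct, 0)
  expect_equal(r0$rq, 1)

  r <- relative_expression(flat_ct(c(2, 2, 2), c(4, 4, 4)), "tgt", "A", "B")
  expect_equal(r$ddct, -2)
  expect_equal(r$rq, 4)
  expect_equal(log2(r$rq), -r$ddct)
})

test_that("swapping conditions inverts RQ and keeps the p-value", {
  set.seed(4)
  ct <- flat_ct(rnorm(3, 2, 0.1), rnorm(3, 3, 0.1))
  ab <- relative_expression(ct, "tgt", "A", "B")
  ba <- relative_expression(ct, "tgt", "B", "A")
  expect_equal(ab$rq * ba$rq, 1)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("RQ is invariant under a constant Ct shift", {
  set.seed(8)
  ct <- flat_ct(rnorm(3, 1, 0.05), rnorm(3, 2, 0.05))
  shifted <- ct
  shifted$ct <- shifted$ct + 5
  a <- relative_expression(ct, "tgt", "A", "B")
  b <- relative_expression(shifted, "tgt", "A", "B")
  expect_equal(a$rq, b$rq)
  expect_equal(a$p_value, b$p_value)
})

test_that("missing references error and single replicates skip the test", {
  ct <- flat_ct(c(1, 1), c(2, 2))
  expect_error(relative_expression(ct, "tgt", "A", "B", ref_genes = "nope"),
               "absent")
  single <- flat_ct(1, 2)
  expect_warning(r <- relative_expression(single, "tgt", "A", "B"),
                 "single replicate")
  expect_equal(r$rq, 2)
  expect_true(is.na(r$p_value))
})

test_that("a planted 2-fold change is recovered with a significant test", {
  hits <- 0L
  ok_rq <- 0L
  n_runs <- 200L
  for (s in seq_len(n_runs)) {
    ct <- simulate_ct_table("tgt", c("A", "B"),
                            log2fc = matrix(c(1, 0), 1, 2,
                                            dimnames = list("tgt", c("A", "B"))),
                            n_rep = 3, sd_ct = 0.1, seed = 1000 + s)
    r <- relative_expression(ct, "tgt", "A", "B",
                             ref_genes = attr(ct, "ref_genes"))
    if (r$rq > 1.7 && r$rq < 2.3) ok_rq <- ok_rq + 1L
    if (isTRUE(r$significant)) hits <- hits + 1L
  }
  expect_gte(ok_rq / n_runs, 0.95)
  expect_gte(hits / n_runs, 0.95)
})

test_that("the four-comparison report labels only the planted contrast", {
  # expression raised only in the sensitive-treated library
  conds <- c(sc = "DSRC", st = "DSRT", tc = "DTRC", tt = "DTRT")
  lfc <- matrix(c(0, 2, 0, 0), 1, 4, dimnames = list("g", unname(conds)))
  ct <- simulate_ct_table("g", unname(conds), log2fc = lfc,
                          n_rep = 3, sd_ct = 0.1, seed = 99)
  rep <- expression_report(ct, "g", panel = conds,
                           ref_genes = attr(ct, "ref_genes"))
  # 'a' (sensitive control vs stress) and '1' (stressed vs stressed) differ
  expect_true(grepl("a", rep$labels))
  expect_true(grepl("1", rep$labels))
  expect_false(grepl("\\*", rep$labels))
  expect_false(grepl("b", rep$labels))

  # identical inputs give no labels at all
  ct0 <- simulate_ct_table("g", unname(conds), n_rep = 3, sd_ct = 0,
                           seed = 100)
  ct0$ct <- round(ct0$ct, 6)
  rep0 <- expression_report(ct0, "g", panel = conds,
                            ref_genes = attr(ct0, "ref_genes"))
  expect_equal(rep0$labels, "")
})
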