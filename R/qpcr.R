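# Stem-loop RT-qPCR support: primer construction, 2^-ddCt relative
# quantification against multiple reference miRNAs, Welch t-tests.

# 44-nt conserved stem-loop backbone; the six 3'-terminal N positions are
# replaced by the reverse complement of the mature miRNA's last six
# nucleotides during primer design.
STEMLOOP_BACKBONE <- "GTCGTATCCAGTGCAGGGTCCGAGGTATTCGCACTGGATACGAC"
UNIVERSAL_REVERSE <- "GTGCAGGGTCCGAGGT"

#' Design stem-loop RT-qPCR primers for a mature miRNA
#'
#' The forward primer is the mature sequence as DNA; the stem-loop RT
#' primer is the 44-nt conserved backbone followed by a 6-nt variable tail
#' complementary to the miRNA's 3'-terminal six nucleotides; the universal
#' reverse primer is a fixed substring of the backbone.
#'
#' @param mature mature miRNA sequence (RNA or DNA, length >= 6).
#' @param mirna_id optional id carried into the result.
#' @return a `primer_set` list: `mirna_id`, `forward`, `stemloop_rt`,
#'   `universal_reverse`, `backbone`, `tail`.
#' @examples
#' design_primers("UGACAGAAGAGAGAGAGCACA")$forward
#' @export
design_primers <- function(mature, mirna_id = NA_character_) {
  mature <- as_rna(mature)
  if (nchar(mature) < 6L) {
    stop("design_primers(): mature must be at least 6 nt")
  }
  last6 <- substr(mature, nchar(mature) - 5L, nchar(mature))
  tail <- as_dna(revcomp_rna(last6))
  structure(list(mirna_id = mirna_id,
                 forward = as_dna(mature),
                 stemloop_rt = paste0(STEMLOOP_BACKBONE, tail),
                 universal_reverse = UNIVERSAL_REVERSE,
                 backbone = STEMLOOP_BACKBONE,
                 tail = tail),
            class = "primer_set")
}

#' @export
print.primer_set <- function(x, ...) {
  cat("Stem-loop RT-qPCR primer set",
      if (!is.na(x$mirna_id)) paste0(" (", x$mirna_id, ")"), "\n", sep = "")
  cat("  forward:          5'-", x$forward, "-3'\n", sep = "")
  cat("  stem-loop RT:     5'-", x$stemloop_rt, "-3'\n", sep = "")
  cat("  universal reverse: 5'-", x$universal_reverse, "-3'\n", sep = "")
  invisible(x)
}

#' Read a Ct table from TSV
#'
#' Expected columns: `gene`, `condition`, `replicate`, `ct`.
#'
#' @param path TSV path.
#' @param ref_genes character vector of reference gene ids.
#' @return a `ct_table` data frame with attribute `ref_genes`.
#' @export
read_ct_table <- function(path, ref_genes = character(0)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "condition", "replicate", "ct") %in% names(df)))
  attr(df, "ref_genes") <- ref_genes
  class(df) <- c("ct_table", "data.frame")
  df
}

# Per-replicate delta-Ct of `gene` vs the arithmetic mean Ct of the
# reference genes in one condition. (Averaging Ct values is the geometric
# mean on the linear 2^-Ct scale, the usual multi-reference normaliser.)
delta_ct <- function(ct, gene, condition, ref_genes) {
  sub <- ct[ct$condition == condition, , drop = FALSE]
  reps <- sort(unique(sub$replicate[sub$gene == gene]))
  if (length(reps) == 0L) {
    stop("delta_ct(): no Ct values for gene ", gene, " in ", condition)
  }
  vapply(reps, function(r) {
    tgt <- sub$ct[sub$gene == gene & sub$replicate == r]
    refs <- vapply(ref_genes, function(g) {
      v <- sub$ct[sub$gene == g & sub$replicate == r]
      if (length(v) == 0L) stop("delta_ct(): reference gene ", g,
                                " missing in ", condition,
                                " replicate ", r)
      mean(v)
    }, 0)
    mean(tgt) - mean(refs)
  }, 0)
}

#' Relative expression of a miRNA between two conditions (2^-ddCt)
#'
#' Per replicate, the target Ct is normalised by the arithmetic mean Ct of
#' the reference genes (delta-Ct); the delta-delta-Ct is the difference of
#' the mean delta-Ct of condition A minus condition B, and the relative
#' quantity is `RQ = 2^-ddCt` (A relative to B). A Welch two-sample,
#' two-tailed t-test compares the replicate delta-Ct sets; with fewer than
#' two replicates in either condition the test is skipped with a warning.
#'
#' @param ct a `ct_table`.
#' @param gene target gene id.
#' @param condition_a,condition_b the two conditions (A is reported
#'   relative to B).
#' @param ref_genes reference gene ids (default: the table's `ref_genes`
#'   attribute).
#' @param alpha significance level (default 0.05).
#' @return an `expression_result` list: `gene`, `condition_a/b`,
#'   `dct_a`/`dct_b` (replicate vectors), `ddct`, `rq`, `t_statistic`,
#'   `p_value`, `significant`.
#' @export
relative_expression <- function(ct, gene, condition_a, condition_b,
                                ref_genes = attr(ct, "ref_genes"),
                                alpha = 0.05) {
  if (is.null(ref_genes) || length(ref_genes) == 0L) {
    stop("relative_expression(): reference gene ids are required")
  }
  missing_ref <- setdiff(ref_genes, unique(ct$gene))
  if (length(missing_ref)) {
    stop("relative_expression(): reference gene(s) absent from the table: ",
         paste(missing_ref, collapse = ", "))
  }
  dct_a <- delta_ct(ct, gene, condition_a, ref_genes)
  dct_b <- delta_ct(ct, gene, condition_b, ref_genes)
  ddct <- mean(dct_a) - mean(dct_b)
  rq <- 2^(-ddct)
  if (length(dct_a) >= 2L && length(dct_b) >= 2L) {
    tt <- tryCatch(stats::t.test(dct_a, dct_b, var.equal = FALSE,
                                 alternative = "two.sided"),
                   error = function(e) NULL)  # e.g. essentially constant data
    t_stat <- if (is.null(tt)) NA_real_ else unname(tt$statistic)
    p <- if (is.null(tt)) NA_real_ else tt$p.value
  } else {
    warning("relative_expression(): a single replicate; t-test skipped")
    t_stat <- NA_real_
    p <- NA_real_
  }
  structure(list(gene = gene, condition_a = condition_a,
                 condition_b = condition_b,
                 dct_a = dct_a, dct_b = dct_b,
                 ddct = ddct, rq = rq,
                 t_statistic = t_stat, p_value = p,
                 significant = !is.na(p) && p < alpha),
            class = "expression_result")
}

#' @export
print.expression_result <- function(x, ...) {
  cat(sprintf("%s: %s vs %s  ddCt = %.3f  RQ = %.3f  p = %s%s\n",
              x$gene, x$condition_a, x$condition_b, x$ddct, x$rq,
              format.pval(x$p_value, digits = 3),
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Significance report across a four-library stress design
#'
#' For each gene and each stress panel of four libraries (sensitive/
#' susceptible control and treated, tolerant/resistant control and
#' treated), runs the four pairwise comparisons used in the source design
#' and labels significant ones (`p < alpha`) with the corresponding codes:
#' `*` control vs control between genotypes, `a` control vs stress in the
#' sensitive genotype, `b` control vs stress in the tolerant genotype,
#' `1` stressed vs stressed between genotypes.
#'
#' @param ct a `ct_table`.
#' @param genes target gene ids.
#' @param panel named character vector with elements `sc`, `st`, `tc`,
#'   `tt`: the sensitive-control, sensitive-treated, tolerant-control and
#'   tolerant-treated condition ids.
#' @param ref_genes reference gene ids (default: attribute of `ct`).
#' @param alpha significance level.
#' @return data frame, one row per gene: RQ of each comparison, its
#'   p-value, and the concatenated significance `labels`.
#' @export
expression_report <- function(ct, genes, panel,
                              ref_genes = attr(ct, "ref_genes"),
                              alpha = 0.05) {
  stopifnot(all(c("sc", "st", "tc", "tt") %in% names(panel)))
  comparisons <- list(
    "*" = c(panel[["sc"]], panel[["tc"]]),
    "a" = c(panel[["st"]], panel[["sc"]]),
    "b" = c(panel[["tt"]], panel[["tc"]]),
    "1" = c(panel[["st"]], panel[["tt"]]))
  rows <- lapply(genes, function(g) {
    res <- lapply(comparisons, function(cc) {
      relative_expression(ct, g, cc[1L], cc[2L], ref_genes, alpha)
    })
    labels <- paste(names(res)[vapply(res, function(r)
      isTRUE(r$significant), logical(1L))], collapse = "")
    data.frame(gene = g,
               rq_genotype_control = res[["*"]]$rq,
               p_genotype_control = res[["*"]]$p_value,
               rq_sensitive_stress = res[["a"]]$rq,
               p_sensitive_stress = res[["a"]]$p_value,
               rq_tolerant_stress = res[["b"]]$rq,
               p_tolerant_stress = res[["b"]]$p_value,
               rq_genotype_stress = res[["1"]]$rq,
               p_genotype_stress = res[["1"]]$p_value,
               labels = labels,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
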