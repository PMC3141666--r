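#' Load a packaged reference table
#'
#' The package ships four reference tables from a soybean stress
#' small-RNA sequencing study, used as ground truth in tests and reports:
#' \describe{
#'   \item{T2 / novel_loci}{novel miRNA families with mature sequence and
#'     precursor locus (id, mature, size, chrom, start, end, length,
#'     sense, arm, region);}
#'   \item{T3 / conserved_families}{families conserved in other plant
#'     species (family, acronym, sequence, size, species);}
#'   \item{T5 / isomir_patterns}{isomiR groups in +n/CORE/+m pattern
#'     notation (group, acronym, pattern, n_isos, chrom, start, end);}
#'   \item{T6 / predicted_targets}{predicted mRNA targets with
#'     miRNA/mRNA pairing strings (mirna_id, locus_target, description,
#'     pairing).}
#' }
#'
#' @param table_id one of `"T2"`, `"T3"`, `"T5"`, `"T6"` (or the
#'   descriptive aliases above).
#' @return a data frame with the columns listed; integer columns are
#'   parsed as integers.
#' @examples
#' head(load_fixture("T2"))
#' @export
load_fixture <- function(table_id) {
  files <- c(T2 = "novel_mirna_loci.tsv",
             novel_loci = "novel_mirna_loci.tsv",
             T3 = "conserved_families.tsv",
             conserved_families = "conserved_families.tsv",
             T5 = "isomir_patterns.tsv",
             isomir_patterns = "isomir_patterns.tsv",
             T6 = "predicted_targets.tsv",
             predicted_targets = "predicted_targets.tsv")
  if (!table_id %in% names(files)) {
    stop("load_fixture(): unknown table id '", table_id, "'; use one of ",
         paste(unique(names(files)), collapse = ", "))
  }
  path <- system.file("extdata", files[[table_id]], package = "stemloop",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          fill = TRUE)
  expected_cols <- list(
    novel_mirna_loci.tsv = c("id", "mature", "size", "chrom", "start",
                             "end", "length", "sense", "arm", "region"),
    conserved_families.tsv = c("family", "acronym", "sequence", "size",
                               "species"),
    isomir_patterns.tsv = c("group", "acronym", "pattern", "n_isos",
                            "chrom", "start", "end"),
    predicted_targets.tsv = c("mirna_id", "locus_target", "description",
                              "pairing"))[[files[[table_id]]]]
  if (!identical(names(df), expected_cols)) {
    stop("load_fixture(): malformed fixture ", files[[table_id]],
         ": expected columns ", paste(expected_cols, collapse = ", "))
  }
  int_cols <- intersect(names(df), c("size", "start", "end", "length",
                                     "n_isos", "group"))
  for (cc in int_cols) {
    v <- suppressWarnings(as.integer(df[[cc]]))
    if (anyNA(v) && !anyNA(df[[cc]])) {
      stop("load_fixture(): non-integer value in column '", cc, "' of ",
           files[[table_id]], " (first bad row: ",
           which(is.na(v) & !is.na(df[[cc]]))[1L], ")")
    }
    df[[cc]] <- v
  }
  df
}

#' Family key of a reference-table id
#'
#' Strips the species prefix and the locus-letter / arm suffixes, e.g.
#' `gma-MIR-Seq04b` and `gma-MIR-Seq04a` both give `Seq04`,
#' `gma-MIR-Seq10-5p` gives `Seq10`.
#'
#' @param id character vector of ids.
#' @return character vector of family keys.
#' @export
fixture_family <- function(id) {
  x <- sub("^[a-z]{3}-MIR-", "", id)
  x <- sub("-(5p|3p)$", "", x)
  sub("^(Seq[0-9]+).*$", "\\1", x)
}
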