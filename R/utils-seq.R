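#' @import Biostrings
#' @importFrom IRanges IRanges
#' @importFrom stats setNames
NULL

# Sequence strings are handled as plain uppercase character vectors.
# Small-RNA tags and precursors are RNA (U); genomes and primers are DNA (T).

#' Normalise a sequence to the RNA alphabet
#'
#' Uppercases and converts T to U. Used on all read/tag input so that
#' catalog matching and duplex evaluation are U/T-insensitive.
#'
#' @param x character vector of sequences.
#' @return character vector over A, C, G, U (other characters untouched).
#' @export
as_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' Normalise a sequence to the DNA alphabet
#'
#' @param x character vector of sequences.
#' @return character vector over A, C, G, T.
#' @export
as_dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' Reverse complement of an RNA sequence
#'
#' @param x character vector of RNA sequences (A/C/G/U).
#' @return character vector of reverse complements.
#' @export
revcomp_rna <- function(x) {
  vapply(chartr("ACGU", "UGCA", as_rna(x)), function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Reverse complement of a DNA sequence
#'
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
revcomp_dna <- function(x) {
  vapply(chartr("ACGT", "TGCA", as_dna(x)), function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

is_valid_rna <- function(x) grepl("^[ACGU]+$", as_rna(x))

# Watson-Crick or G:U wobble pairing weight between two RNA bases.
# Weights follow the folding default: G-C = 3, A-U = 2, G-U = 1, else 0.
pair_weight_one <- function(a, b, weights = c(GC = 3, AU = 2, GU = 1)) {
  key <- paste(sort(c(a, b)), collapse = "")
  switch(key,
    "CG" = unname(weights[["GC"]]),
    "AU" = unname(weights[["AU"]]),
    "GU" = unname(weights[["GU"]]),
    0
  )
}

is_wc_pair <- function(a, b) {
  (a == "A" && b == "U") || (a == "U" && b == "A") ||
    (a == "G" && b == "C") || (a == "C" && b == "G")
}

is_gu_pair <- function(a, b) {
  (a == "G" && b == "U") || (a == "U" && b == "G")
}

is_rna_pair <- function(a, b) is_wc_pair(a, b) || is_gu_pair(a, b)
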