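#' Render the pairing string between a miRNA and a target site
#'
#' Classifies each aligned position of an ungapped miRNA/site duplex:
#' `|` for a Watson-Crick pair (A-U or G-C), `:` for a G:U wobble in either
#' orientation, `-` for a mismatch. The site sequence must be supplied in
#' the pairing orientation, i.e. position i of the site is the base that
#' faces position i of the miRNA in the antiparallel duplex (for a target
#' window read 5'-3' on the transcript, pass its reverse).
#'
#' @param mirna mature miRNA sequence (single string).
#' @param target_site site sequence in pairing orientation, same length.
#' @return a single string over `|`, `:`, `-` of the miRNA length.
#' @examples
#' render_pairing("AGC", "UCG")  # "|||"
#' render_pairing("G", "U")      # ":"
#' @export
render_pairing <- function(mirna, target_site) {
  m <- seq_chars(as_rna(mirna))
  t <- seq_chars(as_rna(target_site))
  if (length(m) != length(t)) {
    stop("render_pairing(): miRNA and site must have equal length (ungapped)")
  }
  sym <- vapply(seq_along(m), function(i) {
    if (is_wc_pair(m[i], t[i])) "|"
    else if (is_gu_pair(m[i], t[i])) ":"
    else "-"
  }, character(1L))
  paste(sym, collapse = "")
}

#' Score a pairing string with mismatch and G:U weights
#'
#' The complementarity score is `mismatch_weight` per `-` symbol plus
#' `gu_weight` per `:` symbol; Watson-Crick pairs cost nothing. Under the
#' default weights (1 and 0.5) a site is reported as a predicted target
#' when its score does not exceed 3.0 points.
#'
#' @param pairing pairing string over `|`, `:`, `-` (whitespace ignored).
#' @param mismatch_weight penalty per mismatch (default 1).
#' @param gu_weight penalty per G:U wobble (default 0.5).
#' @return numeric score.
#' @examples
#' score_pairing_string("--|||")  # 2
#' @export
score_pairing_string <- function(pairing, mismatch_weight = 1, gu_weight = 0.5) {
  p <- gsub("[[:space:]]", "", pairing)
  ch <- seq_chars(p)
  if (length(ch) && !all(ch %in% c("|", ":", "-"))) {
    stop("score_pairing_string(): pairing may contain only '|', ':' and '-'")
  }
  mismatch_weight * sum(ch == "-") + gu_weight * sum(ch == ":")
}
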