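#' Smith-Waterman local alignment
#'
#' Plain local alignment with linear gap penalties, as used to place the
#' reverse-complemented tag (the candidate miRNA-star arm) inside a genomic
#' flank window. Matching is by sequence identity only: G:U wobble is not
#' rewarded here; wobble handling belongs to duplex evaluation and target
#' scoring. U and T are treated as equivalent.
#'
#' Ties on the optimal score are broken towards the smallest subject start,
#' then the smallest query start; the traceback itself prefers diagonal
#' moves, then a gap in the subject, then a gap in the query, so that
#' results are deterministic.
#'
#' @param query,subject sequences (single strings, RNA or DNA alphabet).
#' @param match match score (default +1).
#' @param mismatch mismatch score (default -1).
#' @param gap linear gap penalty per gapped position (default -2).
#' @return an object of class `local_alignment`: a list with `score`,
#'   1-based inclusive `q_start`, `q_end`, `s_start`, `s_end` (all 0 for an
#'   empty alignment), and the gapped `q_aln`/`s_aln` strings.
#' @examples
#' smith_waterman("ACGU", "ACGU")$score  # 4
#' @export
smith_waterman <- function(query, subject, match = 1, mismatch = -1, gap = -2) {
  if (!nzchar(query) || !nzchar(subject)) {
    stop("smith_waterman(): sequences must be non-empty")
  }
  q <- seq_chars(as_rna(query))
  s <- seq_chars(as_rna(subject))
  nq <- length(q)
  ns <- length(s)

  H <- matrix(0, nrow = nq + 1L, ncol = ns + 1L)
  for (i in seq_len(nq)) {
    sub_row <- ifelse(s == q[i], match, mismatch)
    for (j in seq_len(ns)) {
      h <- max(0,
               H[i, j] + sub_row[j],     # diagonal
               H[i, j + 1L] + gap,       # gap in subject (consume query)
               H[i + 1L, j] + gap)       # gap in query (consume subject)
      H[i + 1L, j + 1L] <- h
    }
  }

  best <- max(H)
  if (best <= 0) {
    return(structure(list(score = 0, q_start = 0L, q_end = 0L,
                          s_start = 0L, s_end = 0L, q_aln = "", s_aln = ""),
                     class = "local_alignment"))
  }

  ends <- which(H == best, arr.ind = TRUE)
  # Trace back from every optimal end cell, then pick the alignment with the
  # smallest subject start (then query start, then ends, for determinism).
  trace_one <- function(i, j) {
    qa <- character(0)
    sa <- character(0)
    while (H[i, j] > 0) {
      d <- H[i - 1L, j - 1L] + (if (q[i - 1L] == s[j - 1L]) match else mismatch)
      if (H[i, j] == d) {
        qa <- c(q[i - 1L], qa); sa <- c(s[j - 1L], sa)
        i <- i - 1L; j <- j - 1L
      } else if (H[i, j] == H[i - 1L, j] + gap) {
        qa <- c(q[i - 1L], qa); sa <- c("-", sa)
        i <- i - 1L
      } else {
        qa <- c("-", qa); sa <- c(s[j - 1L], sa)
        j <- j - 1L
      }
    }
    list(q_start = i, s_start = j,
         q_aln = paste(qa, collapse = ""), s_aln = paste(sa, collapse = ""))
  }

  cand <- vector("list", nrow(ends))
  for (k in seq_len(nrow(ends))) {
    tr <- trace_one(ends[k, 1L], ends[k, 2L])
    cand[[k]] <- list(score = best,
                      q_start = tr$q_start, q_end = ends[k, 1L] - 1L,
                      s_start = tr$s_start, s_end = ends[k, 2L] - 1L,
                      q_aln = tr$q_aln, s_aln = tr$s_aln)
  }
  ord <- order(vapply(cand, `[[`, 0L, "s_start"),
               vapply(cand, `[[`, 0L, "q_start"),
               vapply(cand, `[[`, 0L, "s_end"),
               vapply(cand, `[[`, 0L, "q_end"))
  out <- cand[[ord[1L]]]
  out$q_start <- as.integer(out$q_start)
  out$s_start <- as.integer(out$s_start)
  out$q_end <- as.integer(out$q_end)
  out$s_end <- as.integer(out$s_end)
  structure(out, class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat("Local alignment, score", x$score, "\n")
  if (x$score > 0) {
    cat(sprintf("  query   %d-%d  %s\n", x$q_start, x$q_end, x$q_aln))
    cat(sprintf("  subject %d-%d  %s\n", x$s_start, x$s_end, x$s_aln))
  }
  invisible(x)
}
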