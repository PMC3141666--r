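#' Fold an RNA into its maximum-weight non-crossing secondary structure
#'
#' Weighted base-pair maximisation (Nussinov-style dynamic programming)
#' under a minimum hairpin-loop constraint. Pairs are scored G-C = 3,
#' A-U = 2, G-U = 1 by default; the optimal structure maximises the summed
#' pair weight over all non-crossing (pseudoknot-free) structures in which
#' every pair (i, j) satisfies j - i > `min_loop`. The traceback is
#' deterministic: whenever pairing position i attains the optimum, i is
#' paired with the largest valid partner (the outermost choice, which
#' reconstructs long stems in preference to equivalent-score pairings into
#' loop regions); otherwise i is left unpaired.
#'
#' The summed pair weight is a stem-stability proxy, not a thermodynamic
#' free energy; it is not comparable to nearest-neighbour kcal/mol values.
#'
#' @param sequence RNA sequence (a single string; T accepted and read as U).
#' @param min_loop minimum number of unpaired positions enclosed by any
#'   pair (default 3).
#' @param weights named numeric vector with elements `GC`, `AU`, `GU`.
#' @return an object of class `fold_structure`: list with `sequence`,
#'   `dotbracket`, `pairs` (two-column integer matrix, i < j, ordered by i),
#'   `n_pairs`, `score`, and `partner` (integer vector, NA when unpaired).
#' @examples
#' fold_hairpin("GGGAAACCC")$dotbracket  # "(((...)))"
#' @export
fold_hairpin <- function(sequence, min_loop = 3L,
                         weights = c(GC = 3, AU = 2, GU = 1)) {
  s <- as_rna(sequence)
  if (!is_valid_rna(s)) {
    stop("fold_hairpin(): sequence must contain only A, C, G, U/T")
  }
  x <- seq_chars(s)
  n <- length(x)
  min_loop <- as.integer(min_loop)

  # Pairability weight matrix.
  W <- matrix(0, n, n)
  idx_a <- x == "A"; idx_c <- x == "C"; idx_g <- x == "G"; idx_u <- x == "U"
  W[outer(idx_g, idx_c) | outer(idx_c, idx_g)] <- weights[["GC"]]
  W[outer(idx_a, idx_u) | outer(idx_u, idx_a)] <- weights[["AU"]]
  W[outer(idx_g, idx_u) | outer(idx_u, idx_g)] <- weights[["GU"]]

  # M[i, j] = best score on x[i..j]; 0 when j - i <= min_loop.
  M <- matrix(0, n, n)
  if (n > min_loop + 1L) {
    for (d in seq.int(min_loop + 1L, n - 1L)) {
      for (i in seq_len(n - d)) {
        j <- i + d
        best <- M[i + 1L, j]               # i unpaired
        ks <- seq.int(i + min_loop + 1L, j)
        wk <- W[i, ks]
        hit <- wk > 0
        if (any(hit)) {
          ks <- ks[hit]
          inner <- ifelse(ks - 1L >= i + 1L, M[cbind(i + 1L, ks - 1L)], 0)
          outer_ <- ifelse(ks + 1L <= j, M[cbind(pmin(ks + 1L, j), j)], 0)
          outer_[ks + 1L > j] <- 0
          best <- max(best, max(wk[hit] + inner + outer_))
        }
        M[i, j] <- best
      }
    }
  }

  # Deterministic traceback on an explicit stack of subproblems.
  partner <- rep(NA_integer_, n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1L]; j <- iv[2L]
    if (i >= j || j - i <= min_loop) next
    target <- M[i, j]
    if (target == 0) next
    paired <- FALSE
    for (k in seq.int(j, i + min_loop + 1L)) {
      if (W[i, k] == 0) next
      inner <- if (k - 1L >= i + 1L) M[i + 1L, k - 1L] else 0
      outer_ <- if (k + 1L <= j) M[k + 1L, j] else 0
      if (W[i, k] + inner + outer_ == target) {
        partner[i] <- k
        partner[k] <- i
        stack[[length(stack) + 1L]] <- c(i + 1L, k - 1L)
        stack[[length(stack) + 1L]] <- c(k + 1L, j)
        paired <- TRUE
        break
      }
    }
    if (!paired) stack[[length(stack) + 1L]] <- c(i + 1L, j)
  }

  pr <- which(!is.na(partner) & seq_len(n) < partner)
  pairs <- cbind(i = pr, j = partner[pr])
  db <- rep(".", n)
  db[pairs[, 1L]] <- "("
  db[pairs[, 2L]] <- ")"
  structure(list(sequence = s,
                 dotbracket = paste(db, collapse = ""),
                 pairs = pairs,
                 n_pairs = nrow(pairs),
                 score = if (n) M[1L, n] else 0,
                 partner = partner),
            class = "fold_structure")
}

#' @export
print.fold_structure <- function(x, ...) {
  cat(x$sequence, "\n", x$dotbracket, "\n", sep = "")
  cat(sprintf("%d pairs, pair score %g\n", x$n_pairs, x$score))
  invisible(x)
}

# Terminal (hairpin) loops: pairs enclosing no other pair. Returns a data
# frame with the loop-closing pair, loop extent and the depth of the
# enclosing stem (number of pairs nesting around it), used to identify the
# terminal loop of the longest stem.
hairpin_loops <- function(fold) {
  pairs <- fold$pairs
  if (nrow(pairs) == 0L) {
    return(data.frame(i = integer(0), j = integer(0),
                      loop_start = integer(0), loop_end = integer(0),
                      stem_depth = integer(0)))
  }
  encloses_none <- vapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    !any(pairs[, 1L] > i & pairs[, 2L] < j)
  }, logical(1L))
  hp <- pairs[encloses_none, , drop = FALSE]
  depth <- vapply(seq_len(nrow(hp)), function(k) {
    i <- hp[k, 1L]; j <- hp[k, 2L]
    sum(pairs[, 1L] <= i & pairs[, 2L] >= j)
  }, integer(1L))
  data.frame(i = hp[, 1L], j = hp[, 2L],
             loop_start = hp[, 1L] + 1L, loop_end = hp[, 2L] - 1L,
             stem_depth = depth)
}

# The terminal loop of the longest stem (ties: first by position).
terminal_loop <- function(fold) {
  hp <- hairpin_loops(fold)
  if (nrow(hp) == 0L) return(NULL)
  hp <- hp[order(-hp$stem_depth, hp$i), , drop = FALSE]
  hp[1L, ]
}
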