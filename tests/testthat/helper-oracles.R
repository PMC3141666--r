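# Independent oracles used by the dynamic-programming tests. These are
# deliberately naive (enumeration over substring pairs / explicit
# structure enumeration) and share no code with the implementations they
# check.

# Best local alignment score = best global (Needleman-Wunsch) score over
# all pairs of substrings, computed by an independent iterative DP.
brute_force_local_score <- function(q, s, match = 1, mismatch = -1, gap = -2) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  nw <- function(a, b) {
    la <- length(a); lb <- length(b)
    M <- matrix(0, la + 1, lb + 1)
    M[, 1] <- gap * (0:la)
    M[1, ] <- gap * (0:lb)
    for (i in seq_len(la)) {
      for (j in seq_len(lb)) {
        M[i + 1, j + 1] <- max(
          M[i, j] + if (a[i] == b[j]) match else mismatch,
          M[i, j + 1] + gap,
          M[i + 1, j] + gap)
      }
    }
    M[la + 1, lb + 1]
  }
  best <- 0
  for (a1 in seq_along(qc)) for (a2 in a1:length(qc)) {
    for (b1 in seq_along(sc)) for (b2 in b1:length(sc)) {
      best <- max(best, nw(qc[a1:a2], sc[b1:b2]))
    }
  }
  best
}

# Maximum weighted pair score over all non-crossing structures, by
# explicit recursive enumeration (position 1 unpaired, or paired with
# every admissible partner), without memoisation.
enumerate_fold_score <- function(seq, min_loop = 3,
                                 weights = c(GC = 3, AU = 2, GU = 1)) {
  x <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  w <- function(a, b) {
    k <- paste(sort(c(a, b)), collapse = "")
    if (k == "CG") weights[["GC"]]
    else if (k == "AU") weights[["AU"]]
    else if (k == "GU") weights[["GU"]]
    else 0
  }
  rec <- function(i, j) {
    if (i >= j || j - i <= min_loop) return(0)
    best <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      wk <- w(x[i], x[k])
      if (wk > 0) best <- max(best, wk + rec(i + 1, k - 1) + rec(k + 1, j))
    }
    best
  }
  rec(1, length(x))
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                                collapse = "")
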