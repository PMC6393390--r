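# independent oracles used across tests

rand_protein <- function(n, pool = c("A","C","D","E","F","G","H","I","K","L",
                                     "M","N","P","Q","R","S","T","V","W","Y")) {
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# exhaustive global affine alignment score by plain recursion over edit
# operations (no DP); gap of length L costs open + L * ext
bf_global_affine <- function(a, b, mat, open, ext) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  rec <- function(i, j, state) {
    if (i > la && j > lb) return(0)
    best <- -Inf
    if (i <= la && j <= lb) {
      best <- max(best, mat[av[i], bv[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= la) {
      cost <- ext + if (state != "D") open else 0
      best <- max(best, rec(i + 1, j, "D") - cost)
    }
    if (j <= lb) {
      cost <- ext + if (state != "I") open else 0
      best <- max(best, rec(i, j + 1, "I") - cost)
    }
    best
  }
  rec(1, 1, "M")
}

# brute-force local score: best global score over all non-empty substring
# pairs, floored at zero
bf_local_score <- function(a, b, mat, open, ext) {
  la <- nchar(a); lb <- nchar(b)
  best <- 0
  for (i1 in 1:la) for (i2 in i1:la) {
    sa <- substr(a, i1, i2)
    for (j1 in 1:lb) for (j2 in j1:lb) {
      best <- max(best, bf_global_affine(sa, substr(b, j1, j2),
                                         mat, open, ext))
    }
  }
  best
}

# direct per-window motif scoring, independent of the vectorized scanner
bf_window_scores <- function(seq, consensus, mat) {
  s <- strsplit(seq, "")[[1]]; cons <- strsplit(consensus, "")[[1]]
  L <- length(cons)
  vapply(seq_len(length(s) - L + 1), function(p) {
    sum(vapply(seq_len(L), function(i) mat[cons[i], s[p + i - 1]],
               numeric(1)))
  }, numeric(1))
}
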