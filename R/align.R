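#' BLOSUM62 substitution matrix with neutral unknown residues
#'
#' Returns the standard BLOSUM62 matrix restricted to the 20 amino acids
#' plus `X`, with every score involving `X` set to 0 so that unknown
#' residues neither reward nor penalize a match.
#'
#' @return 21 x 21 integer matrix with dimnames over `ACDEFGHIKLMNPQRSTVWYX`.
#' @export
blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62[AA_ALPHABET_X, AA_ALPHABET_X]
  m["X", ] <- 0L
  m[, "X"] <- 0L
  storage.mode(m) <- "integer"
  m
}

#' Smith-Waterman local alignment with affine gaps
#'
#' Optimal local alignment of two protein strings under a substitution
#' matrix and affine gap penalties: a gap of length L costs
#' `gap_open + L * gap_extend` (BLAST protein convention, defaults 11/1).
#' The highest-scoring cell is chosen with ties broken by the smallest
#' target end then query end position; traceback prefers diagonal over
#' vertical over horizontal moves, which makes the result deterministic.
#'
#' @param query,target Protein strings (X allowed, scored 0).
#' @param matrix Substitution matrix (default [blosum62()]).
#' @param gap_open,gap_extend Non-negative gap penalties.
#' @return A list of class `"alignment_result"`: `score`, `q_start`,
#'   `q_end`, `t_start`, `t_end` (1-based inclusive), `aligned_query`,
#'   `aligned_target` (with `-` gaps), `identity`, `gapped`. A pair with no
#'   positive-scoring alignment returns `score = 0` and empty coordinates.
#' @examples
#' local_align("ETKDRGLF", "AAETKDRGLFAA")
#' @export
local_align <- function(query, target, matrix = blosum62(),
                        gap_open = 11, gap_extend = 1) {
  stopifnot(nchar(query) > 0, nchar(target) > 0)
  q <- strsplit(toupper(query), "")[[1]]
  t <- strsplit(toupper(target), "")[[1]]
  n <- length(q); m <- length(t)
  NEG <- -1e9
  H <- base::matrix(0, n + 1, m + 1)
  E <- base::matrix(NEG, n + 1, m + 1)   # gap in query (consume target)
  F_ <- base::matrix(NEG, n + 1, m + 1)  # gap in target (consume query)
  sub <- base::matrix(matrix[q, t], n, m)
  go <- gap_open + gap_extend
  for (i in 1:n) {
    Hi1 <- H[i, ]; Fi1 <- F_[i, ]
    Hi <- H[i + 1, ]; Ei <- E[i + 1, ]; Fi <- F_[i + 1, ]
    for (j in 1:m) {
      e <- max(Hi[j] - go, Ei[j] - gap_extend)
      f <- max(Hi1[j + 1] - go, Fi1[j + 1] - gap_extend)
      h <- max(0, Hi1[j] + sub[i, j], e, f)
      Ei[j + 1] <- e; Fi[j + 1] <- f; Hi[j + 1] <- h
    }
    H[i + 1, ] <- Hi; E[i + 1, ] <- Ei; F_[i + 1, ] <- Fi
  }
  best <- max(H)
  if (best <= 0) {
    return(structure(list(score = 0, q_start = 0L, q_end = 0L,
                          t_start = 0L, t_end = 0L, aligned_query = "",
                          aligned_target = "", identity = NA_real_,
                          gapped = FALSE), class = "alignment_result"))
  }
  # ties: smallest target end, then smallest query end
  hits <- which(H == best, arr.ind = TRUE)
  hits <- hits[order(hits[, 2], hits[, 1]), , drop = FALSE]
  i <- hits[1, 1]; j <- hits[1, 2]
  q_end <- i - 1L; t_end <- j - 1L
  aq <- character(0); at <- character(0)
  state <- "H"
  while (TRUE) {
    if (state == "H") {
      if (H[i, j] == 0) break
      if (i > 1 && j > 1 && H[i, j] == H[i - 1, j - 1] + sub[i - 1, j - 1]) {
        aq <- c(q[i - 1], aq); at <- c(t[j - 1], at)
        i <- i - 1; j <- j - 1
      } else if (H[i, j] == F_[i, j]) {
        state <- "F"
      } else if (H[i, j] == E[i, j]) {
        state <- "E"
      } else stop("traceback failure")     # nocov
    } else if (state == "F") {             # gap in target, consume query
      aq <- c(q[i - 1], aq); at <- c("-", at)
      from_open <- H[i - 1, j] - go
      from_ext <- F_[i - 1, j] - gap_extend
      i <- i - 1
      state <- if (F_[i + 1, j] == from_open && from_open >= from_ext) "H" else "F"
    } else {                               # E: gap in query, consume target
      aq <- c("-", aq); at <- c(t[j - 1], at)
      from_open <- H[i, j - 1] - go
      from_ext <- E[i, j - 1] - gap_extend
      j <- j - 1
      state <- if (E[i, j + 1] == from_open && from_open >= from_ext) "H" else "E"
    }
  }
  q_start <- i; t_start <- j   # i,j are 1 + (0-based start)
  ident <- mean(aq == at & aq != "-")
  structure(list(score = best,
                 q_start = as.integer(q_start), q_end = as.integer(q_end),
                 t_start = as.integer(t_start), t_end = as.integer(t_end),
                 aligned_query = paste(aq, collapse = ""),
                 aligned_target = paste(at, collapse = ""),
                 identity = ident,
                 gapped = any(aq == "-") || any(at == "-")),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("local alignment: score %g, query %d-%d, target %d-%d%s\n",
              x$score, x$q_start, x$q_end, x$t_start, x$t_end,
              if (isTRUE(x$gapped)) " (gapped)" else ""))
  if (nzchar(x$aligned_query)) {
    cat(" ", x$aligned_query, "\n ", x$aligned_target, "\n", sep = "")
  }
  invisible(x)
}

# ungapped self-score of a consensus under the package matrix
self_score <- function(consensus, matrix = blosum62()) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  sum(matrix[cbind(chars, chars)])
}
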