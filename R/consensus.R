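#' Positional residue-count matrix of equal-length segments
#'
#' @param segments Character vector of equal-length, gap-free protein
#'   strings (or a match data.frame with a `matched` column).
#' @return A list of class `"count_matrix"`: `counts` (L x 20 integer
#'   matrix, positions x residues), `length`, `n_segments`. Every row sums
#'   to `n_segments`.
#' @examples
#' build_count_matrix(c("AC", "AC", "AC"))
#' @export
build_count_matrix <- function(segments) {
  if (is.data.frame(segments)) segments <- segments$matched
  stopifnot(length(segments) >= 1)
  L <- nchar(segments[1])
  bad <- which(nchar(segments) != L)
  if (length(bad) > 0) {
    stop(sprintf("segment %d ('%s') has length %d, expected %d",
                 bad[1], segments[bad[1]], nchar(segments[bad[1]]), L),
         call. = FALSE)
  }
  for (i in seq_along(segments)) {
    .check_protein(segments[i], allow_x = FALSE,
                   what = paste("segment", i))
  }
  mat <- base::matrix(0L, nrow = L, ncol = 20,
                      dimnames = list(NULL, AA20))
  split_ <- strsplit(segments, "")
  for (chars in split_) {
    idx <- cbind(seq_len(L), match(chars, AA20))
    mat[idx] <- mat[idx] + 1L
  }
  structure(list(counts = mat, length = L, n_segments = length(segments)),
            class = "count_matrix")
}

#' Consensus string of a count matrix
#'
#' Per position, the residue with the maximal count; ties are broken
#' lexicographically (columns are in alphabetical residue order).
#'
#' @param matrix A `"count_matrix"` from [build_count_matrix()] or a plain
#'   L x 20 count matrix with residue column names.
#' @return Protein string of length L.
#' @export
consensus_string <- function(matrix) {
  counts <- if (inherits(matrix, "count_matrix")) matrix$counts else matrix
  paste(colnames(counts)[apply(counts, 1, which.max)], collapse = "")
}

#' Per-position information content (bits)
#'
#' `IC_j = log2(20) - H_j`, where `H_j` is the Shannon entropy of the
#' position-j residue frequencies. No small-sample correction is applied
#' by default (set `small_sample = TRUE` for the `(19) / (2 ln2 n)`
#' correction used by logo software).
#'
#' @inheritParams consensus_string
#' @param small_sample Apply the small-sample correction (default `FALSE`).
#' @return Numeric vector of length L, each value in \[0, log2(20)\]
#'   (correction can push values slightly below 0; they are clamped).
#' @export
information_content <- function(matrix, small_sample = FALSE) {
  cm <- if (inherits(matrix, "count_matrix")) matrix else
    list(counts = matrix, n_segments = sum(matrix[1, ]))
  freqs <- cm$counts / rowSums(cm$counts)
  H <- apply(freqs, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  ic <- log2(20) - H
  if (small_sample) {
    ic <- pmax(0, ic - 19 / (2 * log(2) * cm$n_segments))
  }
  ic
}

#' Pairwise p-distance matrix of equal-length segments
#'
#' `d(a, b)` is the fraction of mismatching positions.
#'
#' @param segments Character vector of equal-length protein strings;
#'   names (or a `seq_id` column when a match data.frame is given) label
#'   the rows.
#' @return Symmetric n x n numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(segments) {
  if (is.data.frame(segments)) {
    labels <- make.unique(segments$seq_id)
    segments <- stats::setNames(segments$matched, labels)
  }
  if (is.null(names(segments))) {
    names(segments) <- paste0("seg", seq_along(segments))
  }
  L <- nchar(segments[1])
  if (any(nchar(segments) != L)) {
    stop("segments must all have the same length", call. = FALSE)
  }
  n <- length(segments)
  chars <- do.call(rbind, strsplit(segments, ""))
  d <- base::matrix(0, n, n, dimnames = list(names(segments),
                                             names(segments)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) {
        d[i, j] <- d[j, i] <- mean(chars[i, ] != chars[j, ])
      }
    }
  }
  d
}
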