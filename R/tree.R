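#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining producing an unrooted tree. Ties
#' in the Q-matrix are broken by the smallest index pair, making the
#' result deterministic. Negative branch lengths (possible on
#' non-additive distances) are clamped to zero with the deficit moved to
#' the sister branch, preserving the path length between the joined pair.
#'
#' @param dist Symmetric n x n numeric matrix (n >= 3) with zero diagonal;
#'   row names label the leaves (defaults to `t1..tn`).
#' @return A list of class `"segment_tree"`: `tree` (an [ape::phylo]
#'   object), `newick` (string), `labels` (leaf labels).
#' @examples
#' d <- p_distance_matrix(c(a = "ETKD", b = "ETAD", c = "QQQQ"))
#' neighbor_joining(d)$newick
#' @export
neighbor_joining <- function(dist) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (n < 3) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (!isTRUE(all.equal(d, t(d)))) stop("distance matrix must be symmetric",
                                        call. = FALSE)
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal",
                              call. = FALSE)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # each active node carries its newick subtree string
  nodes <- labels
  while (length(nodes) > 3) {
    m <- nrow(d)
    tot <- rowSums(d)
    Q <- (m - 2) * d - outer(tot, tot, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    # smallest (i, j) pair among ties, i < j
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    vi <- d[i, j] / 2 + (tot[i] - tot[j]) / (2 * (m - 2))
    vj <- d[i, j] - vi
    # clamp negatives, moving the deficit to the sister branch
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    merged <- sprintf("(%s:%.10g,%s:%.10g)", nodes[i], vi, nodes[j], vj)
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    nodes <- c(nodes[keep], merged)
    rownames(d) <- colnames(d) <- NULL
  }
  # final unrooted 3-star, closed-form branch lengths
  va <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  vb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  vc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  v <- c(va, vb, vc)
  for (k in 1:3) if (v[k] < 0) v[k] <- 0
  newick <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                    nodes[1], v[1], nodes[2], v[2], nodes[3], v[3])
  tree <- ape::read.tree(text = newick)
  structure(list(tree = tree, newick = newick, labels = labels),
            class = "segment_tree")
}

#' @export
print.segment_tree <- function(x, ...) {
  cat(sprintf("unrooted tree with %d leaves\n", length(x$labels)))
  invisible(x)
}

#' Group segments into k classes by genetic distance
#'
#' Average-linkage hierarchical clustering on the distance matrix, cut to
#' `k` groups. Deterministic for a given input order.
#'
#' @param dist Symmetric distance matrix (e.g. from
#'   [p_distance_matrix()]), or a `"segment_tree"` (its cophenetic
#'   distances are used).
#' @param k Number of classes (default 5); must not exceed the number of
#'   segments.
#' @return Named integer vector mapping each segment to a class in
#'   `1..k`; every class is non-empty.
#' @export
assign_classes <- function(dist, k = 5) {
  d <- if (inherits(dist, "segment_tree")) {
    ape::cophenetic.phylo(dist$tree)
  } else {
    as.matrix(dist)
  }
  if (k > nrow(d)) stop("k (", k, ") exceeds the number of segments (",
                        nrow(d), ")", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  stats::cutree(hc, k = k)
}
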