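#' Classify a dehydrin's segment architecture (YSK shorthand)
#'
#' Converts the segment matches of one protein into the YSK structural
#' shorthand and its type label. Segment counts are taken from the matches;
#' core F-segment matches nested inside an expanded F-segment are counted
#' once, as expanded. The shorthand concatenates, in order, `Y<n>` (if any),
#' `S` (with an explicit count when more than one serine tract is present),
#' and `K<n>`; when F-segments are present, `+F<n>` is appended and an
#' F-alias (e.g. `F3SK2`) is formed by replacing the Y block with the F
#' block, following the FnSKn naming convention for multi-F dehydrins.
#'
#' The type label is one of the five structural types `YnSKn`, `SKn`,
#' `YnKn`, `Kn`, `KnS` — or `none` when no K-segment is found, the
#' K-segment being the dehydrin-defining feature. `KnS` (rather than `SKn`)
#' is assigned when the only serine tract(s) occur after the last K-segment
#' along the sequence.
#'
#' @param matches Match data.frame (as from [scan_motifs()]) for a single
#'   sequence; mixing seq_ids is an error.
#' @return A list of class `"architecture_call"`: `counts` (named integer
#'   vector over Y, S, K, F, H), `shorthand`, `f_alias` (empty string when
#'   no F-segment), `type_label`.
#' @examples
#' rec <- simulate_dehydrin("Y3SK2", seed = 1)
#' classify_architecture(scan_motifs(rec$record))
#' @export
classify_architecture <- function(matches) {
  if (nrow(matches) > 0 && length(unique(matches$seq_id)) > 1) {
    stop("matches mix multiple sequences: ",
         paste(unique(matches$seq_id), collapse = ", "), call. = FALSE)
  }
  m <- matches[order(matches$start), , drop = FALSE]
  fexp <- m[m$motif == "F_expanded", , drop = FALSE]
  fcore <- m[m$motif == "F_core", , drop = FALSE]
  # core hits nested in an expanded hit are the same segment
  if (nrow(fcore) > 0 && nrow(fexp) > 0) {
    nested <- vapply(seq_len(nrow(fcore)), function(i) {
      any(fcore$start[i] >= fexp$start & fcore$end[i] <= fexp$end)
    }, logical(1))
    fcore <- fcore[!nested, , drop = FALSE]
  }
  counts <- c(Y = nrow(m[m$motif == "Y", ]),
              S = nrow(m[m$motif == "S", ]),
              K = nrow(m[m$motif == "K", ]),
              F = nrow(fexp) + nrow(fcore),
              H = nrow(m[m$motif == "H", ]))
  s_block <- if (counts["S"] == 0) "" else
    if (counts["S"] == 1) "S" else paste0("S", counts["S"])
  y_block <- if (counts["Y"] > 0) paste0("Y", counts["Y"]) else ""
  k_block <- if (counts["K"] > 0) paste0("K", counts["K"]) else ""
  shorthand <- paste0(y_block, s_block, k_block)
  f_alias <- ""
  if (counts["F"] > 0) {
    shorthand <- paste0(shorthand, "+F", counts["F"])
    f_alias <- paste0("F", counts["F"], s_block, k_block)
  }
  type_label <- if (counts["K"] == 0) {
    "none"
  } else if (counts["Y"] > 0 && counts["S"] > 0) {
    "YnSKn"
  } else if (counts["Y"] > 0) {
    "YnKn"
  } else if (counts["S"] > 0) {
    s_rows <- m[m$motif == "S", , drop = FALSE]
    last_k <- max(m$start[m$motif == "K"])
    if (all(s_rows$start > last_k)) "KnS" else "SKn"
  } else {
    "Kn"
  }
  structure(list(counts = counts, shorthand = shorthand,
                 f_alias = f_alias, type_label = type_label),
            class = "architecture_call")
}

#' @export
print.architecture_call <- function(x, ...) {
  cat("architecture:", if (nzchar(x$shorthand)) x$shorthand else "(none)",
      if (nzchar(x$f_alias)) paste0("[", x$f_alias, "]") else "",
      "type:", x$type_label, "\n")
  invisible(x)
}
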