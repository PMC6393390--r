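#' Mine a protein database for copies of a segment consensus
#'
#' Re-expresses a two-round homology search as score-thresholded local
#' alignment: the motif consensus is aligned (Smith-Waterman, affine gaps)
#' against every database protein, and non-overlapping hits with score at
#' least `min_score_fraction` of the consensus self-score are extracted
#' iteratively by masking previous hits. Exact-duplicate database entries
#' (identical residues under any id) are dropped first and counted.
#'
#' The e-value gate of a database search is deliberately replaced by the
#' self-score fraction threshold: e-values depend on database size and are
#' irreproducible across database versions, while the self-score fraction
#' is intrinsic to the query.
#'
#' @param motif A `scored_window` [motif_definition()] whose consensus is
#'   the query (e.g. `default_motifs()$F_expanded`).
#' @param db data.frame of protein records ([read_fasta()] output).
#' @param min_score_fraction Hit threshold as a fraction of the consensus
#'   self-score (default 0.5).
#' @param matrix,gap_open,gap_extend Alignment parameters, see
#'   [local_align()].
#' @return A list of class `"mining_result"`: `hits` (match data.frame with
#'   `seq_id`, `motif`, `start`, `end`, `matched`, `score`, `identity`,
#'   `gapped`), `removed_duplicates`, `removed_gapped` (0 until
#'   [filter_gapped_segments()] is applied).
#' @examples
#' db <- data.frame(id = "q", description = "", moltype = "protein",
#'                  residues = "ETKDRGLFDFLGKKEEEE")
#' mine_database(default_motifs()$F_expanded, db)
#' @export
mine_database <- function(motif, db, min_score_fraction = 0.5,
                          matrix = blosum62(), gap_open = 11,
                          gap_extend = 1) {
  stopifnot(inherits(motif, "motif_definition"),
            motif$model == "scored_window")
  if (!is.data.frame(db) || nrow(db) == 0) {
    stop("database must be a non-empty data.frame of records", call. = FALSE)
  }
  dup <- duplicated(db$residues)
  removed_duplicates <- sum(dup)
  db <- db[!dup, , drop = FALSE]
  thr <- min_score_fraction * self_score(motif$consensus, matrix)
  all_hits <- list()
  for (r in seq_len(nrow(db))) {
    seq <- db$residues[r]
    chars <- strsplit(seq, "")[[1]]
    masked <- logical(length(chars))
    repeat {
      work <- chars
      work[masked] <- "X"   # X scores 0: masked regions cannot seed hits
      aln <- local_align(motif$consensus, paste(work, collapse = ""),
                         matrix = matrix, gap_open = gap_open,
                         gap_extend = gap_extend)
      if (aln$score < thr) break
      span <- aln$t_start:aln$t_end
      # a gap could bridge a masked region; reject such hits outright
      if (any(masked[span])) break
      all_hits[[length(all_hits) + 1]] <- data.frame(
        seq_id = db$id[r], motif = motif$name,
        start = aln$t_start, end = aln$t_end,
        matched = substr(seq, aln$t_start, aln$t_end),
        score = aln$score, identity = aln$identity, gapped = aln$gapped)
      masked[span] <- TRUE
    }
  }
  hits <- if (length(all_hits) > 0) {
    h <- do.call(rbind, all_hits)
    h[order(h$seq_id, h$start), , drop = FALSE]
  } else {
    .empty_matches()
  }
  rownames(hits) <- NULL
  structure(list(hits = hits, removed_duplicates = removed_duplicates,
                 removed_gapped = 0L),
            class = "mining_result")
}

#' Remove segments whose alignment to the consensus is gapped
#'
#' Mined segments whose optimal alignment to the query consensus contains
#' an internal insertion or deletion (for example a two-residue insertion
#' splitting the consensus) likely belong to a different family and are
#' removed; `removed_gapped` is incremented accordingly.
#'
#' @param result A `"mining_result"` from [mine_database()].
#' @param motif The motif used for mining (unused for re-alignment — the
#'   gap flag was recorded at extraction time — but kept for interface
#'   symmetry and validation).
#' @return The filtered `"mining_result"`.
#' @export
filter_gapped_segments <- function(result, motif = NULL) {
  stopifnot(inherits(result, "mining_result"))
  gapped <- result$hits$gapped
  result$removed_gapped <- result$removed_gapped + sum(gapped)
  result$hits <- result$hits[!gapped, , drop = FALSE]
  rownames(result$hits) <- NULL
  result
}

#' Per-protein segment copy counts
#'
#' @param result A `"mining_result"`.
#' @return data.frame with one row per protein holding at least one
#'   retained hit: `id`, `copies`, `class` (e.g. `"F3"`), sorted by
#'   descending copy count then id.
#' @export
copy_number_table <- function(result) {
  stopifnot(inherits(result, "mining_result"))
  h <- result$hits
  if (nrow(h) == 0) {
    return(data.frame(id = character(), copies = integer(),
                      class = character()))
  }
  tab <- as.data.frame(table(h$seq_id), stringsAsFactors = FALSE)
  names(tab) <- c("id", "copies")
  tab$copies <- as.integer(tab$copies)
  prefix <- sub("_.*$", "", h$motif[1])   # "F_expanded" -> "F"
  tab$class <- paste0(prefix, tab$copies)
  tab <- tab[order(-tab$copies, tab$id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' @export
print.mining_result <- function(x, ...) {
  cat(sprintf(
    "mining result: %d hits on %d proteins (%d duplicates, %d gapped removed)\n",
    nrow(x$hits), length(unique(x$hits$seq_id)),
    x$removed_duplicates, x$removed_gapped))
  invisible(x)
}
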