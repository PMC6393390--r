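#' Define a conserved-segment motif
#'
#' Three match models are supported:
#' * `scored_window` — an ungapped BLOSUM62-scored sliding window over a
#'   consensus string; a window is a candidate when its score reaches a
#'   fraction `t` of the consensus self-score.
#' * `residue_run` — a maximal run of one residue of length `>= min_run`
#'   (serine tracts).
#' * `windowed_count` — regions where a sliding window of `window_len`
#'   residues contains at least `min_count` copies of the target residue
#'   (histidine-rich segments).
#'
#' @param name Motif name (e.g. `"K"`, `"F_expanded"`).
#' @param model One of `"scored_window"`, `"residue_run"`, `"windowed_count"`.
#' @param consensus Consensus string (scored_window only).
#' @param t Threshold fraction of the consensus self-score, in (0, 1].
#' @param residue Target residue (residue_run / windowed_count).
#' @param min_run Minimum run length (residue_run), at least 2.
#' @param window_len,min_count Window size and minimum residue count
#'   (windowed_count); `min_count <= window_len`.
#' @return An object of class `"motif_definition"`.
#' @export
motif_definition <- function(name,
                             model = c("scored_window", "residue_run",
                                       "windowed_count"),
                             consensus = NULL, t = 0.6,
                             residue = NULL, min_run = 4,
                             window_len = 9, min_count = 5) {
  model <- match.arg(model)
  if (model == "scored_window") {
    if (is.null(consensus) || nchar(consensus) == 0) {
      stop("scored_window motifs need a non-empty consensus", call. = FALSE)
    }
    .check_protein(consensus, what = paste0("motif '", name, "'"))
    stopifnot(t > 0, t <= 1)
  } else if (model == "residue_run") {
    stopifnot(is.character(residue), nchar(residue) == 1, min_run >= 2)
  } else {
    stopifnot(is.character(residue), nchar(residue) == 1,
              min_count <= window_len)
  }
  structure(list(name = name, model = model, consensus = consensus, t = t,
                 residue = residue, min_run = min_run,
                 window_len = window_len, min_count = min_count),
            class = "motif_definition")
}

#' Default dehydrin segment motifs
#'
#' The conserved segments used throughout the package:
#'
#' | name       | model          | definition                          |
#' |------------|----------------|-------------------------------------|
#' | `F_expanded` | scored_window | `ETKDRGLFDFLGKKEEEE` (18 aa), t = 0.6 |
#' | `F_core`     | scored_window | `DRGLFDFLGKK` (11 aa), t = 0.6       |
#' | `K`          | scored_window | `EKKGIMDKIKEKLPG` (15 aa), t = 0.6   |
#' | `Y`          | scored_window | `DEYGNP`, t = 0.8                    |
#' | `S`          | residue_run   | run of `>= 4` serines                |
#' | `H`          | windowed_count| `>= 5` histidines in a 9-residue window |
#'
#' The K-segment default is the literature-standard 15-mer whose charged
#' composition is K5 E2 D1; the expanded F-segment consensus has composition
#' K3 E5 D2 R1 and net formal charge -3. All definitions can be overridden
#' by building your own list of [motif_definition()] objects.
#'
#' @return Named list of `motif_definition` objects.
#' @export
default_motifs <- function() {
  list(
    F_expanded = motif_definition("F_expanded", "scored_window",
                                  consensus = "ETKDRGLFDFLGKKEEEE", t = 0.6),
    F_core = motif_definition("F_core", "scored_window",
                              consensus = "DRGLFDFLGKK", t = 0.6),
    K = motif_definition("K", "scored_window",
                         consensus = "EKKGIMDKIKEKLPG", t = 0.6),
    Y = motif_definition("Y", "scored_window",
                         consensus = "DEYGNP", t = 0.8),
    S = motif_definition("S", "residue_run", residue = "S", min_run = 4),
    H = motif_definition("H", "windowed_count", residue = "H",
                         window_len = 9, min_count = 5)
  )
}

.empty_matches <- function() {
  data.frame(seq_id = character(), motif = character(), start = integer(),
             end = integer(), matched = character(), score = numeric(),
             identity = numeric(), gapped = logical())
}

.seq_and_id <- function(seq) {
  if (is.data.frame(seq)) list(id = seq$id[1], residues = seq$residues[1])
  else list(id = "seq", residues = as.character(seq))
}

#' Scan a protein for a scored-window motif
#'
#' Slides an ungapped window of the consensus length over the sequence and
#' scores each window as the sum of BLOSUM62 scores against the consensus.
#' Windows scoring at least `t * self_score(consensus)` are candidates;
#' non-overlapping candidates are selected greedily in descending score
#' (ties to the leftmost window) and reported sorted by start position.
#'
#' @param seq A one-row record data.frame (from [read_fasta()]) or a plain
#'   protein string.
#' @param motif A `scored_window` [motif_definition()].
#' @param matrix Substitution matrix (default [blosum62()]).
#' @return data.frame of matches: `seq_id`, `motif`, `start`, `end`
#'   (1-based inclusive), `matched`, `score`, `identity`, `gapped`
#'   (always `FALSE` for window scans). Sequences shorter than the motif
#'   give zero rows.
#' @examples
#' m <- default_motifs()$F_expanded
#' scan_motif("ETKDRGLFDFLGKKEEEE", m)
#' @export
scan_motif <- function(seq, motif, matrix = blosum62()) {
  stopifnot(inherits(motif, "motif_definition"),
            motif$model == "scored_window")
  x <- .seq_and_id(seq)
  .check_protein(x$residues, what = x$id)
  cons <- strsplit(motif$consensus, "")[[1]]
  L <- length(cons)
  chars <- strsplit(x$residues, "")[[1]]
  n <- length(chars)
  if (n < L) return(.empty_matches())
  # per-offset score vectors: row lookup of the consensus residue over seq
  nwin <- n - L + 1L
  scores <- numeric(nwin)
  for (i in seq_len(L)) {
    scores <- scores + matrix[cons[i], chars[i:(i + nwin - 1L)]]
  }
  thr <- motif$t * self_score(motif$consensus, matrix)
  cand <- which(scores >= thr)
  if (length(cand) == 0) return(.empty_matches())
  # greedy non-overlap: descending score, leftmost on ties
  ord <- cand[order(-scores[cand], cand)]
  taken <- logical(n)
  keep <- integer(0)
  for (p in ord) {
    if (!any(taken[p:(p + L - 1L)])) {
      keep <- c(keep, p)
      taken[p:(p + L - 1L)] <- TRUE
    }
  }
  keep <- sort(keep)
  matched <- substring(x$residues, keep, keep + L - 1L)
  ident <- vapply(keep, function(p) {
    mean(chars[p:(p + L - 1L)] == cons)
  }, numeric(1))
  data.frame(seq_id = x$id, motif = motif$name, start = keep,
             end = keep + L - 1L, matched = matched,
             score = scores[keep], identity = ident, gapped = FALSE)
}

#' Find maximal residue runs (serine tracts)
#'
#' @inheritParams scan_motif
#' @param motif A `residue_run` [motif_definition()].
#' @return Match data.frame as in [scan_motif()]; score is the run length,
#'   identity 1.
#' @examples
#' find_residue_run("AASSSSSAA", default_motifs()$S)
#' @export
find_residue_run <- function(seq, motif) {
  stopifnot(inherits(motif, "motif_definition"), motif$model == "residue_run")
  x <- .seq_and_id(seq)
  chars <- strsplit(x$residues, "")[[1]]
  r <- rle(chars == motif$residue)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values & r$lengths >= motif$min_run
  if (!any(sel)) return(.empty_matches())
  data.frame(seq_id = x$id, motif = motif$name, start = starts[sel],
             end = ends[sel],
             matched = substring(x$residues, starts[sel], ends[sel]),
             score = as.numeric(r$lengths[sel]), identity = 1, gapped = FALSE)
}

#' Find residue-dense regions by windowed counting (histidine-rich segments)
#'
#' Every window of `window_len` residues containing at least `min_count`
#' copies of the target residue qualifies; overlapping qualifying windows
#' are merged into one reported region. Score is the count of the target
#' residue in the merged region.
#'
#' @inheritParams scan_motif
#' @param motif A `windowed_count` [motif_definition()].
#' @return Match data.frame as in [scan_motif()].
#' @examples
#' find_windowed_count("HHQHHHHVE", default_motifs()$H)
#' @export
find_windowed_count <- function(seq, motif) {
  stopifnot(inherits(motif, "motif_definition"),
            motif$model == "windowed_count")
  x <- .seq_and_id(seq)
  chars <- strsplit(x$residues, "")[[1]]
  n <- length(chars)
  w <- motif$window_len
  if (n < w) return(.empty_matches())
  is_r <- as.integer(chars == motif$residue)
  counts <- as.numeric(stats::filter(is_r, rep(1, w), sides = 1))[w:n]
  ok <- which(counts >= motif$min_count)  # window starting at ok
  if (length(ok) == 0) return(.empty_matches())
  cov <- logical(n)
  for (p in ok) cov[p:(p + w - 1L)] <- TRUE
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values
  score <- vapply(which(sel), function(i) {
    sum(is_r[starts[i]:ends[i]])
  }, numeric(1))
  data.frame(seq_id = x$id, motif = motif$name, start = starts[sel],
             end = ends[sel],
             matched = substring(x$residues, starts[sel], ends[sel]),
             score = score,
             identity = score / (ends[sel] - starts[sel] + 1L),
             gapped = FALSE)
}

#' Scan a protein with a set of motifs
#'
#' Dispatches each motif definition to its match model and binds the
#' results.
#'
#' @inheritParams scan_motif
#' @param motifs Named list of [motif_definition()] objects
#'   (default [default_motifs()]).
#' @return Combined match data.frame, sorted by motif then start.
#' @export
scan_motifs <- function(seq, motifs = default_motifs(), matrix = blosum62()) {
  out <- lapply(motifs, function(m) {
    switch(m$model,
           scored_window = scan_motif(seq, m, matrix),
           residue_run = find_residue_run(seq, m),
           windowed_count = find_windowed_count(seq, m))
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out[order(out$motif, out$start), , drop = FALSE]
}
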