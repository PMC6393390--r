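#' Built-in positional frequency profile of the expanded F-segment
#'
#' The per-position modal residue counts observed across 208 mined
#' expanded F-segments (consensus `ETKDRGLFDFLGKKEEEE`): E197, T67, K92,
#' D188, R207, G207, L150, F200, D198, F204, L123, G167, K142, K149, E93,
#' E114 and E105 at positions 1-17. The available tabulation lists one
#' count fewer than the 18 consensus positions (the four terminal
#' glutamates carry three counts); the package assigns the three counts
#' to positions 15-17 and repeats the last (105) for position 18. The
#' remaining probability mass at each position is spread uniformly over
#' the other 19 residues, which affects information content slightly but
#' not the modal (consensus) residue.
#'
#' @param n_total Total segment count the profile is scaled to
#'   (default 208).
#' @return A `"count_matrix"` (18 x 20) whose rows sum to `n_total` and
#'   whose per-position maxima are the modal counts above.
#' @export
f_segment_profile <- function(n_total = 208) {
  consensus <- strsplit("ETKDRGLFDFLGKKEEEE", "")[[1]]
  modal <- c(197, 67, 92, 188, 207, 207, 150, 200, 198, 204,
             123, 167, 142, 149, 93, 114, 105, 105)
  modal <- pmin(round(modal * n_total / 208), n_total)
  mat <- base::matrix(0L, nrow = 18, ncol = 20,
                      dimnames = list(NULL, AA20))
  for (p in 1:18) {
    others <- setdiff(AA20, consensus[p])
    resid <- n_total - modal[p]
    per <- resid %/% 19L
    extra <- resid %% 19L
    mat[p, others] <- per + c(rep(1L, extra), rep(0L, 19L - extra))
    mat[p, consensus[p]] <- as.integer(modal[p])
  }
  structure(list(counts = mat, length = 18L, n_segments = as.integer(n_total)),
            class = "count_matrix")
}

# linker pool: hydrophilic residues typical of disordered dehydrin
# backbones; serine is excluded so random linkers cannot form spurious
# S-tracts
LINKER_POOL <- c("G", "T", "E", "K", "P", "A")

.random_linker <- function(len_range) {
  len <- sample(len_range[1]:len_range[2], 1)
  paste(sample(LINKER_POOL, len, replace = TRUE), collapse = "")
}

.mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(r) {
      sample(setdiff(AA20, r), 1)
    }, character(1))
  }
  paste(chars, collapse = "")
}

# parse "Y2SK2+F3" / "K1S" style architecture specs into ordered tokens
.parse_arch_spec <- function(spec) {
  f_count <- 0L
  main <- spec
  if (grepl("\\+F", spec)) {
    parts <- strsplit(spec, "+", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !grepl("^F[0-9]+$", parts[2])) {
      stop("unparseable architecture spec: ", spec, call. = FALSE)
    }
    main <- parts[1]
    f_count <- as.integer(sub("F", "", parts[2]))
  }
  if (!grepl("^([YSK][0-9]*)*$", main)) {
    stop("unparseable architecture spec: ", spec, call. = FALSE)
  }
  m <- gregexpr("[YSK][0-9]*", main)[[1]]
  tokens <- regmatches(main, list(m))[[1]]
  segs <- character(0)
  for (tok in tokens) {
    letter <- substr(tok, 1, 1)
    count <- if (nchar(tok) > 1) as.integer(substr(tok, 2, nchar(tok))) else 1L
    segs <- c(segs, rep(letter, count))
  }
  list(segments = c(rep("F", f_count), segs), f_count = f_count)
}

#' Simulate a dehydrin with a planted segment architecture
#'
#' Concatenates the default motif templates (Y = `DEYGNP`, S = a
#' six-serine tract, K = `EKKGIMDKIKEKLPG`, F = the expanded F-segment
#' `ETKDRGLFDFLGKKEEEE`) in the order given by the architecture spec,
#' separated by random hydrophilic linkers, then applies i.i.d. residue
#' substitutions. F copies are placed in the N-terminal region, mirroring
#' multi-F dehydrins whose F-segments sit near the N-terminus.
#'
#' @param spec Architecture string, e.g. `"Y3SK2"`, `"SK2"`, `"K1"`,
#'   `"K2S"`, `"Y2SK2+F3"`.
#' @param linker_len Integer range (length 2) for linker lengths,
#'   default `c(8, 20)`.
#' @param mutation_rate Per-residue substitution probability in
#'   \[0, 0.3\].
#' @param seed Integer seed; fixing it makes the record reproducible.
#' @param id Record id.
#' @return List: `record` (one-row data.frame as from [read_fasta()]) and
#'   `truth` (data.frame of planted segments: `motif`, `start`, `end`,
#'   `template`), plus `spec` and `seed`.
#' @examples
#' sim <- simulate_dehydrin("Y2SK2+F3", seed = 42)
#' classify_architecture(scan_motifs(sim$record))
#' @export
simulate_dehydrin <- function(spec, linker_len = c(8, 20),
                              mutation_rate = 0, seed = 1,
                              id = paste0("synth_", spec)) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 0.3)
  parsed <- .parse_arch_spec(spec)
  templates <- c(Y = "DEYGNP", S = "SSSSSS", K = "EKKGIMDKIKEKLPG",
                 F = "ETKDRGLFDFLGKKEEEE")
  set.seed(seed)
  seq <- .random_linker(linker_len)
  truth <- list()
  for (segment in parsed$segments) {
    tpl <- templates[[segment]]
    start <- nchar(seq) + 1L
    seq <- paste0(seq, tpl)
    truth[[length(truth) + 1]] <- data.frame(
      motif = segment, start = start, end = nchar(seq), template = tpl)
    seq <- paste0(seq, .random_linker(linker_len))
  }
  truth <- do.call(rbind, truth)
  if (is.null(truth)) truth <- data.frame(motif = character(),
                                          start = integer(), end = integer(),
                                          template = character())
  seq <- .mutate_seq(seq, mutation_rate)
  record <- data.frame(id = id, description = paste("synthetic dehydrin", spec),
                       residues = seq, moltype = "protein")
  list(record = record, truth = truth, spec = spec, seed = seed)
}

#' Simulate a protein database with known F-segment copy numbers
#'
#' Each protein receives a number of planted expanded F-segment copies
#' drawn from `copy_distribution`, embedded in random hydrophilic linker
#' background, with optional per-residue substitutions.
#'
#' @param n_proteins Number of database proteins.
#' @param copy_distribution Named probability vector over copy numbers,
#'   e.g. `c("0" = 0.2, "1" = 0.5, "2" = 0.2, "3" = 0.1)`; must sum to 1.
#' @param mutation_rate Per-residue substitution probability.
#' @param seed Integer seed.
#' @param linker_len Linker length range between copies.
#' @return List: `db` (record data.frame), `truth` (data.frame `id`,
#'   `copy`, `start`, `end`), `copies` (named integer vector of true copy
#'   numbers), `seed`.
#' @export
simulate_segment_db <- function(n_proteins = 50,
                                copy_distribution = c("0" = 0.1, "1" = 0.5,
                                                      "2" = 0.25, "3" = 0.15),
                                mutation_rate = 0, seed = 1,
                                linker_len = c(15, 40)) {
  stopifnot(abs(sum(copy_distribution) - 1) < 1e-8)
  set.seed(seed)
  tpl <- "ETKDRGLFDFLGKKEEEE"
  ids <- sprintf("prot%03d", seq_len(n_proteins))
  copies <- sample(as.integer(names(copy_distribution)), n_proteins,
                   replace = TRUE, prob = copy_distribution)
  names(copies) <- ids
  recs <- list(); truth <- list()
  for (i in seq_len(n_proteins)) {
    seq <- .random_linker(linker_len)
    for (cp in seq_len(copies[i])) {
      start <- nchar(seq) + 1L
      seq <- paste0(seq, tpl)
      truth[[length(truth) + 1]] <- data.frame(
        id = ids[i], copy = cp, start = start, end = nchar(seq))
      seq <- paste0(seq, .random_linker(linker_len))
    }
    recs[[i]] <- data.frame(id = ids[i], description = "",
                            residues = .mutate_seq(seq, mutation_rate),
                            moltype = "protein")
  }
  truth <- if (length(truth) > 0) do.call(rbind, truth) else
    data.frame(id = character(), copy = integer(), start = integer(),
               end = integer())
  list(db = do.call(rbind, recs), truth = truth, copies = copies,
       seed = seed)
}

#' Sample segments from a positional frequency profile
#'
#' Draws `n` segments by independent per-position sampling of residues
#' with probabilities proportional to the profile counts.
#'
#' @param profile A `"count_matrix"` (e.g. [f_segment_profile()]) or a
#'   plain L x 20 count matrix with residue column names.
#' @param n Number of segments to draw.
#' @param seed Integer seed.
#' @return Character vector of `n` segments of length L.
#' @examples
#' segs <- sample_from_frequency_profile(f_segment_profile(), 208, seed = 1)
#' consensus_string(build_count_matrix(segs))
#' @export
sample_from_frequency_profile <- function(profile, n, seed = 1) {
  counts <- if (inherits(profile, "count_matrix")) profile$counts else profile
  if (n == 0) return(character(0))
  set.seed(seed)
  L <- nrow(counts)
  cols <- vapply(seq_len(L), function(p) {
    sample(colnames(counts), n, replace = TRUE,
           prob = counts[p, ] / sum(counts[p, ]))
  }, character(n))
  if (n == 1) cols <- base::matrix(cols, nrow = 1)
  apply(cols, 1, paste, collapse = "")
}

#' Simulate a replicated qPCR Ct table with a known fold trajectory
#'
#' Generates `Ct(test) = ct0_test - log2(fold) + N(0, noise_sd)` and
#' `Ct(ref) = ct0_ref + N(0, noise_sd)` for each replicate of each
#' experiment, so that the comparative-Ct analysis of the table should
#' recover `true_folds` up to noise.
#'
#' @param genes Test gene names (default `"RcDhn1"`).
#' @param true_folds Named positive vector of true folds per sample; the
#'   first element is the baseline and should be 1. Default: the
#'   August-February seasonal design with fold trajectory
#'   1, 1, 2, 5, 12, 9.
#' @param ref_gene Reference gene name (default `"RcUbql"`).
#' @param noise_sd Ct noise standard deviation in cycles (default 0.2).
#' @param replicates Technical replicates per experiment (default 3).
#' @param experiments Independent experiments (default 2).
#' @param ct0_test,ct0_ref Baseline Ct levels.
#' @param seed Integer seed.
#' @return List: `table` (Ct data.frame), `truth` (named fold vector per
#'   gene), `seed`.
#' @export
simulate_ct_table <- function(genes = "RcDhn1",
                              true_folds = c(August = 1, September = 1,
                                             October = 2, November = 5,
                                             January = 12, February = 9),
                              ref_gene = "RcUbql", noise_sd = 0.2,
                              replicates = 3, experiments = 2,
                              ct0_test = 26, ct0_ref = 20, seed = 1) {
  stopifnot(all(true_folds > 0))
  set.seed(seed)
  samples <- names(true_folds)
  rows <- list()
  for (s in samples) {
    for (e in seq_len(experiments)) {
      for (r in seq_len(replicates)) {
        for (g in genes) {
          rows[[length(rows) + 1]] <- data.frame(
            sample = s, gene = g, replicate = r, experiment = e,
            ct = ct0_test - log2(true_folds[[s]]) +
              stats::rnorm(1, 0, noise_sd))
        }
        rows[[length(rows) + 1]] <- data.frame(
          sample = s, gene = ref_gene, replicate = r, experiment = e,
          ct = ct0_ref + stats::rnorm(1, 0, noise_sd))
      }
    }
  }
  table <- do.call(rbind, rows)
  truth <- stats::setNames(rep(list(true_folds), length(genes)), genes)
  list(table = table, truth = truth, seed = seed)
}
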