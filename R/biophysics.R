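#' Residue composition of a protein or segment
#'
#' @param seq Protein string (X allowed).
#' @return Named integer vector of counts over the 21-letter alphabet
#'   (`ACDEFGHIKLMNPQRSTVWYX`); the counts sum to the sequence length.
#' @examples
#' residue_composition("ETKDRGLFDFLGKKEEEE")[c("K", "E", "D", "R")]
#' @export
residue_composition <- function(seq) {
  chars <- .check_protein(seq)
  counts <- table(factor(chars, levels = AA_ALPHABET_X))
  stats::setNames(as.integer(counts), names(counts))
}

#' Net formal charge of a segment
#'
#' Counts +1 for each lysine (K) or arginine (R) and -1 for each aspartate
#' (D) or glutamate (E). Histidine and the termini contribute 0: this is
#' the segment-level convention under which the expanded F-segment
#' (composition K3 E5 D2 R1) has net charge -3 while the K-segment
#' consensus (K5 E2 D1) has +2.
#'
#' @param seq Protein string.
#' @return Integer net charge.
#' @examples
#' net_formal_charge("ETKDRGLFDFLGKKEEEE")  # -3
#' @export
net_formal_charge <- function(seq) {
  comp <- residue_composition(seq)
  as.integer(comp["K"] + comp["R"] - comp["D"] - comp["E"])
}

#' Summarize the charged residues of a segment
#'
#' @param seq Protein string.
#' @return String of the form `"K3E5D2R1"`, omitting absent residues
#'   (order K, E, D, R).
#' @export
charged_summary <- function(seq) {
  comp <- residue_composition(seq)
  parts <- vapply(c("K", "E", "D", "R"), function(r) {
    if (comp[r] > 0) paste0(r, comp[r]) else ""
  }, character(1))
  paste(parts, collapse = "")
}

# Kyte-Doolittle hydropathy index; X (unknown) treated as neutral (0)
KD_INDEX <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2, X = 0)

#' Kyte-Doolittle hydropathy profile and GRAVY
#'
#' Per-position hydropathy as a centered moving average of the standard
#' Kyte-Doolittle index over an odd window; at the edges the window is
#' truncated to the available residues. GRAVY (grand average of
#' hydropathy) is the unweighted mean of the raw per-residue indices.
#' The default window of 1 returns the raw indices, appropriate for the
#' short (11-18 residue) conserved segments where smoothing would erase
#' structure.
#'
#' @param seq Protein string.
#' @param window Odd positive integer, at most the sequence length.
#' @return List of class `"hydropathy_profile"`: `window`, `values`
#'   (per-position, each within \[-4.5, 4.5\]), `gravy`.
#' @examples
#' kd_hydropathy("ETKDRGLFDFLGKKEEEE")$gravy
#' @export
kd_hydropathy <- function(seq, window = 1) {
  chars <- .check_protein(seq)
  n <- length(chars)
  if (window %% 2 != 1 || window < 1) {
    stop("window must be an odd positive integer", call. = FALSE)
  }
  if (window > n) stop("window (", window, ") exceeds sequence length (",
                       n, ")", call. = FALSE)
  raw <- unname(KD_INDEX[chars])
  half <- (window - 1) / 2
  values <- vapply(seq_len(n), function(i) {
    mean(raw[max(1, i - half):min(n, i + half)])
  }, numeric(1))
  structure(list(window = window, values = values, gravy = mean(raw)),
            class = "hydropathy_profile")
}

#' @export
print.hydropathy_profile <- function(x, ...) {
  cat(sprintf("Kyte-Doolittle profile: %d positions, window %d, GRAVY %.3f\n",
              length(x$values), x$window, x$gravy))
  invisible(x)
}

# side-chain and terminal pKa sets (positive groups first)
PKA_SETS <- list(
  Bjellqvist = c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98,
                 Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0),
  EMBOSS = c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5,
             Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
)

# Henderson-Hasselbalch net charge of a whole protein at a given pH
.hh_charge <- function(comp, pH, pka) {
  pos <- c(Nterm = 1, K = unname(comp["K"]), R = unname(comp["R"]),
           H = unname(comp["H"]))
  neg <- c(Cterm = 1, D = unname(comp["D"]), E = unname(comp["E"]),
           C = unname(comp["C"]), Y = unname(comp["Y"]))
  sum(pos / (1 + 10^(pH - pka[names(pos)]))) -
    sum(neg / (1 + 10^(pka[names(neg)] - pH)))
}

#' Isoelectric point by Henderson-Hasselbalch bisection
#'
#' Finds the pH at which the protein's net charge is zero, modelling the
#' ionizable side chains (D, E, C, Y, H, K, R) and both termini with the
#' chosen pKa set. Bisection runs until |charge| < 1e-3 or the pH step
#' falls below 0.002; the result is rounded to 2 decimals.
#'
#' @param seq Protein string.
#' @param pka_set `"Bjellqvist"` (Expasy-compatible, default) or
#'   `"EMBOSS"`.
#' @return pI in pH units.
#' @examples
#' isoelectric_point("KKKKKKKKKK") > 10
#' @export
isoelectric_point <- function(seq, pka_set = c("Bjellqvist", "EMBOSS")) {
  pka_set <- match.arg(pka_set)
  stopifnot(nchar(seq) > 0)
  comp <- residue_composition(seq)
  pka <- PKA_SETS[[pka_set]]
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- .hh_charge(comp, mid, pka)
    if (abs(q) < 1e-3 || (hi - lo) / 2 < 0.002) break
    if (q > 0) lo <- mid else hi <- mid
  }
  round(mid, 2)
}

# average (isotope-weighted) residue masses, Da
RESIDUE_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
                  C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
                  H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
                  M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
                  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01524

#' Average molecular weight of a protein
#'
#' Sum of average residue masses plus one water. Unknown residues (X) are
#' rejected because their mass is undefined.
#'
#' @param seq Protein string without X.
#' @return Mass in daltons.
#' @examples
#' molecular_weight("G")  # free glycine, ~75.07 Da
#' @export
molecular_weight <- function(seq) {
  chars <- .check_protein(seq, allow_x = FALSE)
  stopifnot(length(chars) > 0)
  sum(RESIDUE_MASS[chars]) + WATER_MASS
}

#' Biophysical report for a set of records
#'
#' One row per record: length, molecular weight (Da), pI, net formal
#' charge, GRAVY and the charged-residue summary. Suitable for writing as
#' TSV.
#'
#' @param records data.frame of protein records (from [read_fasta()]), or a
#'   named character vector of protein strings.
#' @param pka_set Passed to [isoelectric_point()].
#' @return data.frame with columns `id`, `length`, `mw_da`, `pi`,
#'   `net_charge`, `gravy`, `charged_summary`.
#' @export
biophysics_report <- function(records, pka_set = "Bjellqvist") {
  if (is.data.frame(records)) {
    seqs <- stats::setNames(records$residues, records$id)
  } else {
    seqs <- records
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  }
  do.call(rbind, lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    data.frame(id = id, length = nchar(s),
               mw_da = if (grepl("X", s)) NA_real_ else molecular_weight(s),
               pi = isoelectric_point(s, pka_set),
               net_charge = net_formal_charge(s),
               gravy = kd_hydropathy(s)$gravy,
               charged_summary = charged_summary(s))
  }))
}
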