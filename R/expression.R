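#' Read a Ct table from TSV
#'
#' Expected columns: `sample`, `gene`, `replicate`, `experiment`, `ct`
#' (tab-separated, header row).
#'
#' @param path TSV file path.
#' @return data.frame validated as a Ct table.
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_ct_table(tab)
  tab
}

validate_ct_table <- function(tab) {
  need <- c("sample", "gene", "replicate", "experiment", "ct")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("Ct table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(tab$ct <= 0 | tab$ct >= 45)) {
    stop("Ct values must lie in (0, 45) cycles", call. = FALSE)
  }
  invisible(tab)
}

#' Relative expression by the comparative Ct (2^-ddCt) method
#'
#' For each test gene and sample, computes `dCt = Ct(test) - Ct(ref)`
#' (replicates averaged per sample and gene), then
#' `ddCt = dCt(sample) - dCt(baseline)` and the fold change `2^-ddCt`,
#' with the baseline sample's expression defined as 1. Significance of
#' each sample against the baseline is assessed by a two-tailed Student's
#' t-test on per-replicate fold values (replicates of both independent
#' experiments pooled): `*` for p < 0.05 and `**` for p < 0.01.
#'
#' @param table Ct data.frame with columns `sample`, `gene`, `replicate`,
#'   `experiment`, `ct`.
#' @param test_genes Character vector of test genes (default: all genes
#'   except `ref_gene`).
#' @param ref_gene Reference (normalizer) gene name.
#' @param baseline_sample Baseline sample label (default `"August"`).
#' @param var_equal Classical equal-variance t-test (default `TRUE`);
#'   `FALSE` gives Welch.
#' @return data.frame with one row per gene x sample: `gene`, `sample`,
#'   `delta_ct`, `delta_delta_ct`, `fold`, `p_value` (NA for the
#'   baseline), `flag` (`""`, `*` or `**`).
#' @examples
#' sim <- simulate_ct_table(true_folds = c(August = 1, January = 8), seed = 1)
#' fold_changes(sim$table, ref_gene = "RcUbql")
#' @export
fold_changes <- function(table, test_genes = NULL, ref_gene,
                         baseline_sample = "August", var_equal = TRUE) {
  validate_ct_table(table)
  if (is.null(test_genes)) test_genes <- setdiff(unique(table$gene), ref_gene)
  samples <- unique(table$sample)
  if (!(baseline_sample %in% samples)) {
    stop("baseline sample '", baseline_sample, "' not present", call. = FALSE)
  }
  ref <- table[table$gene == ref_gene, , drop = FALSE]
  out <- list()
  for (g in test_genes) {
    tg <- table[table$gene == g, , drop = FALSE]
    if (nrow(tg) == 0) stop("no rows for test gene '", g, "'", call. = FALSE)
    gaps <- setdiff(unique(tg$sample), unique(ref$sample))
    if (length(gaps) > 0) {
      stop("reference gene '", ref_gene, "' has no rows for sample(s): ",
           paste(gaps, collapse = ", "), call. = FALSE)
    }
    # per-replicate dCt, pairing test and reference within
    # (sample, experiment, replicate)
    key <- function(d) paste(d$sample, d$experiment, d$replicate, sep = "\r")
    ref_ct <- stats::setNames(ref$ct, key(ref))
    rep_dct <- tg$ct - ref_ct[key(tg)]
    if (any(is.na(rep_dct))) {
      stop("reference gene '", ref_gene,
           "' is missing replicates matching test gene '", g, "'",
           call. = FALSE)
    }
    dct <- tapply(rep_dct, tg$sample, mean)
    base_dct <- dct[[baseline_sample]]
    # per-replicate folds relative to the baseline mean dCt (for the t-test)
    rep_fold <- 2^(-(rep_dct - base_dct))
    base_folds <- rep_fold[tg$sample == baseline_sample]
    for (s in samples) {
      ddct <- dct[[s]] - base_dct
      fold <- 2^(-ddct)
      if (s == baseline_sample) {
        p <- NA_real_
      } else {
        # degenerate (zero-variance) replicate folds arise in noise-free
        # simulations; no test is possible there
        p <- tryCatch(stats::t.test(rep_fold[tg$sample == s], base_folds,
                                    var.equal = var_equal)$p.value,
                      error = function(e) NA_real_)
      }
      flag <- if (is.na(p)) "" else if (p < 0.01) "**" else
        if (p < 0.05) "*" else ""
      out[[length(out) + 1]] <- data.frame(
        gene = g, sample = s, delta_ct = unname(dct[[s]]),
        delta_delta_ct = unname(ddct), fold = unname(fold),
        p_value = p, flag = flag)
    }
  }
  do.call(rbind, out)
}

#' PCR amplification efficiency from a dilution standard curve
#'
#' Least-squares fit of Ct against log10(dilution factor); the efficiency
#' is `E = 10^(-1/slope) - 1`, so a perfect doubling series
#' (slope -3.3219) gives E = 1.
#'
#' @param dilution_factors Positive relative template amounts (>= 3
#'   points).
#' @param cts Observed Ct values, same length.
#' @return List: `efficiency`, `slope`, `r_squared`.
#' @examples
#' pcr_efficiency(c(1, 0.1, 0.01), c(20, 23.3219, 26.6439))
#' @export
pcr_efficiency <- function(dilution_factors, cts) {
  stopifnot(length(dilution_factors) == length(cts))
  if (length(cts) < 3) stop("need at least 3 dilution points", call. = FALSE)
  if (any(dilution_factors <= 0)) stop("dilution factors must be positive",
                                       call. = FALSE)
  x <- log10(dilution_factors)
  if (stats::sd(x) == 0) stop("dilution factors have zero variance",
                              call. = FALSE)
  fit <- stats::lm(cts ~ x)
  slope <- unname(stats::coef(fit)[2])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((cts - mean(cts))^2)
  list(efficiency = 10^(-1 / slope) - 1, slope = slope,
       r_squared = 1 - ss_res / ss_tot)
}

#' In-silico PCR amplicon sizing
#'
#' Finds exact matches of the forward primer on the template strand and of
#' the reverse complement of the reverse primer downstream of it; each
#' compatible pair yields a product spanning from the forward primer's
#' first base through the reverse primer's binding end, inclusive.
#'
#' @param template Nucleotide string or one-row record data.frame.
#' @param fwd,rev Primer sequences, 5'->3', at least 15 nt.
#' @return Sorted integer vector of product lengths (bp), or `NULL` when
#'   there is no product.
#' @examples
#' tpl <- paste0("AAAAAAAAAA", "AGAGGTGGTGTTGAACGATCG",
#'               strrep("T", 30), "TGTGCGGTAATAAGTGCGAGA", "CCCCC")
#' insilico_pcr(tpl, "AGAGGTGGTGTTGAACGATCG", "TCTCGCACTTATTACCGCACA")
#' @export
insilico_pcr <- function(template, fwd, rev) {
  tpl <- if (is.data.frame(template)) template$residues[1] else
    toupper(as.character(template))
  fwd <- toupper(fwd); rev <- toupper(rev)
  if (nchar(fwd) < 15 || nchar(rev) < 15) {
    stop("primers must be at least 15 nt", call. = FALSE)
  }
  rev_rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(rev)))
  f_hits <- gregexpr(fwd, tpl, fixed = TRUE)[[1]]
  r_hits <- gregexpr(rev_rc, tpl, fixed = TRUE)[[1]]
  if (f_hits[1] == -1 || r_hits[1] == -1) return(NULL)
  lengths <- integer(0)
  for (f in as.integer(f_hits)) {
    for (r in as.integer(r_hits)) {
      if (r >= f + nchar(fwd)) {
        lengths <- c(lengths, r + nchar(rev) - f)
      }
    }
  }
  if (length(lengths) == 0) return(NULL)
  sort(lengths)
}

#' Fold estimates from band densitometry
#'
#' Intensity ratios relative to a baseline lane whose fold is defined
#' as 1.
#'
#' @param intensities Named numeric vector of band intensities (arbitrary
#'   units).
#' @param baseline Name of the baseline lane (default `"NA_state"`).
#' @return Named numeric vector of folds.
#' @examples
#' densitometry_folds(c(NA_state = 100, CA = 900, DA = 250))
#' @export
densitometry_folds <- function(intensities, baseline = "NA_state") {
  if (!(baseline %in% names(intensities))) {
    stop("baseline lane '", baseline, "' not found", call. = FALSE)
  }
  b <- intensities[[baseline]]
  if (!is.finite(b) || b <= 0) {
    stop("baseline intensity must be positive", call. = FALSE)
  }
  intensities / b
}
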