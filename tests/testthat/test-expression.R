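# small constructed Ct table: 2 replicates x 1 experiment, exact values
make_ct <- function(test_by_sample, ref_ct = 20, reps = 2) {
  rows <- list()
  for (s in names(test_by_sample)) {
    for (r in seq_len(reps)) {
      rows[[length(rows) + 1]] <- data.frame(
        sample = s, gene = "dhn", replicate = r, experiment = 1,
        ct = test_by_sample[[s]][r])
      rows[[length(rows) + 1]] <- data.frame(
        sample = s, gene = "ref", replicate = r, experiment = 1,
        ct = ref_ct)
    }
  }
  do.call(rbind, rows)
}

test_that("the comparative-Ct arithmetic follows the printed formulas", {
  tab <- make_ct(list(August = c(28, 28), M = c(25, 25)))
  fc <- fold_changes(tab, ref_gene = "ref", baseline_sample = "August")
  m <- fc[fc$sample == "M", ]
  expect_equal(m$delta_ct, 5)            # 25 - 20
  expect_equal(m$delta_delta_ct, -3)     # 5 - 8
  expect_equal(m$fold, 8)                # 2^3
  base <- fc[fc$sample == "August", ]
  expect_equal(base$fold, 1)
  expect_equal(base$delta_delta_ct, 0)
  expect_equal(m$fold, 2^(-m$delta_delta_ct))  # identity by construction
})

test_that("missing reference rows are reported as an error", {
  tab <- make_ct(list(August = c(28, 28), M = c(25, 25)))
  tab <- tab[!(tab$gene == "ref" & tab$sample == "M"), ]
  expect_error(fold_changes(tab, ref_gene = "ref",
                            baseline_sample = "August"), "M")
})

test_that("swapping test and reference genes flips the sign of dCt", {
  tab <- make_ct(list(August = c(28, 28.4), M = c(25, 25.2)))
  fwd <- fold_changes(tab, test_genes = "dhn", ref_gene = "ref",
                      baseline_sample = "August")
  rev <- fold_changes(tab, test_genes = "ref", ref_gene = "dhn",
                      baseline_sample = "August")
  expect_equal(fwd$delta_ct, -rev$delta_ct)
})

test_that("significance flags reproduce a hand-computed pooled t-test", {
  tab <- make_ct(list(August = c(28.0, 28.2), M = c(25.0, 25.3)), reps = 2)
  fc <- fold_changes(tab, ref_gene = "ref", baseline_sample = "August")
  # per-replicate folds relative to the baseline mean dCt, as documented
  base_dct <- mean(c(28.0, 28.2)) - 20
  f_m <- 2^(-(c(25.0, 25.3) - 20 - base_dct))
  f_b <- 2^(-(c(28.0, 28.2) - 20 - base_dct))
  n1 <- 2; n2 <- 2
  sp2 <- ((n1 - 1) * var(f_m) + (n2 - 1) * var(f_b)) / (n1 + n2 - 2)
  t_stat <- (mean(f_m) - mean(f_b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p_hand <- 2 * stats::pt(-abs(t_stat), df = n1 + n2 - 2)
  expect_equal(fc$p_value[fc$sample == "M"], p_hand)
  expect_equal(fc$flag[fc$sample == "M"],
               if (p_hand < 0.01) "**" else if (p_hand < 0.05) "*" else "")
})

test_that("noise-free simulated tables invert to the true folds exactly", {
  truth <- c(August = 1, September = 1, October = 2, November = 5,
             January = 12, February = 9)
  sim <- simulate_ct_table(true_folds = truth, noise_sd = 0, seed = 3)
  fc <- fold_changes(sim$table, ref_gene = "RcUbql")
  expect_equal(stats::setNames(fc$fold, fc$sample), truth, tolerance = 1e-12)
})

test_that("noisy folds are recovered within tolerance and flagged significant", {
  truth <- c(August = 1, September = 1, October = 2, November = 5,
             January = 15, February = 9)
  rel_err <- c()
  sig <- c()
  for (seed in 1:30) {
    sim <- simulate_ct_table(true_folds = truth, noise_sd = 0.2, seed = seed)
    fc <- fold_changes(sim$table, ref_gene = "RcUbql")
    est <- stats::setNames(fc$fold, fc$sample)[names(truth)[-1]]
    rel_err <- c(rel_err, abs(est - truth[-1]) / truth[-1])
    sig <- c(sig, fc$flag[fc$sample == "January"] == "**")
  }
  expect_lt(mean(rel_err), 0.25)
  expect_gte(mean(sig), 0.9)
})

test_that("amplification efficiency comes from the standard-curve slope", {
  # perfect doubling series: slope -1/log10(2), efficiency exactly 1
  dil <- c(1, 0.5, 0.25, 0.125)
  cts <- 20 - log2(dil)
  eff <- pcr_efficiency(dil, cts)
  expect_equal(eff$efficiency, 1, tolerance = 1e-9)
  expect_equal(eff$r_squared, 1)
  # slope -3.5 gives 10^(1/3.5) - 1
  cts2 <- 20 + 3.5 * -log10(dil)
  expect_equal(pcr_efficiency(dil, cts2)$efficiency, 10^(1 / 3.5) - 1)
  # noisy points against a hand least-squares fit
  set.seed(71)
  cts3 <- 20 - log2(dil) + rnorm(4, 0, 0.3)
  x <- log10(dil)
  slope_hand <- sum((x - mean(x)) * (cts3 - mean(cts3))) / sum((x - mean(x))^2)
  res <- pcr_efficiency(dil, cts3)
  expect_equal(res$slope, slope_hand)
  expect_equal(res$efficiency, 10^(-1 / slope_hand) - 1)
  expect_error(pcr_efficiency(c(1, 0.5), c(20, 21)), "at least 3")
  expect_error(pcr_efficiency(c(1, 1, 1), c(20, 21, 22)), "variance")
})

test_that("in-silico PCR sizes products from exact primer binding", {
  fwd <- "AGAGGTGGTGTTGAACGATCG"
  rev <- "TCTCGCACTTATTACCGCACA"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev)))
  tpl <- paste0(strrep("A", 10), fwd, strrep("T", 30), rc, strrep("C", 5))
  expect_equal(insilico_pcr(tpl, fwd, rev),
               nchar(fwd) + 30 + nchar(rev))
  expect_null(insilico_pcr(paste0(strrep("A", 10), fwd, strrep("T", 30)),
                           fwd, rev))
  # two reverse sites give two products, sorted
  tpl2 <- paste0(tpl, strrep("G", 12), rc)
  lens <- insilico_pcr(tpl2, fwd, rev)
  expect_equal(length(lens), 2)
  expect_true(all(diff(lens) > 0))
  expect_error(insilico_pcr(tpl, "ACGTACGT", rev), "15")
})

test_that("densitometry folds are intensity ratios with unit baseline", {
  folds <- densitometry_folds(c(NA_state = 100, CA = 900, DA = 250))
  expect_equal(unname(folds), c(1, 9, 2.5))
  expect_equal(unname(densitometry_folds(c(NA_state = 50))), 1)
  expect_error(densitometry_folds(c(NA_state = 0, CA = 1)), "positive")
  expect_error(densitometry_folds(c(CA = 1)), "not found")
})
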