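test_that("default motif set matches the field's segment definitions", {
  m <- default_motifs()
  expect_equal(nchar(m$F_expanded$consensus), 18)
  expect_equal(nchar(m$F_core$consensus), 11)
  comp_k <- residue_composition(m$K$consensus)
  expect_equal(unname(comp_k[c("K", "E", "D")]), c(5L, 2L, 1L))
  expect_equal(m$S$min_run, 4)
  expect_equal(c(m$H$window_len, m$H$min_count), c(9, 5))
})

test_that("a consensus matches itself with identity 1 across the motif span", {
  m <- default_motifs()$F_expanded
  hit <- scan_motif(m$consensus, m)
  expect_equal(nrow(hit), 1)
  expect_equal(c(hit$start, hit$end), c(1, 18))
  expect_equal(hit$identity, 1)
  expect_equal(hit$matched, m$consensus)
})

test_that("a planted motif in neutral background is found at its coordinates", {
  m <- default_motifs()$F_expanded
  seq <- paste0(strrep("G", 10), m$consensus, strrep("G", 22))
  hit <- scan_motif(seq, m)
  expect_equal(nrow(hit), 1)
  expect_equal(c(hit$start, hit$end), c(11, 11 + 17))
  expect_equal(hit$matched, substr(seq, hit$start, hit$end))
})

test_that("a doubly substituted copy still scores above threshold", {
  m <- default_motifs()$F_expanded
  mat <- blosum62()
  set.seed(21)
  copy <- strsplit(m$consensus, "")[[1]]
  pos <- sample(18, 2)
  for (p in pos) copy[p] <- sample(setdiff(rownames(mat)[1:20], copy[p]), 1)
  mutated <- paste(copy, collapse = "")
  # hand-summed window score of the mutated copy against the consensus
  cons_chars <- strsplit(m$consensus, "")[[1]]
  hand <- sum(mat[cbind(cons_chars, copy)])
  thr <- m$t * sum(mat[cbind(cons_chars, cons_chars)])
  expect_gte(hand, thr)
  seq <- paste0(strrep("G", 11), mutated, strrep("G", 9))
  hit <- scan_motif(seq, m)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$start, 12)
  expect_equal(hit$score, hand)
})

test_that("window scores and greedy selection agree with a direct oracle", {
  m <- default_motifs()$K
  mat <- blosum62()
  thr <- m$t * sum(mat[cbind(strsplit(m$consensus, "")[[1]],
                             strsplit(m$consensus, "")[[1]])])
  set.seed(33)
  for (i in 1:20) {
    seq <- paste0(rand_protein(sample(5:15, 1)), m$consensus,
                  rand_protein(sample(5:15, 1)))
    scores <- bf_window_scores(seq, m$consensus, mat)
    cand <- which(scores >= thr)
    # independent greedy emulation: descending score, leftmost tie-break
    ord <- cand[order(-scores[cand], cand)]
    taken <- rep(FALSE, nchar(seq))
    expect_sel <- integer(0)
    for (p in ord) {
      span <- p:(p + nchar(m$consensus) - 1)
      if (!any(taken[span])) { expect_sel <- c(expect_sel, p); taken[span] <- TRUE }
    }
    hits <- scan_motif(seq, m)
    expect_equal(hits$start, sort(expect_sel))
    expect_equal(hits$score, scores[sort(expect_sel)])
    expect_true(all(hits$score >= thr))
  }
})

test_that("scanning is position-equivariant under N-terminal padding", {
  m <- default_motifs()$F_expanded
  seq <- paste0(strrep("G", 5), m$consensus, strrep("G", 5))
  base <- scan_motif(seq, m)
  for (k in c(1, 7, 23)) {
    shifted <- scan_motif(paste0(strrep("A", k), seq), m)
    expect_equal(shifted$start, base$start + k)
    expect_equal(shifted$score, base$score)
  }
})

test_that("matches never overlap and multiple copies are all recovered", {
  m <- default_motifs()$F_expanded
  seq <- paste0("GGGG", m$consensus, strrep("T", 12), m$consensus,
                strrep("P", 8), m$consensus)
  hits <- scan_motif(seq, m)
  expect_equal(nrow(hits), 3)
  ok <- all(hits$start[-1] > hits$end[-nrow(hits)])
  expect_true(ok)
  expect_equal(hits$matched, substring(seq, hits$start, hits$end))
})

test_that("false positives on random backgrounds are rare", {
  m <- default_motifs()$F_expanded
  set.seed(101)
  n_fp <- 0
  for (i in 1:100) {
    if (nrow(scan_motif(rand_protein(100), m)) > 0) n_fp <- n_fp + 1
  }
  expect_lt(n_fp / 100, 0.05)
})

test_that("serine tracts are reported as maximal runs of the minimum length", {
  s_motif <- default_motifs()$S
  hit <- find_residue_run("AASSSSSAA", s_motif)
  expect_equal(c(hit$start, hit$end), c(3, 7))
  expect_equal(hit$score, 5)
  expect_equal(nrow(find_residue_run("ASSA", s_motif)), 0)
  two <- find_residue_run("SSSSAAKKSSSSSS", s_motif)
  expect_equal(two$start, c(1, 9))
  expect_equal(two$end, c(4, 14))
})

test_that("histidine-rich regions follow the windowed-count rule", {
  h <- default_motifs()$H
  hit <- find_windowed_count("HHQHHHHVE", h)
  expect_equal(c(hit$start, hit$end), c(1, 9))
  expect_equal(hit$score, 6)     # six H in the nine-residue window
  expect_equal(nrow(find_windowed_count("HAHAHAHA", h)), 0)
  # brute-force confirmation that no 9-window of HHAAAHHAAAHH has 5 H
  s <- "HHAAAHHAAAHH"
  counts <- vapply(1:(nchar(s) - 8), function(p) {
    sum(strsplit(substr(s, p, p + 8), "")[[1]] == "H")
  }, numeric(1))
  expect_true(all(counts < 5))
  expect_equal(nrow(find_windowed_count(s, h)), 0)
  merged <- find_windowed_count(strrep("H", 20), h)
  expect_equal(nrow(merged), 1)
  expect_equal(c(merged$start, merged$end), c(1, 20))
})

test_that("sequences shorter than the motif give an empty result", {
  m <- default_motifs()$F_expanded
  expect_equal(nrow(scan_motif("MKV", m)), 0)
})
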