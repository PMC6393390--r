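fexp <- function() default_motifs()$F_expanded

test_that("the consensus itself is mined as a single full-span hit", {
  db <- data.frame(id = "q", description = "", moltype = "protein",
                   residues = "ETKDRGLFDFLGKKEEEE")
  res <- mine_database(fexp(), db)
  expect_equal(nrow(res$hits), 1)
  expect_equal(c(res$hits$start, res$hits$end), c(1L, 18L))
  expect_equal(res$removed_duplicates, 0)
})

test_that("exact-duplicate database entries are dropped and counted", {
  rec <- data.frame(id = "a", description = "", moltype = "protein",
                    residues = paste0("GGGG", fexp()$consensus, "GGGG"))
  dup <- rec; dup$id <- "b"
  res <- mine_database(fexp(), rbind(rec, dup))
  expect_equal(res$removed_duplicates, 1)
  expect_equal(unique(res$hits$seq_id), "a")
  expect_equal(nrow(res$hits), 1)
  # dedup-then-mine equals mine-then-merge: same hit set as the single record
  solo <- mine_database(fexp(), rec)
  expect_equal(res$hits, solo$hits)
})

test_that("empty databases are rejected", {
  expect_error(mine_database(fexp(), data.frame()), "non-empty")
})

test_that("planted copies are recovered at exact coordinates with no extras", {
  sim <- simulate_segment_db(n_proteins = 40, seed = 13)
  res <- mine_database(fexp(), sim$db)
  got <- res$hits[order(res$hits$seq_id, res$hits$start),
                  c("seq_id", "start", "end")]
  want <- sim$truth[order(sim$truth$id, sim$truth$start),
                    c("id", "start", "end")]
  expect_equal(nrow(got), nrow(want))     # sensitivity 1, FDR 0
  expect_equal(got$seq_id, want$id)
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
  # retained hits never overlap within a protein
  by_prot <- split(res$hits, res$hits$seq_id)
  for (h in by_prot) {
    h <- h[order(h$start), ]
    if (nrow(h) > 1) expect_true(all(h$start[-1] > h$end[-nrow(h)]))
  }
})

test_that("mutated copies are recovered with high sensitivity and no extras", {
  found <- 0; planted <- 0; spurious <- 0
  for (seed in 1:10) {
    sim <- simulate_segment_db(n_proteins = 20, mutation_rate = 0.1,
                               seed = seed)
    res <- mine_database(fexp(), sim$db)
    planted <- planted + nrow(sim$truth)
    for (i in seq_len(nrow(sim$truth))) {
      found <- found + any(
        res$hits$seq_id == sim$truth$id[i] &
          res$hits$start <= sim$truth$end[i] &
          res$hits$end >= sim$truth$start[i])
    }
    for (j in seq_len(nrow(res$hits))) {
      spurious <- spurious + !any(
        sim$truth$id == res$hits$seq_id[j] &
          sim$truth$start <= res$hits$end[j] &
          sim$truth$end >= res$hits$start[j])
    }
  }
  expect_gte(found / planted, 0.95)  # a copy can draw enough substitutions
                                     # to fall below the score threshold
  expect_equal(spurious, 0)          # no hits outside planted segments
})

test_that("hits re-score above the threshold and slices match", {
  sim <- simulate_segment_db(n_proteins = 15, mutation_rate = 0.05, seed = 23)
  res <- mine_database(fexp(), sim$db)
  thr <- 0.5 * local_align(fexp()$consensus, fexp()$consensus)$score
  expect_true(all(res$hits$score >= thr))
  seqs <- stats::setNames(sim$db$residues, sim$db$id)
  expect_equal(res$hits$matched,
               unname(substring(seqs[res$hits$seq_id], res$hits$start,
                                res$hits$end)))
})

test_that("segments with internal insertions are filtered as gapped", {
  cons <- fexp()$consensus
  ins <- paste0(substr(cons, 1, 9), "CG", substr(cons, 10, 18))
  subbed <- paste0("AA", substr(cons, 3, 16), "AA")  # substitutions only
  db <- data.frame(id = c("gapped", "subbed"), description = "",
                   moltype = "protein",
                   residues = c(paste0(strrep("G", 10), ins, strrep("G", 10)),
                                paste0(strrep("G", 10), subbed, strrep("G", 10))))
  res <- mine_database(fexp(), db)
  expect_equal(sum(res$hits$gapped), 1)
  filt <- filter_gapped_segments(res)
  expect_equal(filt$removed_gapped, 1)
  expect_equal(unique(filt$hits$seq_id), "subbed")
  # filtering an empty result is a no-op
  empty <- mine_database(fexp(), data.frame(
    id = "bg", description = "", moltype = "protein",
    residues = strrep("G", 60)))
  expect_equal(nrow(filter_gapped_segments(empty)$hits), 0)
})

test_that("copy-number table sorts by count and labels classes", {
  sim <- simulate_segment_db(
    n_proteins = 12, copy_distribution = c("0" = 0.25, "1" = 0.25,
                                           "2" = 0.25, "3" = 0.25),
    seed = 29)
  ct <- copy_number_table(mine_database(fexp(), sim$db))
  expect_true(all(diff(ct$copies) <= 0))
  expect_equal(ct$class, paste0("F", ct$copies))
  expect_false(any(names(sim$copies)[sim$copies == 0] %in% ct$id))
})
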