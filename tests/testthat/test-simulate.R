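test_that("identical configurations give byte-identical studies", {
  a <- simulate_study(sim_config(seed = 42, n_transcripts = 3,
                                 length_range = c(600L, 900L)))
  b <- simulate_study(sim_config(seed = 42, n_transcripts = 3,
                                 length_range = c(600L, 900L)))
  expect_identical(a$transcripts, b$transcripts)
  expect_identical(a$truth_orfs, b$truth_orfs)
  expect_identical(a$variants, b$variants)
  expect_identical(lapply(a$tracks, `[[`, "scores"),
                   lapply(b$tracks, `[[`, "scores"))
  # different seed: different sequences, same schema
  c2 <- simulate_study(sim_config(seed = 43, n_transcripts = 3,
                                  length_range = c(600L, 900L)))
  expect_false(identical(a$transcripts[[1]]$sequence,
                         c2$transcripts[[1]]$sequence))
  expect_identical(names(a$truth_orfs), names(c2$truth_orfs))
})

test_that("every planted altORF is recovered by prediction", {
  sim <- simulate_study(sim_config(seed = 7, n_transcripts = 6,
                                   n_partial = 1L))
  for (tid in names(sim$transcripts)) {
    pred <- predict_altorfs(sim$transcripts[[tid]])
    tr <- sim$truth_orfs[sim$truth_orfs$transcript_id == tid, ]
    key <- paste(pred$start, pred$end)
    expect_true(all(paste(tr$start, tr$end) %in% key))
    # classes and frame offsets match the plant
    m <- match(paste(tr$start, tr$end), key)
    expect_equal(pred$category[m], tr$category)
    expect_equal(pred$frame_offset[m], tr$frame_offset)
    # and nothing unplanned survives at the policing threshold
    expect_equal(nrow(pred), nrow(tr))
  }
  # truth is consistent with direct translation of the emitted sequence
  for (i in seq_len(nrow(sim$truth_orfs))) {
    tr <- sim$truth_orfs[i, ]
    got <- translate_orf(substring(sim$transcripts[[tr$transcript_id]]$sequence,
                                   tr$start + 1, tr$end))
    expect_identical(got$protein, tr$protein)
    expect_true(got$terminated)
  }
})

test_that("lncRNA transcripts carry planted lncRNA ORFs", {
  sim <- simulate_study(sim_config(seed = 3, n_transcripts = 3,
                                   lncrna_fraction = 1, n_lncrna_orf = 2L))
  for (tid in names(sim$transcripts)) {
    expect_null(sim$transcripts[[tid]]$cds)
    tr <- sim$truth_orfs[sim$truth_orfs$transcript_id == tid, ]
    expect_equal(nrow(tr), 2L)
    expect_true(all(tr$category == "lncRNA_orf"))
    pred <- predict_altorfs(sim$transcripts[[tid]])
    expect_true(all(paste(tr$start, tr$end) %in% paste(pred$start, pred$end)))
  }
})

test_that("background GC is honoured", {
  sim <- simulate_study(sim_config(seed = 15, n_transcripts = 40,
                                   length_range = c(400L, 600L),
                                   n_uorf = 0L, n_dorf = 0L, n_nested = 0L,
                                   cds_fraction = 0.3, n_variants = 0L,
                                   gc = 0.42))
  seqs <- paste(vapply(sim$transcripts, `[[`, character(1), "sequence"),
                collapse = "")
  gc <- mean(strsplit(seqs, "")[[1]] %in% c("G", "C"))
  # coding constraints pull GC slightly; within 2 points of target
  expect_lt(abs(gc - 0.42), 0.02)
})

test_that("planted altProt lengths track the configured median", {
  cfg <- sim_config(seed = 1)
  set.seed(99)
  # the generator's own length distribution at n = 500
  lens <- polyorf:::draw_altprot_len(cfg, n = 500L)
  expect_lt(abs(stats::median(lens) - 45) / 45, 0.10)
  expect_true(all(lens >= 30 & lens <= 300))
})

test_that("variant enrichment factors shape the draw as specified", {
  sim <- simulate_study(sim_config(seed = 8, n_transcripts = 1,
                                   n_variants = 0L))
  tx <- sim$transcripts[[1]]
  orfs <- predict_altorfs(tx)
  sp <- synonymous_space(tx, orfs)
  cov <- attr(sp, "coverage")
  expect_gt(cov, 0)

  # factor 0: never inside an altORF; factor Inf: always inside
  v0 <- simulate_variants(tx, orfs, 200, enrichment_factor = 0, seed = 1)
  s0 <- scan_silent_altering(v0, list(tx))
  expect_equal(sum(s0$positional_hit), 0L)
  vI <- simulate_variants(tx, orfs, 200, enrichment_factor = Inf, seed = 1)
  sI <- scan_silent_altering(vI, list(tx))
  expect_true(all(sI$positional_hit))

  # factor 1: hit fraction within 3 SE of the space coverage
  v1 <- simulate_variants(tx, orfs, 10000, enrichment_factor = 1, seed = 2)
  s1 <- scan_silent_altering(v1, list(tx))
  frac <- sum(s1$occurrence_count[s1$positional_hit]) /
    sum(s1$occurrence_count)
  se <- sqrt(cov * (1 - cov) / 10000)
  expect_lt(abs(frac - cov), 3 * se)

  # all draws are canonical-synonymous
  expect_true(all(s1$canonical_effect %in% c("synonymous", "stop_retained")))
})

test_that("infeasible configurations fail before sampling", {
  expect_error(sim_config(length_range = c(300L, 400L), cds_fraction = 0.8,
                          n_uorf = 1L),
               "infeasible")
  expect_error(sim_config(length_range = c(300L, 400L), cds_fraction = 0.25,
                          n_nested = 2L),
               "infeasible")
})
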