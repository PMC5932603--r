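test_that("synonymous space enumerates silent pairs with correct flags", {
  tx <- transcript("s", paste0("CCC", "ATGAAATAA", "CCC"), cds = c(3L, 12L))
  sp <- synonymous_space(tx, predict_altorfs(tx))
  # AAA -> AAG at the wobble position, and the stop swaps; never the start
  expect_true(all(sp$tpos >= 3 & sp$tpos < 12))
  expect_true(any(sp$tpos == 8 & sp$alt == "G"))        # Lys AAA -> AAG
  expect_true(any(sp$tpos == 10 & sp$alt == "G"))       # TAA -> TGA
  expect_false(any(sp$tpos %in% 3:5))                   # ATG contributes none
  # re-checking every pair in the canonical frame gives a silent effect
  eff <- variant_effects(tx$sequence, 3L, 12L, sp$tpos, sp$alt)
  expect_true(all(eff$effect %in% c("synonymous", "stop_retained")))
  # no altORFs anywhere: all flags false
  expect_false(any(sp$positional))
  expect_false(any(sp$altering))
  # lncRNA has no synonymous space
  expect_error(synonymous_space(transcript("l", strrep("ACGT", 10)),
                                data.frame()), "no CDS")
})

test_that("space flags are consistent with effect_on_orf on the dual toy", {
  tx <- dual_toy()
  orfs <- predict_altorfs(tx, orf_params(min_aa = 2))
  sp <- synonymous_space(tx, orfs)
  for (i in seq_len(nrow(sp))) {
    inside <- sp$tpos[i] >= orfs$start & sp$tpos[i] < orfs$end
    expect_equal(sp$positional[i], any(inside))
    if (any(inside)) {
      eff <- variant_effects(tx$sequence, orfs$start[1], orfs$end[1],
                             sp$tpos[i], sp$alt[i])
      expect_equal(sp$altering[i],
                   eff$effect %in% c("missense", "nonsense", "stop_loss",
                                     "start_loss"))
    }
  }
})

test_that("enrichment test handles the degenerate geometries", {
  sim <- simulate_study(sim_config(seed = 9, n_transcripts = 2,
                                   length_range = c(700L, 900L),
                                   n_variants = 30L))
  scan <- scan_silent_altering(sim$variants, sim$transcripts)

  # zero altORFs anywhere -> fraction 0
  tx <- transcript("flat", paste0(strrep("C", 40), "ATGAAACCCGGGTAA",
                                  strrep("C", 40)), cds = c(40L, 55L))
  sp <- synonymous_space(tx, predict_altorfs(tx))
  vv <- data.frame(transcript_id = "flat", tpos = sp$tpos, ref = sp$ref,
                   alt = sp$alt, occurrence_count = 1L)
  s0 <- scan_silent_altering(vv, list(tx))
  e0 <- enrichment_test(s0, list(tx), n_perm = 19, seed = 1)
  expect_equal(e0$frac_positional, 0)
  expect_equal(e0$frac_altering, 0)
  expect_equal(e0$expected_frac, 0)
  expect_equal(e0$p_perm, 1)  # saturation: null equals observed

  expect_error(enrichment_test(s0[0, ], list(tx)), "no canonical-synonymous")

  # determinism: identical seed, identical result
  e1 <- enrichment_test(scan, sim$transcripts, n_perm = 99, seed = 42)
  e2 <- enrichment_test(scan, sim$transcripts, n_perm = 99, seed = 42)
  expect_identical(e1[names(e1) != "per_gene"], e2[names(e2) != "per_gene"])
  expect_identical(e1$per_gene, e2$per_gene)

  # expected_frac equals the mean permuted fraction within MC error
  e3 <- enrichment_test(scan, sim$transcripts, n_perm = 2000, seed = 3)
  se <- stats::sd(e3$perm_fractions) / sqrt(e3$n_perm)
  expect_lt(abs(mean(e3$perm_fractions) - e3$expected_frac), 4 * se + 1e-9)
})

test_that("fully covered synonymous space saturates the test", {
  # nested altORF spanning nearly the whole short CDS
  set.seed(31)
  sim <- simulate_study(sim_config(seed = 31, n_transcripts = 1,
                                   length_range = c(700L, 800L),
                                   n_uorf = 0L, n_dorf = 0L, n_nested = 1L,
                                   n_variants = 0L))
  tx <- sim$transcripts[[1]]
  orfs <- predict_altorfs(tx)
  sp <- synonymous_space(tx, orfs)
  inside <- sp[sp$positional, , drop = FALSE]
  vv <- data.frame(transcript_id = tx$id, tpos = inside$tpos,
                   ref = inside$ref, alt = inside$alt, occurrence_count = 1L)
  scan <- scan_silent_altering(vv, list(tx))
  enr <- enrichment_test(scan, list(tx), n_perm = 99, seed = 1)
  expect_equal(enr$frac_positional, 1.0)
  expect_gt(enr$p_perm, 0.001)  # not spuriously tiny under partial coverage
})

test_that("per-gene summary does the Table-1 arithmetic", {
  # single gene, 10 synonymous SNVs, 3 altering -> 30%, flag true
  sim <- simulate_study(sim_config(seed = 12, n_transcripts = 1,
                                   length_range = c(700L, 900L),
                                   n_variants = 1L))
  tx <- sim$transcripts[[1]]
  orfs <- predict_altorfs(tx)
  sp <- synonymous_space(tx, orfs)
  alt_pairs <- sp[sp$altering, ][1:3, ]
  clean <- sp[!sp$positional, ][1:7, ]
  vv <- rbind(alt_pairs[, c("tpos", "ref", "alt")],
              clean[, c("tpos", "ref", "alt")])
  vv <- data.frame(transcript_id = tx$id, vv, occurrence_count = 1L)
  scan <- scan_silent_altering(vv, list(tx))
  tab <- summarize_genes(scan, list(tx),
                         stats::setNames(list(orfs), tx$id))
  g <- tab[tab$gene == tx$gene_id, ]
  expect_equal(g$n_syn_snvs, 10L)
  expect_equal(g$n_altering, 3L)
  expect_equal(g$pct_altering, 30.0)
  expect_true(g$gene_flag)
  expect_equal(tab$n_syn_snvs[tab$gene == "ALL"], 10L)

  # median altProt length over two altered proteins of 31 and 45 aa
  expect_equal(stats::median(c(31, 45)), 38)
})
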