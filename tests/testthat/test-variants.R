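test_that("apply_snv substitutes exactly one base and checks the reference", {
  expect_equal(apply_snv("ATG", 2, "G", "A"), "ATA")
  expect_error(apply_snv("ATG", 0, "C", "A"), "mismatch")
  expect_equal(apply_snv(apply_snv("ATG", 2, "G", "A"), 2, "A", "G"), "ATG")
})

test_that("effect classification on a toy ORF covers every class", {
  tx <- transcript("t", "ATGCGATAA", cds = c(0L, 9L))
  orf <- list(start = 0L, end = 9L)
  eff <- function(tpos, ref, alt) {
    effect_on_orf(list(tpos = tpos, ref = ref, alt = alt), orf, tx)$effect
  }
  expect_equal(eff(5, "A", "G"), "synonymous")   # CGA -> CGG, both Arg
  expect_equal(eff(3, "C", "T"), "nonsense")     # CGA -> TGA
  expect_equal(eff(2, "G", "C"), "start_loss")   # ATG -> ATC
  expect_equal(eff(7, "A", "C"), "stop_loss")    # TAA -> TCA
  expect_equal(eff(4, "G", "A"), "missense")     # CGA -> CAA
  tx2 <- transcript("t2", "ATGAAATAA", cds = c(0L, 9L))
  expect_equal(effect_on_orf(list(tpos = 7, ref = "A", alt = "G"),
                             list(start = 0L, end = 9L), tx2)$effect,
               "stop_retained")                   # TAA -> TGA
  expect_error(eff(5, "G", "A"), "mismatch")
})

test_that("position-2 substitutions in sense codons are never synonymous", {
  # exhaustive over 64 codons x 9 substitutions, against the hand table;
  # the only position-2 silent change is the TAA<->TGA stop swap
  code <- genetic_code()
  for (cod in names(HAND_CODE)) {
    seq <- paste0(cod, "TAA")
    for (pos in 0:2) {
      ref <- substr(cod, pos + 1, pos + 1)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        eff <- variant_effects(seq, 0L, 6L, pos, alt, code)
        # agreement with the whole-protein-diff oracle
        expect_identical(eff$effect, bf_effect(seq, 0L, 6L, pos, alt))
        if (pos == 1 && HAND_CODE[cod] != "*") {
          expect_false(eff$effect %in% c("synonymous", "stop_retained"))
        }
        if (pos == 1 && eff$effect == "stop_retained") {
          expect_true(cod %in% c("TAA", "TGA"))
        }
      }
    }
  }
})

test_that("annotate_variant flags silent-but-altering on the dual toy", {
  tx <- dual_toy()
  orfs <- predict_altorfs(tx, orf_params(min_aa = 2))
  rec <- annotate_variant(list(tpos = 8, ref = "A", alt = "G"), tx, orfs)
  expect_equal(rec$canonical_effect$effect, "synonymous")  # GGA -> GGG
  expect_equal(rec$altorf_effects$effect, "missense")      # GAT -> GGT
  expect_true(rec$silent_but_altering)
  # verified by translating both full ORFs before and after the mutation
  mut <- apply_snv(tx$sequence, 8, "A", "G")
  expect_identical(translate_orf(substr(mut, 1, 18))$protein,
                   translate_orf(substr(tx$sequence, 1, 18))$protein)
  expect_false(identical(translate_orf(substr(mut, 5, 13))$protein,
                         translate_orf(substr(tx$sequence, 5, 13))$protein))

  # canonical missense is never silent-but-altering
  rec2 <- annotate_variant(list(tpos = 7, ref = "G", alt = "A"), tx, orfs)
  expect_equal(rec2$canonical_effect$effect, "missense")
  expect_false(rec2$silent_but_altering)

  # 5' UTR SNV with no altORF overlap: no canonical effect, empty effects
  tx3 <- transcript("t3", paste0("CCCCCC", "ATGAAATAA"), cds = c(6L, 15L))
  rec3 <- annotate_variant(list(tpos = 1, ref = "C", alt = "A"), tx3,
                           predict_altorfs(tx3, orf_params(min_aa = 1)))
  expect_null(rec3$canonical_effect)
  expect_equal(nrow(rec3$altorf_effects), 0L)
  expect_false(rec3$silent_but_altering)
})

test_that("exhaustive SNV scan agrees with the whole-protein-diff oracle", {
  set.seed(202)
  r <- random_transcript_bf("ex1", 300, min_aa = 10L)
  expect_false(is.null(r$cds))  # this seed yields a CDS
  tx <- r$tx
  orfs <- predict_altorfs(tx, orf_params(min_aa = 10L))
  all_orfs <- rbind(orfs[, c("start", "end")],
                    data.frame(start = r$cds[1], end = r$cds[2]))
  for (i in seq_len(nrow(all_orfs))) {
    s <- all_orfs$start[i]; e <- all_orfs$end[i]
    for (tpos in s:(e - 1L)) {
      ref <- substr(tx$sequence, tpos + 1, tpos + 1)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        expect_identical(
          variant_effects(tx$sequence, s, e, tpos, alt)$effect,
          bf_effect(tx$sequence, s, e, tpos, alt)
        )
      }
    }
  }
})

test_that("scan_silent_altering conserves counts and orders records", {
  sim <- simulate_study(sim_config(seed = 5, n_transcripts = 3,
                                   length_range = c(600L, 900L),
                                   n_variants = 25L))
  v <- sim$variants
  # add a variant on an unknown transcript: skipped with warning, counted
  v2 <- rbind(v, data.frame(transcript_id = "NOPE", tpos = 3L, ref = "A",
                            alt = "C", occurrence_count = 2L))
  v2$ref[v2$transcript_id == "NOPE"] <- "A"
  expect_warning(scan <- scan_silent_altering(v2, sim$transcripts),
                 "unknown")
  ctr <- attr(scan, "counters")
  expect_equal(ctr[["n_input"]], sum(v2$occurrence_count))
  expect_equal(ctr[["n_skipped"]], 2L)
  expect_equal(ctr[["n_records"]], sum(v$occurrence_count))
  # deterministic ordering
  expect_false(is.unsorted(order(scan$transcript_id, scan$tpos, scan$alt)))
  # every simulated variant is canonical-synonymous by construction
  expect_true(all(scan$canonical_effect %in% c("synonymous",
                                               "stop_retained")))

  # altORF-free transcripts yield zero altering hits
  tx <- transcript("flat", paste0(strrep("C", 30), "ATGAAATAA",
                                  strrep("C", 30)), cds = c(30L, 39L))
  sp <- synonymous_space(tx, predict_altorfs(tx))
  vv <- data.frame(transcript_id = "flat", tpos = sp$tpos, ref = sp$ref,
                   alt = sp$alt, occurrence_count = 1L)
  s2 <- scan_silent_altering(vv, list(tx))
  expect_equal(sum(s2$altering_hit), 0L)
  expect_equal(sum(s2$silent_but_altering), 0L)
})
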