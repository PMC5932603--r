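test_that("enumerate_orfs finds constructed ORFs and honours the rules", {
  one <- enumerate_orfs("ATGAAATAG", orf_params(min_aa = 1))
  expect_equal(nrow(one), 1L)
  expect_equal(one$start, 0L)
  expect_equal(one$end, 9L)
  expect_equal(one$protein, "MK")
  expect_true(one$has_stop)

  expect_equal(nrow(enumerate_orfs("AAAAAAAAA")), 0L)
  expect_equal(nrow(enumerate_orfs("")), 0L)
  expect_error(enumerate_orfs("ATGXYZ"), "alphabet")

  # 5'-most start per (frame, stop) by default; all starts on request
  seq <- "ATGATGAAATAG"  # two in-frame starts sharing one stop
  expect_equal(enumerate_orfs(seq, orf_params(min_aa = 1))$start, 0L)
  expect_equal(enumerate_orfs(seq, orf_params(min_aa = 1,
                                              report_all_starts = TRUE))$start,
               c(0L, 3L))

  # require_stop controls open-ended ORFs
  open <- "ATGAAAAAAAAA"
  expect_equal(nrow(enumerate_orfs(open, orf_params(min_aa = 1))), 0L)
  no_stop <- enumerate_orfs(open, orf_params(min_aa = 1,
                                             require_stop = FALSE))
  expect_equal(no_stop$end, 12L)
  expect_false(no_stop$has_stop)
})

test_that("enumerate_orfs equals the brute-force per-position scanner", {
  set.seed(101)
  for (rep in 1:40) {
    seq <- random_dna(sample(200:1200, 1))
    for (min_aa in c(1L, 5L, 20L)) {
      got <- enumerate_orfs(seq, orf_params(min_aa = min_aa))
      want <- bf_enumerate_orfs(seq, min_aa = min_aa)
      expect_equal(got[, c("start", "end", "frame", "length_aa", "has_stop")],
                   want, ignore_attr = TRUE)
      # every reported ORF satisfies the type invariants
      if (nrow(got)) {
        expect_true(all((got$end - got$start) %% 3 == 0))
        expect_true(all(substring(seq, got$start + 1, got$start + 3) == "ATG"))
        expect_false(any(grepl("\\*", got$protein)))
        expect_equal(got$length_aa,
                     (got$end - got$start) %/% 3L - as.integer(got$has_stop))
      }
    }
  }
})

test_that("classification follows the interval rules", {
  tx <- transcript("t", paste0(strrep("A", 12), "ATG", strrep("AAG", 4),
                               "TAA", strrep("A", 20)),
                   cds = c(12L, 30L))
  mk <- function(s, e) data.frame(start = s, end = e, frame = s %% 3L,
                                  protein = "", length_aa = (e - s) / 3 - 1,
                                  has_stop = TRUE)
  expect_equal(classify_orfs(mk(0L, 9L), tx)$category, "uORF")
  expect_equal(classify_orfs(mk(34L, 49L), tx)$category, "dORF")
  expect_equal(classify_orfs(mk(12L, 30L), tx)$category, "canonical")
  expect_equal(classify_orfs(mk(13L, 28L), tx)$category, "overlap_nested")
  expect_equal(classify_orfs(mk(13L, 28L), tx)$frame_offset, 1L)
  expect_equal(classify_orfs(mk(4L, 22L), tx)$category, "overlap_partial")
  expect_error(classify_orfs(mk(40L, 61L), tx), "bounds")

  lnc <- transcript("l", strrep("ACGT", 10))
  expect_equal(classify_orfs(mk(0L, 9L), lnc)$category, "lncRNA_orf")
  expect_true(is.na(classify_orfs(mk(0L, 9L), lnc)$frame_offset))
})

test_that("predict_altorfs excludes canonical and in-frame overlaps", {
  tx <- dual_toy()
  got <- predict_altorfs(tx, orf_params(min_aa = 2))
  expect_equal(nrow(got), 1L)
  expect_equal(got$start, 4L)
  expect_equal(got$end, 13L)
  expect_equal(got$frame_offset, 1L)
  expect_equal(got$protein, "MD")
  expect_equal(got$category, "overlap_nested")
  # confirmed by direct translation
  expect_equal(translate_orf(substring(tx$sequence, 5, 13))$protein, "MD")

  # internal in-frame ATG sharing the CDS's stop is not an altORF
  tx2 <- transcript("t2", "ATGAAAATGAAATAA", cds = c(0L, 15L))
  got2 <- predict_altorfs(tx2, orf_params(min_aa = 1))
  expect_equal(nrow(got2), 0L)

  # lncRNA transcript: planted 35-aa ORF surfaces as lncRNA_orf at default
  # min_aa = 30
  body <- paste(rep("GCT", 34), collapse = "")
  lnc <- transcript("l1", paste0("CCC", "ATG", body, "TAA", "CCC"))
  got3 <- predict_altorfs(lnc)
  expect_equal(got3$category, "lncRNA_orf")
  expect_equal(got3$length_aa, 35L)
})

test_that("raising min_aa never adds an ORF (nested survivor sets)", {
  set.seed(77)
  for (rep in 1:10) {
    r <- random_transcript_bf(paste0("r", rep), sample(500:1500, 1),
                              min_aa = 10L)
    prev <- NULL
    for (min_aa in c(5L, 10L, 20L, 40L)) {
      cur <- predict_altorfs(r$tx, orf_params(min_aa = min_aa))
      key <- paste(cur$start, cur$end)
      if (!is.null(prev)) expect_true(all(key %in% prev))
      prev <- key
    }
  }
})
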