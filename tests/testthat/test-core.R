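test_that("translation follows the standard code, stops at the first stop", {
  expect_equal(translate_orf("ATGAAATAG"), list(protein = "MK",
                                                terminated = TRUE))
  expect_equal(translate_orf("TAA"), list(protein = "", terminated = TRUE))
  expect_equal(translate_orf("ATGNNNAAA")$protein, "MXK")
  expect_error(translate_orf("ATGA"), "multiple of 3")
  expect_error(translate_orf(""), "non-empty")

  # all 64 codons against an independently transcribed code table
  code <- genetic_code()
  for (cod in names(HAND_CODE)) {
    expect_identical(unname(code$codon_to_aa[cod]), unname(HAND_CODE[cod]))
  }
  expect_setequal(stop_codons(code), c("TAA", "TAG", "TGA"))
  expect_length(code$codon_to_aa, 64L)
})

test_that("codon_position does the arithmetic and partitions an ORF", {
  expect_equal(codon_position(list(start = 10, end = 19), 10),
               list(codon_index = 0L, codon_pos = 1L))
  expect_equal(codon_position(list(start = 10, end = 19), 15),
               list(codon_index = 1L, codon_pos = 3L))
  expect_equal(codon_position(list(start = 4, end = 13), 8),
               list(codon_index = 1L, codon_pos = 2L))
  expect_error(codon_position(list(start = 4, end = 13), 13), "outside")

  orf <- list(start = 6L, end = 27L)
  cp <- codon_position(orf, 6:26)
  expect_equal(sort(unique(cp$codon_pos)), 1:3)
  # each position maps to exactly one (codon_index, codon_pos)
  expect_false(any(duplicated(paste(cp$codon_index, cp$codon_pos))))
  expect_equal(length(cp$codon_index), 21L)
})

test_that("genomic/transcript projection matches the exon arithmetic", {
  exons <- rbind(c(100L, 110L), c(120L, 130L))
  mp <- coordinate_map(exons, "+")
  mm <- coordinate_map(exons, "-")
  expect_equal(genomic_to_transcript(mp, 121), 11L)
  expect_equal(genomic_to_transcript(mm, 100), 19L)
  expect_true(is.na(genomic_to_transcript(mp, 115)))
  expect_true(is.na(genomic_to_transcript(mp, 99)))
  expect_equal(transcript_to_genomic(mm, 0), 129L)  # last base of last exon
  expect_error(transcript_to_genomic(mp, 20), "out of range")
})

test_that("coordinate round trip holds on random exon structures", {
  set.seed(11)
  for (rep in 1:50) {
    n_ex <- sample(1:4, 1)
    widths <- sample(30:150, n_ex, replace = TRUE)
    gaps <- sample(20:200, n_ex, replace = TRUE)
    starts <- sample(1000:2000, 1) + cumsum(gaps) +
      c(0L, cumsum(widths))[seq_len(n_ex)]
    exons <- cbind(starts, starts + widths)
    for (strand in c("+", "-")) {
      m <- coordinate_map(exons, strand)
      tpos <- 0:(m$length - 1L)
      g <- transcript_to_genomic(m, tpos)
      expect_equal(genomic_to_transcript(m, g), tpos)
      # every exonic genomic position has exactly one image
      expect_false(any(duplicated(g)))
    }
  }
})

test_that("minus-strand transcripts load as the sense strand", {
  # sense transcript on the minus strand of a small contig
  sense <- "ATGAAACCCGGGTTTTAA"
  contig <- paste0("GGGG", revcomp(sense), "CCCC")
  exons <- rbind(c(4L, 4L + nchar(sense)))
  tx <- transcript("m1", sense, exons = exons, strand = "-",
                   chrom = "c", cds = c(0L, 18L))
  m <- coordinate_map_of(tx)
  # translating the stored sense sequence equals translating the
  # reverse-complement of the genomic slice
  gslice <- substring(contig, exons[1] + 1L, exons[2])
  expect_identical(translate_orf(revcomp(gslice))$protein,
                   translate_orf(tx$sequence)$protein)
})

test_that("transcript invariants are enforced at construction", {
  expect_error(transcript("x", "ATGAA", cds = c(0L, 5L)), "multiple of 3")
  expect_error(transcript("x", "AAAGGGTAA", cds = c(0L, 9L)), "ATG")
  expect_error(transcript("x", "ATGAAAGGG", cds = c(0L, 9L)), "stop")
  expect_error(transcript("x", "ATGAAATAA", cds = c(0L, 12L)), "outside")
  expect_error(transcript("x", "ATGXXATAA"), "alphabet")
  expect_silent(transcript("x", "ATGAAATAA", cds = c(0L, 9L)))
})
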