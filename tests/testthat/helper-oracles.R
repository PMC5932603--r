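# Independent oracles and small fixture builders. These deliberately avoid
# the package's own code paths: the code table is hand-transcribed, the ORF
# scanner walks positions one by one, and the effect oracle diffs whole
# translated proteins.

# hand-transcribed standard genetic code (independent of Biostrings)
HAND_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)
HAND_STOPS <- names(HAND_CODE)[HAND_CODE == "*"]

# brute-force ORF scanner: test every position for ATG, walk codon by codon
# to the first stop, then apply the length / dedup rules independently
bf_enumerate_orfs <- function(seq, min_aa = 30L, require_stop = TRUE,
                              report_all_starts = FALSE) {
  n <- nchar(seq)
  rows <- list()
  for (p in 0:(n - 3L)) {
    if (substr(seq, p + 1L, p + 3L) != "ATG") next
    q <- p
    stop_at <- NA_integer_
    while (q + 3L <= n) {
      cod <- substr(seq, q + 1L, q + 3L)
      if (q > p && cod %in% HAND_STOPS) {
        stop_at <- q
        break
      }
      q <- q + 3L
    }
    if (is.na(stop_at)) {
      if (require_stop) next
      end <- p + 3L * ((n - p) %/% 3L)
      len <- (end - p) %/% 3L
      if (len < min_aa) next
      rows[[length(rows) + 1L]] <-
        data.frame(start = p, end = end, frame = p %% 3L, length_aa = len,
                   has_stop = FALSE, group = paste0(p %% 3L, ".open"))
    } else {
      len <- (stop_at - p) %/% 3L
      if (len < min_aa) next
      rows[[length(rows) + 1L]] <-
        data.frame(start = p, end = stop_at + 3L, frame = p %% 3L,
                   length_aa = len, has_stop = TRUE,
                   group = paste0(p %% 3L, ".", stop_at))
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      frame = integer(0), length_aa = integer(0),
                      has_stop = logical(0)))
  }
  df <- do.call(rbind, rows)
  if (!report_all_starts) {
    df <- df[order(df$group, df$start), , drop = FALSE]
    df <- df[!duplicated(df$group), , drop = FALSE]
  }
  df$group <- NULL
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# filter rules applied on top of the brute-force scan: drop the canonical
# interval and any CDS-overlapping ORF in the canonical frame
bf_predict_altorfs <- function(seq, cds, min_aa = 30L) {
  df <- bf_enumerate_orfs(seq, min_aa = min_aa)
  if (is.null(cds) || !nrow(df)) return(df)
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    s <- df$start[i]; e <- df$end[i]
    if (s == cds[1] && e == cds[2]) next
    overlaps <- s < cds[2] && e > cds[1]
    if (overlaps && (s - cds[1]) %% 3L == 0L) next
    keep[i] <- TRUE
  }
  df[keep, , drop = FALSE]
}

bf_translate_all <- function(seq, start, end) {
  cs <- seq.int(start, end - 3L, by = 3L)
  aa <- HAND_CODE[substring(seq, cs + 1L, cs + 3L)]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

# whole-protein-diff oracle: translate the full ORF before and after the
# substitution and classify from the (single) changed residue
bf_effect <- function(seq, orf_start, orf_end, tpos, alt) {
  ref_aa <- bf_translate_all(seq, orf_start, orf_end)
  mut <- seq
  substr(mut, tpos + 1L, tpos + 1L) <- alt
  alt_aa <- bf_translate_all(mut, orf_start, orf_end)
  ci <- (tpos - orf_start) %/% 3L
  stopifnot(all(ref_aa[-(ci + 1L)] == alt_aa[-(ci + 1L)]))
  r <- ref_aa[ci + 1L]
  a <- alt_aa[ci + 1L]
  cstart <- orf_start + 3L * ci
  alt_codon <- substr(mut, cstart + 1L, cstart + 3L)
  if (r == "X" || a == "X") return("unknown")
  if (r == "*" && a == "*") return("stop_retained")
  if (r == a) return("synonymous")
  if (a == "*") return("nonsense")
  if (r == "*") return("stop_loss")
  if (ci == 0L && alt_codon != "ATG") return("start_loss")
  "missense"
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# random transcript whose CDS (if any) is chosen by the brute-force scanner,
# keeping CDS selection independent of the implementation under test
random_transcript_bf <- function(id, len, min_aa = 30L, gc = 0.5) {
  seq <- random_dna(len, gc)
  orfs <- bf_enumerate_orfs(seq, min_aa = min_aa)
  cds <- NULL
  if (nrow(orfs)) {
    best <- orfs[which.max(orfs$length_aa), ]
    if (best$has_stop) cds <- c(best$start, best$end)
  }
  list(tx = transcript(id, seq, cds = cds), cds = cds, seq = seq)
}

# the dual-coding toy used across modules: canonical MHGLI with a nested
# frame-offset-1 altORF encoding "MD"
dual_toy <- function() {
  transcript("toy1", "ATGCATGGATTGATATAA", gene_id = "TOY", cds = c(0L, 18L))
}
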