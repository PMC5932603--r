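#' ORF enumeration parameters
#'
#' Defaults follow the working definition of an alternative ORF used
#' throughout this package: an ATG-initiated reading frame, in any of the
#' three frames of a mature transcript, encoding at least 30 amino acids
#' (the OpenProt-style minimal cut-off). ORFs shorter than `smorf_max_aa`
#' (100 codons) are additionally tagged as smORFs.
#'
#' @param min_aa Minimum protein length in amino acids, stop excluded
#'   (default 30).
#' @param require_stop Must an ORF terminate within the transcript?
#'   (default `TRUE`). When `FALSE`, ORFs without an in-frame stop extend to
#'   the last complete codon and carry `has_stop = FALSE`.
#' @param start_codons Set of permitted start codons (default `"ATG"`).
#' @param report_all_starts Report every qualifying start per (frame, stop)
#'   rather than only the 5'-most (default `FALSE`).
#' @param smorf_max_aa smORF annotation threshold in aa (default 100; tag
#'   only, no filtering).
#' @return An object of class `orf_params`.
#' @export
orf_params <- function(min_aa = 30L, require_stop = TRUE,
                       start_codons = "ATG", report_all_starts = FALSE,
                       smorf_max_aa = 100L) {
  min_aa <- as.integer(min_aa)
  stopifnot(min_aa >= 1L, is.logical(require_stop),
            all(nchar(start_codons) == 3L), !any(grepl("[^ACGT]", start_codons)))
  structure(
    list(min_aa = min_aa, require_stop = isTRUE(require_stop),
         start_codons = toupper(start_codons),
         report_all_starts = isTRUE(report_all_starts),
         smorf_max_aa = as.integer(smorf_max_aa)),
    class = "orf_params"
  )
}

#' @noRd
empty_orf_df <- function() {
  data.frame(start = integer(0), end = integer(0), frame = integer(0),
              protein = character(0), length_aa = integer(0),
              has_stop = logical(0), stringsAsFactors = FALSE)
}

#' Enumerate open reading frames on a sequence
#'
#' Scans all three reading frames for ORFs beginning at a start codon and
#' extending to the first in-frame stop (included in the footprint). Codons
#' containing `N` translate to `"X"` and never act as start or stop codons.
#'
#' @param seq DNA string over `{A,C,G,T,N}`.
#' @param params An [orf_params()] object.
#' @param code Genetic code.
#' @return data.frame with columns `start`, `end` (0-based half-open,
#'   stop included), `frame` (`start %% 3`), `protein`, `length_aa`,
#'   `has_stop`, sorted by (start, end).
#' @examples
#' enumerate_orfs("ATGAAATAG", orf_params(min_aa = 1))
#' @export
enumerate_orfs <- function(seq, params = orf_params(), code = genetic_code()) {
  if (length(seq) != 1L || !is.character(seq)) {
    stop("'seq' must be a single string", call. = FALSE)
  }
  if (nchar(seq) == 0L) return(empty_orf_df())
  seq <- toupper(seq)
  check_alphabet(seq)
  n <- nchar(seq)
  out <- vector("list", 3L)
  for (f in 0:2) {
    ncod <- (n - f) %/% 3L
    if (ncod < 2L) next
    cs <- f + 3L * (seq_len(ncod) - 1L)       # 0-based codon starts
    cod <- substring(seq, cs + 1L, cs + 3L)
    aa <- codons_to_aa(cod, code)
    starts <- which(cod %in% params$start_codons)
    stops <- which(aa == "*")
    if (!length(starts)) next
    # first in-frame stop strictly after each start (start codons are sense)
    nxt <- findInterval(starts, stops) + 1L
    j <- ifelse(nxt <= length(stops), stops[nxt], NA_integer_)
    rows <- lapply(seq_along(starts), function(k) {
      i <- starts[k]
      jk <- j[k]
      if (is.na(jk)) {
        if (params$require_stop) return(NULL)
        len <- ncod - i + 1L
        if (len < params$min_aa) return(NULL)
        data.frame(start = f + 3L * (i - 1L), end = f + 3L * ncod, frame = f,
                   protein = paste(aa[i:ncod], collapse = ""),
                   length_aa = len, has_stop = FALSE,
                   group = ncod + 1L, stringsAsFactors = FALSE)
      } else {
        len <- jk - i
        if (len < params$min_aa) return(NULL)
        data.frame(start = f + 3L * (i - 1L), end = f + 3L * jk, frame = f,
                   protein = paste(aa[i:(jk - 1L)], collapse = ""),
                   length_aa = len, has_stop = TRUE,
                   group = jk, stringsAsFactors = FALSE)
      }
    })
    df <- do.call(rbind, rows)
    if (is.null(df) || !nrow(df)) next
    if (!params$report_all_starts) {
      # 5'-most start per (frame, stop) group
      df <- df[order(df$group, df$start), , drop = FALSE]
      df <- df[!duplicated(df$group), , drop = FALSE]
    }
    out[[f + 1L]] <- df
  }
  res <- do.call(rbind, out)
  if (is.null(res) || !nrow(res)) return(empty_orf_df())
  res$group <- NULL
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

ORF_CATEGORIES <- c("canonical", "uORF", "dORF", "overlap_nested",
                    "overlap_partial", "lncRNA_orf")

#' Classify ORFs relative to the canonical CDS
#'
#' Adds `category` and `frame_offset` columns to an ORF table. Categories:
#' `uORF` (entirely 5' of the CDS), `dORF` (entirely 3'), `overlap_nested`
#' (inside the CDS), `overlap_partial` (crossing a CDS boundary),
#' `canonical` (identical interval), and `lncRNA_orf` on transcripts with
#' no CDS. `frame_offset` is `(start - cds_start) %% 3` (NA without a CDS).
#'
#' @param orfs ORF data.frame from [enumerate_orfs()].
#' @param tx A [transcript()].
#' @return The ORF table with `category` and `frame_offset` columns.
#' @export
classify_orfs <- function(orfs, tx) {
  n <- nchar(tx$sequence)
  if (nrow(orfs) && (min(orfs$start) < 0L || max(orfs$end) > n)) {
    stop("ORF outside transcript bounds [0,", n, ")", call. = FALSE)
  }
  if (is.null(tx$cds)) {
    orfs$category <- rep("lncRNA_orf", nrow(orfs))
    orfs$frame_offset <- rep(NA_integer_, nrow(orfs))
    return(orfs)
  }
  c1 <- tx$cds[1]; c2 <- tx$cds[2]
  cat <- character(nrow(orfs))
  for (i in seq_len(nrow(orfs))) {
    s <- orfs$start[i]; e <- orfs$end[i]
    cat[i] <- if (s == c1 && e == c2) "canonical"
      else if (e <= c1) "uORF"
      else if (s >= c2) "dORF"
      else if (s >= c1 && e <= c2) "overlap_nested"
      else "overlap_partial"
  }
  orfs$category <- cat
  orfs$frame_offset <- (orfs$start - c1) %% 3L
  orfs
}

#' Predict alternative ORFs on a transcript
#'
#' Enumerates ORFs in all three frames and removes (a) the canonical CDS
#' itself and (b) CDS-overlapping ORFs in the canonical frame
#' (frame offset 0; in-frame truncations or extensions are not alternative
#' ORFs). Same-frame ORFs that do not overlap the CDS (e.g. a uORF whose
#' absolute frame happens to match) are kept. Each surviving ORF is
#' classified and tagged as a smORF when shorter than
#' `params$smorf_max_aa` codons.
#'
#' @param tx A [transcript()].
#' @param params An [orf_params()] object.
#' @param code Genetic code.
#' @return data.frame with columns `transcript_id`, `gene_id`, `orf_id`,
#'   `start`, `end`, `frame`, `frame_offset`, `category`, `length_aa`,
#'   `smorf`, `has_stop`, `protein`.
#' @examples
#' tx <- transcript("t1", "ATGCATGGATTGATATAA", cds = c(0L, 18L))
#' predict_altorfs(tx, orf_params(min_aa = 2))  # nested altORF "MD"
#' @export
predict_altorfs <- function(tx, params = orf_params(), code = genetic_code()) {
  orfs <- enumerate_orfs(tx$sequence, params, code)
  orfs <- classify_orfs(orfs, tx)
  if (!is.null(tx$cds) && nrow(orfs)) {
    c1 <- tx$cds[1]; c2 <- tx$cds[2]
    overlaps <- orfs$start < c2 & orfs$end > c1
    drop <- orfs$category == "canonical" | (overlaps & orfs$frame_offset == 0L)
    orfs <- orfs[!drop, , drop = FALSE]
  }
  n <- nrow(orfs)
  out <- data.frame(
    transcript_id = rep(tx$id, n), gene_id = rep(tx$gene_id, n),
    orf_id = if (n) sprintf("%s.altORF%03d", tx$id, seq_len(n)) else character(0),
    start = orfs$start, end = orfs$end, frame = orfs$frame,
    frame_offset = orfs$frame_offset, category = orfs$category,
    length_aa = orfs$length_aa, smorf = orfs$length_aa < params$smorf_max_aa,
    has_stop = orfs$has_stop, protein = orfs$protein,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Canonical CDS as a one-row ORF table
#' @noRd
canonical_orf <- function(tx, code = genetic_code()) {
  if (is.null(tx$cds)) return(NULL)
  prot <- translate_orf(substring(tx$sequence, tx$cds[1] + 1L, tx$cds[2]),
                        code)
  data.frame(
    transcript_id = tx$id, gene_id = tx$gene_id,
    orf_id = paste0(tx$id, ".CDS"),
    start = tx$cds[1], end = tx$cds[2], frame = tx$cds[1] %% 3L,
    frame_offset = 0L, category = "canonical",
    length_aa = nchar(prot$protein), smorf = FALSE, has_stop = TRUE,
    protein = prot$protein, stringsAsFactors = FALSE
  )
}
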