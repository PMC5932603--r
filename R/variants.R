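EFFECT_LEVELS <- c("synonymous", "stop_retained", "missense", "nonsense",
                   "stop_loss", "start_loss", "unknown")
ALTERING_EFFECTS <- c("missense", "nonsense", "stop_loss", "start_loss")
SILENT_EFFECTS <- c("synonymous", "stop_retained")
# most severe first, for the record-level top alteration
SEVERITY_ORDER <- c("nonsense", "stop_loss", "start_loss", "missense",
                    "stop_retained", "synonymous", "unknown")

#' Apply a single-nucleotide substitution to a sequence
#'
#' @param seq DNA string.
#' @param tpos 0-based position of the substitution.
#' @param ref Expected reference base at `tpos`; a mismatch is a
#'   data-integrity error and aborts.
#' @param alt Alternative base.
#' @return The substituted sequence.
#' @export
apply_snv <- function(seq, tpos, ref, alt) {
  obs <- substring(seq, tpos + 1L, tpos + 1L)
  if (obs != ref) {
    stop("reference mismatch at position ", tpos, ": expected '", ref,
         "', sequence has '", obs, "'", call. = FALSE)
  }
  substr(seq, tpos + 1L, tpos + 1L) <- alt
  seq
}

#' Consequences of substitutions within one ORF (vectorised)
#'
#' Classifies each `(tpos, alt)` substitution against the reading frame of a
#' single ORF. Classification is a pure function of the reference codon, the
#' alternative codon, and the codon index: equal sense amino acids are
#' `synonymous`; two stop codons are `stop_retained`; sense-to-stop is
#' `nonsense`; stop-to-sense is `stop_loss`; a codon-0 change that destroys
#' the start codon is `start_loss`; anything else is `missense`. Codons
#' containing `N` give `unknown`.
#'
#' @param seq Transcript sequence.
#' @param orf_start,orf_end ORF interval (0-based half-open, stop included).
#' @param tpos,alt Parallel vectors of positions and alternative bases.
#' @param code Genetic code.
#' @param start_codons Permitted start codons (for the start-loss rule).
#' @return data.frame with `effect`, `codon_index`, `codon_pos`,
#'   `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`.
#' @export
variant_effects <- function(seq, orf_start, orf_end, tpos, alt,
                            code = genetic_code(), start_codons = "ATG") {
  tpos <- as.integer(tpos)
  if (any(tpos < orf_start | tpos >= orf_end)) {
    stop("SNV position outside ORF [", orf_start, ",", orf_end, ")",
         call. = FALSE)
  }
  ci <- (tpos - orf_start) %/% 3L
  cp <- (tpos - orf_start) %% 3L + 1L
  cstart <- orf_start + 3L * ci
  ref_codon <- substring(seq, cstart + 1L, cstart + 3L)
  alt_codon <- paste0(substring(ref_codon, 1L, cp - 1L), alt,
                      substring(ref_codon, cp + 1L, 3L))
  ref_aa <- codons_to_aa(ref_codon, code)
  alt_aa <- codons_to_aa(alt_codon, code)
  effect <- ifelse(
    ref_aa == "X" | alt_aa == "X", "unknown",
    ifelse(ref_aa == "*" & alt_aa == "*", "stop_retained",
    ifelse(ref_aa == alt_aa, "synonymous",
    ifelse(alt_aa == "*", "nonsense",
    ifelse(ref_aa == "*", "stop_loss",
    ifelse(ci == 0L & !(alt_codon %in% start_codons), "start_loss",
           "missense"))))))
  data.frame(effect = effect, codon_index = ci, codon_pos = cp,
             ref_codon = ref_codon, alt_codon = alt_codon,
             ref_aa = ref_aa, alt_aa = alt_aa, stringsAsFactors = FALSE)
}

#' Consequence of one SNV in one ORF
#'
#' Scalar wrapper around [variant_effects()] that also verifies the SNV's
#' reference allele against the transcript sequence.
#'
#' @param snv List or one-row data.frame with `tpos`, `ref`, `alt`.
#' @param orf List or one-row data.frame with `start`, `end`.
#' @param tx A [transcript()].
#' @param code Genetic code.
#' @return One-row effect data.frame (see [variant_effects()]).
#' @examples
#' tx <- transcript("t", "ATGCGATAA", cds = c(0L, 9L))
#' effect_on_orf(list(tpos = 5, ref = "A", alt = "G"),
#'               list(start = 0, end = 9), tx)  # synonymous (CGA -> CGG)
#' @export
effect_on_orf <- function(snv, orf, tx, code = genetic_code()) {
  obs <- substring(tx$sequence, snv$tpos + 1L, snv$tpos + 1L)
  if (obs != snv$ref) {
    stop("reference mismatch at position ", snv$tpos, ": expected '",
         snv$ref, "', transcript has '", obs, "'", call. = FALSE)
  }
  variant_effects(tx$sequence, as.integer(orf$start), as.integer(orf$end),
                  snv$tpos, snv$alt, code)
}

#' Dual-frame annotation of one SNV
#'
#' Computes the SNV's consequence in the canonical frame (when it falls
#' inside the CDS) and in every overlapping alternative ORF, and flags it as
#' silent-but-altering when it is synonymous or stop-retained canonically
#' yet missense/nonsense/stop-loss/start-loss in at least one altORF.
#'
#' @param snv List with `tpos`, `ref`, `alt` (transcript space).
#' @param tx A [transcript()].
#' @param orfs altORF table from [predict_altorfs()].
#' @param code Genetic code.
#' @return List of class `dual_effect`: `snv`, `canonical_effect` (or
#'   `NULL`), `altorf_effects` (data.frame, one row per overlapping altORF),
#'   `silent_but_altering`.
#' @export
annotate_variant <- function(snv, tx, orfs, code = genetic_code()) {
  canonical <- NULL
  if (!is.null(tx$cds) && snv$tpos >= tx$cds[1] && snv$tpos < tx$cds[2]) {
    canonical <- effect_on_orf(snv, list(start = tx$cds[1], end = tx$cds[2]),
                               tx, code)
  }
  hit <- orfs[orfs$category != "canonical" &
                orfs$start <= snv$tpos & snv$tpos < orfs$end, , drop = FALSE]
  alt_eff <- if (nrow(hit)) {
    eff <- do.call(rbind, lapply(seq_len(nrow(hit)), function(i) {
      variant_effects(tx$sequence, hit$start[i], hit$end[i],
                      snv$tpos, snv$alt, code)
    }))
    cbind(orf_id = hit$orf_id, category = hit$category, eff,
          stringsAsFactors = FALSE)
  } else {
    data.frame(orf_id = character(0), category = character(0),
               effect = character(0))
  }
  silent <- !is.null(canonical) && canonical$effect %in% SILENT_EFFECTS &&
    any(alt_eff$effect %in% ALTERING_EFFECTS)
  structure(list(snv = snv, canonical_effect = canonical,
                 altorf_effects = alt_eff, silent_but_altering = silent),
            class = "dual_effect")
}

#' @export
print.dual_effect <- function(x, ...) {
  cat("<dual_effect> pos", x$snv$tpos, x$snv$ref, ">", x$snv$alt, "\n")
  cat("  canonical:",
      if (is.null(x$canonical_effect)) "outside CDS"
      else x$canonical_effect$effect, "\n")
  if (nrow(x$altorf_effects)) {
    for (i in seq_len(nrow(x$altorf_effects))) {
      cat("  ", x$altorf_effects$orf_id[i], ": ",
          x$altorf_effects$effect[i], "\n", sep = "")
    }
  }
  cat("  silent_but_altering:", x$silent_but_altering, "\n")
  invisible(x)
}

#' Scan a variant set for silent-but-altering SNVs
#'
#' Annotates every SNV in the canonical frame and in all overlapping
#' alternative ORFs of its transcript. Variants on unknown transcripts are
#' skipped with a warning and counted. Variant multiplicity across samples
#' is carried in `occurrence_count`; set `unique = TRUE` to collapse
#' duplicates to one occurrence each.
#'
#' @param variants data.frame with columns `transcript_id`, `tpos`, `ref`,
#'   `alt` and optionally `occurrence_count` (default 1).
#' @param transcriptome Named list of [transcript()] objects.
#' @param params [orf_params()] used for altORF prediction.
#' @param unique Collapse occurrence multiplicity.
#' @param code Genetic code.
#' @param orfs_by_tx Optional pre-computed list of altORF tables keyed by
#'   transcript id (skips re-prediction).
#' @return Object of class `silent_scan`: a data.frame with one row per
#'   variant (ordered by transcript, position, alt) carrying
#'   `canonical_effect`, `positional_hit`, `altering_hit`,
#'   `silent_but_altering`, `top_alt_effect` and `n_altorfs_hit`; the long
#'   per-(variant, ORF) effect table is in `attr(, "effects")` and summary
#'   counters in `attr(, "counters")`.
#' @export
scan_silent_altering <- function(variants, transcriptome,
                                 params = orf_params(), unique = FALSE,
                                 code = genetic_code(), orfs_by_tx = NULL) {
  stopifnot(all(c("transcript_id", "tpos", "ref", "alt") %in%
                  names(variants)))
  if (is.null(variants$occurrence_count)) variants$occurrence_count <- 1L
  if (unique) variants$occurrence_count <- 1L
  transcriptome <- as_transcriptome(transcriptome)
  known <- variants$transcript_id %in% names(transcriptome)
  n_skipped <- sum(variants$occurrence_count[!known])
  if (n_skipped > 0) {
    warning(n_skipped, " variant occurrence(s) on unknown transcripts skipped",
            call. = FALSE)
  }
  variants <- variants[known, , drop = FALSE]

  rec_list <- list()
  eff_list <- list()
  for (tid in unique(variants$transcript_id)) {
    tx <- transcriptome[[tid]]
    v <- variants[variants$transcript_id == tid, , drop = FALSE]
    obs <- substring(tx$sequence, v$tpos + 1L, v$tpos + 1L)
    if (any(obs != v$ref)) {
      bad <- which(obs != v$ref)[1]
      stop("reference mismatch on '", tid, "' at position ", v$tpos[bad],
           ": expected '", v$ref[bad], "', transcript has '", obs[bad], "'",
           call. = FALSE)
    }
    orfs <- if (!is.null(orfs_by_tx)) orfs_by_tx[[tid]]
            else predict_altorfs(tx, params, code)
    canon <- rep(NA_character_, nrow(v))
    if (!is.null(tx$cds)) {
      inside <- v$tpos >= tx$cds[1] & v$tpos < tx$cds[2]
      if (any(inside)) {
        canon[inside] <- variant_effects(tx$sequence, tx$cds[1], tx$cds[2],
                                         v$tpos[inside], v$alt[inside],
                                         code)$effect
      }
    }
    positional <- logical(nrow(v))
    top <- rep(NA_character_, nrow(v))
    n_hit <- integer(nrow(v))
    altering <- logical(nrow(v))
    if (!is.null(orfs) && nrow(orfs)) {
      for (i in seq_len(nrow(orfs))) {
        sel <- v$tpos >= orfs$start[i] & v$tpos < orfs$end[i]
        if (!any(sel)) next
        eff <- variant_effects(tx$sequence, orfs$start[i], orfs$end[i],
                               v$tpos[sel], v$alt[sel], code)
        eff_list[[length(eff_list) + 1L]] <- data.frame(
          transcript_id = tid, tpos = v$tpos[sel], ref = v$ref[sel],
          alt = v$alt[sel], orf_id = orfs$orf_id[i],
          category = orfs$category[i], effect = eff$effect,
          codon_index = eff$codon_index, codon_pos = eff$codon_pos,
          ref_aa = eff$ref_aa, alt_aa = eff$alt_aa, stringsAsFactors = FALSE
        )
        positional[sel] <- TRUE
        n_hit[sel] <- n_hit[sel] + 1L
        altering[sel] <- altering[sel] | eff$effect %in% ALTERING_EFFECTS
        rank_new <- match(eff$effect, SEVERITY_ORDER)
        rank_old <- match(top[sel], SEVERITY_ORDER)
        repl <- is.na(rank_old) | rank_new < rank_old
        top[sel][repl] <- eff$effect[repl]
      }
    }
    rec_list[[length(rec_list) + 1L]] <- data.frame(
      transcript_id = tid, gene_id = tx$gene_id, tpos = v$tpos, ref = v$ref,
      alt = v$alt, occurrence_count = v$occurrence_count,
      canonical_effect = canon, positional_hit = positional,
      altering_hit = altering,
      silent_but_altering = !is.na(canon) & canon %in% SILENT_EFFECTS &
        altering,
      top_alt_effect = top, n_altorfs_hit = n_hit, stringsAsFactors = FALSE
    )
  }
  records <- if (length(rec_list)) do.call(rbind, rec_list) else
    data.frame(transcript_id = character(0), gene_id = character(0),
               tpos = integer(0), ref = character(0), alt = character(0),
               occurrence_count = integer(0),
               canonical_effect = character(0), positional_hit = logical(0),
               altering_hit = logical(0), silent_but_altering = logical(0),
               top_alt_effect = character(0), n_altorfs_hit = integer(0),
               stringsAsFactors = FALSE)
  records <- order_variants(records)
  rownames(records) <- NULL
  effects <- if (length(eff_list)) do.call(rbind, eff_list) else NULL
  syn <- records$canonical_effect %in% SILENT_EFFECTS
  attr(records, "effects") <- effects
  attr(records, "counters") <- c(
    n_input = sum(records$occurrence_count) + n_skipped,
    n_skipped = n_skipped,
    n_records = sum(records$occurrence_count),
    n_synonymous = sum(records$occurrence_count[syn]),
    n_positional_syn = sum(records$occurrence_count[syn &
                                                      records$positional_hit]),
    n_altering_syn = sum(records$occurrence_count[records$silent_but_altering])
  )
  class(records) <- c("silent_scan", class(records))
  records
}

#' @export
print.silent_scan <- function(x, ...) {
  ctr <- attr(x, "counters")
  cat("<silent_scan>", nrow(x), "distinct SNVs,", ctr[["n_records"]],
      "occurrences (", ctr[["n_skipped"]], "skipped )\n")
  cat("  canonical-synonymous occurrences:", ctr[["n_synonymous"]], "\n")
  cat("  ... within an altORF footprint: ", ctr[["n_positional_syn"]], "\n")
  cat("  ... altering an altProt:        ", ctr[["n_altering_syn"]], "\n")
  invisible(x)
}

#' Coerce a list of transcripts into a named list keyed by id
#' @noRd
as_transcriptome <- function(transcriptome) {
  if (inherits(transcriptome, "transcript")) {
    transcriptome <- list(transcriptome)
  }
  ids <- vapply(transcriptome, function(t) t$id, character(1))
  names(transcriptome) <- ids
  transcriptome
}
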