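#' Canonical-synonymous substitution space of a transcript
#'
#' Enumerates every `(tpos, alt)` substitution within the CDS that is
#' synonymous or stop-retained in the canonical frame. This is the sample
#' space of the permutation null: under "chance", a canonical-synonymous SNV
#' is equally likely at any of these pairs. Each pair carries two flags:
#' `positional` (it falls inside some altORF footprint, stop codon included)
#' and `altering` (its consequence in at least one altORF is
#' missense/nonsense/stop-loss/start-loss).
#'
#' @param tx A [transcript()] with a CDS.
#' @param orfs altORF table from [predict_altorfs()].
#' @param code Genetic code.
#' @return data.frame (`tpos`, `ref`, `alt`, `positional`, `altering`) with
#'   attributes `transcript_id` and `coverage` (mean of `positional`).
#' @export
synonymous_space <- function(tx, orfs, code = genetic_code()) {
  if (is.null(tx$cds)) {
    stop("transcript '", tx$id, "' has no CDS (lncRNA): no synonymous space",
         call. = FALSE)
  }
  tpos <- tx$cds[1]:(tx$cds[2] - 1L)
  ref <- substring(tx$sequence, tpos + 1L, tpos + 1L)
  grid <- expand.grid(i = seq_along(tpos), alt = DNA_BASES,
                      stringsAsFactors = FALSE)
  grid <- grid[ref[grid$i] != grid$alt, , drop = FALSE]
  pos <- tpos[grid$i]
  eff <- variant_effects(tx$sequence, tx$cds[1], tx$cds[2], pos, grid$alt,
                         code)
  keep <- eff$effect %in% SILENT_EFFECTS
  space <- data.frame(tpos = pos[keep], ref = ref[grid$i][keep],
                      alt = grid$alt[keep], stringsAsFactors = FALSE)
  space <- space[order(space$tpos, space$alt), , drop = FALSE]
  rownames(space) <- NULL
  space$positional <- FALSE
  space$altering <- FALSE
  alt_orfs <- orfs[orfs$category != "canonical", , drop = FALSE]
  for (i in seq_len(nrow(alt_orfs))) {
    sel <- space$tpos >= alt_orfs$start[i] & space$tpos < alt_orfs$end[i]
    if (!any(sel)) next
    space$positional[sel] <- TRUE
    oe <- variant_effects(tx$sequence, alt_orfs$start[i], alt_orfs$end[i],
                          space$tpos[sel], space$alt[sel], code)
    space$altering[sel] <- space$altering[sel] |
      oe$effect %in% ALTERING_EFFECTS
  }
  attr(space, "transcript_id") <- tx$id
  attr(space, "coverage") <- if (nrow(space)) mean(space$positional) else NA_real_
  space
}

#' Permutation test for altORF enrichment among synonymous SNVs
#'
#' Quantifies "higher than expected by chance": the observed
#' occurrence-weighted fraction of canonical-synonymous SNVs whose position
#' falls inside an alternative-ORF footprint (`frac_positional`; the
#' headline "fell within a predicted alternative protein" quantity) and the
#' fraction altering at least one altProt (`frac_altering`), compared with a
#' permutation null that redraws, per transcript, the same number of
#' occurrences uniformly with replacement from that transcript's
#' canonical-synonymous substitution space. The null therefore conditions on
#' gene composition and per-gene mutation counts, isolating positional
#' enrichment. Empirical p-values are +1-corrected:
#' `p = (1 + #\{permuted >= observed\}) / (n_perm + 1)`.
#'
#' @param scan A `silent_scan` from [scan_silent_altering()] (only
#'   canonical-synonymous records are used), or a compatible data.frame.
#' @param transcriptome Named list of [transcript()] objects.
#' @param orfs_by_tx Optional list of altORF tables keyed by transcript id;
#'   computed with `params` when missing.
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed; identical seeds give identical results.
#' @param params [orf_params()] used when `orfs_by_tx` is missing.
#' @param spaces Optional pre-computed [synonymous_space()] tables keyed by
#'   transcript id.
#' @param code Genetic code.
#' @return Object of class `enrichment_result`; see Details. Includes the
#'   per-gene Table-1-style summary in `$per_gene` and the vector of
#'   permuted positional fractions in `$perm_fractions`.
#' @export
enrichment_test <- function(scan, transcriptome, orfs_by_tx = NULL,
                            n_perm = 1000L, seed = 1L,
                            params = orf_params(), spaces = NULL,
                            code = genetic_code()) {
  stopifnot(n_perm >= 1L)
  transcriptome <- as_transcriptome(transcriptome)
  records <- as.data.frame(scan)
  records <- records[!is.na(records$canonical_effect) &
                       records$canonical_effect %in% SILENT_EFFECTS, ,
                     drop = FALSE]
  if (!nrow(records)) {
    stop("no canonical-synonymous variant records to test", call. = FALSE)
  }
  if (is.null(records$occurrence_count)) records$occurrence_count <- 1L

  tids <- unique(records$transcript_id)
  if (is.null(orfs_by_tx)) {
    orfs_by_tx <- lapply(transcriptome[tids], predict_altorfs, params = params,
                         code = code)
  }
  if (is.null(spaces)) {
    spaces <- lapply(tids, function(tid) {
      synonymous_space(transcriptome[[tid]], orfs_by_tx[[tid]], code)
    })
    names(spaces) <- tids
  }
  empty <- vapply(spaces[tids], nrow, integer(1)) == 0L
  if (any(empty)) {
    warning("excluding transcript(s) with empty synonymous space: ",
            paste(tids[empty], collapse = ", "), call. = FALSE)
    records <- records[!records$transcript_id %in% tids[empty], , drop = FALSE]
    tids <- tids[!empty]
    if (!nrow(records)) stop("no records left after exclusions", call. = FALSE)
  }

  m_t <- vapply(tids, function(tid) {
    sum(records$occurrence_count[records$transcript_id == tid])
  }, numeric(1))
  M <- sum(m_t)
  n_positional <- sum(records$occurrence_count[records$positional_hit])
  n_altering <- sum(records$occurrence_count[records$silent_but_altering])
  frac_positional <- n_positional / M
  frac_altering <- n_altering / M
  coverage <- vapply(spaces[tids], attr, numeric(1), which = "coverage")
  expected_frac <- sum(m_t * coverage) / M

  perm <- run_seeded(seed, {
    pos_tot <- numeric(n_perm)
    alt_tot <- numeric(n_perm)
    for (tid in tids) {
      sp <- spaces[[tid]]
      m <- m_t[[tid]]
      idx <- sample.int(nrow(sp), m * n_perm, replace = TRUE)
      pos_tot <- pos_tot + colSums(matrix(sp$positional[idx], nrow = m))
      alt_tot <- alt_tot + colSums(matrix(sp$altering[idx], nrow = m))
    }
    list(pos = pos_tot / M, alt = alt_tot / M)
  })
  eps <- 1e-12
  p_perm <- (1 + sum(perm$pos >= frac_positional - eps)) / (n_perm + 1)
  p_altering <- (1 + sum(perm$alt >= frac_altering - eps)) / (n_perm + 1)

  structure(
    list(n_variants = M, n_positional = n_positional,
         n_altering = n_altering, frac_positional = frac_positional,
         frac_altering = frac_altering, expected_frac = expected_frac,
         p_perm = p_perm, p_altering = p_altering,
         n_perm = as.integer(n_perm), seed = as.integer(seed),
         perm_fractions = perm$pos, perm_fractions_altering = perm$alt,
         per_gene = summarize_genes(scan, transcriptome, orfs_by_tx)),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Permutation test for altORF enrichment among synonymous SNVs\n\n")
  cat(sprintf("  %d canonical-synonymous SNV occurrences\n", x$n_variants))
  cat(sprintf("  within an altORF footprint : %d (%.1f%%)\n",
              x$n_positional, 100 * x$frac_positional))
  cat(sprintf("  altering an altProt        : %d (%.1f%%)\n",
              x$n_altering, 100 * x$frac_altering))
  cat(sprintf("  expected by chance         : %.1f%%\n",
              100 * x$expected_frac))
  cat(sprintf("  permutation p (positional) : %.4g  [n_perm = %d, seed = %d]\n",
              x$p_perm, x$n_perm, x$seed))
  cat(sprintf("  permutation p (altering)   : %.4g\n", x$p_altering))
  invisible(x)
}

#' @export
summary.enrichment_result <- function(object, ...) {
  print(object)
  cat("\nPer-gene summary:\n")
  print(object$per_gene, row.names = FALSE)
  invisible(object)
}

#' Table-1-style per-gene summary
#'
#' For each gene: the number of canonical-synonymous SNV occurrences, how
#' many fall inside an altORF footprint and how many alter at least one
#' altProt (counts and percentages), a gene-level flag (at least one
#' altering SNV), the median length of the distinct altered altProts, and a
#' breakdown of altered altORFs by class. A pooled `ALL` footer row
#' reproduces the headline metrics.
#'
#' @param scan A `silent_scan` from [scan_silent_altering()].
#' @param transcriptome Named list of transcripts.
#' @param orfs_by_tx List of altORF tables keyed by transcript id (for
#'   altProt lengths and classes).
#' @return data.frame, one row per gene plus the pooled `ALL` row.
#' @export
summarize_genes <- function(scan, transcriptome, orfs_by_tx) {
  transcriptome <- as_transcriptome(transcriptome)
  records <- as.data.frame(scan)
  records <- records[!is.na(records$canonical_effect) &
                       records$canonical_effect %in% SILENT_EFFECTS, ,
                     drop = FALSE]
  effects <- attr(scan, "effects")
  all_orfs <- do.call(rbind, orfs_by_tx)

  gene_row <- function(recs, gene) {
    n_syn <- sum(recs$occurrence_count)
    n_pos <- sum(recs$occurrence_count[recs$positional_hit])
    n_alt <- sum(recs$occurrence_count[recs$silent_but_altering])
    altered_ids <- character(0)
    if (!is.null(effects) && nrow(recs)) {
      key <- paste(recs$transcript_id, recs$tpos, recs$alt)
      sel <- effects$effect %in% ALTERING_EFFECTS &
        paste(effects$transcript_id, effects$tpos, effects$alt) %in%
          key[recs$silent_but_altering]
      altered_ids <- unique(effects$orf_id[sel])
    }
    lens <- all_orfs$length_aa[match(altered_ids, all_orfs$orf_id)]
    cats <- all_orfs$category[match(altered_ids, all_orfs$orf_id)]
    data.frame(
      gene = gene, n_syn_snvs = n_syn, n_positional = n_pos,
      pct_positional = if (n_syn) round(100 * n_pos / n_syn, 1) else NA_real_,
      n_altering = n_alt,
      pct_altering = if (n_syn) round(100 * n_alt / n_syn, 1) else NA_real_,
      gene_flag = n_alt >= 1,
      median_altprot_len_aa = if (length(lens)) stats::median(lens) else NA_real_,
      n_uORF = sum(cats == "uORF"), n_dORF = sum(cats == "dORF"),
      n_overlap = sum(cats %in% c("overlap_nested", "overlap_partial")),
      n_lncRNA_orf = sum(cats == "lncRNA_orf"),
      stringsAsFactors = FALSE
    )
  }

  genes <- unique(records$gene_id)
  rows <- lapply(genes, function(g) {
    gene_row(records[records$gene_id == g, , drop = FALSE], g)
  })
  out <- do.call(rbind, c(rows, list(gene_row(records, "ALL"))))
  rownames(out) <- NULL
  out
}
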