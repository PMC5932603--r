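#' Simulation configuration
#'
#' Describes a synthetic study: transcripts carrying a canonical CDS plus
#' planted alternative ORFs of requested classes, synonymous SNV sets drawn
#' from the canonical-synonymous substitution space (optionally enriched
#' inside altORF footprints), and per-base conservation tracks with
#' codon-position-3 depression in the frames that carry ORFs. Planted
#' altProt lengths follow a log-normal distribution with median 45 aa
#' (the reported median length of predicted alternative proteins),
#' truncated to `altprot_len_range`. The same configuration always produces
#' byte-identical output.
#'
#' @param seed Integer RNG seed.
#' @param n_transcripts Number of transcripts.
#' @param length_range Transcript length range in nt (uniform).
#' @param gc GC content of background sequence.
#' @param cds_fraction Fraction of the transcript occupied by the CDS.
#' @param n_uorf,n_dorf,n_nested,n_partial Planted altORFs per coding
#'   transcript, by class.
#' @param lncrna_fraction Fraction of transcripts emitted as lncRNAs
#'   (no CDS).
#' @param n_lncrna_orf Planted ORFs per lncRNA transcript.
#' @param altprot_len_median Target median altProt length (aa).
#' @param altprot_len_sdlog Log-scale sd of the length distribution.
#' @param altprot_len_range Truncation bounds (aa).
#' @param n_variants Synonymous SNV occurrences per coding transcript.
#' @param enrichment_factor Sampling weight of altORF-overlapping pairs
#'   relative to the rest of the synonymous space; 1 is the exact null,
#'   0 avoids altORFs, `Inf` samples only inside them.
#' @param track_depth Conservation elevation of codon positions 1-2 over
#'   position 3 within each ORF footprint.
#' @param track_noise_sd Gaussian noise sd of the track baseline.
#' @param min_aa Minimum ORF length used when policing incidental ORFs.
#' @param two_exon Give every gene a two-exon structure (exercises splice
#'   projection); single-exon otherwise.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_transcripts = 25L,
                       length_range = c(900L, 1800L), gc = 0.5,
                       cds_fraction = 0.5, n_uorf = 1L, n_dorf = 1L,
                       n_nested = 1L, n_partial = 0L,
                       lncrna_fraction = 0, n_lncrna_orf = 1L,
                       altprot_len_median = 45, altprot_len_sdlog = 0.25,
                       altprot_len_range = c(30L, 300L),
                       n_variants = 40L, enrichment_factor = 1,
                       track_depth = 1, track_noise_sd = 0.5,
                       min_aa = 30L, two_exon = TRUE) {
  cfg <- structure(
    list(seed = as.integer(seed), n_transcripts = as.integer(n_transcripts),
         length_range = as.integer(length_range), gc = gc,
         cds_fraction = cds_fraction, n_uorf = as.integer(n_uorf),
         n_dorf = as.integer(n_dorf), n_nested = as.integer(n_nested),
         n_partial = as.integer(n_partial),
         lncrna_fraction = lncrna_fraction,
         n_lncrna_orf = as.integer(n_lncrna_orf),
         altprot_len_median = altprot_len_median,
         altprot_len_sdlog = altprot_len_sdlog,
         altprot_len_range = as.integer(altprot_len_range),
         n_variants = as.integer(n_variants),
         enrichment_factor = enrichment_factor,
         track_depth = track_depth, track_noise_sd = track_noise_sd,
         min_aa = as.integer(min_aa), two_exon = isTRUE(two_exon)),
    class = "sim_config"
  )
  with(cfg, {
    stopifnot(n_transcripts >= 1L, length_range[1] >= 300L,
              length_range[2] >= length_range[1], gc > 0, gc < 1,
              cds_fraction > 0.2, cds_fraction < 0.9,
              enrichment_factor >= 0, track_depth >= 0, track_noise_sd >= 0,
              lncrna_fraction >= 0, lncrna_fraction <= 1,
              min_aa >= 1L, altprot_len_range[1] >= 2L)
  })
  # feasibility before any sampling: smallest plantable ORF must fit the
  # smallest region it can be asked into
  min_len <- cfg$length_range[1]
  min_fp <- 3L * cfg$altprot_len_range[1] + 3L
  utr_min <- floor(min_len * (1 - cfg$cds_fraction) / 2)
  cds_min <- 3L * (min_len * cfg$cds_fraction) %/% 3L
  if ((cfg$n_uorf > 0 || cfg$n_partial > 0) && utr_min < cfg$n_uorf * min_fp +
        cfg$n_partial * 9L) {
    stop("infeasible config: 5' UTR (", utr_min,
         " nt) too short for the requested upstream ORFs", call. = FALSE)
  }
  if (cfg$n_dorf > 0 && utr_min < cfg$n_dorf * min_fp) {
    stop("infeasible config: 3' UTR too short for the requested dORFs",
         call. = FALSE)
  }
  if ((cfg$n_nested + cfg$n_partial) > 0 &&
        cds_min < (cfg$n_nested + cfg$n_partial) * (min_fp + 12L)) {
    stop("infeasible config: CDS too short for the requested overlapping ORFs",
         call. = FALSE)
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, ":", x$n_transcripts, "transcripts of",
      x$length_range[1], "-", x$length_range[2], "nt\n")
  cat("  planted per coding transcript: ", x$n_uorf, " uORF, ", x$n_dorf,
      " dORF, ", x$n_nested, " nested, ", x$n_partial, " partial\n", sep = "")
  cat("  ", x$n_variants, " synonymous SNVs (enrichment factor ",
      x$enrichment_factor, "), track depth ", x$track_depth, " sd ",
      x$track_noise_sd, "\n", sep = "")
  invisible(x)
}

SENSE_CODONS <- NULL  # filled lazily

#' @noRd
sense_codons <- function(code = genetic_code()) {
  names(code$codon_to_aa)[code$codon_to_aa != "*"]
}

#' Codon sampling weights matching a background GC content (product of
#' per-base probabilities), so coding regions do not distort the target GC
#' @noRd
codon_gc_weights <- function(codons, gc) {
  pb <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(strsplit(codons, "", fixed = TRUE), function(tri) {
    prod(pb[tri])
  }, numeric(1))
}

#' Truncated log-normal altProt length draw (inverse CDF)
#' @noRd
draw_altprot_len <- function(cfg, cap = Inf, n = 1L) {
  lo <- cfg$altprot_len_range[1]
  hi <- min(cfg$altprot_len_range[2], cap)
  if (hi < lo) return(rep(NA_integer_, n))
  ml <- log(cfg$altprot_len_median)
  plo <- stats::plnorm(lo - 0.5, ml, cfg$altprot_len_sdlog)
  phi <- stats::plnorm(hi + 0.5, ml, cfg$altprot_len_sdlog)
  u <- stats::runif(n, plo, phi)
  pmin(pmax(as.integer(round(stats::qlnorm(u, ml, cfg$altprot_len_sdlog))),
            lo), hi)
}

# ---- constructive planting -------------------------------------------------

#' Positions whose bases are frozen (start/stop codons of canonical and
#' planted ORFs); edits there are never allowed.
#' @noRd
locked_positions <- function(cds, planted) {
  lock <- integer(0)
  if (!is.null(cds)) lock <- c(cds[1]:(cds[1] + 2L), (cds[2] - 3L):(cds[2] - 1L))
  for (p in planted) {
    lock <- c(lock, p$start:(p$start + 2L), (p$end - 3L):(p$end - 1L))
  }
  lock
}

#' Would writing `base` at 0-based `pos` keep every registered reading frame
#' (canonical + planted ORFs) free of new in-frame stops?
#' @noRd
edit_ok <- function(seqv, pos, base, cds, planted, stops) {
  frames <- planted
  if (!is.null(cds)) frames <- c(frames, list(list(start = cds[1],
                                                   end = cds[2])))
  for (o in frames) {
    if (pos < o$start || pos >= o$end) next
    cs <- o$start + 3L * ((pos - o$start) %/% 3L)
    tri <- seqv[(cs + 1L):(cs + 3L)]
    tri[pos - cs + 1L] <- base
    if (paste(tri, collapse = "") %in% stops) return(FALSE)
  }
  TRUE
}

#' Write an ORF (ATG + sense body + stop) into seqv at 0-based `s`,
#' protein length `aa`. Positions in `forced` (named by position, value =
#' base) must keep their base; codons overlapping the canonical frame must
#' not create canonical stops. Returns the updated vector or NULL.
#' @noRd
write_orf_into <- function(seqv, s, aa, cds, stops, sense, forced = NULL,
                           sense_w = NULL) {
  n_codons <- aa + 1L
  for (k in seq_len(n_codons)) {
    cpos <- s + 3L * (k - 1L)
    cand <- if (k == 1L) "ATG" else if (k == n_codons) sample(stops)
            else sample(sense, prob = sense_w)
    # honour forced bases (canonical start/stop codons under the footprint)
    if (!is.null(forced)) {
      fidx <- match(as.character(cpos + 0:2), names(forced))
      if (any(!is.na(fidx))) {
        keep <- vapply(cand, function(tri_s) {
          tri <- strsplit(tri_s, "", fixed = TRUE)[[1]]
          all(tri[!is.na(fidx)] == forced[fidx[!is.na(fidx)]])
        }, logical(1))
        cand <- cand[keep]
      }
    }
    ok <- FALSE
    for (tri_s in cand) {
      tri <- strsplit(tri_s, "", fixed = TRUE)[[1]]
      tmp <- seqv
      tmp[(cpos + 1L):(cpos + 3L)] <- tri
      # canonical frame must stay sense wherever this codon overlaps the CDS
      bad <- FALSE
      if (!is.null(cds)) {
        for (p in cpos:(cpos + 2L)) {
          if (p >= cds[1] && p < cds[2]) {
            cc <- cds[1] + 3L * ((p - cds[1]) %/% 3L)
            if (paste(tmp[(cc + 1L):(cc + 3L)], collapse = "") %in% stops) {
              bad <- TRUE
              break
            }
          }
        }
      }
      if (!bad) {
        seqv <- tmp
        ok <- TRUE
        break
      }
    }
    if (!ok) return(NULL)
  }
  seqv
}

#' Destroy an incidental ORF by mutating its start codon or inserting an
#' early in-frame stop, without breaking canonical or planted ORFs.
#' @noRd
destroy_orf <- function(seqv, orf, cds, planted, stops, min_aa) {
  lock <- locked_positions(cds, planted)
  # (a) break the ATG
  for (p in orf$start + 0:2) {
    if (p %in% lock) next
    for (b in setdiff(DNA_BASES, seqv[p + 1L])) {
      if (edit_ok(seqv, p, b, cds, planted, stops)) {
        seqv[p + 1L] <- b
        return(seqv)
      }
    }
  }
  # (b) insert an early stop in the ORF's own frame
  ncod <- (orf$end - orf$start) %/% 3L
  for (k in seq_len(min(min_aa - 1L, ncod - 1L))) {
    cs <- orf$start + 3L * k
    tri <- seqv[(cs + 1L):(cs + 3L)]
    for (j in 1:3) {
      p <- cs + j - 1L
      if (p %in% lock) next
      for (b in setdiff(DNA_BASES, tri[j])) {
        tri2 <- tri
        tri2[j] <- b
        if (!(paste(tri2, collapse = "") %in% stops)) next
        if (edit_ok(seqv, p, b, cds, planted, stops)) {
          seqv[p + 1L] <- b
          return(seqv)
        }
      }
    }
  }
  NULL
}

#' Simulate one transcript with planted altORFs; returns transcript, truth
#' rows and the genomic scaffolding. Uses the current RNG stream.
#' @noRd
simulate_one_transcript <- function(tid, gid, cfg, code = genetic_code()) {
  stops <- stop_codons(code)
  sense <- sense_codons(code)
  sw <- codon_gc_weights(sense, cfg$gc)
  params <- orf_params(min_aa = cfg$min_aa)
  is_lnc <- stats::runif(1) < cfg$lncrna_fraction

  for (attempt in 1:25) {
    L <- sample_one(cfg$length_range[1]:cfg$length_range[2])
    seqv <- sample(DNA_BASES, L, replace = TRUE,
                   prob = c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2,
                            (1 - cfg$gc) / 2))
    planted <- list()
    cds <- NULL
    ok <- TRUE

    if (!is_lnc) {
      cds_len <- 3L * (as.integer(L * cfg$cds_fraction) %/% 3L)
      u5 <- (L - cds_len) %/% 2L
      cds <- c(u5, u5 + cds_len)
      seqv[(cds[1] + 1L):(cds[1] + 3L)] <- c("A", "T", "G")
      body <- sample(sense, cds_len / 3L - 2L, replace = TRUE, prob = sw)
      seqv[(cds[1] + 4L):(cds[2] - 3L)] <-
        unlist(strsplit(body, "", fixed = TRUE))
      seqv[(cds[2] - 2L):(cds[2])] <-
        strsplit(sample(stops, 1L), "", fixed = TRUE)[[1]]
      forced <- stats::setNames(
        seqv[c(cds[1]:(cds[1] + 2L), (cds[2] - 3L):(cds[2] - 1L)) + 1L],
        as.character(c(cds[1]:(cds[1] + 2L), (cds[2] - 3L):(cds[2] - 1L))))

      occupied <- list()
      place_free <- function(region_lo, region_hi, fp) {
        # random start in [region_lo, region_hi - fp] avoiding occupied
        if (region_hi - fp < region_lo) return(NA_integer_)
        cand <- shuffle(region_lo:(region_hi - fp))
        for (s in cand) {
          clash <- any(vapply(occupied, function(o) {
            s < o[2] && (s + fp) > o[1]
          }, logical(1)))
          if (!clash) return(s)
        }
        NA_integer_
      }

      plant_class <- function(class, n) {
        for (k in seq_len(n)) {
          planted_ok <- FALSE
          for (try in 1:20) {
            if (class == "uORF") {
              cap <- (cds[1] %/% 3L) - 1L
              aa <- draw_altprot_len(cfg, cap)
              if (is.na(aa)) break
              fp <- 3L * aa + 3L
              s <- place_free(0L, cds[1], fp)
              if (is.na(s)) next
              newv <- write_orf_into(seqv, s, aa, NULL, stops, sense,
                                     sense_w = sw)
            } else if (class == "dORF") {
              cap <- ((L - cds[2]) %/% 3L) - 1L
              aa <- draw_altprot_len(cfg, cap)
              if (is.na(aa)) break
              fp <- 3L * aa + 3L
              s <- place_free(cds[2], L, fp)
              if (is.na(s)) next
              newv <- write_orf_into(seqv, s, aa, NULL, stops, sense,
                                     sense_w = sw)
            } else if (class == "overlap_nested") {
              cap <- ((cds[2] - cds[1] - 12L) %/% 3L) - 1L
              aa <- draw_altprot_len(cfg, cap)
              if (is.na(aa)) break
              fp <- 3L * aa + 3L
              offset <- sample(1:2, 1L)
              lo <- cds[1] + 3L + offset        # s == cds_start + offset mod 3
              if (cds[2] - 3L - fp < lo) next
              cand <- shuffle(seq(lo, cds[2] - 3L - fp, by = 3L))
              s <- NA_integer_
              for (sc in cand) {
                clash <- any(vapply(occupied, function(o) {
                  sc < o[2] && (sc + fp) > o[1]
                }, logical(1)))
                if (!clash) { s <- sc; break }
              }
              if (is.na(s)) next
              newv <- write_orf_into(seqv, s, aa, cds, stops, sense, forced,
                                     sense_w = sw)
            } else { # overlap_partial, crossing the 5' CDS boundary
              aa <- draw_altprot_len(cfg, ((cds[2] - 9L) %/% 3L) - 1L)
              if (is.na(aa)) break
              fp <- 3L * aa + 3L
              offset <- sample(1:2, 1L)
              # start in the 5' UTR (s == cds_start + offset mod 3),
              # stop inside the CDS body
              r <- (cds[1] + offset) %% 3L
              cand <- seq(r, cds[1] - 1L, by = 3L)
              cand <- cand[(cand + fp) > cds[1] + 3L &
                             (cand + fp) <= cds[2] - 3L]
              if (!length(cand)) next
              cand <- utils::head(shuffle(cand), 20L)
              s <- NA_integer_
              for (sc in cand) {
                clash <- any(vapply(occupied, function(o) {
                  sc < o[2] && (sc + fp) > o[1]
                }, logical(1)))
                if (!clash) { s <- sc; break }
              }
              if (is.na(s)) next
              newv <- write_orf_into(seqv, s, aa, cds, stops, sense, forced,
                                     sense_w = sw)
            }
            if (is.null(newv)) next
            seqv <<- newv
            fp <- 3L * aa + 3L
            occupied[[length(occupied) + 1L]] <<- c(s, s + fp)
            planted[[length(planted) + 1L]] <<-
              list(start = s, end = s + fp, class = class)
            planted_ok <- TRUE
            break
          }
          if (!planted_ok) return(FALSE)
        }
        TRUE
      }

      ok <- plant_class("uORF", cfg$n_uorf) &&
        plant_class("dORF", cfg$n_dorf) &&
        plant_class("overlap_nested", cfg$n_nested) &&
        plant_class("overlap_partial", cfg$n_partial)
    } else {
      occupied <- list()
      for (k in seq_len(cfg$n_lncrna_orf)) {
        aa <- draw_altprot_len(cfg, (L %/% 3L) - 2L)
        if (is.na(aa)) { ok <- FALSE; break }
        fp <- 3L * aa + 3L
        s <- NA_integer_
        for (try in 1:50) {
          sc <- sample.int(L - fp + 1L, 1L) - 1L
          clash <- any(vapply(occupied, function(o) {
            sc < o[2] && (sc + fp) > o[1]
          }, logical(1)))
          if (!clash) { s <- sc; break }
        }
        if (is.na(s)) { ok <- FALSE; break }
        newv <- write_orf_into(seqv, s, aa, NULL, stops, sense,
                               sense_w = sw)
        if (is.null(newv)) { ok <- FALSE; break }
        seqv <- newv
        occupied[[length(occupied) + 1L]] <- c(s, s + fp)
        planted[[length(planted) + 1L]] <-
          list(start = s, end = s + fp, class = "lncRNA_orf")
      }
    }
    if (!ok) next

    # police incidental ORFs: anything predict_altorfs reports beyond the
    # planted set is edited away (start broken or early stop inserted)
    repaired <- TRUE
    for (iter in 1:40) {
      tx <- transcript(tid, paste(seqv, collapse = ""), gene_id = gid,
                       cds = cds, code = code)
      pred <- predict_altorfs(tx, params, code)
      pkey <- vapply(planted, function(p) paste(p$start, p$end), character(1))
      extra <- pred[!paste(pred$start, pred$end) %in% pkey, , drop = FALSE]
      have_all <- all(pkey %in% paste(pred$start, pred$end))
      if (!nrow(extra) && have_all) break
      if (!nrow(extra) && !have_all) { repaired <- FALSE; break }
      fixed_any <- FALSE
      for (i in seq_len(nrow(extra))) {
        newv <- destroy_orf(seqv, list(start = extra$start[i],
                                       end = extra$end[i]),
                            cds, planted, stops, cfg$min_aa)
        if (!is.null(newv)) {
          seqv <- newv
          fixed_any <- TRUE
        }
      }
      if (!fixed_any) { repaired <- FALSE; break }
      if (iter == 40L) repaired <- FALSE
    }
    if (!repaired) next

    # final verification: planted set recovered with the demanded classes
    tx <- transcript(tid, paste(seqv, collapse = ""), gene_id = gid,
                     cds = cds, code = code)
    pred <- predict_altorfs(tx, params, code)
    key <- paste(pred$start, pred$end)
    match_ok <- TRUE
    for (p in planted) {
      i <- match(paste(p$start, p$end), key)
      if (is.na(i) || pred$category[i] != p$class) { match_ok <- FALSE; break }
    }
    if (!match_ok) next

    # genomic scaffolding: optional two-exon structure on a private contig
    tx <- add_gene_structure(tx, cfg)
    truth <- if (length(planted)) {
      data.frame(
        transcript_id = tid,
        orf_id = sprintf("%s.planted%02d", tid, seq_along(planted)),
        start = vapply(planted, `[[`, integer(1), "start"),
        end = vapply(planted, `[[`, integer(1), "end"),
        category = vapply(planted, `[[`, character(1), "class"),
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(transcript_id = character(0), orf_id = character(0),
                 start = integer(0), end = integer(0),
                 category = character(0), stringsAsFactors = FALSE)
    }
    if (nrow(truth)) {
      truth$frame <- truth$start %% 3L
      truth$frame_offset <- if (is.null(cds)) NA_integer_ else
        (truth$start - cds[1]) %% 3L
      truth$length_aa <- (truth$end - truth$start) %/% 3L - 1L
      truth$protein <- vapply(seq_len(nrow(truth)), function(i) {
        translate_orf(substring(tx$sequence, truth$start[i] + 1L,
                                truth$end[i]), code)$protein
      }, character(1))
    }
    return(list(transcript = tx, truth = truth,
                contig = attr(tx, "contig_seq")))
  }
  stop("failed to simulate transcript '", tid,
       "' after 25 attempts; relax the configuration", call. = FALSE)
}

#' Attach a (possibly spliced) genomic context to a transcript
#' @noRd
add_gene_structure <- function(tx, cfg) {
  L <- nchar(tx$sequence)
  strand <- sample(c("+", "-"), 1L)
  chrom <- paste0("chr_", tx$id)
  flank <- 100L
  if (cfg$two_exon && L >= 300L) {
    sp <- sample(100:(L - 100L), 1L)      # transcript-space split point
    ilen <- sample(50:200, 1L)
    t1 <- substring(tx$sequence, 1L, sp)
    t2 <- substring(tx$sequence, sp + 1L, L)
    intron <- paste(sample(DNA_BASES, ilen, replace = TRUE), collapse = "")
    lflank <- paste(sample(DNA_BASES, flank, replace = TRUE), collapse = "")
    rflank <- paste(sample(DNA_BASES, flank, replace = TRUE), collapse = "")
    if (strand == "+") {
      contig <- paste0(lflank, t1, intron, t2, rflank)
      exons <- rbind(c(flank, flank + sp),
                     c(flank + sp + ilen, flank + sp + ilen + (L - sp)))
    } else {
      contig <- paste0(lflank, revcomp(t2), intron, revcomp(t1), rflank)
      exons <- rbind(c(flank, flank + (L - sp)),
                     c(flank + (L - sp) + ilen, flank + (L - sp) + ilen + sp))
    }
  } else {
    lflank <- paste(sample(DNA_BASES, flank, replace = TRUE), collapse = "")
    rflank <- paste(sample(DNA_BASES, flank, replace = TRUE), collapse = "")
    body <- if (strand == "+") tx$sequence else revcomp(tx$sequence)
    contig <- paste0(lflank, body, rflank)
    exons <- rbind(c(flank, flank + L))
  }
  out <- transcript(tx$id, tx$sequence, gene_id = tx$gene_id, exons = exons,
                    strand = strand, chrom = chrom, cds = tx$cds)
  attr(out, "contig_seq") <- contig
  out
}

#' Draw synonymous SNVs from a transcript's substitution space
#'
#' Samples `n` SNV occurrences with replacement from the
#' canonical-synonymous space of a transcript. Pairs inside altORF
#' footprints receive sampling weight `enrichment_factor`, others weight 1;
#' a factor of 1 is the exact null, 0 avoids altORFs and `Inf` samples only
#' inside them. All emitted SNVs are synonymous (or stop-retained) in the
#' canonical frame by construction.
#'
#' @param tx A coding [transcript()].
#' @param orfs altORF table from [predict_altorfs()].
#' @param n Number of occurrences to draw.
#' @param enrichment_factor Relative weight of altORF-overlapping pairs.
#' @param seed Optional seed (uses the current RNG stream when `NULL`).
#' @param space Optional pre-computed [synonymous_space()].
#' @param code Genetic code.
#' @return SNV data.frame (`transcript_id`, `tpos`, `ref`, `alt`,
#'   `occurrence_count`), duplicates aggregated, deterministically ordered.
#' @export
simulate_variants <- function(tx, orfs, n, enrichment_factor = 1,
                              seed = NULL, space = NULL,
                              code = genetic_code()) {
  if (is.null(space)) space <- synonymous_space(tx, orfs, code)
  if (!nrow(space)) stop("empty synonymous space on '", tx$id, "'",
                         call. = FALSE)
  w <- if (is.infinite(enrichment_factor)) as.numeric(space$positional)
       else ifelse(space$positional, enrichment_factor, 1)
  if (all(w == 0)) stop("all sampling weights are zero", call. = FALSE)
  idx <- run_seeded(seed,
                    sample.int(nrow(space), n, replace = TRUE, prob = w))
  tab <- table(idx)
  i <- as.integer(names(tab))
  out <- data.frame(transcript_id = tx$id, tpos = space$tpos[i],
                    ref = space$ref[i], alt = space$alt[i],
                    occurrence_count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- order_variants(out)
  rownames(out) <- NULL
  out
}

#' Simulate a conservation track with frame-specific periodicity
#'
#' Gaussian baseline noise; within each supplied ORF footprint, codon
#' positions 1 and 2 of that ORF's frame are elevated by `depth` relative to
#' position 3. Overlapping ORFs superpose additively, mimicking the layered
#' purifying-selection signal of dual-coding regions.
#'
#' @param tx A [transcript()].
#' @param orfs ORF table (planted altORFs, typically plus the canonical CDS
#'   row) with `start` and `end` columns.
#' @param depth Elevation of codon positions 1-2 (score units).
#' @param noise_sd Baseline noise sd.
#' @param seed Optional seed (uses the current RNG stream when `NULL`).
#' @return A [conservation_track()] with `attr(, "planted_frames")`.
#' @export
simulate_conservation_track <- function(tx, orfs, depth = 1, noise_sd = 0.5,
                                        seed = NULL) {
  stopifnot(depth >= 0, noise_sd >= 0)
  L <- nchar(tx$sequence)
  x <- run_seeded(seed, stats::rnorm(L, 0, noise_sd))
  for (i in seq_len(NROW(orfs))) {
    s <- orfs$start[i]; e <- orfs$end[i]
    pos <- s:(e - 1L)
    cp <- (pos - s) %% 3L + 1L
    x[pos + 1L] <- x[pos + 1L] + depth * (cp != 3L)
  }
  tr <- conservation_track(tx$id, x, 0L)
  attr(tr, "planted_frames") <-
    sort(unique(as.integer(orfs$start %% 3L)))
  tr
}

#' Simulate a complete study
#'
#' Generates the full synthetic stand-in for an observational study:
#' a transcriptome with planted altORFs, per-transcript synonymous SNV sets
#' and conservation tracks, together with the ground-truth tables needed to
#' verify every downstream call. Fully determined by the configuration.
#'
#' @param cfg A [sim_config()].
#' @param code Genetic code.
#' @return List of class `sim_study` with `transcripts` (named list),
#'   `truth_orfs`, `variants`, `tracks`, `contigs`, `planted_frames`,
#'   `config`.
#' @export
simulate_study <- function(cfg = sim_config(), code = genetic_code()) {
  run_seeded(cfg$seed, {
    txs <- list()
    truth <- list()
    contigs <- character(0)
    variants <- list()
    tracks <- list()
    frames <- list()
    for (i in seq_len(cfg$n_transcripts)) {
      tid <- sprintf("TX%04d", i)
      gid <- sprintf("GENE%04d", i)
      one <- simulate_one_transcript(tid, gid, cfg, code)
      txs[[tid]] <- one$transcript
      truth[[tid]] <- one$truth
      contigs[[one$transcript$chrom]] <- one$contig
      orfs <- predict_altorfs(one$transcript,
                              orf_params(min_aa = cfg$min_aa), code)
      if (!is.null(one$transcript$cds) && cfg$n_variants > 0) {
        variants[[tid]] <- simulate_variants(
          one$transcript, orfs, cfg$n_variants, cfg$enrichment_factor,
          code = code)
      }
      track_orfs <- rbind(
        one$truth[, c("start", "end")],
        if (!is.null(one$transcript$cds))
          data.frame(start = one$transcript$cds[1],
                     end = one$transcript$cds[2])
      )
      tracks[[tid]] <- simulate_conservation_track(
        one$transcript, track_orfs, cfg$track_depth, cfg$track_noise_sd)
      frames[[tid]] <- attr(tracks[[tid]], "planted_frames")
    }
    structure(
      list(transcripts = txs,
           truth_orfs = do.call(rbind, c(truth,
                                         list(make.row.names = FALSE))),
           variants = do.call(rbind, c(variants,
                                       list(make.row.names = FALSE))),
           tracks = tracks, contigs = contigs, planted_frames = frames,
           config = cfg),
      class = "sim_study"
    )
  })
}
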