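#' Run the full analysis pipeline on standard input files
#'
#' Loads a transcriptome (FASTA + GFF3), predicts alternative ORFs, projects
#' VCF SNVs into transcript space and classifies them in every frame, tests
#' the enrichment of canonical-synonymous SNVs inside altORF footprints
#' against the stratified permutation null, and (when a bedGraph track is
#' supplied) scans each region for frame-specific triplet periodicity.
#' Writes TSV/JSON outputs plus a run manifest (seeds, parameters, input
#' checksums); a rerun with the same manifest is byte-identical.
#'
#' @param fasta,gff3 Genome and annotation paths.
#' @param vcf Optional VCF of SNVs.
#' @param bedgraph Optional bedGraph of per-base conservation scores
#'   (transcript-space regions named by transcript id).
#' @param outdir Output directory.
#' @param params [orf_params()].
#' @param n_perm,seed,alpha Enrichment / periodicity settings.
#' @param wavelet [wavelet_params()] for reported denoised tracks.
#' @param unique Collapse variant multiplicity.
#' @return Invisible list with `transcripts`, `orfs`, `scan`, `enrichment`,
#'   `periodicity`, and the output `paths`.
#' @export
run_pipeline <- function(fasta, gff3, vcf = NULL, bedgraph = NULL,
                         outdir = ".", params = orf_params(),
                         n_perm = 1000L, seed = 1L, alpha = 0.05,
                         wavelet = wavelet_params(), unique = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  transcriptome <- load_transcriptome(fasta, gff3)
  orfs_by_tx <- lapply(transcriptome, predict_altorfs, params = params)
  orfs <- do.call(rbind, c(unname(orfs_by_tx), list(make.row.names = FALSE)))

  paths <- c(orfs = file.path(outdir, "altorfs.tsv"))
  write_orf_table(orfs, transcriptome, paths[["orfs"]])

  scan <- NULL
  enr <- NULL
  if (!is.null(vcf)) {
    variants <- read_vcf_snvs(vcf, transcriptome)
    scan <- scan_silent_altering(variants, transcriptome, params,
                                 unique = unique, orfs_by_tx = orfs_by_tx)
    paths[["effects"]] <- file.path(outdir, "variant_effects.tsv")
    paths[["variants"]] <- file.path(outdir, "variant_summary.tsv")
    eff <- attr(scan, "effects")
    utils::write.table(
      eff %||% data.frame(), paths[["effects"]], sep = "\t",
      quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(scan), paths[["variants"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths[["gene_report"]] <- file.path(outdir, "gene_report.json")
    jsonlite::write_json(gene_report(scan, transcriptome, orfs_by_tx),
                         paths[["gene_report"]], auto_unbox = TRUE,
                         digits = NA)
    has_syn <- any(scan$canonical_effect %in% SILENT_EFFECTS, na.rm = TRUE)
    if (has_syn) {
      enr <- enrichment_test(scan, transcriptome, orfs_by_tx,
                             n_perm = n_perm, seed = seed)
      paths[["enrichment"]] <- file.path(outdir, "enrichment.json")
      paths[["per_gene"]] <- file.path(outdir, "per_gene.tsv")
      jsonlite::write_json(
        enr[c("n_variants", "n_positional", "n_altering", "frac_positional",
              "frac_altering", "expected_frac", "p_perm", "p_altering",
              "n_perm", "seed")],
        paths[["enrichment"]], auto_unbox = TRUE, digits = NA)
      utils::write.table(enr$per_gene, paths[["per_gene"]], sep = "\t",
                         quote = FALSE, row.names = FALSE)
    } else {
      message("run_pipeline: no canonical-synonymous variants; ",
              "enrichment test skipped")
    }
  }

  periodicity <- NULL
  if (!is.null(bedgraph)) {
    regions <- intersect(
      unique(utils::read.delim(bedgraph, header = FALSE)[[1]]),
      names(transcriptome))
    periodicity <- lapply(regions, function(rid) {
      tr <- read_bedgraph_track(bedgraph, rid)
      res <- frame_periodicity(tr, n_perm = n_perm, seed = seed,
                               wavelet = wavelet)
      res$detected <- detect_coding_frames(res, alpha = alpha)
      res
    })
    names(periodicity) <- regions
    paths[["periodicity"]] <- file.path(outdir, "periodicity.tsv")
    tab <- do.call(rbind, lapply(periodicity, function(r) {
      data.frame(region = r$region_id, frame = 0:2, delta = r$delta,
                 p = r$p, detected = 0:2 %in% r$detected,
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(tab, paths[["periodicity"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  paths[["manifest"]] <- file.path(outdir, "manifest.json")
  inputs <- c(fasta = fasta, gff3 = gff3, vcf = vcf, bedgraph = bedgraph)
  jsonlite::write_json(
    list(package = "polyorf",
         version = as.character(utils::packageVersion("polyorf")),
         seed = seed, n_perm = n_perm, alpha = alpha,
         params = unclass(params),
         inputs = as.list(tools::md5sum(inputs))),
    paths[["manifest"]], auto_unbox = TRUE, digits = NA)

  invisible(list(transcripts = transcriptome, orfs = orfs, scan = scan,
                 enrichment = enr, periodicity = periodicity, paths = paths))
}

#' altORF table writer with genomic footprints where exons are known
#' @noRd
write_orf_table <- function(orfs, transcriptome, path) {
  if (is.null(orfs) || !nrow(orfs)) {
    writeLines(paste(c("transcript_id", "gene_id", "orf_id", "start", "end",
                       "genomic_start", "genomic_end", "frame_offset",
                       "category", "length_aa", "smorf", "protein"),
                     collapse = "\t"), path)
    return(invisible(path))
  }
  gs <- rep(NA_integer_, nrow(orfs))
  ge <- rep(NA_integer_, nrow(orfs))
  for (i in seq_len(nrow(orfs))) {
    tx <- transcriptome[[orfs$transcript_id[i]]]
    if (is.null(tx$exons)) next
    blocks <- project_to_genomic(coordinate_map_of(tx), orfs$start[i],
                                 orfs$end[i])
    gs[i] <- min(blocks$gstart)
    ge[i] <- max(blocks$gend)
  }
  out <- cbind(orfs[, c("transcript_id", "gene_id", "orf_id", "start",
                        "end")],
               genomic_start = gs, genomic_end = ge,
               orfs[, c("frame_offset", "category", "length_aa", "smorf",
                        "protein")])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-gene report: transcript geometry, altORF intervals and relative SNV
#' positions, for plotting gene diagrams.
#' @noRd
gene_report <- function(scan, transcriptome, orfs_by_tx) {
  records <- as.data.frame(scan)
  lapply(transcriptome, function(tx) {
    orfs <- orfs_by_tx[[tx$id]]
    v <- records[records$transcript_id == tx$id, , drop = FALSE]
    list(
      transcript_id = tx$id, gene_id = tx$gene_id,
      length = nchar(tx$sequence),
      cds = if (is.null(tx$cds)) NULL else as.list(tx$cds),
      altorfs = if (NROW(orfs)) {
        lapply(seq_len(nrow(orfs)), function(i) {
          list(orf_id = orfs$orf_id[i], start = orfs$start[i],
               end = orfs$end[i], category = orfs$category[i])
        })
      } else list(),
      snvs = if (nrow(v)) {
        lapply(seq_len(nrow(v)), function(i) {
          list(tpos = v$tpos[i], rel_pos = v$tpos[i] / nchar(tx$sequence),
               alt = v$alt[i], silent_but_altering = v$silent_but_altering[i])
        })
      } else list()
    )
  })
}
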