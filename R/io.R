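# Readers and writers for the standard formats. GFF3 (1-based inclusive)
# and VCF (1-based) coordinates are converted to the internal 0-based
# half-open transcript convention at this boundary; BED/bedGraph outputs are
# 0-based half-open per those standards.

#' Load a transcriptome from genome FASTA + GFF3
#'
#' Splices exon features into mature sense-strand transcripts
#' (minus-strand genes are reverse-complemented at load) and projects CDS
#' features into transcript space. Transcript invariants (CDS frame, ATG
#' start, terminal stop) are enforced per record: violators are rejected
#' with a diagnostic and the run continues; the rejection summary is in
#' `attr(, "rejected")`.
#'
#' @param fasta Path to the genome FASTA.
#' @param gff3 Path to the GFF3 annotation (exon and CDS features keyed to
#'   transcript ids via `Parent`).
#' @param code Genetic code.
#' @return Named list of [transcript()] objects.
#' @export
load_transcriptome <- function(fasta, gff3, code = genetic_code()) {
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gff <- rtracklayer::import(gff3)
  feat_type <- as.character(gff$type)
  parent <- vapply(as.list(gff$Parent), function(p) {
    if (length(p)) sub("^transcript:", "", p[[1]]) else NA_character_
  }, character(1))
  ids <- sub("^transcript:", "", gff$ID %||% rep(NA_character_, length(gff)))

  tx_rows <- which(feat_type %in% c("mRNA", "lnc_RNA", "transcript"))
  out <- list()
  rejected <- list()
  for (i in tx_rows) {
    tid <- ids[i]
    gene <- parent[i]
    if (is.na(gene)) gene <- tid
    gene <- sub("^gene:", "", gene)
    ex <- which(feat_type == "exon" & parent == tid)
    cd <- which(feat_type == "CDS" & parent == tid)
    reject <- function(reason) {
      rejected[[length(rejected) + 1L]] <<-
        data.frame(transcript_id = tid, reason = reason,
                   stringsAsFactors = FALSE)
    }
    if (!length(ex)) {
      reject("no exon features")
      next
    }
    chrom <- as.character(GenomicRanges::seqnames(gff[ex[1]]))
    strand <- as.character(GenomicRanges::strand(gff[ex[1]]))
    if (!strand %in% c("+", "-")) {
      reject("missing strand")
      next
    }
    exm <- cbind(GenomicRanges::start(gff[ex]) - 1L,
                 GenomicRanges::end(gff[ex]))
    exm <- exm[order(exm[, 1]), , drop = FALSE]
    if (!chrom %in% names(genome)) {
      reject(paste0("contig '", chrom, "' absent from FASTA"))
      next
    }
    pieces <- vapply(seq_len(nrow(exm)), function(k) {
      as.character(Biostrings::subseq(genome[[chrom]], exm[k, 1] + 1L,
                                      exm[k, 2]))
    }, character(1))
    seq <- paste(pieces, collapse = "")
    if (strand == "-") seq <- revcomp(seq)
    map <- coordinate_map(exm, strand)
    cds <- NULL
    if (length(cd)) {
      gpos <- unlist(lapply(cd, function(k) {
        (GenomicRanges::start(gff[k]) - 1L):(GenomicRanges::end(gff[k]) - 1L)
      }))
      tpos <- genomic_to_transcript(map, gpos)
      if (anyNA(tpos)) {
        reject("CDS outside exons")
        next
      }
      cds <- c(min(tpos), max(tpos) + 1L)
    }
    tx <- tryCatch(
      transcript(tid, seq, gene_id = gene, exons = exm, strand = strand,
                 chrom = chrom, cds = cds, code = code),
      error = function(e) conditionMessage(e)
    )
    if (is.character(tx)) {
      reject(tx)
      next
    }
    out[[tid]] <- tx
  }
  rej <- if (length(rejected)) do.call(rbind, rejected) else
    data.frame(transcript_id = character(0), reason = character(0))
  if (nrow(rej)) {
    message("load_transcriptome: rejected ", nrow(rej), " record(s): ",
            paste(unique(rej$transcript_id), collapse = ", "))
  }
  attr(out, "rejected") <- rej
  out
}

#' Load a transcriptome from transcript-space FASTA + CDS table
#'
#' @param fasta Transcript-space FASTA (one record per transcript).
#' @param cds_table TSV with columns `transcript_id`, `gene_id`,
#'   `cds_start`, `cds_end` (0-based half-open; NA for lncRNA).
#' @param code Genetic code.
#' @return Named list of [transcript()] objects.
#' @export
load_transcriptome_tsv <- function(fasta, cds_table, code = genetic_code()) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  tab <- utils::read.delim(cds_table, stringsAsFactors = FALSE)
  out <- list()
  rejected <- list()
  for (i in seq_len(nrow(tab))) {
    tid <- tab$transcript_id[i]
    if (!tid %in% names(seqs)) {
      rejected[[length(rejected) + 1L]] <-
        data.frame(transcript_id = tid, reason = "absent from FASTA")
      next
    }
    cds <- if (is.na(tab$cds_start[i])) NULL else
      c(tab$cds_start[i], tab$cds_end[i])
    tx <- tryCatch(
      transcript(tid, as.character(seqs[[tid]]),
                 gene_id = tab$gene_id[i] %||% tid, cds = cds, code = code),
      error = function(e) conditionMessage(e)
    )
    if (is.character(tx)) {
      rejected[[length(rejected) + 1L]] <-
        data.frame(transcript_id = tid, reason = tx)
      next
    }
    out[[tid]] <- tx
  }
  attr(out, "rejected") <- if (length(rejected)) do.call(rbind, rejected) else
    data.frame(transcript_id = character(0), reason = character(0))
  out
}

#' Read SNVs from a VCF and project them into transcript space
#'
#' Multiallelic records are split; non-SNV and intronic records are skipped
#' and counted; alleles are complemented for minus-strand transcripts;
#' `occurrence_count` reflects record multiplicity.
#'
#' @param path VCF path (plain text or gzip).
#' @param transcriptome Named list of [transcript()] objects with exon
#'   structures.
#' @return SNV data.frame (`transcript_id`, `tpos`, `ref`, `alt`,
#'   `occurrence_count`) with skip counters in `attr(, "skipped")`.
#' @export
read_vcf_snvs <- function(path, transcriptome) {
  transcriptome <- as_transcriptome(transcriptome)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (!nrow(fix)) {
    out <- data.frame(transcript_id = character(0), tpos = integer(0),
                      ref = character(0), alt = character(0),
                      occurrence_count = integer(0))
    attr(out, "skipped") <- c(non_snv = 0L, unmapped = 0L, ref_mismatch = 0L)
    return(out)
  }
  by_chrom <- split(seq_along(transcriptome),
                    vapply(transcriptome, function(t) t$chrom %||% NA_character_,
                           character(1)))
  rows <- list()
  n_non_snv <- 0L
  n_unmapped <- 0L
  n_mismatch <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (alt in alts) {
      if (nchar(fix$REF[i]) != 1L || nchar(alt) != 1L ||
            !fix$REF[i] %in% DNA_BASES || !alt %in% DNA_BASES) {
        n_non_snv <- n_non_snv + 1L
        next
      }
      txi <- by_chrom[[fix$CHROM[i]]]
      if (is.null(txi)) {
        n_unmapped <- n_unmapped + 1L
        next
      }
      gpos <- as.integer(fix$POS[i]) - 1L
      mapped <- FALSE
      for (k in txi) {
        tx <- transcriptome[[k]]
        tpos <- genomic_to_transcript(coordinate_map_of(tx), gpos)
        if (is.na(tpos)) next
        ref <- fix$REF[i]
        a <- alt
        if (tx$strand == "-") {
          ref <- comp_base(ref)
          a <- comp_base(a)
        }
        obs <- substring(tx$sequence, tpos + 1L, tpos + 1L)
        if (obs != ref) {
          n_mismatch <- n_mismatch + 1L
          warning("VCF record ", fix$CHROM[i], ":", fix$POS[i],
                  " reference mismatch on '", tx$id, "' (expected '", ref,
                  "', transcript has '", obs, "'); skipped", call. = FALSE)
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          transcript_id = tx$id, tpos = tpos, ref = ref, alt = a,
          stringsAsFactors = FALSE)
        mapped <- TRUE
      }
      if (!mapped) n_unmapped <- n_unmapped + 1L
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript_id = character(0), tpos = integer(0),
               ref = character(0), alt = character(0))
  if (nrow(out)) {
    key <- paste(out$transcript_id, out$tpos, out$alt)
    agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
    out <- out[!duplicated(key), , drop = FALSE]
    out$occurrence_count <- agg$Freq[match(paste(out$transcript_id, out$tpos,
                                                 out$alt), agg$key)]
    out <- order_variants(out)
    rownames(out) <- NULL
  } else {
    out$occurrence_count <- integer(0)
  }
  attr(out, "skipped") <- c(non_snv = n_non_snv, unmapped = n_unmapped,
                            ref_mismatch = n_mismatch)
  out
}

#' Read a per-base conservation track from bedGraph
#'
#' Expands interval scores to one value per base over the requested region.
#' Gaps abort with the first gap named unless `interpolate = TRUE`, which
#' fills them linearly.
#'
#' @param path bedGraph path.
#' @param region_id Chromosome/region name to extract.
#' @param start,end Optional 0-based half-open sub-interval (defaults to the
#'   region's data span).
#' @param interpolate Linearly fill gaps instead of failing.
#' @return A [conservation_track()].
#' @export
read_bedgraph_track <- function(path, region_id, start = NULL, end = NULL,
                                interpolate = FALSE) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == region_id]
  if (!length(gr)) stop("region '", region_id, "' not found in ", path,
                        call. = FALSE)
  s0 <- GenomicRanges::start(gr) - 1L
  e0 <- GenomicRanges::end(gr)
  start <- start %||% min(s0)
  end <- end %||% max(e0)
  x <- rep(NA_real_, end - start)
  for (k in seq_along(gr)) {
    lo <- max(s0[k], start)
    hi <- min(e0[k], end)
    if (hi > lo) x[(lo - start + 1L):(hi - start)] <- gr$score[k]
  }
  if (anyNA(x)) {
    if (!interpolate) {
      stop("gap in track '", region_id, "' at position ",
           start + which(is.na(x))[1] - 1L,
           " (use interpolate = TRUE to fill)", call. = FALSE)
    }
    x <- stats::approx(which(!is.na(x)), x[!is.na(x)], xout = seq_along(x),
                       rule = 2)$y
  }
  conservation_track(region_id, x, start)
}

#' Write a conservation track as bedGraph (run-length compressed)
#' @param track A [conservation_track()].
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  x <- track$scores
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- c(0L, utils::head(ends, -1))
  lines <- sprintf("%s\t%d\t%d\t%s", track$region_id,
                   track$offset + starts, track$offset + ends,
                   formatC(r$values, format = "g", digits = 10))
  writeLines(lines, path)
  invisible(path)
}

#' Write a fixture bundle to disk
#'
#' Materialises a simulated study as standard files: genome FASTA, GFF3
#' (gene/mRNA/exon/CDS), VCF of the synonymous SNVs (genomic coordinates,
#' strand-resolved alleles, one record per occurrence), bedGraph
#' conservation tracks (transcript space), and ground-truth TSV/JSON. The
#' bundle reloads losslessly through [load_transcriptome()],
#' [read_vcf_snvs()] and [read_bedgraph_track()].
#'
#' @param x A [sim_config()] or the result of [simulate_study()].
#' @param outdir Output directory (created if needed).
#' @return Invisible named vector of file paths.
#' @export
write_fixture_bundle <- function(x, outdir) {
  sim <- if (inherits(x, "sim_config")) simulate_study(x) else x
  stopifnot(inherits(sim, "sim_study"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(outdir, "genome.fa"),
    gff3 = file.path(outdir, "annotation.gff3"),
    vcf = file.path(outdir, "variants.vcf"),
    bedgraph = file.path(outdir, "conservation.bedGraph"),
    truth_orfs = file.path(outdir, "truth_orfs.tsv"),
    truth_variants = file.path(outdir, "truth_variants.tsv"),
    truth = file.path(outdir, "truth.json")
  )

  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$contigs), paths[["fasta"]])

  gff <- c("##gff-version 3")
  for (tx in sim$transcripts) {
    map <- coordinate_map_of(tx)
    glo <- min(tx$exons[, 1]) + 1L
    ghi <- max(tx$exons[, 2])
    ttype <- if (is.null(tx$cds)) "lnc_RNA" else "mRNA"
    gff <- c(gff,
      sprintf("%s\tpolyorf\tgene\t%d\t%d\t.\t%s\t.\tID=gene:%s",
              tx$chrom, glo, ghi, tx$strand, tx$gene_id),
      sprintf("%s\tpolyorf\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Parent=gene:%s",
              tx$chrom, ttype, glo, ghi, tx$strand, tx$id, tx$gene_id),
      sprintf("%s\tpolyorf\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
              tx$chrom, tx$exons[, 1] + 1L, tx$exons[, 2], tx$strand, tx$id))
    if (!is.null(tx$cds)) {
      blocks <- project_to_genomic(map, tx$cds[1], tx$cds[2])
      # transcript-order blocks for phase computation
      ord <- if (tx$strand == "+") order(blocks$gstart) else
        order(-blocks$gstart)
      cum <- 0L
      phase <- integer(nrow(blocks))
      for (k in ord) {
        phase[k] <- (3L - cum %% 3L) %% 3L
        cum <- cum + blocks$gend[k] - blocks$gstart[k]
      }
      gff <- c(gff, sprintf(
        "%s\tpolyorf\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
        tx$chrom, blocks$gstart + 1L, blocks$gend, tx$strand, phase, tx$id))
    }
  }
  writeLines(gff, paths[["gff3"]])

  vcf <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(sim$contigs),
                   nchar(sim$contigs)),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (!is.null(sim$variants) && nrow(sim$variants)) {
    v <- sim$variants
    recs <- lapply(seq_len(nrow(v)), function(i) {
      tx <- sim$transcripts[[v$transcript_id[i]]]
      gpos <- transcript_to_genomic(coordinate_map_of(tx), v$tpos[i])
      ref <- v$ref[i]
      alt <- v$alt[i]
      if (tx$strand == "-") {
        ref <- comp_base(ref)
        alt <- comp_base(alt)
      }
      data.frame(chrom = tx$chrom, pos = gpos + 1L, ref = ref, alt = alt,
                 n = v$occurrence_count[i], stringsAsFactors = FALSE)
    })
    recs <- do.call(rbind, recs)
    recs <- recs[order(recs$chrom, recs$pos, recs$alt), , drop = FALSE]
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", recs$chrom, recs$pos,
                    recs$ref, recs$alt)
    vcf <- c(vcf, rep(body, recs$n))
  }
  writeLines(vcf, paths[["vcf"]])

  bg <- unlist(lapply(sim$tracks, function(tr) {
    x <- tr$scores
    sprintf("%s\t%d\t%d\t%s", tr$region_id, tr$offset + seq_along(x) - 1L,
            tr$offset + seq_along(x), formatC(x, format = "g", digits = 10))
  }))
  writeLines(bg, paths[["bedgraph"]])

  utils::write.table(sim$truth_orfs, paths[["truth_orfs"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  if (!is.null(sim$variants) && nrow(sim$variants)) {
    truth_var <- scan_silent_altering(
      sim$variants, sim$transcripts,
      orf_params(min_aa = sim$config$min_aa))
    utils::write.table(as.data.frame(truth_var), paths[["truth_variants"]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    writeLines("transcript_id\ttpos\tref\talt", paths[["truth_variants"]])
  }

  jsonlite::write_json(
    list(seed = sim$config$seed,
         n_transcripts = sim$config$n_transcripts,
         planted_frames = sim$planted_frames,
         track_depth = sim$config$track_depth,
         track_noise_sd = sim$config$track_noise_sd),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
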