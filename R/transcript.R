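#' Construct a mature transcript
#'
#' A transcript carries the sense-strand sequence of the mature (spliced)
#' RNA, an optional exon structure anchoring it to a genome, and an optional
#' canonical CDS. All transcript-space coordinates in this package are
#' 0-based half-open (BED-like); GFF3 and VCF coordinates are converted at
#' the I/O boundary. Minus-strand genes are reverse-complemented at load so
#' that all downstream logic is strand-free.
#'
#' @param id Transcript identifier.
#' @param sequence Sense-strand DNA of the mature transcript (`A,C,G,T,N`).
#' @param gene_id Gene identifier (defaults to `id`).
#' @param exons Optional two-column matrix/data.frame of genomic exon
#'   intervals (0-based half-open), in genomic order, non-overlapping.
#' @param strand `"+"` or `"-"` (required when `exons` given).
#' @param chrom Chromosome/contig name of the exons.
#' @param cds Optional length-2 integer vector: transcript-space CDS interval
#'   (0-based half-open), stop codon included.
#' @param code Genetic code used to validate the CDS.
#' @return An object of class `transcript`.
#' @examples
#' tx <- transcript("t1", "ATGCATGGATTGATATAA", cds = c(0L, 18L))
#' @export
transcript <- function(id, sequence, gene_id = id, exons = NULL,
                       strand = NULL, chrom = NULL, cds = NULL,
                       code = genetic_code()) {
  sequence <- toupper(sequence)
  check_alphabet(sequence)
  n <- nchar(sequence)
  if (!is.null(exons)) {
    exons <- as.matrix(exons)[, 1:2, drop = FALSE]
    storage.mode(exons) <- "integer"
    colnames(exons) <- c("start", "end")
    if (is.null(strand) || !strand %in% c("+", "-")) {
      stop("transcript '", id, "': exons require strand '+' or '-'",
           call. = FALSE)
    }
    if (any(exons[, 2] <= exons[, 1])) {
      stop("transcript '", id, "': empty or reversed exon interval",
           call. = FALSE)
    }
    if (is.unsorted(exons[, 1]) ||
        any(utils::head(exons[, 2], -1) > utils::tail(exons[, 1], -1))) {
      stop("transcript '", id, "': exons must be sorted and non-overlapping",
           call. = FALSE)
    }
    if (sum(exons[, 2] - exons[, 1]) != n) {
      stop("transcript '", id, "': sequence length ", n,
           " != summed exon length ", sum(exons[, 2] - exons[, 1]),
           call. = FALSE)
    }
  }
  if (!is.null(cds)) {
    cds <- as.integer(cds)
    validate_cds(sequence, cds, code, id)
  }
  structure(
    list(id = id, gene_id = gene_id, sequence = sequence, exons = exons,
         strand = strand, chrom = chrom, cds = cds),
    class = "transcript"
  )
}

#' @noRd
validate_cds <- function(sequence, cds, code, id) {
  n <- nchar(sequence)
  len <- cds[2] - cds[1]
  if (cds[1] < 0L || cds[2] > n) {
    stop("transcript '", id, "': CDS [", cds[1], ",", cds[2],
         ") outside sequence [0,", n, ")", call. = FALSE)
  }
  if (len %% 3L != 0L) {
    stop("transcript '", id, "': CDS length ", len,
         " is not a multiple of 3 (frame)", call. = FALSE)
  }
  if (len < 6L) stop("transcript '", id, "': CDS shorter than 6 nt",
                     call. = FALSE)
  if (substring(sequence, cds[1] + 1L, cds[1] + 3L) != "ATG") {
    stop("transcript '", id, "': CDS does not begin with ATG", call. = FALSE)
  }
  last <- substring(sequence, cds[2] - 2L, cds[2])
  if (!last %in% stop_codons(code)) {
    stop("transcript '", id, "': CDS does not end in a stop codon",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.transcript <- function(x, ...) {
  cat("<transcript>", x$id, "gene", x$gene_id, "-", nchar(x$sequence), "nt\n")
  if (!is.null(x$cds)) {
    cat("  CDS [", x$cds[1], ",", x$cds[2], ") (",
        (x$cds[2] - x$cds[1]) / 3 - 1, " aa)\n", sep = "")
  } else {
    cat("  no CDS (lncRNA)\n")
  }
  if (!is.null(x$exons)) {
    cat("  ", nrow(x$exons), " exon(s) on ", x$chrom, " (", x$strand, ")\n",
        sep = "")
  }
  invisible(x)
}

#' Genomic-transcript coordinate map
#'
#' Bidirectional projection between genomic and transcript coordinates,
#' derived from an exon structure. On the minus strand, transcript position 0
#' is the last base of the last genomic exon.
#'
#' @param exons Two-column matrix of genomic exon intervals (0-based
#'   half-open), genomic order.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `coordinate_map`.
#' @export
coordinate_map <- function(exons, strand) {
  exons <- as.matrix(exons)[, 1:2, drop = FALSE]
  storage.mode(exons) <- "integer"
  stopifnot(strand %in% c("+", "-"))
  widths <- exons[, 2] - exons[, 1]
  structure(
    list(exons = exons, strand = strand,
         offsets = c(0L, cumsum(widths))[seq_len(nrow(exons))],
         length = sum(widths)),
    class = "coordinate_map"
  )
}

#' @rdname coordinate_map
#' @param tx A `transcript` with exons.
#' @export
coordinate_map_of <- function(tx) {
  if (is.null(tx$exons)) stop("transcript '", tx$id, "' has no exon structure",
                              call. = FALSE)
  coordinate_map(tx$exons, tx$strand)
}

#' Project genomic positions into transcript space
#'
#' Intronic or out-of-range positions map to `NA` (the "unmapped" signal);
#' callers decide whether to skip or fail.
#'
#' @param map A [coordinate_map()].
#' @param gpos Integer vector of genomic positions (0-based).
#' @return Integer vector of transcript positions, `NA` where unmapped.
#' @examples
#' m <- coordinate_map(rbind(c(100, 110), c(120, 130)), "+")
#' genomic_to_transcript(m, 121)  # 11
#' @export
genomic_to_transcript <- function(map, gpos) {
  gpos <- as.integer(gpos)
  i <- findInterval(gpos, map$exons[, 1])
  ok <- i >= 1L & gpos < map$exons[pmax(i, 1L), 2]
  off <- rep(NA_integer_, length(gpos))
  off[ok] <- map$offsets[i[ok]] + gpos[ok] - map$exons[i[ok], 1]
  if (map$strand == "-") off <- map$length - 1L - off
  off
}

#' Project transcript positions back to the genome
#'
#' Exact inverse of [genomic_to_transcript()].
#'
#' @param map A [coordinate_map()].
#' @param tpos Integer vector of transcript positions (0-based).
#' @return Integer vector of genomic positions.
#' @export
transcript_to_genomic <- function(map, tpos) {
  tpos <- as.integer(tpos)
  if (any(tpos < 0L | tpos >= map$length)) {
    stop("transcript position out of range [0,", map$length, ")",
         call. = FALSE)
  }
  off <- if (map$strand == "-") map$length - 1L - tpos else tpos
  i <- findInterval(off, map$offsets)
  map$exons[i, 1] + (off - map$offsets[i])
}

#' Project a transcript interval to genomic blocks
#'
#' @param map A [coordinate_map()].
#' @param start,end Transcript interval, 0-based half-open.
#' @return data.frame of genomic blocks (`gstart`, `gend`, 0-based half-open,
#'   genomic order) whose widths sum to `end - start`.
#' @export
project_to_genomic <- function(map, start, end) {
  stopifnot(end > start)
  g <- sort(transcript_to_genomic(map, start:(end - 1L)))
  brk <- c(0L, which(diff(g) != 1L), length(g))
  data.frame(
    gstart = g[utils::head(brk, -1) + 1L],
    gend = g[utils::tail(brk, -1)] + 1L
  )
}

#' Codon index and codon position of a transcript position within an ORF
#'
#' @param orf A one-row ORF data.frame or list with `start` and `end`
#'   (0-based half-open transcript interval).
#' @param pos Transcript position(s) inside the ORF.
#' @return List with `codon_index` (0-based) and `codon_pos` (1, 2 or 3).
#' @examples
#' codon_position(list(start = 10, end = 19), 15)  # index 1, position 3
#' @export
codon_position <- function(orf, pos) {
  start <- as.integer(orf$start)
  end <- as.integer(orf$end)
  pos <- as.integer(pos)
  if (any(pos < start | pos >= end)) {
    stop("position outside ORF [", start, ",", end, ")", call. = FALSE)
  }
  list(codon_index = (pos - start) %/% 3L,
       codon_pos = (pos - start) %% 3L + 1L)
}
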