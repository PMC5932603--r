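#' Genetic code table
#'
#' Returns a genetic code object mapping all 64 codons to single-letter amino
#' acids, with `"*"` marking stop codons. Table 1 (the standard code) is the
#' default; other NCBI table ids (e.g. 2 for vertebrate mitochondrial, where
#' mitochondria-encoded small ORFs live) are supported through
#' [Biostrings::getGeneticCode()].
#'
#' @param table_id NCBI genetic code table id (default `1`, the standard code).
#' @return An object of class `genetic_code` with fields `table_id` and
#'   `codon_to_aa` (named character vector of length 64).
#' @examples
#' code <- genetic_code()
#' code$codon_to_aa[["ATG"]]  # "M"
#' @export
genetic_code <- function(table_id = 1L) {
  tbl <- Biostrings::getGeneticCode(as.character(table_id))
  tbl <- tbl[order(names(tbl))]
  stopifnot(length(tbl) == 64L, all(nchar(names(tbl)) == 3L))
  structure(
    list(table_id = as.integer(table_id), codon_to_aa = tbl),
    class = "genetic_code"
  )
}

#' Stop codons of a genetic code
#' @param code A [genetic_code()] object.
#' @return Character vector of stop codons (`TAA`, `TAG`, `TGA` for table 1).
#' @export
stop_codons <- function(code = genetic_code()) {
  names(code$codon_to_aa)[code$codon_to_aa == "*"]
}

#' Translate codons to amino acids, N-containing codons to "X"
#' @noRd
codons_to_aa <- function(codons, code) {
  aa <- unname(code$codon_to_aa[codons])
  aa[is.na(aa)] <- "X"
  aa
}

#' Translate a DNA sequence
#'
#' Translates an in-frame DNA sequence, stopping at the first stop codon.
#' Codons containing `N` translate to `"X"` and never terminate translation.
#'
#' @param seq DNA string over `{A,C,G,T,N}` with length a multiple of 3.
#' @param code A [genetic_code()] object.
#' @return A list with `protein` (amino-acid string, stop excluded) and
#'   `terminated` (`TRUE` iff a stop codon was reached).
#' @examples
#' translate_orf("ATGAAATAG")  # protein "MK", terminated TRUE
#' @export
translate_orf <- function(seq, code = genetic_code()) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L) {
    stop("'seq' must be a single non-empty DNA string", call. = FALSE)
  }
  if (nchar(seq) %% 3L != 0L) {
    stop("sequence length (", nchar(seq), ") is not a multiple of 3",
         call. = FALSE)
  }
  check_alphabet(seq)
  aa <- codons_to_aa(interval_codons(seq, 0L, nchar(seq)), code)
  hit <- which(aa == "*")
  if (length(hit)) {
    list(protein = paste(aa[seq_len(hit[1L] - 1L)], collapse = ""),
         terminated = TRUE)
  } else {
    list(protein = paste(aa, collapse = ""), terminated = FALSE)
  }
}
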