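# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a fixed RNG seed, restoring global RNG state
#' @noRd
run_seeded <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

#' Reverse-complement a DNA string (A/C/G/T/N)
#' @noRd
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Complement single bases
#' @noRd
comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

#' @noRd
check_alphabet <- function(seq, allow_n = TRUE) {
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  if (any(grepl(pat, seq))) {
    stop("sequence contains characters outside the {A,C,G,T",
         if (allow_n) ",N" else "", "} alphabet", call. = FALSE)
  }
  invisible(TRUE)
}

#' Split a 0-based half-open interval [start, end) into codon strings
#' @noRd
interval_codons <- function(seq, start, end) {
  stopifnot((end - start) %% 3 == 0)
  cs <- seq.int(start, end - 3L, by = 3L)
  substring(seq, cs + 1L, cs + 3L)
}

#' Deterministic row ordering used for all variant tables
#' @noRd
order_variants <- function(df) {
  df[order(df$transcript_id, df$tpos, df$alt), , drop = FALSE]
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Permute a vector safely (no scalar expansion like sample())
#' @noRd
shuffle <- function(x) x[sample.int(length(x))]

#' Draw one element safely
#' @noRd
sample_one <- function(x) x[sample.int(length(x), 1L)]
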