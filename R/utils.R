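#' Reverse complement of a DNA string
#'
#' Plain-character convenience wrapper used throughout the junction code,
#' where sequences are short (flanks, heptamers, 41-bp windows).
#'
#' @param x Character vector of ACGT strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; cohort percentages are reported with
#' the conventional half-away-from-zero rule (100 * 10/12 -> 83.3).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# 0-based half-open substring of a chromosome string: [start, end)
substr0 <- function(seq, start, end) {
  if (start < 0 || end > nchar(seq) || end < start) {
    stop("substring [", start, ", ", end, ") outside sequence of length ",
         nchar(seq))
  }
  substr(seq, start + 1L, end)
}

# Assign characters into a chromosome string, 0-based start
`substr0<-` <- function(seq, start, value) {
  substr(seq, start + 1L, start + nchar(value)) <- value
  seq
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Integer encoding A=1 C=2 G=3 T=4 for motif arithmetic
DNA_BASES4 <- c("A", "C", "G", "T")

dna_to_int <- function(x) {
  match(strsplit(x, "", fixed = TRUE)[[1]], DNA_BASES4)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
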