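#' Round half away from zero
#'
#' Fixed-rule decimal rounding where ties go up (2.345 -> 2.35 at two
#' digits), unlike [round()]'s banker's rounding. All percentages the
#' package prints use this rule.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a total, rounded half-up to two decimals
#'
#' @param n numerator count.
#' @param total denominator count.
#' @return numeric percentage on the 0-100 scale, two decimals.
#' @export
percent_of <- function(n, total) {
  stopifnot(total > 0)
  round_half_up(100 * n / total, 2)
}

# format a half-up 2-decimal percentage with trailing zeros ("0.28")
fmt_pct2 <- function(p) sprintf("%.2f", p)

#' Reverse complement of a DNA character string
#'
#' Thin wrapper over [Biostrings::reverseComplement()] for plain
#' character input; N maps to N.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# validate a DNAStringSet / character set over the {A,C,G,T,N} alphabet
assert_dna_alphabet <- function(seqs, ids = names(seqs)) {
  chr <- as.character(seqs)
  bad <- grepl("[^ACGTN]", chr)
  if (any(bad)) {
    stop("sequence(s) with characters outside {A,C,G,T,N}: ",
         paste(ids[bad], collapse = ", "))
  }
  invisible(TRUE)
}

# stable ordering used everywhere a deterministic sequence order is
# needed: length descending, then id ascending
order_len_desc_id_asc <- function(lens, ids) {
  order(-lens, ids, method = "radix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
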