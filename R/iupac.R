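# IUPAC nucleotide machinery shared by the whole package.
#
# Every symbol is represented internally as a 4-bit mask (A=1, C=2, G=4, T=8);
# two symbols are compatible iff their masks intersect. Sequences are held as
# uppercase ACGT...N strings with U already mapped to T.

IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L,  Y = 10L, S = 6L,  W = 9L,
  K = 12L, M = 3L,  B = 14L, D = 13L,
  H = 11L, V = 7L,  N = 15L
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W",
  K = "M", M = "K", B = "V", D = "H",
  H = "D", V = "B", N = "N"
)

# lookup table indexed by ASCII code, NA for non-IUPAC characters
.mask_lut <- local({
  lut <- rep(NA_integer_, 256L)
  lut[utf8ToInt(paste(names(IUPAC_MASK), collapse = ""))] <- unname(IUPAC_MASK)
  lut
})

#' Normalize a nucleotide string
#'
#' Uppercases, maps U to T and strips whitespace. The result is validated
#' against the IUPAC alphabet `ACGTRYSWKMBDHVN`; the first offending position
#' is named in the error. Normalization is idempotent.
#'
#' @param x Character vector of nucleotide strings.
#' @param what Label used in error messages (e.g. a record id).
#' @return Character vector of normalized sequences.
#' @export
#' @examples
#' normalize_sequence("acgu")  # "ACGT"
normalize_sequence <- function(x, what = "sequence") {
  x <- gsub("[ \t\r\n]", "", toupper(as.character(x)))
  x <- chartr("U", "T", x)
  bad <- !vapply(x, function(s) all(!is.na(.mask_lut[utf8ToInt(s)])), logical(1))
  if (any(bad)) {
    s <- x[which(bad)[1]]
    pos <- which(is.na(.mask_lut[utf8ToInt(s)]))[1]
    stop(sprintf("%s contains non-IUPAC symbol '%s' at position %d",
                 what, substr(s, pos, pos), pos), call. = FALSE)
  }
  x
}

# integer 4-bit mask vector for one sequence (assumed normalized)
seq_to_mask <- function(s) {
  .mask_lut[utf8ToInt(s)]
}

#' Reverse complement with full IUPAC support
#'
#' @param x Character vector of (possibly degenerate) nucleotide strings.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  x <- normalize_sequence(x)
  comp <- chartr(paste(names(IUPAC_COMPLEMENT), collapse = ""),
                 paste(unname(IUPAC_COMPLEMENT), collapse = ""), x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

#' Do two IUPAC symbols match?
#'
#' Match semantics are non-empty intersection of the two symbols' base sets,
#' so degenerate-vs-degenerate comparisons are symmetric (e.g. H vs N matches).
#'
#' @param primer_symbol,reference_symbol Single IUPAC characters (vectorized).
#' @return Logical vector.
#' @export
#' @examples
#' iupac_match("R", "A")  # TRUE
#' iupac_match("R", "C")  # FALSE
iupac_match <- function(primer_symbol, reference_symbol) {
  a <- .mask_lut[utf8ToInt(paste(normalize_sequence(primer_symbol, "primer symbol"), collapse = ""))]
  b <- .mask_lut[utf8ToInt(paste(normalize_sequence(reference_symbol, "reference symbol"), collapse = ""))]
  bitwAnd(a, b) > 0L
}

#' Expand a degenerate oligo into all literal sequences
#'
#' @param x A single IUPAC string.
#' @return Character vector of all ACGT expansions.
#' @export
#' @examples
#' length(expand_degenerate("CARR"))  # 4
expand_degenerate <- function(x) {
  x <- normalize_sequence(x, "oligo")
  sets <- lapply(seq_to_mask(x), function(m) {
    c("A", "C", "G", "T")[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L]
  })
  do.call(paste0, rev(expand.grid(rev(sets), stringsAsFactors = FALSE)))
}
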