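# Global pairwise identity.
#
# Alignment is Needleman-Wunsch with free end gaps (match +1, mismatch -1,
# affine internal gap penalty: -2 for the first gap base, -1 per additional
# base). Identity excludes terminal-gap columns, with the denominator
# floored at the shorter sequence's length:
#   identity = 100 * matches / max(non-terminal-gap columns, min(m, n)).
# The floor matters: with free end gaps, the score-optimal "alignment" of
# two unrelated sequences is a handful of perfectly matching terminal bases,
# which would otherwise report near-100 identity for junk; the floor turns
# that into the near-zero coverage-weighted identity it really is, while an
# exact prefix/substring still scores 100 and substitution-only pairs score
# exactly their Hamming identity.

# identity for vectors of aligned (gapped) strings of equal per-pair length
.aligned_identity <- function(p_aln, s_aln) {
  vapply(seq_along(p_aln), function(i) {
    pv <- utf8ToInt(p_aln[i])
    sv <- utf8ToInt(s_aln[i])
    gap <- 45L  # "-"
    pg <- pv == gap
    sg <- sv == gap
    n <- length(pv)
    any_gap <- pg | sg
    lead <- if (any_gap[1]) which(!any_gap)[1] - 1L else 0L
    trail <- if (any_gap[n]) n - which(!any_gap)[length(which(!any_gap))] else 0L
    counted <- n - lead - trail
    denom <- max(counted, min(sum(!pg), sum(!sg)))  # coverage floor
    if (denom <= 0) return(0)
    matches <- sum(pv == sv & !pg)
    100 * matches / denom
  }, numeric(1))
}

# align many patterns against one subject; returns numeric identity vector.
# The DP lives in compiled code (src/nw_identity.cpp); the reference-grade
# but much slower Biostrings route below is kept for cross-checking.
.identity_to_subject <- function(patterns, subject) {
  if (length(patterns) == 0) return(numeric(0))
  .nw_identity_cpp(patterns, subject)
}

# independent slow path via Biostrings; used by the test suite to validate
# the compiled aligner
.identity_to_subject_biostrings <- function(patterns, subject) {
  if (length(patterns) == 0) return(numeric(0))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(patterns),
    subject = Biostrings::DNAString(subject),
    type = "overlap", substitutionMatrix = mat,
    gapOpening = 1, gapExtension = 1
  )
  p_aln <- as.character(Biostrings::alignedPattern(aln))
  s_aln <- as.character(Biostrings::alignedSubject(aln))
  .aligned_identity(p_aln, s_aln)
}

#' Global percent identity between sequences
#'
#' Needleman-Wunsch global alignment with free end gaps; identity is
#' 100 x matching columns / alignment columns, excluding terminal-gap
#' columns and flooring the denominator at the shorter sequence's length
#' (so exact prefixes/substrings score 100 while a trivial short overlap of
#' unrelated sequences scores near 0). Symmetric, and
#' `global_identity(x, x) == 100`.
#'
#' @param a,b Character vectors of sequences (recycled pairwise).
#' @return Numeric vector of percent identities in `[0, 100]`.
#' @export
#' @examples
#' global_identity("ACGT", "ACGA")    # 75
#' global_identity("ACGTAA", "ACGT")  # 100: end gaps are free
global_identity <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(normalize_sequence(a), n)
  b <- rep_len(normalize_sequence(b), n)
  vapply(seq_len(n), function(i) .identity_to_subject(a[i], b[i]), numeric(1))
}
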