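#' Create a primer object
#'
#' A primer is a named 5'->3' IUPAC-degenerate oligo. The sequence is
#' normalized (uppercase, U->T) and validated; primers shorter than 10 nt are
#' rejected as they cannot carry the fit criteria meaningfully.
#'
#' @param name Short label, e.g. `"UniPlantF"`.
#' @param iupac 5'->3' sequence, IUPAC ambiguity codes allowed.
#' @return An object of class `primer` (also a one-row list with `name`,
#'   `sequence`, `length`).
#' @export
#' @examples
#' parse_primer("UniPlantF", "TGTGAATTGCARRATYCMG")
parse_primer <- function(name, iupac) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (!is.character(iupac) || length(iupac) != 1 || !nzchar(iupac)) {
    stop("primer sequence must be a non-empty string", call. = FALSE)
  }
  seq <- normalize_sequence(iupac, sprintf("primer '%s'", name))
  if (nchar(seq) < 10) {
    stop(sprintf("primer '%s' is shorter than 10 nt", name), call. = FALSE)
  }
  structure(
    list(name = name, sequence = seq, length = nchar(seq)),
    class = "primer"
  )
}

#' @export
print.primer <- function(x, ...) {
  cat(sprintf("<primer> %s  5'-%s-3'  (%d nt, %d expansions)\n",
              x$name, x$sequence, x$length,
              prod(vapply(seq_to_mask(x$sequence), function(m) sum(bitwAnd(m, c(1L,2L,4L,8L)) > 0L), integer(1)))))
  invisible(x)
}

#' The UniPlant ITS2 primer pair
#'
#' Convenience constructor for the short-amplicon plant ITS2 primer pair
#' UniPlantF / UniPlantR used throughout the package examples. UniPlantF has
#' 16 literal expansions, UniPlantR has 144.
#'
#' @return A named list with elements `fwd` and `rev`, both `primer` objects.
#' @export
uniplant_primers <- function() {
  list(
    fwd = parse_primer("UniPlantF", "TGTGAATTGCARRATYCMG"),
    rev = parse_primer("UniPlantR", "CCCGHYTGAYYTGRGGTCDC")
  )
}

#' Read primers from a tab-separated file
#'
#' Expected format: two columns `name<TAB>sequence`, no header.
#'
#' @param path Path to the primer TSV.
#' @return A list of `primer` objects named by primer name.
#' @export
read_primers <- function(path) {
  if (!file.exists(path)) stop(sprintf("primer file not found: %s", path), call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("name", "sequence"),
                           colClasses = "character")
  out <- purrr::map2(tab$name, tab$sequence, parse_primer)
  stats::setNames(out, tab$name)
}
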