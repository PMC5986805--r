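# Reference-database IO: FASTA records, taxonomy tables.
#
# Records travel through the package as tibbles with columns
# record_id / accession / sequence / truncation. `truncation` records which
# priming regions a sequence spans: "full" (both), "forward_only",
# "reverse_only" or "internal" (neither); databases assembled from archive
# downloads routinely mix full-length and partial sequences, and partial ones
# can only be tested against one primer.

TRUNCATION_LEVELS <- c("full", "forward_only", "reverse_only", "internal")

#' Read a reference database from FASTA
#'
#' The token before the first whitespace in each header becomes the
#' `record_id`. Sequences are normalized (uppercase, U->T). Two optional
#' `key=value` header tags are honoured: `trunc=` (one of `full`,
#' `forward_only`, `reverse_only`, `internal`; default `full`) and `acc=`
#' (accession). Duplicate record ids and empty sequences are hard errors.
#'
#' @param path Path to a FASTA file (any line wrapping).
#' @return A tibble with columns `record_id`, `accession`, `sequence`,
#'   `truncation`, one row per FASTA entry in input order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  # read as raw strings: normalization (case, U->T) happens here, and a DNA
  # alphabet check at parse time would reject the U/lowercase we accept
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0) stop(sprintf("no FASTA records in %s", path), call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate record_id in %s: %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")), call. = FALSE)
  }
  get_tag <- function(key) {
    vapply(headers, function(h) {
      m <- regmatches(h, regexpr(sprintf("(?<=\\b%s=)\\S+", key), h, perl = TRUE))
      if (length(m)) m else NA_character_
    }, character(1), USE.NAMES = FALSE)
  }
  seqs <- as.character(set)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop(sprintf("empty sequence for record '%s' in %s", ids[which(empty)[1]], path),
         call. = FALSE)
  }
  trunc <- get_tag("trunc")
  trunc[is.na(trunc)] <- "full"
  bad <- !trunc %in% TRUNCATION_LEVELS
  if (any(bad)) {
    stop(sprintf("invalid trunc= tag '%s' for record '%s'",
                 trunc[which(bad)[1]], ids[which(bad)[1]]), call. = FALSE)
  }
  tibble::tibble(
    record_id = ids,
    accession = get_tag("acc"),
    sequence = vapply(seq_along(seqs), function(i) {
      normalize_sequence(seqs[i], sprintf("record '%s'", ids[i]))
    }, character(1)),
    truncation = trunc
  )
}

#' Write a reference database to FASTA
#'
#' Inverse of [read_fasta()]: `trunc=` and `acc=` tags are emitted when
#' non-default/non-missing so that a read/write cycle round-trips records.
#'
#' @param records Tibble with at least `record_id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  records <- as_record_tbl(records)
  hdr <- records$record_id
  extra <- character(nrow(records))
  has_acc <- !is.na(records$accession)
  extra[has_acc] <- paste0(" acc=", records$accession[has_acc])
  not_full <- records$truncation != "full"
  extra[not_full] <- paste0(extra[not_full], " trunc=", records$truncation[not_full])
  set <- Biostrings::DNAStringSet(records$sequence)
  names(set) <- paste0(hdr, extra)
  Biostrings::writeXStringSet(set, path, format = "fasta")
  invisible(path)
}

# coerce/validate a records data frame, filling optional columns
as_record_tbl <- function(records) {
  records <- tibble::as_tibble(records)
  if (!all(c("record_id", "sequence") %in% names(records))) {
    stop("records must have columns 'record_id' and 'sequence'", call. = FALSE)
  }
  if (anyDuplicated(records$record_id)) {
    stop(sprintf("duplicate record_id: %s",
                 paste(unique(records$record_id[duplicated(records$record_id)]), collapse = ", ")),
         call. = FALSE)
  }
  if (!"accession" %in% names(records)) records$accession <- NA_character_
  if (!"truncation" %in% names(records)) records$truncation <- "full"
  if (any(!nzchar(records$sequence))) {
    stop(sprintf("empty sequence for record '%s'",
                 records$record_id[which(!nzchar(records$sequence))[1]]), call. = FALSE)
  }
  records[c("record_id", "accession", "sequence", "truncation")]
}

#' Read a taxonomy table
#'
#' Tab-separated with header columns `record_id`, `species`, `genus`,
#' `family`, `order`. Consistency of the rank hierarchy is enforced: a
#' species must map to a single genus, a genus to a single family and a
#' family to a single order; every rank label must be non-empty.
#'
#' @param path Path to the TSV.
#' @return A tibble with the five columns above.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop(sprintf("taxonomy file not found: %s", path), call. = FALSE)
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  validate_taxonomy(tab)
}

#' Validate a taxonomy table
#'
#' Checks the invariants described in [read_taxonomy()] on an in-memory
#' data frame and returns it as a tibble.
#'
#' @param taxonomy Data frame with `record_id`, `species`, `genus`,
#'   `family`, `order`.
#' @return The validated tibble.
#' @export
validate_taxonomy <- function(taxonomy) {
  taxonomy <- tibble::as_tibble(taxonomy)
  needed <- c("record_id", "species", "genus", "family", "order")
  if (!all(needed %in% names(taxonomy))) {
    stop(sprintf("taxonomy must have columns: %s", paste(needed, collapse = ", ")),
         call. = FALSE)
  }
  taxonomy <- taxonomy[needed]
  ok_mat <- sapply(taxonomy, function(col) !is.na(col) & nzchar(col))
  missing_rank <- if (nrow(taxonomy) == 1) any(!ok_mat) else rowSums(!ok_mat) > 0
  if (any(missing_rank)) {
    stop(sprintf("taxonomy row for record '%s' has a missing rank",
                 taxonomy$record_id[which(missing_rank)[1]]), call. = FALSE)
  }
  if (anyDuplicated(taxonomy$record_id)) {
    stop(sprintf("taxonomy has duplicate record_id: %s",
                 paste(unique(taxonomy$record_id[duplicated(taxonomy$record_id)]), collapse = ", ")),
         call. = FALSE)
  }
  check_unique <- function(child, parent) {
    bad <- taxonomy |>
      dplyr::distinct(.data[[child]], .data[[parent]]) |>
      dplyr::count(.data[[child]]) |>
      dplyr::filter(.data$n > 1)
    if (nrow(bad) > 0) {
      stop(sprintf("%s '%s' is mapped to multiple %s labels",
                   child, bad[[child]][1], parent), call. = FALSE)
    }
  }
  check_unique("species", "genus")
  check_unique("genus", "family")
  check_unique("family", "order")
  taxonomy
}

#' Write a taxonomy table to TSV
#'
#' @param taxonomy Taxonomy tibble (see [read_taxonomy()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  readr::write_tsv(validate_taxonomy(taxonomy), path, progress = FALSE)
  invisible(path)
}
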