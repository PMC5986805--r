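# Degenerate-primer in silico PCR.
#
# Fit criteria follow ecoPCR-style screening: a primer binds a window when the
# number of IUPAC-incompatible positions is at most `max_mismatches` AND the
# last `anchor_len` bases at the primer's 3' end all match exactly (set-wise).
# All coordinates are 0-based, half-open on the scanned strand (BED-style), so
# `insert_length = rev_start - fwd_end` with no off-by-one corrections.

#' In silico PCR configuration
#'
#' Bundles the primer-fit and amplicon-length criteria. Defaults follow the
#' screening conditions used throughout the package: at most 3 mismatches per
#' primer, an exact-match 2-base 3' anchor, and insert lengths (amplicon minus
#' both priming sites) between 100 and 500 bp.
#'
#' @param max_mismatches Maximum IUPAC mismatches tolerated per primer.
#' @param anchor_len Number of 3'-terminal primer bases that must match
#'   exactly (set-wise); mismatches here disqualify the site regardless of
#'   the total count.
#' @param min_insert,max_insert Allowed insert length range in bp (insert =
#'   amplicon minus both priming sites).
#' @param max_n_frac Records whose sequence contains more than this fraction
#'   of N are excluded from PCR (status `EXCLUDED_N`); N matches every base
#'   under the intersection rule, so N-rich junk would otherwise inflate
#'   coverage.
#' @param match_rule `"intersect"` (default): primer and reference symbols
#'   match when their IUPAC sets intersect. `"contain"`: the reference
#'   symbol's set must be contained in the primer's.
#' @return A list of class `pcr_config`.
#' @export
pcr_config <- function(max_mismatches = 3L, anchor_len = 2L,
                       min_insert = 100L, max_insert = 500L,
                       max_n_frac = 0.05,
                       match_rule = c("intersect", "contain")) {
  match_rule <- match.arg(match_rule)
  stopifnot(max_mismatches >= 0, anchor_len >= 0,
            min_insert <= max_insert, max_n_frac >= 0, max_n_frac <= 1)
  structure(list(max_mismatches = as.integer(max_mismatches),
                 anchor_len = as.integer(anchor_len),
                 min_insert = as.integer(min_insert),
                 max_insert = as.integer(max_insert),
                 max_n_frac = max_n_frac,
                 match_rule = match_rule),
            class = "pcr_config")
}

# positions failing the match rule, vectorized over window starts.
# Returns list(mismatches = int vector over starts, anchor_bad = logical).
.scan_core <- function(primer_mask, seq_mask, anchor_js, match_rule) {
  k <- length(primer_mask)
  n <- length(seq_mask) - k + 1L
  if (n < 1L) return(list(mismatches = integer(0), anchor_bad = logical(0)))
  mm <- integer(n)
  anchor_bad <- logical(n)
  for (j in seq_len(k)) {
    s <- seq_mask[j:(j + n - 1L)]
    fail <- if (match_rule == "intersect") {
      bitwAnd(primer_mask[j], s) == 0L
    } else {
      bitwAnd(primer_mask[j], s) != s
    }
    mm <- mm + fail
    if (j %in% anchor_js) anchor_bad <- anchor_bad | fail
  }
  list(mismatches = mm, anchor_bad = anchor_bad)
}

#' Count primer/window mismatches and check the 3' anchor
#'
#' @param primer A `primer` object (see [parse_primer()]).
#' @param window Sequence window of exactly the primer's length, as written
#'   on the strand the primer anneals to (5'->3' alongside the primer).
#' @param anchor_len Number of 3'-terminal primer positions requiring an
#'   exact set-wise match.
#' @param match_rule See [pcr_config()].
#' @return A list with `mismatches` (integer) and `anchor_ok` (logical).
#' @export
#' @examples
#' p <- parse_primer("UniPlantF", "TGTGAATTGCARRATYCMG")
#' count_mismatches(p, "TGTGAATTGCAAGATCCAG")  # 0 mismatches, anchor ok
count_mismatches <- function(primer, window, anchor_len = 2L,
                             match_rule = "intersect") {
  stopifnot(inherits(primer, "primer"))
  window <- normalize_sequence(window, "window")
  if (nchar(window) != primer$length) {
    stop(sprintf("window length (%d) != primer length (%d)",
                 nchar(window), primer$length), call. = FALSE)
  }
  k <- primer$length
  anchor_js <- if (anchor_len > 0) (k - anchor_len + 1L):k else integer(0)
  res <- .scan_core(seq_to_mask(primer$sequence), seq_to_mask(window),
                    anchor_js, match_rule)
  list(mismatches = res$mismatches[1], anchor_ok = !res$anchor_bad[1])
}

#' Scan a reference sequence for primer binding sites
#'
#' Slides the primer over every window of the forward strand. For
#' `strand = "reverse"` the reverse complement of the primer is scanned
#' against the forward strand (i.e. sites where the primer would anneal to
#' the reverse strand); the 3' anchor then corresponds to the *left* edge of
#' the matched window in forward-strand coordinates.
#'
#' @param sequence A single reference sequence (character scalar).
#' @param primer A `primer` object.
#' @param strand `"forward"` or `"reverse"`.
#' @param config A [pcr_config()].
#' @return A tibble with columns `primer_name`, `strand`, `start`, `end`
#'   (0-based half-open on the forward strand), `mismatches`, `anchor_ok`
#'   (always `TRUE` for reported hits), sorted by `start`. Zero rows when no
#'   window satisfies the fit criteria.
#' @export
scan_binding_sites <- function(sequence, primer, strand = c("forward", "reverse"),
                               config = pcr_config()) {
  strand <- match.arg(strand)
  stopifnot(inherits(primer, "primer"))
  sequence <- normalize_sequence(sequence)
  k <- primer$length
  sm <- seq_to_mask(sequence)
  if (strand == "forward") {
    pm <- seq_to_mask(primer$sequence)
    anchor_js <- if (config$anchor_len > 0) (k - config$anchor_len + 1L):k else integer(0)
  } else {
    pm <- seq_to_mask(reverse_complement(primer$sequence))
    anchor_js <- if (config$anchor_len > 0) seq_len(config$anchor_len) else integer(0)
  }
  res <- .scan_core(pm, sm, anchor_js, config$match_rule)
  keep <- which(res$mismatches <= config$max_mismatches & !res$anchor_bad)
  tibble::tibble(
    primer_name = rep(primer$name, length(keep)),
    strand = rep(strand, length(keep)),
    start = keep - 1L,
    end = keep - 1L + k,
    mismatches = res$mismatches[keep],
    anchor_ok = rep(TRUE, length(keep))
  )
}

# statuses a full-length record can take
PCR_STATUSES <- c("MATCH", "NO_FORWARD", "NO_REVERSE", "NO_SITE", "LENGTH_FAIL",
                  "SINGLE_PRIMER_F_OK", "SINGLE_PRIMER_R_OK", "SINGLE_PRIMER_FAIL",
                  "EXCLUDED_N")

.empty_pcr_row <- function(record_id, status) {
  tibble::tibble(
    record_id = record_id, status = status, orientation = NA_character_,
    fwd_start = NA_integer_, fwd_end = NA_integer_, fwd_mismatches = NA_integer_,
    rev_start = NA_integer_, rev_end = NA_integer_, rev_mismatches = NA_integer_,
    insert_length = NA_integer_, amplicon_length = NA_integer_
  )
}

# candidate amplicons on one strand orientation of one sequence
.orient_pairs <- function(sequence, fwd, rev, config) {
  fh <- scan_binding_sites(sequence, fwd, "forward", config)
  rh <- scan_binding_sites(sequence, rev, "reverse", config)
  pairs <- NULL
  if (nrow(fh) > 0 && nrow(rh) > 0) {
    pairs <- tidyr::crossing(
      fh |> dplyr::select(fwd_start = "start", fwd_end = "end", fwd_mismatches = "mismatches"),
      rh |> dplyr::select(rev_start = "start", rev_end = "end", rev_mismatches = "mismatches")
    ) |>
      dplyr::filter(.data$rev_start >= .data$fwd_end) |>
      dplyr::mutate(insert_length = .data$rev_start - .data$fwd_end)
  }
  list(fwd_hits = nrow(fh), rev_hits = nrow(rh), pairs = pairs)
}

#' In silico PCR on a single sequence
#'
#' Finds all forward/reverse binding-site pairs in valid orientation
#' (reverse site downstream of the forward site), on the given strand and on
#' its reverse complement, and reports the best amplicon: fewest total
#' mismatches, ties broken by shortest insert, then leftmost forward start,
#' then the plus orientation. Pairs whose insert length (amplicon minus both
#' priming sites) falls outside `[min_insert, max_insert]` are rejected;
#' status `LENGTH_FAIL` is reported when sites exist but no pair is within
#' bounds, `NO_FORWARD`/`NO_REVERSE`/`NO_SITE` when sites are absent.
#'
#' @param sequence A single full-length reference sequence.
#' @param fwd,rev Forward and reverse `primer` objects (both given 5'->3').
#' @param config A [pcr_config()].
#' @param record_id Id used in the output row.
#' @return A one-row tibble: `record_id`, `status`, `orientation` (`"+"` when
#'   the amplicon lies on the given strand, `"-"` for its reverse
#'   complement; coordinates refer to the scanned strand), hit coordinates
#'   and mismatch counts, `insert_length`, `amplicon_length`.
#' @export
simulate_pcr <- function(sequence, fwd, rev, config = pcr_config(),
                         record_id = "query") {
  if (is.data.frame(sequence)) {
    rec <- as_record_tbl(sequence)
    if (nrow(rec) != 1) stop("simulate_pcr takes a single record", call. = FALSE)
    if (rec$truncation != "full") {
      stop(sprintf("record '%s' is truncated ('%s'); use classify_single_primer_fit()",
                   rec$record_id, rec$truncation), call. = FALSE)
    }
    record_id <- rec$record_id
    sequence <- rec$sequence
  }
  sequence <- normalize_sequence(sequence, sprintf("record '%s'", record_id))
  n_frac <- stringr::str_count(sequence, "N") / nchar(sequence)
  if (n_frac > config$max_n_frac) {
    return(.empty_pcr_row(record_id, "EXCLUDED_N"))
  }
  plus <- .orient_pairs(sequence, fwd, rev, config)
  minus <- .orient_pairs(reverse_complement(sequence), fwd, rev, config)
  all_pairs <- dplyr::bind_rows(
    if (!is.null(plus$pairs)) dplyr::mutate(plus$pairs, orientation = "+"),
    if (!is.null(minus$pairs)) dplyr::mutate(minus$pairs, orientation = "-")
  )
  if (!is.null(all_pairs) && nrow(all_pairs) > 0) {
    ok <- all_pairs |>
      dplyr::filter(.data$insert_length >= config$min_insert,
                    .data$insert_length <= config$max_insert)
    if (nrow(ok) > 0) {
      best <- ok |>
        dplyr::arrange(.data$fwd_mismatches + .data$rev_mismatches,
                       .data$insert_length, .data$fwd_start,
                       .data$orientation != "+") |>
        dplyr::slice(1)
      return(tibble::tibble(
        record_id = record_id, status = "MATCH", orientation = best$orientation,
        fwd_start = best$fwd_start, fwd_end = best$fwd_end,
        fwd_mismatches = best$fwd_mismatches,
        rev_start = best$rev_start, rev_end = best$rev_end,
        rev_mismatches = best$rev_mismatches,
        insert_length = best$insert_length,
        amplicon_length = best$insert_length + fwd$length + rev$length
      ))
    }
    return(.empty_pcr_row(record_id, "LENGTH_FAIL"))
  }
  has_fwd <- plus$fwd_hits > 0 || minus$fwd_hits > 0
  has_rev <- plus$rev_hits > 0 || minus$rev_hits > 0
  status <- if (has_fwd && has_rev) "LENGTH_FAIL"  # sites on incompatible strands/order
  else if (!has_fwd && !has_rev) "NO_SITE"
  else if (!has_fwd) "NO_FORWARD"
  else "NO_REVERSE"
  .empty_pcr_row(record_id, status)
}

#' Test one primer against a partial record
#'
#' For records that do not span both priming regions, primers are tested
#' independently: the record *fits* the primer when at least one binding
#' site passes the mismatch and anchor criteria on either strand.
#'
#' @param sequence The record's sequence.
#' @param primer The `primer` to test.
#' @param config A [pcr_config()].
#' @return `"fit"` or `"no_fit"`.
#' @export
classify_single_primer_fit <- function(sequence, primer, config = pcr_config()) {
  sequence <- normalize_sequence(sequence)
  n_hits <- nrow(scan_binding_sites(sequence, primer, "forward", config)) +
    nrow(scan_binding_sites(sequence, primer, "reverse", config))
  if (n_hits > 0) "fit" else "no_fit"
}

#' In silico PCR over a reference database
#'
#' Runs [simulate_pcr()] on every full-length record and routes truncated
#' records to [classify_single_primer_fit()] (statuses
#' `SINGLE_PRIMER_F_OK` / `SINGLE_PRIMER_R_OK` / `SINGLE_PRIMER_FAIL`;
#' records spanning neither priming region report `SINGLE_PRIMER_FAIL`).
#'
#' @param records Records tibble (see [read_fasta()]).
#' @param fwd,rev Forward and reverse `primer` objects.
#' @param config A [pcr_config()].
#' @return A tibble with one row per record (same order as input) with the
#'   columns of [simulate_pcr()].
#' @export
insilico_pcr <- function(records, fwd, rev, config = pcr_config()) {
  records <- as_record_tbl(records)
  purrr::pmap(records, function(record_id, accession, sequence, truncation) {
    if (truncation == "full") {
      simulate_pcr(sequence, fwd, rev, config, record_id = record_id)
    } else if (truncation == "internal") {
      .empty_pcr_row(record_id, "SINGLE_PRIMER_FAIL")
    } else {
      primer <- if (truncation == "forward_only") fwd else rev
      fit <- classify_single_primer_fit(sequence, primer, config)
      status <- if (fit == "no_fit") "SINGLE_PRIMER_FAIL"
      else if (truncation == "forward_only") "SINGLE_PRIMER_F_OK"
      else "SINGLE_PRIMER_R_OK"
      .empty_pcr_row(record_id, status)
    }
  }) |> dplyr::bind_rows()
}

#' Summarize primer fit by taxonomic rank
#'
#' A species counts as *matched* when at least one of its full-length records
#' amplifies (`MATCH`); species are the counting unit at every rank, so a
#' family row reports how many of its tested species matched. Only species
#' with at least one full-length, non-excluded record count as tested.
#' A `Total` row is appended.
#'
#' @param results Output of [insilico_pcr()].
#' @param taxonomy Taxonomy tibble; every `record_id` in `results` must be
#'   present.
#' @param rank `"species"`, `"genus"` or `"family"`.
#' @return A tibble with the grouping columns for the rank, `n_tested`,
#'   `n_matched` and `percent_matched`.
#' @export
summarize_fit_by_rank <- function(results, taxonomy, rank = c("family", "genus", "species")) {
  rank <- match.arg(rank)
  taxonomy <- validate_taxonomy(taxonomy)
  unknown <- setdiff(results$record_id, taxonomy$record_id)
  if (length(unknown) > 0) {
    stop(sprintf("record_id not in taxonomy: %s",
                 paste(utils::head(unknown, 5), collapse = ", ")), call. = FALSE)
  }
  per_species <- results |>
    dplyr::filter(.data$status %in% c("MATCH", "NO_FORWARD", "NO_REVERSE",
                                      "NO_SITE", "LENGTH_FAIL")) |>
    dplyr::inner_join(taxonomy, by = "record_id") |>
    dplyr::group_by(.data$order, .data$family, .data$genus, .data$species) |>
    dplyr::summarise(matched = any(.data$status == "MATCH"), .groups = "drop")
  group_cols <- switch(rank,
    species = c("order", "family", "genus", "species"),
    genus = c("order", "family", "genus"),
    family = c("order", "family")
  )
  body <- per_species |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(n_tested = dplyr::n(),
                     n_matched = sum(.data$matched), .groups = "drop") |>
    dplyr::mutate(percent_matched = 100 * .data$n_matched / .data$n_tested) |>
    dplyr::arrange(.data$order, .data$family)
  total <- tibble::tibble(
    n_tested = nrow(per_species),
    n_matched = sum(per_species$matched)
  )
  total[[group_cols[length(group_cols)]]] <- "Total"
  total$percent_matched <- if (total$n_tested > 0) 100 * total$n_matched / total$n_tested else NA_real_
  dplyr::bind_rows(body, total)
}

#' Mean amplicon (insert) length per family
#'
#' Uses `MATCH` records only; every matching record of a species contributes.
#' The standard error is the sample SD of insert lengths over records divided
#' by sqrt(n records), reported as 0 for single-record families. Families
#' with no matching record are omitted.
#'
#' @param results Output of [insilico_pcr()].
#' @param taxonomy Taxonomy tibble.
#' @return A tibble: `order`, `family`, `n_species`, `n_records`,
#'   `mean_insert`, `se_insert`.
#' @export
amplicon_length_table <- function(results, taxonomy) {
  taxonomy <- validate_taxonomy(taxonomy)
  results |>
    dplyr::filter(.data$status == "MATCH") |>
    dplyr::inner_join(taxonomy, by = "record_id") |>
    dplyr::group_by(.data$order, .data$family) |>
    dplyr::summarise(
      n_species = dplyr::n_distinct(.data$species),
      n_records = dplyr::n(),
      mean_insert = mean(.data$insert_length),
      se_insert = ifelse(dplyr::n() == 1, 0,
                         stats::sd(.data$insert_length) / sqrt(dplyr::n())),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$order, .data$family)
}

#' Extract amplicon inserts from matched records
#'
#' Pulls the insert (between the two priming sites, excluding both) and the
#' full amplicon (priming sites included) for every `MATCH` result. For
#' minus-orientation matches coordinates refer to the reverse complement of
#' the stored sequence, which is handled here.
#'
#' @param records Records tibble.
#' @param results Output of [insilico_pcr()].
#' @return A tibble: `record_id`, `insert`, `amplicon`.
#' @export
extract_amplicons <- function(records, results) {
  records <- as_record_tbl(records)
  hits <- dplyr::filter(results, .data$status == "MATCH") |>
    dplyr::inner_join(dplyr::select(records, "record_id", "sequence"), by = "record_id")
  if (nrow(hits) == 0) {
    return(tibble::tibble(record_id = character(0), insert = character(0),
                          amplicon = character(0)))
  }
  seqs <- ifelse(hits$orientation == "-", reverse_complement(hits$sequence), hits$sequence)
  tibble::tibble(
    record_id = hits$record_id,
    insert = substr(seqs, hits$fwd_end + 1L, hits$rev_start),
    amplicon = substr(seqs, hits$fwd_start + 1L, hits$rev_end)
  )
}
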