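# Closest-match taxonomic assignment.
#
# Queries are labelled by their highest-identity reference(s); when the top
# hits span multiple species the assignment is promoted to the lowest rank
# they share (genus, then family), and queries whose best identity falls
# below the floor stay unassigned. This is the recommended alternative to
# MOTU clustering when a comprehensive reference library exists: it tolerates
# intraspecific/paralogous variation without a clustering threshold.

# k-mer presence profiles used by the prescreen (k fixed at 5 to keep the
# profile matrices small even for large read sets)
.kmer_presence <- function(seqs, k = 5L) {
  sets <- Biostrings::DNAStringSet(seqs)
  counts <- Biostrings::oligonucleotideFrequency(sets, width = k, step = 1L)
  counts > 0
}

#' Assign query sequences to taxa by closest reference match
#'
#' Computes global identity (end gaps free) of each query to references and
#' assigns at the lowest taxonomic rank shared by all references tying for
#' the best identity (within `tie_window` percentage points). Queries whose
#' best identity is below `min_identity` are unassigned.
#'
#' `method = "exact"` aligns each query to every reference;
#' `method = "prescreen"` restricts alignment to the `top_n` references
#' sharing the most 6-mers with the query (plus ties), which is near-exact in
#' practice and much faster on read sets.
#'
#' @param queries A records-like tibble (`record_id`, `sequence`; an optional
#'   `sample_id` column is carried through), or a character vector of
#'   sequences (auto-named `q1`, `q2`, ...).
#' @param records Reference records tibble.
#' @param taxonomy Taxonomy tibble covering the references.
#' @param min_identity Identity floor (percent) below which queries are
#'   unassigned.
#' @param tie_window References within this many percentage points of the
#'   best identity count as tied (0 = strict maximum).
#' @param method `"exact"` or `"prescreen"`.
#' @param top_n Candidate count for the prescreen.
#' @return A tibble with one row per query: `query_id`, `best_identity`,
#'   `n_best`, `matched_ids` (comma-joined), `assigned_rank` (`species`,
#'   `genus`, `family` or `unassigned`) and `assigned_taxon`, plus
#'   `sample_id` when supplied.
#' @export
assign_best_match <- function(queries, records, taxonomy,
                              min_identity = 90, tie_window = 0,
                              method = c("exact", "prescreen"), top_n = 10L) {
  method <- match.arg(method)
  records <- as_record_tbl(records)
  taxonomy <- validate_taxonomy(taxonomy)
  if (nrow(records) == 0) stop("reference database is empty", call. = FALSE)
  if (is.character(queries)) {
    queries <- tibble::tibble(record_id = paste0("q", seq_along(queries)),
                              sequence = queries)
  }
  queries <- tibble::as_tibble(queries)
  if (!all(c("record_id", "sequence") %in% names(queries))) {
    stop("queries must have columns 'record_id' and 'sequence'", call. = FALSE)
  }
  if (nrow(queries) == 0 || any(!nzchar(queries$sequence))) {
    stop("queries must be non-empty sequences", call. = FALSE)
  }
  queries$sequence <- normalize_sequence(queries$sequence, "query")
  nq <- nrow(queries)
  nr <- nrow(records)

  # candidate reference indices per query
  cand <- if (method == "exact" || nr <= top_n) {
    rep(list(seq_len(nr)), nq)
  } else {
    qk <- .kmer_presence(queries$sequence)
    rk <- t(.kmer_presence(records$sequence))
    # chunked shared-kmer counts (queries x refs) to bound memory on big read sets
    chunks <- split(seq_len(nq), ceiling(seq_len(nq) / 2000))
    unlist(lapply(chunks, function(idx) {
      shared <- qk[idx, , drop = FALSE] %*% rk
      lapply(seq_along(idx), function(i) {
        sc <- shared[i, ]
        cut <- sort(sc, decreasing = TRUE)[min(top_n, nr)]
        which(sc >= cut)
      })
    }), recursive = FALSE)
  }

  # batch alignments by reference so each pairwiseAlignment call carries
  # many query patterns against one reference subject
  by_ref <- split(rep(seq_len(nq), lengths(cand)), unlist(cand))
  best_identity <- rep(-Inf, nq)
  best_refs <- vector("list", nq)
  ident_store <- vector("list", length(by_ref))
  names(ident_store) <- names(by_ref)
  for (ref_chr in names(by_ref)) {
    ri <- as.integer(ref_chr)
    qi <- by_ref[[ref_chr]]
    ident_store[[ref_chr]] <- .identity_to_subject(queries$sequence[qi],
                                                   records$sequence[ri])
  }
  for (ref_chr in names(by_ref)) {
    ri <- as.integer(ref_chr)
    qi <- by_ref[[ref_chr]]
    ident <- ident_store[[ref_chr]]
    upd <- ident > best_identity[qi]
    best_identity[qi[upd]] <- ident[upd]
  }
  for (ref_chr in names(by_ref)) {
    ri <- as.integer(ref_chr)
    qi <- by_ref[[ref_chr]]
    ident <- ident_store[[ref_chr]]
    tied <- ident >= best_identity[qi] - tie_window
    for (j in which(tied)) {
      best_refs[[qi[j]]] <- c(best_refs[[qi[j]]], ri)
    }
  }

  tax <- taxonomy[match(records$record_id, taxonomy$record_id), ]
  out <- purrr::map(seq_len(nq), function(i) {
    refs <- best_refs[[i]]
    bi <- best_identity[i]
    if (!is.finite(bi) || bi < min_identity) {
      return(tibble::tibble(query_id = queries$record_id[i],
                            best_identity = ifelse(is.finite(bi), bi, NA_real_),
                            n_best = 0L, matched_ids = NA_character_,
                            assigned_rank = "unassigned",
                            assigned_taxon = NA_character_))
    }
    hit_tax <- tax[refs, ]
    rank <- if (dplyr::n_distinct(hit_tax$species) == 1) "species"
    else if (dplyr::n_distinct(hit_tax$genus) == 1) "genus"
    else if (dplyr::n_distinct(hit_tax$family) == 1) "family"
    else "unassigned"
    taxon <- switch(rank,
                    species = hit_tax$species[1],
                    genus = hit_tax$genus[1],
                    family = hit_tax$family[1],
                    unassigned = NA_character_)
    tibble::tibble(query_id = queries$record_id[i], best_identity = bi,
                   n_best = length(refs),
                   matched_ids = paste(records$record_id[refs], collapse = ","),
                   assigned_rank = rank, assigned_taxon = taxon)
  }) |> dplyr::bind_rows()
  if ("sample_id" %in% names(queries)) {
    out$sample_id <- queries$sample_id
  }
  out
}

#' Per-sample presence/absence (frequency of occurrence) matrix
#'
#' Collapses assignments to taxon presence per sample — the recommended
#' quantification unit for diet metabarcoding (read counts are not reliable
#' abundance measures).
#'
#' @param assignments Output of [assign_best_match()] carrying a `sample_id`
#'   column.
#' @return A wide tibble: one row per assigned taxon, columns
#'   `assigned_rank`, `assigned_taxon`, then one 0/1 column per sample.
#' @export
occurrence_matrix <- function(assignments) {
  if (!"sample_id" %in% names(assignments)) {
    stop("assignments must carry a sample_id column", call. = FALSE)
  }
  assignments |>
    dplyr::filter(.data$assigned_rank != "unassigned") |>
    dplyr::distinct(.data$assigned_rank, .data$assigned_taxon, .data$sample_id) |>
    dplyr::mutate(present = 1L) |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "present",
                       values_fill = 0L) |>
    dplyr::arrange(.data$assigned_rank, .data$assigned_taxon)
}
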