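# Taxonomic resolution of a barcode region.
#
# Sequences are prefix-dereplicated (identical sequences, or sequences that
# are exact prefixes of longer ones, collapse into one cluster); a taxon is
# unambiguously identifiable at a rank when no cluster mixes it with another
# taxon of that rank.

#' Remove duplicate sequences within species
#'
#' For each species, exact duplicate sequences are reduced to one record (the
#' first in input order among the duplicates; duplicates are identical so
#' length is tied). Identical sequences shared *across* species are retained
#' — they are the signal the resolution analysis needs.
#'
#' @param records Records tibble.
#' @param taxonomy Taxonomy tibble.
#' @return The deduplicated records tibble.
#' @export
deduplicate_same_species <- function(records, taxonomy) {
  records <- as_record_tbl(records)
  taxonomy <- validate_taxonomy(taxonomy)
  records |>
    dplyr::inner_join(dplyr::select(taxonomy, "record_id", "species"), by = "record_id") |>
    dplyr::distinct(.data$species, .data$sequence, .keep_all = TRUE) |>
    dplyr::select(-"species")
}

#' Prefix dereplication
#'
#' Greedy collapse of identical-or-prefix sequences: records are processed
#' from longest to shortest (ties broken lexicographically, then by input
#' order); each record joins the first existing cluster whose representative
#' it equals or is a prefix of, otherwise it founds a new cluster with itself
#' as representative. The result is deterministic given the input.
#'
#' @param records Records tibble (normalized sequences).
#' @param exact_only If `TRUE`, only exact equality collapses records
#'   (strict prefixes stay separate).
#' @return A tibble with one row per record: `cluster_id`, `record_id`,
#'   `representative_id`, `is_representative`.
#' @export
#' @examples
#' recs <- tibble::tibble(record_id = c("a", "b", "c"),
#'                        sequence = c("ACGTA", "ACGT", "ACGG"))
#' derep_prefix(recs)  # {a, b} and {c}
derep_prefix <- function(records, exact_only = FALSE) {
  records <- as_record_tbl(records)
  ord <- order(-nchar(records$sequence), records$sequence)
  ids <- records$record_id[ord]
  seqs <- records$sequence[ord]
  n <- length(seqs)
  rep_seq <- character(0)
  rep_id <- character(0)
  cluster <- integer(n)
  for (i in seq_len(n)) {
    hit <- if (exact_only) {
      match(seqs[i], rep_seq)
    } else {
      which(startsWith(rep_seq, seqs[i]))[1]
    }
    if (is.na(hit) || length(hit) == 0) {
      rep_seq <- c(rep_seq, seqs[i])
      rep_id <- c(rep_id, ids[i])
      cluster[i] <- length(rep_seq)
    } else {
      cluster[i] <- hit
    }
  }
  tibble::tibble(
    cluster_id = cluster,
    record_id = ids,
    representative_id = rep_id[cluster],
    is_representative = ids == rep_id[cluster]
  ) |> dplyr::arrange(.data$cluster_id)
}

#' Taxonomic resolution at species, genus and family ranks
#'
#' A taxon at a given rank is *resolved* when every dereplication cluster
#' containing any of its sequences contains only that taxon at that rank;
#' sharing a cluster with a different taxon leaves both unresolved.
#'
#' @param clusters Output of [derep_prefix()].
#' @param taxonomy Taxonomy tibble covering every clustered record.
#' @param ranks Character vector of ranks to report.
#' @return A tibble of class `resolution_report` with columns `rank`,
#'   `n_taxa`, `n_resolved`, `percent_resolved`. The unresolved taxa and
#'   their conflicting partners are attached as attribute `"unresolved"`
#'   (see [unresolved_taxa()]).
#' @export
taxonomic_resolution <- function(clusters, taxonomy,
                                 ranks = c("species", "genus", "family")) {
  taxonomy <- validate_taxonomy(taxonomy)
  stopifnot(all(ranks %in% c("species", "genus", "family", "order")))
  unknown <- setdiff(clusters$record_id, taxonomy$record_id)
  if (length(unknown) > 0) {
    stop(sprintf("clustered record_id not in taxonomy: %s",
                 paste(utils::head(unknown, 5), collapse = ", ")), call. = FALSE)
  }
  joined <- dplyr::inner_join(clusters, taxonomy, by = "record_id")
  summaries <- list()
  unresolved_all <- list()
  for (rk in ranks) {
    per_cluster <- joined |>
      dplyr::distinct(.data$cluster_id, taxon = .data[[rk]])
    conflicted <- per_cluster |>
      dplyr::add_count(.data$cluster_id, name = "n_taxa_in_cluster") |>
      dplyr::filter(.data$n_taxa_in_cluster > 1)
    taxa <- unique(per_cluster$taxon)
    bad_taxa <- unique(conflicted$taxon)
    summaries[[rk]] <- tibble::tibble(
      rank = rk,
      n_taxa = length(taxa),
      n_resolved = length(taxa) - length(bad_taxa),
      percent_resolved = 100 * (length(taxa) - length(bad_taxa)) / length(taxa)
    )
    if (nrow(conflicted) > 0) {
      unresolved_all[[rk]] <- conflicted |>
        dplyr::group_by(.data$cluster_id) |>
        dplyr::group_modify(function(df, key) {
          tibble::tibble(
            taxon = df$taxon,
            partners = vapply(seq_along(df$taxon),
                              function(i) paste(df$taxon[-i], collapse = ","),
                              character(1))
          )
        }) |>
        dplyr::ungroup() |>
        dplyr::mutate(rank = rk, .before = 1)
    }
  }
  out <- dplyr::bind_rows(summaries)
  attr(out, "unresolved") <- dplyr::bind_rows(unresolved_all)
  class(out) <- c("resolution_report", class(out))
  out
}

#' Unresolved taxa and their conflicting partners
#'
#' @param report A `resolution_report` from [taxonomic_resolution()].
#' @return A tibble: `rank`, `cluster_id`, `taxon`, `partners` (comma-joined
#'   taxa sharing the cluster). Zero rows when everything is resolved.
#' @export
unresolved_taxa <- function(report) {
  out <- attr(report, "unresolved")
  if (is.null(out)) {
    out <- tibble::tibble(rank = character(0), cluster_id = integer(0),
                          taxon = character(0), partners = character(0))
  }
  out
}
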