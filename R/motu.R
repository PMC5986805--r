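# MOTU clustering and the identity-threshold sweep.
#
# Mirrors the UCLUST-style greedy centroid strategy: one clustering pass at a
# base threshold (95% by default), then higher cut-offs are inferred from the
# stored identities instead of re-clustering the whole database. Members that
# fall below a cut-off re-cluster greedily *within* their base cluster, so a
# species whose haplotypes leave a shared centroid together is not counted as
# split. Full re-clustering at each threshold is available as a cross-check.

#' Greedy centroid clustering
#'
#' Records are processed in length-descending order (ties: input order). Each
#' record joins the first centroid (in creation order) with global identity
#' at or above `base_threshold`, else founds a new cluster. Identity of every
#' member to its centroid is stored; a centroid's identity to itself is 100.
#'
#' @param records Records tibble.
#' @param base_threshold Percent identity threshold for the base pass.
#' @return A tibble of one row per record: `cluster_id`, `record_id`,
#'   `centroid_id`, `identity`, `is_centroid`.
#' @export
cluster_greedy <- function(records, base_threshold = 95) {
  records <- as_record_tbl(records)
  if (nrow(records) == 0) stop("no records to cluster", call. = FALSE)
  ord <- order(-nchar(records$sequence))  # stable: ties keep input order
  ids <- records$record_id[ord]
  seqs <- records$sequence[ord]
  n <- length(seqs)
  centroid_seq <- character(0)
  centroid_id <- character(0)
  cluster <- integer(n)
  identity <- numeric(n)
  for (i in seq_len(n)) {
    hit <- NA_integer_
    if (length(centroid_seq) > 0) {
      ident <- .identity_to_subject(centroid_seq, seqs[i])
      ok <- which(ident >= base_threshold)
      if (length(ok) > 0) hit <- ok[1]
    }
    if (is.na(hit)) {
      centroid_seq <- c(centroid_seq, seqs[i])
      centroid_id <- c(centroid_id, ids[i])
      cluster[i] <- length(centroid_seq)
      identity[i] <- 100
    } else {
      cluster[i] <- hit
      identity[i] <- ident[hit]
    }
  }
  tibble::tibble(
    cluster_id = cluster,
    record_id = ids,
    centroid_id = centroid_id[cluster],
    identity = identity,
    is_centroid = ids == centroid_id[cluster]
  ) |> dplyr::arrange(.data$cluster_id)
}

# pairwise identity matrix among a small set of sequences (named)
.pairwise_identity <- function(seqs) {
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      ident <- .identity_to_subject(seqs[(i + 1):n], seqs[i])
      m[i, (i + 1):n] <- ident
      m[(i + 1):n, i] <- ident
    }
  }
  m
}

# greedy sub-clustering of members (ordered) given a pairwise identity matrix
.greedy_from_matrix <- function(members, identity_matrix, threshold) {
  sub <- integer(length(members))
  heads <- integer(0)
  for (i in seq_along(members)) {
    hit <- NA_integer_
    if (length(heads) > 0) {
      ident <- identity_matrix[members[heads], members[i]]
      ok <- which(ident >= threshold)
      if (length(ok) > 0) hit <- ok[1]
    }
    if (is.na(hit)) {
      heads <- c(heads, i)
      sub[i] <- length(heads)
    } else {
      sub[i] <- hit
    }
  }
  sub
}

#' Sweep clustering thresholds above the base pass
#'
#' For each threshold `t` in `grid`, members of each base cluster whose
#' identity to the centroid is at least `t` remain with the centroid;
#' members below `t` re-cluster greedily among themselves (within the base
#' cluster) at `t`. A species is *resolved* at `t` when no MOTU at `t`
#' contains two or more species, and *unsplit* when all its records fall in
#' a single MOTU; both definitions are reported.
#'
#' @param assignments Output of [cluster_greedy()] at the grid minimum.
#' @param records The records that were clustered (sequences are needed to
#'   re-threshold within base clusters).
#' @param taxonomy Taxonomy tibble covering all records.
#' @param grid Integer percent thresholds; all must be at or above the base
#'   threshold used for `assignments`.
#' @param base_threshold The base threshold `assignments` were built with.
#' @return An object of class `threshold_sweep`: a list with
#'   `$species` (per threshold x species: `n_motus`, `resolved`,
#'   `resolved_unsplit`), `$orders` (per threshold x order: `n_species`,
#'   `n_resolved`, `percent_resolved`, `n_resolved_unsplit`,
#'   `percent_resolved_unsplit`) and `$motus` (per threshold: record ->
#'   MOTU id).
#' @export
threshold_sweep <- function(assignments, records, taxonomy, grid = 95:100,
                            base_threshold = 95) {
  records <- as_record_tbl(records)
  taxonomy <- validate_taxonomy(taxonomy)
  if (any(grid < base_threshold)) {
    stop("grid thresholds must all be >= the base threshold", call. = FALSE)
  }
  seqs <- stats::setNames(records$sequence, records$record_id)
  tax <- dplyr::select(taxonomy, "record_id", "species", "order")
  # per base cluster: member ids in greedy order (length desc, input order)
  base <- assignments |>
    dplyr::left_join(tibble::tibble(record_id = records$record_id,
                                    .len = nchar(records$sequence),
                                    .pos = seq_len(nrow(records))),
                     by = "record_id") |>
    dplyr::arrange(.data$cluster_id, -.data$.len, .data$.pos)
  clusters <- split(base, base$cluster_id)
  pw <- lapply(clusters, function(cl) {
    if (nrow(cl) > 1) .pairwise_identity(seqs[cl$record_id]) else NULL
  })
  motu_rows <- list()
  for (t in grid) {
    rows <- lapply(seq_along(clusters), function(ci) {
      cl <- clusters[[ci]]
      if (nrow(cl) == 1) {
        motu <- 1L
      } else {
        stay <- cl$identity >= t
        motu <- integer(nrow(cl))
        motu[stay] <- 1L
        if (any(!stay)) {
          dropped <- which(!stay)  # already in greedy order
          motu[dropped] <- 1L + .greedy_from_matrix(cl$record_id[dropped],
                                                    pw[[ci]], t)
        }
      }
      tibble::tibble(threshold = t, record_id = cl$record_id,
                     motu_id = sprintf("c%d_t%d_m%d", ci, t, motu))
    })
    motu_rows[[as.character(t)]] <- dplyr::bind_rows(rows)
  }
  motus <- dplyr::bind_rows(motu_rows) |>
    dplyr::left_join(tax, by = "record_id")
  motu_species <- motus |>
    dplyr::distinct(.data$threshold, .data$motu_id, .data$species) |>
    dplyr::add_count(.data$threshold, .data$motu_id, name = "n_species_in_motu")
  species_tbl <- motu_species |>
    dplyr::group_by(.data$threshold, .data$species) |>
    dplyr::summarise(
      n_motus = dplyr::n(),
      resolved = all(.data$n_species_in_motu == 1),
      .groups = "drop"
    ) |>
    dplyr::mutate(resolved_unsplit = .data$resolved & .data$n_motus == 1) |>
    dplyr::left_join(dplyr::distinct(tax, .data$species, .data$order), by = "species")
  orders_tbl <- species_tbl |>
    dplyr::group_by(.data$threshold, .data$order) |>
    dplyr::summarise(
      n_species = dplyr::n(),
      n_resolved = sum(.data$resolved),
      percent_resolved = 100 * mean(.data$resolved),
      n_resolved_unsplit = sum(.data$resolved_unsplit),
      percent_resolved_unsplit = 100 * mean(.data$resolved_unsplit),
      .groups = "drop"
    )
  structure(list(species = species_tbl, orders = orders_tbl, motus = motus,
                 grid = as.integer(grid), base_threshold = base_threshold),
            class = "threshold_sweep")
}

#' Full re-clustering cross-check for the threshold sweep
#'
#' Re-runs [cluster_greedy()] from scratch at each grid threshold and reports
#' the same per-species resolution table; used to validate the
#' re-thresholding shortcut of [threshold_sweep()].
#'
#' @inheritParams threshold_sweep
#' @return A tibble like `$species` of [threshold_sweep()].
#' @export
threshold_sweep_recluster <- function(records, taxonomy, grid = 95:100) {
  taxonomy <- validate_taxonomy(taxonomy)
  tax <- dplyr::select(taxonomy, "record_id", "species", "order")
  purrr::map(grid, function(t) {
    cl <- cluster_greedy(records, base_threshold = t)
    cl |>
      dplyr::left_join(tax, by = "record_id") |>
      dplyr::distinct(.data$cluster_id, .data$species) |>
      dplyr::add_count(.data$cluster_id, name = "n_species_in_motu") |>
      dplyr::group_by(.data$species) |>
      dplyr::summarise(n_motus = dplyr::n(),
                       resolved = all(.data$n_species_in_motu == 1),
                       .groups = "drop") |>
      dplyr::mutate(resolved_unsplit = .data$resolved & .data$n_motus == 1,
                    threshold = t, .before = 1)
  }) |> dplyr::bind_rows()
}

#' Order-level resolution matrix
#'
#' Rows are orders, columns are thresholds; cells hold the chosen metric.
#'
#' @param sweep A `threshold_sweep` object.
#' @param metric One of `"percent_resolved"`, `"n_resolved"`,
#'   `"percent_resolved_unsplit"`, `"n_resolved_unsplit"`.
#' @return A wide tibble, one row per order plus `n_species`.
#' @export
order_resolution_matrix <- function(sweep, metric = c("percent_resolved",
                                                      "n_resolved",
                                                      "percent_resolved_unsplit",
                                                      "n_resolved_unsplit")) {
  metric <- match.arg(metric)
  stopifnot(inherits(sweep, "threshold_sweep"))
  if (nrow(sweep$orders) == 0) stop("empty sweep: no orders to report", call. = FALSE)
  sweep$orders |>
    dplyr::select("order", "n_species", "threshold", dplyr::all_of(metric)) |>
    tidyr::pivot_wider(names_from = "threshold", values_from = dplyr::all_of(metric),
                       names_prefix = "t") |>
    dplyr::arrange(.data$order)
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf("<threshold_sweep> base %s%%, grid %s\n", x$base_threshold,
              paste(x$grid, collapse = ",")))
  print(order_resolution_matrix(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.threshold_sweep <- function(x, ...) x$species

#' @exportS3Method generics::glance
glance.threshold_sweep <- function(x, ...) {
  x$species |>
    dplyr::group_by(.data$threshold) |>
    dplyr::summarise(n_species = dplyr::n(),
                     percent_resolved = 100 * mean(.data$resolved),
                     percent_resolved_unsplit = 100 * mean(.data$resolved_unsplit),
                     .groups = "drop")
}

#' Heat-map of order-level resolution across thresholds
#'
#' @param object A `threshold_sweep` object.
#' @param metric Cell metric, see [order_resolution_matrix()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.threshold_sweep <- function(object, metric = "percent_resolved", ...) {
  dat <- object$orders
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$threshold), y = .data$order,
                                    fill = .data[[metric]])) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_resolved), size = 3) +
    ggplot2::scale_fill_gradient(low = "firebrick", high = "palegreen3",
                                 limits = c(0, 100)) +
    ggplot2::labs(x = "clustering threshold (%)", y = NULL, fill = metric) +
    ggplot2::theme_minimal()
}
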