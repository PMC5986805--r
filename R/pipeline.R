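# End-to-end orchestration: simulate/load -> in silico PCR -> coverage and
# length tables -> resolution -> threshold sweep -> (optional) assignment and
# length-bias comparison, with stage TSVs and a reproducibility manifest.

#' Run the full primer-evaluation pipeline
#'
#' Executes every analysis stage on either a synthetic database (config
#' section `simulation`) or user-supplied files (config section `input` with
#' `fasta` and `taxonomy` paths), writing one TSV per stage plus a JSON-like
#' YAML manifest with input/output checksums. Re-running with the same
#' config and seed reproduces byte-identical stage outputs.
#'
#' The config is a nested list (or path to a YAML file) with sections:
#' \describe{
#'   \item{seed}{integer; seeds every stochastic stage.}
#'   \item{simulation}{arguments for [simulation_spec()] (optional).}
#'   \item{input}{`fasta` and `taxonomy` paths (optional; exactly one of
#'     `simulation`/`input` is required).}
#'   \item{pcr}{`max_mismatches`, `anchor_len`, `min_insert`, `max_insert`.}
#'   \item{clustering}{`base_threshold`, `grid`.}
#'   \item{assignment}{optional: `diet` (named weights), `n_reads`,
#'     `error_rate`, `max_truncation`, `contaminant_fraction`,
#'     `min_identity`.}
#' }
#'
#' @param config A nested list or a path to a YAML config file.
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly: a list with the config snapshot, per
#'   stage output paths and md5 checksums, record counts per PCR status, and
#'   the headline summary tibble (also written to `summary.tsv`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config), call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  paths <- list()
  emit <- function(name, tbl) {
    p <- file.path(out_dir, paste0(name, ".tsv"))
    readr::write_tsv(tbl, p, progress = FALSE)
    paths[[name]] <<- p
    tbl
  }

  # --- stage: load or simulate the reference database -----------------------
  truth <- NULL
  if (!is.null(config$simulation)) {
    db <- stage("simulate", {
      spec <- do.call(simulation_spec, c(config$simulation, list(rng_seed = seed)))
      simulate_refdb(spec)
    })
    records <- db$records
    taxonomy <- db$taxonomy
    truth <- db$truth
    emit("truth", truth)
  } else if (!is.null(config$input)) {
    records <- stage("load", {
      if (is.null(config$input$fasta) || !file.exists(config$input$fasta)) {
        stop(sprintf("input FASTA missing: %s", config$input$fasta %||% "<unset>"))
      }
      read_fasta(config$input$fasta)
    })
    taxonomy <- stage("load", {
      if (is.null(config$input$taxonomy) || !file.exists(config$input$taxonomy)) {
        stop(sprintf("input taxonomy missing: %s", config$input$taxonomy %||% "<unset>"))
      }
      read_taxonomy(config$input$taxonomy)
    })
  } else {
    stop("config must provide either 'simulation' or 'input'", call. = FALSE)
  }
  emit("records", dplyr::select(records, -"sequence"))

  primers <- uniplant_primers()
  pcr_cfg <- do.call(pcr_config, config$pcr %||% list())

  # --- stage: in silico PCR --------------------------------------------------
  pcr <- stage("insilico_pcr", insilico_pcr(records, primers$fwd, primers$rev, pcr_cfg))
  emit("pcr_results", pcr)
  status_counts <- dplyr::count(pcr, .data$status, name = "n_records")
  message(sprintf("[insilico_pcr] %d records: %s", nrow(pcr),
                  paste(sprintf("%s=%d", status_counts$status, status_counts$n_records),
                        collapse = ", ")))

  pcr_target <- dplyr::semi_join(pcr, taxonomy, by = "record_id")
  fit_species <- stage("coverage", summarize_fit_by_rank(pcr_target, taxonomy, "species"))
  fit_family <- stage("coverage", summarize_fit_by_rank(pcr_target, taxonomy, "family"))
  emit("fit_by_species", fit_species)
  emit("fit_by_family", fit_family)
  lengths_tbl <- stage("lengths", amplicon_length_table(pcr_target, taxonomy))
  emit("length_table", lengths_tbl)

  # --- stage: taxonomic resolution on dereplicated inserts -------------------
  inserts <- stage("resolution", {
    extract_amplicons(records, pcr_target) |>
      dplyr::transmute(record_id = .data$record_id, sequence = .data$insert)
  })
  res_report <- stage("resolution", {
    dedup <- deduplicate_same_species(inserts, taxonomy)
    taxonomic_resolution(derep_prefix(dedup), taxonomy)
  })
  emit("resolution", tibble::as_tibble(res_report))
  emit("unresolved_taxa", unresolved_taxa(res_report))

  # --- stage: clustering threshold sweep -------------------------------------
  cl_cfg <- config$clustering %||% list()
  base_thr <- cl_cfg$base_threshold %||% 95
  grid <- as.integer(cl_cfg$grid %||% 95:100)
  sweep <- stage("threshold_sweep", {
    assignments <- cluster_greedy(inserts, base_threshold = base_thr)
    threshold_sweep(assignments, inserts, taxonomy, grid = grid,
                    base_threshold = base_thr)
  })
  emit("sweep_orders", sweep$orders)
  emit("sweep_species", sweep$species)
  emit("sweep_matrix", order_resolution_matrix(sweep))

  # --- stage: optional diet-read assignment + length bias --------------------
  assign_tbl <- NULL
  length_cmp <- NULL
  if (!is.null(config$assignment) && !is.null(truth)) {
    acfg <- config$assignment
    sim_reads <- stage("assignment", {
      diet <- unlist(acfg$diet)
      simulate_diet_reads(
        structure(list(records = records, taxonomy = taxonomy,
                       truth = truth, spec = NULL), class = "synthetic_refdb"),
        diet = diet,
        n_reads = acfg$n_reads %||% 1000,
        error_rate = acfg$error_rate %||% 0.01,
        max_truncation = acfg$max_truncation %||% 0.1,
        contaminant_fraction = acfg$contaminant_fraction %||% 0,
        seed = seed + 1L
      )
    })
    assign_tbl <- stage("assignment", {
      assign_best_match(sim_reads$reads, records, taxonomy,
                        min_identity = acfg$min_identity %||% 90,
                        method = "prescreen")
    })
    emit("assignments", assign_tbl)
    length_cmp <- stage("length_bias", {
      obs <- nchar(sim_reads$reads$sequence)
      ref <- dplyr::filter(truth, !.data$is_contaminant)$insert_length
      compare_length_distributions(obs, ref)
    })
    emit("length_bias_summary", glance(length_cmp))
  }

  # --- headline summary ------------------------------------------------------
  total_row <- dplyr::filter(fit_species, .data$species == "Total")
  res_tbl <- tibble::as_tibble(res_report)
  summary_tbl <- tibble::tibble(
    metric = c("species_tested", "species_coverage_percent",
               paste0(res_tbl$rank, "_resolution_percent")),
    value = c(total_row$n_tested, total_row$percent_matched,
              res_tbl$percent_resolved)
  )
  emit("summary", summary_tbl)

  manifest <- list(
    seed = seed,
    config = config,
    n_records = nrow(records),
    status_counts = stats::setNames(as.list(status_counts$n_records),
                                    status_counts$status),
    outputs = lapply(paths, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    versions = list(
      ampliscreen = as.character(utils::packageVersion("ampliscreen")),
      R = paste(R.version$major, R.version$minor, sep = ".")
    )
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  manifest$summary <- summary_tbl
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
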