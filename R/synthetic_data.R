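# Synthetic ITS2-like reference databases and read sets with planted truth.
#
# Every species' record is [5' flank | forward priming site with a planted
# mismatch count | insert | reverse-complemented reverse priming site with a
# planted mismatch count | 3' flank]. Inserts evolve down the taxonomy by
# substitutions placed in disjoint per-branch position blocks, which makes
# pairwise divergences additive and exactly recoverable: haplotypes of one
# species differ at 2h sites, congeneric species at 2(m+h), confamilial
# genera at 2(g+m+h), with h/m/g derived from the requested intraspecific,
# congeneric and congeneric-genus divergences. Families receive independent
# random ancestor inserts (each with its own length), so between-family
# identity sits at the random background level.

#' Specification for a synthetic reference database
#'
#' Defaults emulate a short-amplicon plant ITS2 reference database: insert
#' lengths (amplicon minus priming sites) around 290 bp within 187-387 bp,
#' ~0.5% intraspecific divergence, ~3% between congeners, ~8% between
#' confamilial genera, most species carrying 0 primer mismatches and 12%
#' failing the fit criteria outright, and ~5% non-target (fungal-like)
#' contaminant sequences without priming sites.
#'
#' @param n_families,genera_per_family,species_per_genus Taxonomy shape.
#' @param families_per_order Families are grouped into orders of this size.
#' @param haplotypes_per_species Either a single count or a named probability
#'   vector (names = haplotype counts) sampled per species.
#' @param insert_mean,insert_sd,insert_min,insert_max Insert length
#'   distribution (bp); one length is drawn per family (truncated normal).
#' @param d_intra,d_species,d_genus,d_family Pairwise divergence targets
#'   (proportions) between haplotypes, congeneric species, confamilial
#'   genera, and families; must be strictly increasing. `d_family` is
#'   nominal: families are generated independently.
#' @param mismatch_probs Named probability vector over planted per-primer
#'   mismatch counts; the last class (name `"4"`) plants a failing site
#'   (>3 mismatches or a broken 3' anchor). Species are apportioned to
#'   classes exactly (largest remainder), not sampled, so planted coverage
#'   is exact.
#' @param anchor_break_prob Within the failing class, probability that the
#'   failure is a broken 3' anchor rather than 4 mismatches.
#' @param contaminant_fraction Fraction of emitted records that are
#'   non-target contaminants (no priming sites, excluded from the taxonomy).
#' @param truncation_fraction Fraction of target records truncated to span
#'   only one priming region.
#' @param n_identical_pairs Number of within-genus species pairs planted
#'   with identical sequence sets (for resolution analyses).
#' @param flank_len Length range (min, max) of the random flanks.
#' @param rng_seed Integer seed; identical spec + seed gives identical output.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_families = 10L, genera_per_family = 2L,
                            species_per_genus = 3L, families_per_order = 2L,
                            haplotypes_per_species = 2L,
                            insert_mean = 290, insert_sd = 25,
                            insert_min = 187, insert_max = 387,
                            d_intra = 0.005, d_species = 0.03,
                            d_genus = 0.08, d_family = 0.15,
                            mismatch_probs = c(`0` = 0.70, `1` = 0.10,
                                               `2` = 0.05, `3` = 0.03,
                                               `4` = 0.12),
                            anchor_break_prob = 0.25,
                            contaminant_fraction = 0.05,
                            truncation_fraction = 0,
                            n_identical_pairs = 0L,
                            flank_len = c(20L, 35L),
                            rng_seed = 1L) {
  if (n_families < 1 || genera_per_family < 1 || species_per_genus < 1) {
    stop("taxonomy counts must all be positive", call. = FALSE)
  }
  if (!(d_intra < d_species && d_species < d_genus && d_genus < d_family)) {
    stop("divergences must satisfy d_intra < d_species < d_genus < d_family",
         call. = FALSE)
  }
  if (abs(sum(mismatch_probs) - 1) > 1e-8) {
    stop("mismatch_probs must sum to 1", call. = FALSE)
  }
  if (is.null(names(mismatch_probs))) {
    stop("mismatch_probs must be named by mismatch count", call. = FALSE)
  }
  if (insert_min > insert_max) {
    stop("insert bounds incompatible: insert_min > insert_max", call. = FALSE)
  }
  if (insert_sd == 0 && (insert_mean < insert_min || insert_mean > insert_max)) {
    stop("insert bounds incompatible: fixed insert_mean outside [insert_min, insert_max]",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  n_sp <- x$n_families * x$genera_per_family * x$species_per_genus
  cat(sprintf("<simulation_spec> %d families x %d genera x %d species = %d species (seed %d)\n",
              x$n_families, x$genera_per_family, x$species_per_genus, n_sp, x$rng_seed))
  invisible(x)
}

# exact apportionment of n units to classes by largest remainder
.apportion <- function(probs, n) {
  quota <- probs * n
  counts <- floor(quota)
  left <- n - sum(counts)
  if (left > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(left)]
    counts[extra] <- counts[extra] + 1
  }
  stats::setNames(as.integer(counts), names(probs))
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute the given 1-based positions of a sequence with different bases
.substitute_at <- function(seq_chars, positions) {
  for (p in positions) {
    seq_chars[p] <- sample(setdiff(c("A", "C", "G", "T"), seq_chars[p]), 1)
  }
  seq_chars
}

#' Simulate a taxonomy table (species level)
#'
#' Systematic labels: species `Sp<fam>_<gen>_<sp>`, genus `Gen<fam>_<gen>`,
#' family `Fam<fam>`, order `Ord<n>`. Deterministic (no randomness).
#'
#' @param spec A [simulation_spec()].
#' @return A tibble with one row per species: `species`, `genus`, `family`,
#'   `order`.
#' @export
simulate_taxonomy <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  purrr::map(seq_len(spec$n_families), function(f) {
    ord <- sprintf("Ord%02d", ceiling(f / spec$families_per_order))
    fam <- sprintf("Fam%02d", f)
    purrr::map(seq_len(spec$genera_per_family), function(g) {
      tibble::tibble(
        species = sprintf("Sp%02d_%d_%d", f, g, seq_len(spec$species_per_genus)),
        genus = sprintf("Gen%02d_%d", f, g),
        family = fam, order = ord
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

# plant `k` mismatches into one literal expansion of `primer`; anchor_break
# plants one mismatch inside the 3' anchor instead. Returns list(site,
# mismatches, anchor_ok) where `site` is written 5'->3' alongside the primer.
.plant_primer_site <- function(primer, k, anchor_break, anchor_len = 2L) {
  lit <- strsplit(sample(expand_degenerate(primer$sequence), 1), "")[[1]]
  masks <- seq_to_mask(primer$sequence)
  len <- primer$length
  non_anchor <- seq_len(len - anchor_len)
  mutate_out_of_set <- function(chars, pos) {
    for (p in pos) {
      allowed <- c("A", "C", "G", "T")[bitwAnd(masks[p], c(1L, 2L, 4L, 8L)) > 0L]
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), allowed), 1)
    }
    chars
  }
  if (anchor_break) {
    pos <- sample((len - anchor_len + 1L):len, 1)
    lit <- mutate_out_of_set(lit, pos)
    list(site = paste(lit, collapse = ""), mismatches = 1L, anchor_ok = FALSE)
  } else {
    pos <- if (k > 0) sample(non_anchor, k) else integer(0)
    lit <- mutate_out_of_set(lit, pos)
    list(site = paste(lit, collapse = ""), mismatches = as.integer(k), anchor_ok = TRUE)
  }
}

#' Simulate a reference database with planted ground truth
#'
#' See [simulation_spec()] for the generative model. Contaminant records
#' appear in `$records` and `$truth` but not in `$taxonomy` (the taxonomy
#' covers the curated target flora only). Every emitted record has exactly
#' one truth row.
#'
#' @param spec A [simulation_spec()].
#' @param fwd,rev The primer pair to plant (defaults: the UniPlant pair).
#' @return A list of class `synthetic_refdb`: `$records` (records tibble),
#'   `$taxonomy` (record-level taxonomy of target records), `$truth`
#'   (per-record planted parameters: taxonomy, haplotype index, planted
#'   per-primer mismatches and anchor status, `primer_fit`, insert
#'   coordinates and length, `is_contaminant`, `truncation`), and `$spec`.
#' @export
simulate_refdb <- function(spec, fwd = uniplant_primers()$fwd,
                           rev = uniplant_primers()$rev) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$rng_seed)
  taxa <- simulate_taxonomy(spec)
  n_sp <- nrow(taxa)

  # exact apportionment of species to planted mismatch classes
  class_counts <- .apportion(spec$mismatch_probs, n_sp)
  class_per_species <- sample(rep(names(class_counts), class_counts))
  names(class_per_species) <- taxa$species

  hap_n <- spec$haplotypes_per_species
  hap_per_species <- if (length(hap_n) == 1 && is.null(names(hap_n))) {
    rep(as.integer(hap_n), n_sp)
  } else {
    as.integer(sample(names(hap_n), n_sp, replace = TRUE, prob = hap_n))
  }
  names(hap_per_species) <- taxa$species

  config <- pcr_config()
  max_mm <- config$max_mismatches
  draw_insert_len <- function() {
    if (spec$insert_sd == 0) return(as.integer(round(spec$insert_mean)))
    for (i in 1:1000) {
      L <- as.integer(round(stats::rnorm(1, spec$insert_mean, spec$insert_sd)))
      if (L >= spec$insert_min && L <= spec$insert_max) return(L)
    }
    stop("insert bounds incompatible: truncated normal rejection failed", call. = FALSE)
  }

  fam_groups <- split(taxa, taxa$family)[unique(taxa$family)]
  rec_rows <- list()
  truth_rows <- list()
  for (fam in names(fam_groups)) {
    ft <- fam_groups[[fam]]
    L <- draw_insert_len()
    h <- max(0L, as.integer(round(L * spec$d_intra / 2)))
    m <- max(0L, as.integer(round(L * spec$d_species / 2)) - h)
    g <- max(0L, as.integer(round(L * spec$d_genus / 2)) - m - h)
    genera <- unique(ft$genus)
    n_hap_fam <- sum(hap_per_species[ft$species])
    need <- length(genera) * g + nrow(ft) * m + n_hap_fam * h
    for (attempt in 1:25) {
      ancestor <- strsplit(.random_dna(L), "")[[1]]
      # disjoint position blocks make pairwise distances exactly additive;
      # fall back to independent draws if a family needs more sites than L
      pool <- if (need <= L) sample(seq_len(L)) else NULL
      take <- function(nn) {
        if (nn == 0) return(integer(0))
        if (is.null(pool)) return(sample(seq_len(L), nn))
        out <- pool[seq_len(nn)]
        pool <<- pool[-seq_len(nn)]
        out
      }
      fam_rec <- list()
      fam_truth <- list()
      ok <- TRUE
      for (gen in genera) {
        gen_chars <- .substitute_at(ancestor, take(g))
        gt <- ft[ft$genus == gen, ]
        for (si in seq_len(nrow(gt))) {
          sp <- gt$species[si]
          sp_chars <- .substitute_at(gen_chars, take(m))
          cls <- class_per_species[[sp]]
          passes <- cls %in% as.character(0:max_mm)
          anchor_break <- !passes && stats::runif(1) < spec$anchor_break_prob
          k <- if (passes) as.integer(cls) else max_mm + 1L
          fsite <- .plant_primer_site(fwd, k, anchor_break, config$anchor_len)
          rsite <- .plant_primer_site(rev, k, anchor_break, config$anchor_len)
          flank5 <- .random_dna(sample(spec$flank_len[1]:spec$flank_len[2], 1))
          flank3 <- .random_dna(sample(spec$flank_len[1]:spec$flank_len[2], 1))
          for (hi in seq_len(hap_per_species[[sp]])) {
            hap_chars <- .substitute_at(sp_chars, take(h))
            insert <- paste(hap_chars, collapse = "")
            seqfull <- paste0(flank5, fsite$site, insert,
                              reverse_complement(rsite$site), flank3)
            rid <- sprintf("%s_h%d", sp, hi)
            fam_rec[[rid]] <- tibble::tibble(record_id = rid,
                                             accession = NA_character_,
                                             sequence = seqfull,
                                             truncation = "full")
            fam_truth[[rid]] <- tibble::tibble(
              record_id = rid, species = sp, genus = gen, family = fam,
              order = gt$order[si], haplotype = hi,
              fwd_mismatches = fsite$mismatches, rev_mismatches = rsite$mismatches,
              fwd_anchor_ok = fsite$anchor_ok, rev_anchor_ok = rsite$anchor_ok,
              primer_fit = passes,
              insert_start = nchar(flank5) + fwd$length,
              insert_end = nchar(flank5) + fwd$length + L,
              insert_length = L,
              is_contaminant = FALSE, truncation = "full"
            )
          }
        }
      }
      fam_rec <- dplyr::bind_rows(fam_rec)
      fam_truth <- dplyr::bind_rows(fam_truth)
      # consistency guard: planted sites must be the only sites the screen sees
      chk <- insilico_pcr(fam_rec, fwd, rev, config)
      chk <- dplyr::left_join(chk, fam_truth, by = "record_id")
      good <- ifelse(chk$primer_fit,
                     chk$status == "MATCH" &
                       chk$fwd_mismatches.x == chk$fwd_mismatches.y &
                       chk$rev_mismatches.x == chk$rev_mismatches.y &
                       chk$insert_length.x == chk$insert_length.y,
                     chk$status != "MATCH")
      if (all(good)) { ok <- TRUE; break }
      ok <- FALSE
    }
    if (!ok) stop(sprintf("could not realize planted truth for family %s", fam),
                  call. = FALSE)
    rec_rows[[fam]] <- fam_rec
    truth_rows[[fam]] <- fam_truth
  }
  records <- dplyr::bind_rows(rec_rows)
  truth <- dplyr::bind_rows(truth_rows)

  # planted identical-sequence species pairs (within genus)
  if (spec$n_identical_pairs > 0) {
    if (spec$species_per_genus < 2) {
      stop("identical pairs need species_per_genus >= 2", call. = FALSE)
    }
    genera <- unique(taxa$genus)
    if (length(genera) < spec$n_identical_pairs) {
      stop("not enough genera for the requested identical pairs", call. = FALSE)
    }
    chosen <- sample(genera, spec$n_identical_pairs)
    for (gen in chosen) {
      sps <- taxa$species[taxa$genus == gen][1:2]
      src <- truth$record_id[truth$species == sps[1]]
      dst <- truth$record_id[truth$species == sps[2]]
      n_copy <- min(length(src), length(dst))
      # drop extra target haplotypes, then mirror the source records
      drop <- setdiff(dst, dst[seq_len(n_copy)])
      records <- records[!records$record_id %in% drop, ]
      truth <- truth[!truth$record_id %in% drop, ]
      for (i in seq_len(n_copy)) {
        records$sequence[records$record_id == dst[i]] <-
          records$sequence[records$record_id == src[i]]
        cols <- c("fwd_mismatches", "rev_mismatches", "fwd_anchor_ok",
                  "rev_anchor_ok", "primer_fit", "insert_start", "insert_end",
                  "insert_length")
        truth[truth$record_id == dst[i], cols] <-
          truth[truth$record_id == src[i], cols]
      }
    }
  }

  # truncation to a single priming region
  n_trunc <- round(spec$truncation_fraction * nrow(records))
  if (n_trunc > 0) {
    pick <- sample(nrow(records), n_trunc)
    for (j in seq_along(pick)) {
      i <- pick[j]
      tr <- truth[truth$record_id == records$record_id[i], ]
      half <- tr$insert_start + floor(tr$insert_length / 2)
      if (j %% 2 == 1) {
        records$sequence[i] <- substr(records$sequence[i], 1, half)
        records$truncation[i] <- "forward_only"
      } else {
        records$sequence[i] <- substr(records$sequence[i], half + 1,
                                      nchar(records$sequence[i]))
        records$truncation[i] <- "reverse_only"
      }
      truth$truncation[truth$record_id == records$record_id[i]] <-
        records$truncation[i]
    }
  }

  # non-target contaminants: no priming sites, absent from the taxonomy
  n_cont <- round(spec$contaminant_fraction * nrow(records) /
                    (1 - spec$contaminant_fraction))
  if (n_cont > 0) {
    cont <- purrr::map(seq_len(n_cont), function(i) {
      for (attempt in 1:25) {
        len <- sample(seq(spec$insert_min, spec$insert_max), 1) +
          fwd$length + rev$length
        s <- .random_dna(len)
        res <- simulate_pcr(s, fwd, rev, config, record_id = "tmp")
        if (res$status == "NO_SITE") {
          return(tibble::tibble(record_id = sprintf("Cont%03d", i),
                                accession = NA_character_,
                                sequence = s, truncation = "full"))
        }
      }
      stop("could not generate a contaminant without priming sites", call. = FALSE)
    }) |> dplyr::bind_rows()
    records <- dplyr::bind_rows(records, cont)
    truth <- dplyr::bind_rows(truth, tibble::tibble(
      record_id = cont$record_id, species = NA_character_,
      genus = NA_character_, family = NA_character_, order = NA_character_,
      haplotype = NA_integer_, fwd_mismatches = NA_integer_,
      rev_mismatches = NA_integer_, fwd_anchor_ok = NA, rev_anchor_ok = NA,
      primer_fit = FALSE, insert_start = NA_integer_, insert_end = NA_integer_,
      insert_length = nchar(cont$sequence) - fwd$length - rev$length,
      is_contaminant = TRUE, truncation = "full"
    ))
  }

  taxonomy <- truth |>
    dplyr::filter(!.data$is_contaminant) |>
    dplyr::select("record_id", "species", "genus", "family", "order")
  structure(list(records = records, taxonomy = validate_taxonomy(taxonomy),
                 truth = truth, spec = spec),
            class = "synthetic_refdb")
}

#' @export
print.synthetic_refdb <- function(x, ...) {
  cat(sprintf("<synthetic_refdb> %d records (%d contaminants), %d species, seed %d\n",
              nrow(x$records), sum(x$truth$is_contaminant),
              dplyr::n_distinct(stats::na.omit(x$truth$species)), x$spec$rng_seed))
  invisible(x)
}

#' Simulate degraded diet reads from a known species mixture
#'
#' Reads are sampled from the amplicon inserts of the named species in
#' proportion to their weights (multinomially), 3'-truncated by a uniform
#' fraction up to `max_truncation`, and perturbed by uniform substitution
#' errors. Optionally a fraction of non-target contaminant reads (random
#' composition, no counterpart in the database) is mixed in.
#'
#' @param refdb A `synthetic_refdb`.
#' @param diet Named numeric vector: species -> mixture weight.
#' @param n_reads Total number of reads.
#' @param error_rate Per-base substitution probability (capped at 0.1).
#' @param max_truncation Maximum fraction of the insert removed from the
#'   3' end (uniform per read).
#' @param contaminant_fraction Fraction of reads that are non-target.
#' @param sample_id Sample label attached to every read.
#' @param seed Integer seed.
#' @return A list of class `synthetic_reads`: `$reads` (tibble `record_id`,
#'   `sequence`, `sample_id`) and `$truth` (per read: source species and
#'   record, error/truncation counts, `is_contaminant`).
#' @export
simulate_diet_reads <- function(refdb, diet, n_reads = 1000,
                                error_rate = 0.01, max_truncation = 0.1,
                                contaminant_fraction = 0,
                                sample_id = "sample1", seed = 1L) {
  stopifnot(inherits(refdb, "synthetic_refdb"))
  if (length(diet) == 0) stop("diet must name at least one species", call. = FALSE)
  if (is.null(names(diet)) || any(!nzchar(names(diet)))) {
    stop("diet must be a named species -> weight vector", call. = FALSE)
  }
  if (error_rate > 0.1) stop("error_rate above 0.1 is not supported", call. = FALSE)
  known <- unique(stats::na.omit(refdb$truth$species))
  missing <- setdiff(names(diet), known)
  if (length(missing) > 0) {
    stop(sprintf("diet species not in the reference database: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  set.seed(seed)
  n_cont <- round(n_reads * contaminant_fraction)
  n_plant <- n_reads - n_cont
  counts <- stats::rmultinom(1, n_plant, diet / sum(diet))[, 1]
  # usable source records: full-length, with planted inserts
  src_tbl <- refdb$truth |>
    dplyr::filter(!.data$is_contaminant, .data$truncation == "full",
                  .data$species %in% names(diet))
  seqs <- stats::setNames(refdb$records$sequence, refdb$records$record_id)
  reads <- list()
  truths <- list()
  ridx <- 0L
  for (sp in names(counts)) {
    for (r in seq_len(counts[[sp]])) {
      ridx <- ridx + 1L
      cand <- src_tbl[src_tbl$species == sp, ]
      row <- cand[sample(nrow(cand), 1), ]
      insert <- substr(seqs[[row$record_id]], row$insert_start + 1L, row$insert_end)
      cut <- floor(stats::runif(1, 0, max_truncation) * nchar(insert))
      read <- substr(insert, 1, nchar(insert) - cut)
      chars <- strsplit(read, "")[[1]]
      err_pos <- which(stats::runif(length(chars)) < error_rate)
      chars <- .substitute_at(chars, err_pos)
      rid <- sprintf("read%06d", ridx)
      reads[[rid]] <- tibble::tibble(record_id = rid,
                                     sequence = paste(chars, collapse = ""),
                                     sample_id = sample_id)
      truths[[rid]] <- tibble::tibble(read_id = rid, species = sp,
                                      source_record = row$record_id,
                                      n_errors = length(err_pos),
                                      trunc_bases = cut,
                                      is_contaminant = FALSE,
                                      sample_id = sample_id)
    }
  }
  for (c in seq_len(n_cont)) {
    ridx <- ridx + 1L
    rid <- sprintf("read%06d", ridx)
    len <- sample(150:350, 1)
    reads[[rid]] <- tibble::tibble(record_id = rid, sequence = .random_dna(len),
                                   sample_id = sample_id)
    truths[[rid]] <- tibble::tibble(read_id = rid, species = NA_character_,
                                    source_record = NA_character_,
                                    n_errors = NA_integer_, trunc_bases = NA_integer_,
                                    is_contaminant = TRUE, sample_id = sample_id)
  }
  structure(list(reads = dplyr::bind_rows(reads),
                 truth = dplyr::bind_rows(truths)),
            class = "synthetic_reads")
}

#' Simulate mock-community designs
#'
#' Builds 6-species mock communities across three treatments balancing
#' amplicon length classes: `equal` (3 long + 3 short), `short_bias`
#' (2 long + 4 short) and `long_bias` (4 long + 2 short). Species with
#' insert lengths of 267-280 bp are classified short and 310-336 bp long;
#' at least 4 species per class are required.
#'
#' @param refdb A `synthetic_refdb`.
#' @param n_per_treatment Communities per treatment (default 5, so 15 total).
#' @param seed Integer seed.
#' @return A design tibble: `community_id`, `treatment`, `species`,
#'   `length_class`, `insert_length`.
#' @export
simulate_mock_communities <- function(refdb, n_per_treatment = 5L, seed = 1L) {
  stopifnot(inherits(refdb, "synthetic_refdb"))
  set.seed(seed)
  sp_len <- refdb$truth |>
    dplyr::filter(!.data$is_contaminant) |>
    dplyr::distinct(.data$species, .data$insert_length) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(insert_length = .data$insert_length[1], .groups = "drop")
  short <- sp_len |> dplyr::filter(.data$insert_length >= 267, .data$insert_length <= 280)
  long <- sp_len |> dplyr::filter(.data$insert_length >= 310, .data$insert_length <= 336)
  if (nrow(short) < 4 || nrow(long) < 4) {
    stop(sprintf("need >= 4 species per length class (have %d short, %d long)",
                 nrow(short), nrow(long)), call. = FALSE)
  }
  design <- list(equal = c(long = 3, short = 3),
                 short_bias = c(long = 2, short = 4),
                 long_bias = c(long = 4, short = 2))
  cid <- 0L
  out <- list()
  for (treat in names(design)) {
    for (i in seq_len(n_per_treatment)) {
      cid <- cid + 1L
      pick_long <- long[sample(nrow(long), design[[treat]][["long"]]), ]
      pick_short <- short[sample(nrow(short), design[[treat]][["short"]]), ]
      out[[cid]] <- dplyr::bind_rows(
        dplyr::mutate(pick_long, length_class = "long"),
        dplyr::mutate(pick_short, length_class = "short")
      ) |>
        dplyr::mutate(community_id = sprintf("MC%02d", cid),
                      treatment = treat, .before = 1)
    }
  }
  dplyr::bind_rows(out) |>
    dplyr::select("community_id", "treatment", "species", "length_class",
                  "insert_length")
}
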