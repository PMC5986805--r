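test_that("simulated taxonomy has the requested shape and is consistent", {
  spec <- simulation_spec(n_families = 2, genera_per_family = 2,
                          species_per_genus = 2)
  taxa <- simulate_taxonomy(spec)
  expect_equal(nrow(taxa), 8)
  expect_equal(dplyr::n_distinct(taxa$genus), 4)
  expect_equal(dplyr::n_distinct(taxa$family), 2)
  expect_equal(simulate_taxonomy(spec), taxa)  # deterministic
  expect_error(simulation_spec(n_families = 0), "positive")
})

test_that("spec validation catches inconsistent parameters", {
  expect_error(simulation_spec(d_intra = 0.05, d_species = 0.03), "d_intra")
  expect_error(simulation_spec(mismatch_probs = c(`0` = 0.5, `4` = 0.4)), "sum to 1")
  expect_error(simulation_spec(insert_min = 400, insert_max = 300), "incompatible")
  expect_error(simulation_spec(insert_mean = 600, insert_sd = 0), "incompatible")
})

test_that("every record carries exactly one truth row and ids are unique", {
  spec <- simulation_spec(n_families = 3, genera_per_family = 2,
                          species_per_genus = 2, truncation_fraction = 0.2,
                          rng_seed = 61)
  db <- simulate_refdb(spec)
  expect_setequal(db$records$record_id, db$truth$record_id)
  expect_equal(anyDuplicated(db$records$record_id), 0L)
  expect_true(all(db$taxonomy$record_id %in% db$records$record_id))
  expect_false(any(db$truth$is_contaminant[db$truth$record_id %in% db$taxonomy$record_id]))
  # truncated records are flagged in records and truth alike
  expect_equal(db$records$truncation[match(db$truth$record_id, db$records$record_id)],
               db$truth$truncation)
})

test_that("identical spec and seed give byte-identical databases", {
  spec <- simulation_spec(n_families = 2, genera_per_family = 2,
                          species_per_genus = 3, rng_seed = 62)
  expect_equal(simulate_refdb(spec)$records, simulate_refdb(spec)$records)
  expect_equal(simulate_refdb(spec)$truth, simulate_refdb(spec)$truth)
})

test_that("planted primer-fit classes are recovered by the screen", {
  spec <- simulation_spec(n_families = 5, genera_per_family = 2,
                          species_per_genus = 2, haplotypes_per_species = 1,
                          mismatch_probs = c(`0` = 0.5, `2` = 0.25, `4` = 0.25),
                          contaminant_fraction = 0, rng_seed = 63)
  db <- simulate_refdb(spec)
  p <- uniplant_primers()
  pcr <- insilico_pcr(db$records, p$fwd, p$rev)
  joined <- dplyr::inner_join(pcr, db$truth, by = "record_id")
  expect_equal(joined$status == "MATCH", joined$primer_fit)
  ok <- joined[joined$primer_fit, ]
  expect_equal(ok$fwd_mismatches.x, ok$fwd_mismatches.y)
  expect_equal(ok$insert_length.x, ok$insert_length.y)
  # exact apportionment: 20 species -> 10 / 5 / 5
  expect_equal(sum(joined$primer_fit), 15L)
})

test_that("realized pairwise identities sit at the planted divergences", {
  spec <- simulation_spec(n_families = 2, genera_per_family = 2,
                          species_per_genus = 2, haplotypes_per_species = 2,
                          mismatch_probs = c(`0` = 1), contaminant_fraction = 0,
                          rng_seed = 64)
  db <- simulate_refdb(spec)
  p <- uniplant_primers()
  ins <- extract_amplicons(db$records, insilico_pcr(db$records, p$fwd, p$rev))
  seqs <- stats::setNames(ins$insert, ins$record_id)
  tr <- db$truth
  intra <- global_identity(seqs[["Sp01_1_1_h1"]], seqs[["Sp01_1_1_h2"]])
  congener <- global_identity(seqs[["Sp01_1_1_h1"]], seqs[["Sp01_1_2_h1"]])
  crossgenus <- global_identity(seqs[["Sp01_1_1_h1"]], seqs[["Sp01_2_1_h1"]])
  expect_lt(abs(intra - 99.5), 0.5)
  expect_lt(abs(congener - 97), 0.5)
  expect_lt(abs(crossgenus - 92), 0.7)
})

test_that("diet reads follow the mixture and respect caps", {
  spec <- simulation_spec(n_families = 3, genera_per_family = 2,
                          species_per_genus = 2, haplotypes_per_species = 1,
                          mismatch_probs = c(`0` = 1), contaminant_fraction = 0,
                          rng_seed = 65)
  db <- simulate_refdb(spec)
  expect_error(simulate_diet_reads(db, c(Sp01_1_1 = 1), error_rate = 0.5),
               "error_rate")
  expect_error(simulate_diet_reads(db, numeric(0)), "at least one")
  expect_error(simulate_diet_reads(db, c(NotASpecies = 1)), "not in the reference")

  # single-species, error-free, untruncated reads are exact insert copies
  one <- simulate_diet_reads(db, c(Sp01_1_1 = 1), n_reads = 10, error_rate = 0,
                             max_truncation = 0, seed = 66)
  tr <- db$truth[db$truth$record_id == "Sp01_1_1_h1", ]
  insert <- substr(db$records$sequence[db$records$record_id == "Sp01_1_1_h1"],
                   tr$insert_start + 1, tr$insert_end)
  expect_equal(unique(one$reads$sequence), insert)
  expect_equal(unique(one$truth$species), "Sp01_1_1")

  # mixture proportions within multinomial error; truth covers every read
  diet <- c(Sp01_1_1 = 3, Sp02_1_1 = 1, Sp03_2_2 = 1)
  mix <- simulate_diet_reads(db, diet, n_reads = 1000, error_rate = 0.01,
                             contaminant_fraction = 0.1, seed = 67)
  expect_equal(nrow(mix$reads), 1000)
  expect_setequal(mix$reads$record_id, mix$truth$read_id)
  expect_equal(sum(mix$truth$is_contaminant), 100)
  props <- table(mix$truth$species) / 900
  expect_lt(abs(props[["Sp01_1_1"]] - 0.6), 0.06)
})

test_that("mock communities follow the length-class treatments", {
  # force half the families short (270 bp) and half long (320 bp)
  specs <- list(
    simulation_spec(n_families = 3, genera_per_family = 2, species_per_genus = 2,
                    haplotypes_per_species = 1, insert_mean = 270, insert_sd = 0,
                    mismatch_probs = c(`0` = 1), contaminant_fraction = 0,
                    rng_seed = 68),
    simulation_spec(n_families = 3, genera_per_family = 2, species_per_genus = 2,
                    haplotypes_per_species = 1, insert_mean = 320, insert_sd = 0,
                    mismatch_probs = c(`0` = 1), contaminant_fraction = 0,
                    rng_seed = 69)
  )
  dbs <- lapply(specs, simulate_refdb)
  merged <- structure(list(
    records = dplyr::bind_rows(dbs[[1]]$records,
                               dplyr::mutate(dbs[[2]]$records,
                                             record_id = paste0("L", record_id))),
    truth = dplyr::bind_rows(dbs[[1]]$truth,
                             dplyr::mutate(dbs[[2]]$truth,
                                           record_id = paste0("L", record_id),
                                           species = paste0("L", species))),
    spec = specs[[1]]
  ), class = "synthetic_refdb")
  mc <- simulate_mock_communities(merged, seed = 70)
  expect_equal(dplyr::n_distinct(mc$community_id), 15)
  per <- mc |> dplyr::count(community_id, treatment, length_class) |>
    tidyr::pivot_wider(names_from = "length_class", values_from = "n")
  expect_true(all(per$long >= 2 & per$short >= 2))
  expect_true(all(per$long + per$short == 6))
  eq <- per[per$treatment == "equal", ]
  expect_true(all(eq$long == 3 & eq$short == 3))
  expect_equal(simulate_mock_communities(merged, seed = 70), mc)  # deterministic
  expect_error(simulate_mock_communities(dbs[[1]], seed = 1), "length class")
})
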