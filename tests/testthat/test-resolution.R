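test_that("prefix dereplication collapses equal-or-prefix sequences", {
  recs <- records_tbl(c("a", "b", "c"), c("ACGTA", "ACGT", "ACGG"))
  cl <- derep_prefix(recs)
  expect_equal(sort(cl$record_id[cl$cluster_id == cl$cluster_id[cl$record_id == "a"]]),
               c("a", "b"))
  expect_equal(cl$representative_id[cl$record_id == "b"], "a")
  expect_equal(dplyr::n_distinct(cl$cluster_id), 2)

  # exact-only mode keeps strict prefixes apart
  cl2 <- derep_prefix(recs, exact_only = TRUE)
  expect_equal(dplyr::n_distinct(cl2$cluster_id), 3)

  # all distinct -> singletons; all identical -> one cluster
  withr::local_seed(21)
  distinct <- records_tbl(paste0("r", 1:5), replicate(5, rand_dna(30)))
  expect_equal(dplyr::n_distinct(derep_prefix(distinct)$cluster_id), 5)
  same <- records_tbl(paste0("s", 1:3), rep(rand_dna(40), 3))
  expect_equal(dplyr::n_distinct(derep_prefix(same)$cluster_id), 1)
})

test_that("same-species duplicates are removed, cross-species kept", {
  withr::local_seed(22)
  s1 <- rand_dna(50); s2 <- rand_dna(50)
  recs <- records_tbl(c("a1", "a2", "a3", "b1"), c(s1, s1, s2, s1))
  tax <- taxonomy_tbl(c("a1", "a2", "a3", "b1"),
                      c("GA_a", "GA_a", "GA_a", "GA_b"))
  out <- deduplicate_same_species(recs, tax)
  expect_equal(sort(out$record_id), c("a1", "a3", "b1"))  # a2 dropped, b1 kept
})

test_that("resolution counts taxa sharing identical sequences as unresolved", {
  withr::local_seed(23)
  shared <- rand_dna(60)
  # two congeneric species share a sequence; a third species is distinct
  recs <- records_tbl(c("r1", "r2", "r3"), c(shared, shared, rand_dna(60)))
  tax <- taxonomy_tbl(c("r1", "r2", "r3"), c("GA_x", "GA_y", "GB_z"),
                      genus = c("GA", "GA", "GB"))
  rep <- taxonomic_resolution(derep_prefix(recs), tax)
  expect_equal(rep$percent_resolved[rep$rank == "species"], 100 * 1 / 3)
  expect_equal(rep$percent_resolved[rep$rank == "genus"], 100)
  expect_equal(rep$percent_resolved[rep$rank == "family"], 100)
  un <- unresolved_taxa(rep)
  expect_setequal(un$taxon[un$rank == "species"], c("GA_x", "GA_y"))

  # species from different families sharing a sequence fail at every rank
  tax2 <- taxonomy_tbl(c("r1", "r2", "r3"), c("GA_x", "GB_y", "GC_z"),
                       genus = c("GA", "GB", "GC"),
                       family = c("FamA", "FamB", "FamC"))
  rep2 <- taxonomic_resolution(derep_prefix(recs), tax2)
  expect_equal(rep2$n_resolved[rep2$rank == "family"], 1L)
  expect_equal(rep2$percent_resolved[rep2$rank == "species"], 100 * 1 / 3)
})

test_that("unique sequences give 100% resolution at every rank", {
  withr::local_seed(24)
  recs <- records_tbl(paste0("r", 1:6), replicate(6, rand_dna(80)))
  tax <- taxonomy_tbl(paste0("r", 1:6), paste0("G", 1:6, "_sp"),
                      genus = paste0("G", 1:6))
  rep <- taxonomic_resolution(derep_prefix(recs), tax)
  expect_equal(rep$percent_resolved, c(100, 100, 100))
})

test_that("planting k within-genus identical pairs lowers species resolution exactly", {
  withr::local_seed(25)
  n_genera <- 10
  k <- 3
  rows <- list()
  for (g in seq_len(n_genera)) {
    s1 <- rand_dna(70)
    s2 <- if (g <= k) s1 else rand_dna(70)  # first k genera get identical pairs
    rows[[g]] <- tibble::tibble(
      record_id = sprintf("g%d_%d", g, 1:2),
      sequence = c(s1, s2),
      species = sprintf("Gen%d_sp%d", g, 1:2),
      genus = sprintf("Gen%d", g)
    )
  }
  dat <- dplyr::bind_rows(rows)
  recs <- records_tbl(dat$record_id, dat$sequence)
  tax <- taxonomy_tbl(dat$record_id, dat$species, genus = dat$genus)
  S <- 2 * n_genera
  rep <- taxonomic_resolution(derep_prefix(recs), tax)
  expect_equal(rep$percent_resolved[rep$rank == "species"], 100 * (S - 2 * k) / S)
  expect_equal(rep$percent_resolved[rep$rank == "genus"], 100)

  # resolution is invariant to record order (cluster numbering may differ)
  perm <- sample(nrow(recs))
  rep_shuf <- taxonomic_resolution(derep_prefix(recs[perm, ]), tax)
  expect_equal(rep_shuf$n_resolved, rep$n_resolved)
  expect_equal(rep_shuf$percent_resolved, rep$percent_resolved)
  expect_setequal(unresolved_taxa(rep_shuf)$taxon, unresolved_taxa(rep)$taxon)
})
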