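test_that("global identity follows the end-gap-free metric", {
  expect_equal(global_identity("ACGT", "ACGT"), 100)
  expect_equal(global_identity("ACGT", "ACGA"), 75)
  expect_equal(global_identity("ACGTAA", "ACGT"), 100)  # terminal gaps excluded
  expect_equal(global_identity("ACGT", "ACGTAA"), 100)  # symmetric
  expect_equal(global_identity("AACGTT", "AACGTT"), 100)
})

test_that("greedy clustering separates planted divergence levels", {
  withr::local_seed(31)
  a <- rand_dna(300)
  b <- sub_at(a, sample(300, 6))   # 2% substitutions -> identity 98
  c_seq <- rand_dna(300)           # unrelated, identity far below 95
  recs <- records_tbl(c("A", "B", "C"), c(a, b, c_seq))
  cl <- cluster_greedy(recs, 95)
  expect_equal(cl$cluster_id[cl$record_id == "A"], cl$cluster_id[cl$record_id == "B"])
  expect_false(cl$cluster_id[cl$record_id == "C"] == cl$cluster_id[cl$record_id == "A"])
  expect_equal(cl$identity[cl$record_id == "B"], 98)

  one <- cluster_greedy(records_tbl("solo", rand_dna(100)))
  expect_equal(one$identity, 100)
  expect_true(one$is_centroid)

  same <- cluster_greedy(records_tbl(c("x", "y", "z"), rep(a, 3)), 95)
  expect_equal(dplyr::n_distinct(same$cluster_id), 1)
})

test_that("threshold sweep separates haplotypes only at 100%", {
  withr::local_seed(32)
  x1 <- rand_dna(300)
  x2 <- sub_at(x1, sample(300, 3))  # 99% identity haplotype pair
  y <- rand_dna(300)
  recs <- records_tbl(c("x1", "x2", "y"), c(x1, x2, y))
  tax <- taxonomy_tbl(c("x1", "x2", "y"), c("GX_a", "GX_a", "GY_b"),
                      genus = c("GX", "GX", "GY"))
  cl <- cluster_greedy(recs, 95)
  sw <- threshold_sweep(cl, recs, tax, grid = 95:100)
  xa <- sw$species[sw$species$species == "GX_a", ]
  expect_true(all(xa$resolved))
  expect_equal(xa$n_motus[xa$threshold <= 99], rep(1L, 5))
  expect_equal(xa$n_motus[xa$threshold == 100], 2L)
})

test_that("identical sequences are never separated at any threshold", {
  withr::local_seed(33)
  shared <- rand_dna(250)
  recs <- records_tbl(c("p1", "q1", "r1"), c(shared, shared, rand_dna(250)))
  tax <- taxonomy_tbl(c("p1", "q1", "r1"), c("GA_p", "GA_q", "GB_r"),
                      genus = c("GA", "GA", "GB"))
  sw <- threshold_sweep(cluster_greedy(recs, 95), recs, tax, grid = 95:100)
  bad <- sw$species[sw$species$species %in% c("GA_p", "GA_q"), ]
  expect_false(any(bad$resolved))  # unresolved at every threshold incl. 100
  ok <- sw$species[sw$species$species == "GB_r", ]
  expect_true(all(ok$resolved))
})

test_that("per-species MOTU count is non-decreasing in the threshold", {
  withr::local_seed(34)
  # one genus: three species at ~97%, two haplotypes each at ~99.4%
  base <- rand_dna(350)
  recs <- list(); tax <- list()
  for (s in 1:3) {
    sp_seq <- sub_at(base, 1:5 + (s - 1) * 5)
    for (h in 1:2) {
      id <- sprintf("s%d_h%d", s, h)
      recs[[id]] <- tibble::tibble(record_id = id,
                                   sequence = sub_at(sp_seq, 340 + h + (s - 1) * 3))
      tax[[id]] <- tibble::tibble(record_id = id, species = sprintf("G_sp%d", s))
    }
  }
  recs <- records_tbl(dplyr::bind_rows(recs)$record_id, dplyr::bind_rows(recs)$sequence)
  taxdf <- dplyr::bind_rows(tax)
  tax <- taxonomy_tbl(taxdf$record_id, taxdf$species, genus = "G")
  sw <- threshold_sweep(cluster_greedy(recs, 95), recs, tax, grid = 95:100)
  counts <- sw$species |>
    dplyr::arrange(.data$species, .data$threshold) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(mono = all(diff(.data$n_motus) >= 0))
  expect_true(all(counts$mono))
})

test_that("re-thresholding matches full re-clustering on planted structure", {
  withr::local_seed(35)
  base <- rand_dna(300)
  ids <- character(0); seqs <- character(0); sp <- character(0)
  for (s in 1:3) {
    sp_seq <- sub_at(base, 1:6 + (s - 1) * 6)   # congeners ~96% pairwise
    for (h in 1:2) {
      ids <- c(ids, sprintf("t%d_%d", s, h))
      seqs <- c(seqs, sub_at(sp_seq, 290 + h + (s - 1) * 2))
      sp <- c(sp, sprintf("GT_sp%d", s))
    }
  }
  recs <- records_tbl(ids, seqs)
  tax <- taxonomy_tbl(ids, sp, genus = "GT")
  sw <- threshold_sweep(cluster_greedy(recs, 95), recs, tax, grid = 95:100)
  full <- threshold_sweep_recluster(recs, tax, grid = 95:100)
  got <- sw$species |> dplyr::select("threshold", "species", "resolved") |>
    dplyr::arrange(.data$threshold, .data$species)
  want <- full |> dplyr::select("threshold", "species", "resolved") |>
    dplyr::arrange(.data$threshold, .data$species)
  expect_equal(got, want)
})

test_that("sweep validates its inputs and builds the order matrix", {
  withr::local_seed(36)
  recs <- records_tbl(c("a", "b"), c(rand_dna(100), rand_dna(100)))
  tax <- taxonomy_tbl(c("a", "b"), c("GA_a", "GB_b"), genus = c("GA", "GB"))
  cl <- cluster_greedy(recs, 95)
  expect_error(threshold_sweep(cl, recs, tax, grid = 90:100), "base threshold")
  sw <- threshold_sweep(cl, recs, tax, grid = 95:100)
  m <- order_resolution_matrix(sw)
  expect_equal(names(m), c("order", "n_species", paste0("t", 95:100)))
  expect_equal(unname(unlist(m[1, paste0("t", 95:100)])), rep(100, 6))
})
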