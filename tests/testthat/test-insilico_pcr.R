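p <- uniplant_primers()

test_that("IUPAC matching uses set intersection", {
  expect_true(iupac_match("R", "A"))
  expect_false(iupac_match("R", "C"))
  expect_true(iupac_match("H", "N"))   # degenerate vs degenerate: intersect
  expect_true(iupac_match("N", "G"))
  expect_error(iupac_match("X", "A"), "non-IUPAC")
})

test_that("count_mismatches counts set failures and checks the 3' anchor", {
  window <- "TGTGAATTGCAAGATCCAG"  # one expansion of UniPlantF
  expect_equal(count_mismatches(p$fwd, window),
               list(mismatches = 0L, anchor_ok = TRUE))
  w1 <- sub_at(window, 2)  # single planted substitution outside the anchor
  expect_equal(count_mismatches(p$fwd, w1),
               list(mismatches = 1L, anchor_ok = TRUE))
  wa <- paste0(substr(window, 1, 18), "A")  # last base G -> A
  expect_false(count_mismatches(p$fwd, wa)$anchor_ok)
  expect_error(count_mismatches(p$fwd, "ACGT"), "length")
})

test_that("scan_binding_sites finds planted sites and respects the budget", {
  withr::local_seed(101)
  site <- uniplant_f_lit()
  seq1 <- paste0(rand_dna(40), site, rand_dna(40))
  hits <- scan_binding_sites(seq1, p$fwd, "forward")
  expect_equal(hits$start, 40L)
  expect_equal(hits$end, 40L + 19L)
  expect_equal(hits$mismatches, 0L)

  # four substitutions exceed the default budget of three
  seq4 <- paste0(rand_dna(40), sub_at(site, c(2, 5, 8, 11)), rand_dna(40))
  expect_equal(nrow(scan_binding_sites(seq4, p$fwd, "forward")), 0)
  cfg4 <- pcr_config(max_mismatches = 4)
  expect_equal(scan_binding_sites(seq4, p$fwd, "forward", cfg4)$mismatches, 4L)

  # reverse-strand site: reverse complement of the primer on the + strand
  seqr <- paste0(rand_dna(30), reverse_complement(uniplant_r_lit()), rand_dna(30))
  rhits <- scan_binding_sites(seqr, p$rev, "reverse")
  expect_equal(rhits$start, 30L)
})

test_that("scanner agrees with the brute-force expansion oracle", {
  withr::local_seed(102)
  cfg <- pcr_config()
  for (i in 1:40) {
    s <- rand_dna(sample(250:400, 1))
    # plant a forward site with 0-5 substitutions at a random position
    k <- sample(0:5, 1)
    site <- sub_at(uniplant_f_lit(), if (k > 0) sample(1:17, k) else integer(0))
    pos <- sample(1:(nchar(s) - 19), 1)
    s <- paste0(substr(s, 1, pos - 1), site, substr(s, pos + 19, nchar(s)))
    for (primer in list(p$fwd, p$rev)) {
      for (strand in c("forward", "reverse")) {
        got <- scan_binding_sites(s, primer, strand, cfg)
        want <- oracle_scan(s, primer$sequence, strand)
        expect_equal(got$start, want$start)
        expect_equal(got$mismatches, want$mismatches)
      }
    }
  }
})

test_that("simulate_pcr reports the planted amplicon and length bounds", {
  withr::local_seed(103)
  rec <- planted_record(insert_len = 200)
  res <- simulate_pcr(rec$sequence, p$fwd, p$rev)
  expect_equal(res$status, "MATCH")
  expect_equal(res$insert_length, 200L)
  expect_equal(res$amplicon_length, 239L)  # 200 + 19 + 20
  expect_equal(res$fwd_start, rec$fwd_start)

  short <- planted_record(insert_len = 90)
  expect_equal(simulate_pcr(short$sequence, p$fwd, p$rev)$status, "LENGTH_FAIL")

  norev <- paste0(rand_dna(20), uniplant_f_lit(), rand_dna(200))
  expect_equal(simulate_pcr(norev, p$fwd, p$rev)$status, "NO_REVERSE")
  nofwd <- paste0(rand_dna(200), reverse_complement(uniplant_r_lit()), rand_dna(20))
  expect_equal(simulate_pcr(nofwd, p$fwd, p$rev)$status, "NO_FORWARD")
  expect_equal(simulate_pcr(rand_dna(300), p$fwd, p$rev)$status, "NO_SITE")
})

test_that("best amplicon minimizes mismatches then insert length", {
  withr::local_seed(104)
  # two forward sites: a 2-mismatch site upstream, an exact site downstream
  f2 <- sub_at(uniplant_f_lit(), c(3, 6))
  s <- paste0(rand_dna(15), f2, rand_dna(120), uniplant_f_lit(), rand_dna(150),
              reverse_complement(uniplant_r_lit()), rand_dna(20))
  res <- simulate_pcr(s, p$fwd, p$rev)
  expect_equal(res$status, "MATCH")
  expect_equal(res$fwd_mismatches, 0L)       # exact site wins despite longer ampl.
  expect_equal(res$fwd_start, 15L + 19L + 120L)
})

test_that("simulate_pcr is strand-symmetric", {
  withr::local_seed(105)
  for (i in 1:10) {
    rec <- planted_record(insert_len = sample(150:350, 1))
    plus <- simulate_pcr(rec$sequence, p$fwd, p$rev)
    minus <- simulate_pcr(reverse_complement(rec$sequence), p$fwd, p$rev)
    expect_equal(minus$status, "MATCH")
    expect_equal(minus$insert_length, plus$insert_length)
  }
})

test_that("raising the mismatch budget or widening bounds never loses hits", {
  withr::local_seed(106)
  seqs <- replicate(20, {
    k <- sample(0:5, 1)
    planted_record(insert_len = sample(80:550, 1),
                   fwd_site = sub_at(uniplant_f_lit(),
                                     if (k > 0) sample(1:17, k) else integer(0)))$sequence
  })
  statuses <- vapply(0:5, function(mm) {
    cfg <- pcr_config(max_mismatches = mm)
    sum(vapply(seqs, function(s) simulate_pcr(s, p$fwd, p$rev, cfg)$status == "MATCH",
               logical(1)))
  }, numeric(1))
  expect_true(all(diff(statuses) >= 0))

  narrow <- pcr_config(min_insert = 150, max_insert = 300)
  wide <- pcr_config(min_insert = 100, max_insert = 500)
  m_narrow <- vapply(seqs, function(s) simulate_pcr(s, p$fwd, p$rev, narrow)$status == "MATCH", logical(1))
  m_wide <- vapply(seqs, function(s) simulate_pcr(s, p$fwd, p$rev, wide)$status == "MATCH", logical(1))
  expect_true(all(m_wide >= m_narrow))
})

test_that("truncated records are routed to single-primer classification", {
  withr::local_seed(107)
  expect_error(simulate_pcr(records_tbl("t1", rand_dna(100), "forward_only"),
                            p$fwd, p$rev), "classify_single_primer_fit")
  fwd_only <- paste0(rand_dna(20), uniplant_f_lit(), rand_dna(60))
  expect_equal(classify_single_primer_fit(fwd_only, p$fwd), "fit")
  expect_equal(classify_single_primer_fit(rand_dna(80), p$fwd), "no_fit")
  broken <- paste0(rand_dna(20), paste0(substr(uniplant_f_lit(), 1, 18), "A"),
                   rand_dna(60))
  expect_equal(classify_single_primer_fit(broken, p$fwd), "no_fit")

  recs <- records_tbl(c("a", "b", "c"),
                      c(fwd_only, rand_dna(80), planted_record()$sequence),
                      c("forward_only", "reverse_only", "full"))
  res <- insilico_pcr(recs, p$fwd, p$rev)
  expect_equal(res$status, c("SINGLE_PRIMER_F_OK", "SINGLE_PRIMER_FAIL", "MATCH"))
})

test_that("N-rich records are excluded from screening", {
  withr::local_seed(108)
  rec <- planted_record(insert_len = 150)
  n_insert <- paste(rep("N", 150), collapse = "")
  n_rec <- planted_record(insert_len = 150, insert = n_insert)
  res <- insilico_pcr(records_tbl(c("ok", "junk"),
                                  c(rec$sequence, n_rec$sequence)),
                      p$fwd, p$rev)
  expect_equal(res$status, c("MATCH", "EXCLUDED_N"))
})

test_that("fit summaries count species, not records", {
  tax <- taxonomy_tbl(
    record_id = c("r1", "r2", "r3", "r4", "r5", "r6", "r7"),
    species = c("CypA_1", "CypA_2", "CypB_1", "CypB_2", "PoaA_1", "PoaA_1", "PoaA_1"),
    genus = c("CypA", "CypA", "CypB", "CypB", "PoaA", "PoaA", "PoaA"),
    family = c(rep("Cyperaceae", 4), rep("Poaceae", 3)),
    order = "Poales"
  )
  results <- tibble::tibble(
    record_id = paste0("r", 1:7),
    status = c("NO_REVERSE", "NO_SITE", "LENGTH_FAIL", "NO_REVERSE",
               "NO_SITE", "MATCH", "NO_SITE")
  )
  fam <- summarize_fit_by_rank(results, tax, "family")
  cyp <- fam[fam$family == "Cyperaceae", ]
  poa <- fam[fam$family == "Poaceae", ]
  expect_equal(cyp$percent_matched, 0)     # 4 species, none amplify
  expect_equal(cyp$n_tested, 4L)
  expect_equal(poa$percent_matched, 100)   # 1 of 3 haplotype records suffices
  tot <- fam[fam$family == "Total", ]
  expect_equal(tot$n_tested, 5L)
  expect_equal(tot$n_matched, 1L)
  expect_error(summarize_fit_by_rank(tibble::tibble(record_id = "zz", status = "MATCH"),
                                     tax), "not in taxonomy")
})

test_that("length table reports per-family mean and SE of inserts", {
  tax <- taxonomy_tbl(record_id = c("a", "b", "c", "d"),
                      species = c("GA_1", "GA_2", "GB_1", "GC_1"),
                      genus = c("GA", "GA", "GB", "GC"),
                      family = c("FamA", "FamA", "FamB", "FamC"),
                      order = "OrdA")
  results <- tibble::tibble(
    record_id = c("a", "b", "c", "d"),
    status = c("MATCH", "MATCH", "MATCH", "NO_SITE"),
    insert_length = c(300L, 310L, 330L, NA)
  )
  tbl <- amplicon_length_table(results, tax)
  expect_equal(tbl$family, c("FamA", "FamB"))  # FamC has no MATCH: omitted
  expect_equal(tbl$mean_insert, c(305, 330))
  expect_equal(tbl$se_insert, c(5, 0))         # single-record family prints 0
})

test_that("extract_amplicons recovers the planted insert on both strands", {
  withr::local_seed(109)
  rec <- planted_record(insert_len = 180)
  recs <- records_tbl(c("plus", "minus"),
                      c(rec$sequence, reverse_complement(rec$sequence)))
  res <- insilico_pcr(recs, p$fwd, p$rev)
  amp <- extract_amplicons(recs, res)
  expect_equal(amp$insert[amp$record_id == "plus"], rec$insert)
  expect_equal(amp$insert[amp$record_id == "minus"], rec$insert)
})
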