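# Shared fixture builders: everything is generated in code at test time.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# substitute exactly the given 1-based positions with a different base
sub_at <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}

# one literal expansion of each UniPlant primer (fixed choice for fixtures)
uniplant_f_lit <- function() expand_degenerate(uniplant_primers()$fwd$sequence)[1]
uniplant_r_lit <- function() expand_degenerate(uniplant_primers()$rev$sequence)[1]

# planted amplicon record: flank5 | fwd site | insert | rc(rev site) | flank3
planted_record <- function(insert_len = 200, flank5 = 20, flank3 = 25,
                           fwd_site = uniplant_f_lit(),
                           rev_site = uniplant_r_lit(),
                           insert = NULL) {
  if (is.null(insert)) insert <- rand_dna(insert_len)
  list(
    sequence = paste0(rand_dna(flank5), fwd_site, insert,
                      reverse_complement(rev_site), rand_dna(flank3)),
    insert = insert, fwd_start = flank5, flank5 = flank5
  )
}

records_tbl <- function(ids, seqs, truncation = "full") {
  tibble::tibble(record_id = ids, sequence = seqs,
                 truncation = rep_len(truncation, length(ids)))
}

# minimal consistent taxonomy: species label "Gg_s" -> genus "Gg"
taxonomy_tbl <- function(record_id, species, genus = NULL, family = NULL,
                         order = NULL) {
  if (is.null(genus)) genus <- sub("_[^_]+$", "", species)
  if (is.null(family)) family <- rep("FamA", length(species))
  if (is.null(order)) order <- rep("OrdA", length(species))
  tibble::tibble(record_id = record_id, species = species, genus = genus,
                 family = family, order = order)
}

write_temp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
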