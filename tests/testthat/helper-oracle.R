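# Brute-force binding-site oracle, independent of the package's scanner:
# expand the degenerate primer into every literal sequence, Hamming-scan each
# literal over the reference, and merge (a window is a hit when some literal
# is within the mismatch budget and some literal matches the 3' anchor
# exactly; the reported mismatch count is the minimum over literals).

.oracle_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)
.oracle_comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                  S = "S", W = "W", K = "M", M = "K", B = "V", D = "H",
                  H = "D", V = "B", N = "N")

# returns data.frame(start (0-based), mismatches) sorted by start
oracle_scan <- function(sequence, primer_iupac, strand,
                        max_mismatches = 3, anchor_len = 2) {
  pr <- strsplit(primer_iupac, "")[[1]]
  if (strand == "reverse") pr <- rev(unname(.oracle_comp[pr]))
  k <- length(pr)
  anchor_pos <- if (strand == "forward") (k - anchor_len + 1):k else seq_len(anchor_len)
  sv <- strsplit(sequence, "")[[1]]
  n <- length(sv) - k + 1
  if (n < 1) return(data.frame(start = integer(0), mismatches = integer(0)))
  # shared Hamming contribution of non-degenerate positions, then add each
  # literal's choice at degenerate positions
  degen <- which(lengths(.oracle_sets[pr]) > 1)
  fixed <- setdiff(seq_len(k), degen)
  base_mm <- integer(n)
  base_anchor <- integer(n)
  for (j in fixed) {
    fail <- sv[j:(j + n - 1)] != .oracle_sets[[pr[j]]]
    base_mm <- base_mm + fail
    if (j %in% anchor_pos) base_anchor <- base_anchor + fail
  }
  fail_by_pos <- lapply(degen, function(j) {
    lapply(.oracle_sets[[pr[j]]], function(b) sv[j:(j + n - 1)] != b)
  })
  names(fail_by_pos) <- degen
  combos <- expand.grid(lapply(degen, function(j) seq_along(.oracle_sets[[pr[j]]])))
  best_mm <- rep(Inf, n)
  best_anchor <- rep(Inf, n)
  if (nrow(combos) == 0) {
    best_mm <- base_mm
    best_anchor <- base_anchor
  } else {
    for (li in seq_len(nrow(combos))) {
      mm <- base_mm
      amm <- base_anchor
      for (d in seq_along(degen)) {
        fail <- fail_by_pos[[d]][[combos[li, d]]]
        mm <- mm + fail
        if (degen[d] %in% anchor_pos) amm <- amm + fail
      }
      best_mm <- pmin(best_mm, mm)
      best_anchor <- pmin(best_anchor, amm)
    }
  }
  hit <- which(best_mm <= max_mismatches & best_anchor == 0)
  data.frame(start = hit - 1L, mismatches = as.integer(best_mm[hit]))
}
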