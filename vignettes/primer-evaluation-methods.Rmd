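---
title: "Evaluating short-amplicon metabarcoding primers in silico: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating short-amplicon metabarcoding primers in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliscreen)
library(dplyr)
```

`ampliscreen` answers, entirely in silico, the questions that decide whether
a candidate metabarcoding primer pair is usable: does it amplify the target
taxa (coverage), can the amplified region tell taxa apart (resolution), and
how should reads be identified downstream (MOTU clustering thresholds versus
closest-match assignment). This vignette documents the models behind each
stage, the tunable parameters with their defaults, the synthetic-data
generator used to validate everything, and the numerical choices and known
limitations a careful user should be aware of.

## Primer-fit model

A degenerate primer is a pool of literal oligos described by IUPAC ambiguity
codes (the motivating plant ITS2 pair: UniPlantF, 19 nt, 16 expansions;
UniPlantR, 20 nt, 144 expansions). The screen slides the primer along every
window of the reference (both orientations) and counts the positions whose
IUPAC sets fail to intersect. A window is a binding site when

- mismatches ≤ `max_mismatches` (default **3** per primer), and
- the last `anchor_len` bases at the primer's 3' end match exactly set-wise
  (default **2**) — polymerase extension is most sensitive to 3' terminal
  mismatches, so a single mismatch there disqualifies the site regardless of
  the total count.

Set intersection makes degenerate-vs-degenerate comparison symmetric (H
matches N); a strict-containment rule is available via
`pcr_config(match_rule = "contain")` for users who consider an N in a
reference insufficient evidence of a match. Because N intersects everything,
records with more than `max_n_frac` (default 5%) N content are excluded
outright rather than being allowed to "amplify" on noise.

Amplicons are formed from every forward/reverse site pair in valid
orientation; the *insert* (amplicon minus both priming sites) must lie
within `min_insert`–`max_insert` (default **100–500 bp**). We apply the
bounds to the insert rather than the primer-inclusive amplicon because the
headline length range of the motivating primer set (187–387 bp) is quoted
net of priming sites; the primer-inclusive length is also reported. When
several pairs qualify, the reported amplicon minimizes total mismatches,
then insert length, then leftmost forward start, then plus orientation — an
arbitrary but fixed tie-break, chosen for determinism. All coordinates are
0-based half-open (BED-style), so `insert = rev_start − fwd_end` without
off-by-one corrections.

Records that span only one priming region cannot be amplified in silico;
they are routed to single-primer classification (`SINGLE_PRIMER_*`
statuses) and excluded from coverage denominators, mirroring how partial
database sequences are reported separately in practice. Truncation state is
explicit metadata (a `trunc=` FASTA header tag) rather than something we
infer, because inference from sequence content alone is unreliable.

Coverage (`summarize_fit_by_rank()`) counts **species** as its unit at every
rank: a species is covered when at least one of its records amplifies, and a
family row reports how many of its tested species were covered. This
matches how primer-fit tables are normally presented and makes the numbers
insensitive to how many sequences per species a database happens to hold.

## Taxonomic resolution

Resolution asks whether the amplified region can distinguish taxa, not
whether primers bind. Amplicon inserts are first deduplicated *within*
species (identical duplicates from one species carry no information), then
prefix-dereplicated: a sequence joins a cluster when it equals, or is an
exact prefix of, the cluster representative (longest-first greedy order,
lexicographic tie-break, for determinism). Prefix collapse treats a shorter
sequence that is consistent with a longer one as indistinguishable from it,
which is the conservative choice for mixed-length databases; an
`exact_only` toggle restricts collapse to exact equality. A taxon is
*resolved* at a rank when no cluster mixes it with a different taxon at
that rank, and the report lists every unresolved taxon with its conflicting
partners.

The resolution percentages follow the familiar empirical pattern: nearly
all losses happen at the species rank (congeneric species sharing identical
sequences), with genus- and family-level ambiguity an order of magnitude
rarer.

One deliberate divergence from common practice: resolution here is computed
on the full amplicon insert, not on an HMM-extracted subregion. Boundary
extraction tools are out of scope; on synthetic data the generator controls
region boundaries exactly, so nothing is lost there, but users comparing
against published numbers computed on extracted ITS2 should expect small
differences.

## Identity, clustering, and the threshold sweep

Pairwise identity underlies both clustering and assignment. The definition:
Needleman–Wunsch global alignment with free end gaps (match +1, mismatch
−1, internal gaps −2 to open and −1 to extend), identity = 100 × matching
columns / alignment columns, excluding terminal-gap columns, **with the
denominator floored at the shorter sequence's length**. The floor deserves
explanation: with fully free end gaps, the score-optimal "alignment" of two
unrelated sequences is a handful of coincidentally matching terminal bases,
which would report near-100% identity for junk; flooring the denominator
turns that into the near-zero, coverage-weighted identity it really is,
while an exact substring still scores 100 and substitution-only pairs score
exactly their Hamming identity. The DP is compiled code (`src/`), with the
much slower Biostrings alignment kept as an independent cross-check in the
test suite.

Clustering mirrors the greedy centroid strategy of the standard tools:
records in length-descending order either join the first centroid at ≥ 95%
identity or found a new cluster (`cluster_greedy()`). The threshold sweep
(`threshold_sweep()`) then *re-thresholds* the 95% run at each cut-off
t ∈ {95…100}: members at ≥ t identity to their centroid stay; members below
t re-cluster greedily among themselves within the base cluster. Re-using
the base run instead of re-clustering from scratch is how this diagnostic
is computed in practice from a single cluster-format output file; the
package also ships full re-clustering (`threshold_sweep_recluster()`) as a
cross-check, and the two agree on planted structure in the test suite.
An early design that dropped sub-threshold members as singletons was
discarded: it brands any species whose haplotypes sit in a congener's base
cluster as "split", making the resolved-and-unsplit diagnostic unable to
identify the correct threshold window even on cleanly separable data.

Two summary definitions are reported side by side, because "resolvable by
clustering" is used in both senses in the literature: *resolved* (no MOTU
contains two species) and *resolved-and-unsplit* (additionally, all the
species' records share one MOTU). On data with intraspecific divergence
d\_intra and congeneric divergence d\_species, species are
resolved-and-unsplit exactly for thresholds in
(100 − d\_species, 100 − d\_intra] — the window the sweep is designed to
expose. Identical sequences never separate at any threshold, so species
pairs sharing sequences stay unresolved even at 100%, which is the
strongest argument against pure MOTU identification when such pairs exist.

## Closest-match assignment

Given a comprehensive reference library, the package's recommended
identification route skips clustering: each query is assigned to the
reference(s) with the highest identity. All references within `tie_window`
(default 0, i.e. exact ties only) of the best identity are collected; the
assignment is made at the lowest rank they share — species, else genus,
else family — and queries whose best identity falls below
`assign_min_identity` (default **90%**) stay unassigned, which doubles as
the non-target (fungal-like contaminant) filter in place of an online
BLAST. Tie promotion is what makes intraspecific and paralogous variation
harmless: multiple ITS2 copies of one species tie at the species rank, and
a query from a species missing from the library lands on its congeners and
is promoted to genus.

Exhaustive alignment against every reference is exact but quadratic;
`method = "prescreen"` ranks references by shared 5-mers and aligns only the
`top_n` candidates (ties included). On planted read sets the prescreen
reproduces the exhaustive assignments; it remains an approximation, and the
test suite checks agreement rather than assuming it.

## Length-bias diagnostics

Shorter amplicons can be preferentially amplified from degraded samples, so
the package compares observed read-length distributions against the
reference database with a Mann–Whitney–Wilcoxon rank-sum test implemented
from first principles: midranks for ties, W = rank-sum of the first sample,
U = W − n₁(n₁+1)/2 (so U₁ + U₂ = n₁n₂ always). The two-sided p doubles the
smaller tail. For n₁+n₂ ≤ 16 without ties the null distribution is
enumerated exactly over all C(n₁+n₂, n₁) rank assignments; otherwise a
normal approximation with tie correction, continuity correction, and — in
the untied case — an Edgeworth kurtosis term
(γ₂ = −(6/5)(n₁²+n₂²+n₁n₂+n₁+n₂)/(n₁n₂(N+1))) is used, which keeps the
approximation within ~10⁻³ of exact at n₁ = n₂ = 8. Because which sample's
rank-sum a published W refers to is often ambiguous, both orientations are
reported. The histogram table and `autoplot()` method reproduce the
standard observed-vs-reference length figure.

## The synthetic-data generator

Every stage is validated against databases with planted, exactly
recoverable truth (`simulate_refdb()`). Each species' record is

```
[5' flank | forward priming site | insert | reverse-complemented reverse priming site | 3' flank]
```

with these generative choices:

- **Primer fit is planted per species.** Species are apportioned *exactly*
  (largest-remainder, then shuffled) to mismatch classes — by default 70%
  carry 0 mismatches, 10% / 5% / 3% carry 1 / 2 / 3, and 12% fail outright
  (4 mismatches, or a broken 3' anchor with probability
  `anchor_break_prob`). Exact apportionment rather than multinomial
  sampling is what makes planted coverage a sharp expectation (88.0% on 500
  species) instead of a stochastic one. After generation every record is
  re-screened, and a family whose random flanks or inserts created an
  unplanned binding site is redrawn, so the planted truth is exactly what
  the screen sees.
- **Divergence is additive by construction.** Within a family, substitution
  sites are allocated in *disjoint blocks* per branch (genus, species,
  haplotype), so pairwise distances add exactly: haplotypes differ at 2h
  sites, congeners at 2(m+h), confamilial genera at 2(g+m+h), with h, m, g
  derived from the requested pairwise divergences (defaults: d\_intra 0.5%,
  d\_species 3%, d\_genus 8%). This gives the threshold sweep a sharp
  expected window. Families receive independent random ancestor inserts,
  each with its own length drawn once per family (normal, mean 290 bp, sd
  25, truncated to 187–387 bp) — so within-family length variance is zero
  by design and `d_family` is nominal; between-family identity sits at the
  ~50% random background.
- **Substitution-only evolution.** No indels in priming sites or inserts:
  planted mismatch counts and identities stay oracle-checkable. Real ITS2
  has indels; this is a validation harness, not a sequence evolution model.
- **Contaminants** (default 5% of records) are random-composition sequences
  without priming sites, present in the records and truth tables but not in
  the taxonomy — emulating non-target material that survives into a real
  database or read pool without modelling fungal ITS biology.
- **Diet reads** are sampled multinomially from the amplicon inserts of a
  named species mixture, with uniform substitution errors (rate capped at
  0.1) and uniform 3' truncation up to a set fraction — emulating degraded
  faecal amplicons. **Mock-community designs** assemble 15 six-species
  communities across three length-balance treatments (3+3, 2 long + 4
  short, 4 long + 2 short; short = 267–280 bp, long = 310–336 bp inserts).

What passing tests on these data do **not** show: robustness to indel
variation, chimeras, PCR stochasticity, secondary structure, or the messy
taxonomy of real databases. The generator validates the *algorithms*; real
databases will be noisier in ways the truth tables cannot represent.

## Numerical choices and degenerate inputs

- Problem sizes in the validation suite: the scanner is checked against a
  brute-force expansion + Hamming oracle on 1000 random sequences with
  planted sites; coverage on 500 species; resolution on 300 species with 21
  planted identical pairs; assignment on 10,000 simulated reads. These
  sizes make the planted expectations exact while keeping the suite quick
  to run.
- `derep_prefix`, `cluster_greedy` and the sweep are deterministic given
  input order; ties in length fall back to input order everywhere.
- `simulate_pcr` on a record with sites on both strands in invalid
  orientation reports `LENGTH_FAIL` (sites exist, no valid pair), not
  `NO_SITE`.
- Identity of an empty overlap is 0, never NaN; a rank-sum test on two
  identical constant samples returns p = 1.
- The mismatch budget is **≤ 3** ("maximum of three") rather than < 3; the
  two phrasings circulate for this criterion, the operational description
  is the former, and `pcr_config(max_mismatches =)` lets users apply
  either.
- `run_pipeline()` derives stage seeds from one config seed; stage TSVs are
  byte-identical across reruns and their md5 sums land in the manifest.

## Known limitations

- In silico fit is an optimistic proxy: thermodynamics (Tm, dimers,
  hairpins) are out of scope, so a "fitting" primer can still fail in
  vitro.
- Prefix dereplication can mark a species unresolved because its sequence
  is a strict prefix of another species' longer sequence — arguably an
  artifact of mixed-length databases; use `exact_only = TRUE` to measure
  its effect.
- The k-mer prescreen is near-exact, not exact; exhaustive mode exists for
  when certainty matters more than speed.
- Read counts are deliberately never converted into abundances; the
  occurrence matrix (presence/absence per sample) is the supported
  quantitative unit.
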