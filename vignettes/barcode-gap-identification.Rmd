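---
title: "Barcode gaps, thresholds, and species identification with barcodekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barcode gaps, thresholds, and species identification with barcodekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodekit)
```

## The problem

DNA barcoding assigns specimens to species using short standardized
genomic regions — for land plants, typically the plastid loci rbcLa and
matK. The approach works when a *barcode gap* exists: within-species
(intraspecific) distances are small and between-species (interspecific)
distances are much larger, so an unknown sequence lands unambiguously
near its own species. The setting barcodekit targets is identification of
material that cannot be identified morphologically — dried, powdered or
otherwise processed plant material of the kind sold in traditional
medicine markets — against a curated reference library of sequences from
vouchered, expert-identified specimens.

The package implements the complete distance-based analysis: pairwise
distances, barcode-gap statistics, threshold optimization, three
leave-one-out identification estimators, percent-identity matching of
degraded queries with vernacular-name adjudication, and a bootstrapped
neighbour-joining tree for query placement. A seeded synthetic-library
generator makes every stage testable end to end without any sequence
downloads.

## Distances

Distances between aligned sequences use the Kimura two-parameter (K2P)
model, the de-facto standard in barcoding studies. With $P$ the
proportion of compared sites showing a transition (purine–purine or
pyrimidine–pyrimidine difference) and $Q$ the proportion showing a
transversion,

$$d = -\tfrac{1}{2}\,\ln\!\left[(1 - 2P - Q)\sqrt{1 - 2Q}\right].$$

Comparisons use **pairwise deletion**: for each pair, only columns where
both sequences carry an unambiguous A/C/G/T are counted. This is the
right policy for degraded queries, which arrive truncated and peppered
with Ns; complete deletion would throw away most of the alignment.
Ambiguity codes are treated as missing rather than fractionally matched —
simpler and conservative, and consequential only for heavily degraded
material.

Two situations yield a *missing* (NA) distance rather than a number:

* the pair overlaps on fewer than `min_overlap` sites (default 100, the
  point below which K2P estimates on ~500–900 bp barcodes become
  noise-dominated);
* the correction's log argument is non-positive (saturation). Missing is
  preferable to `Inf` because downstream summaries can skip and count NAs
  explicitly.

The uncorrected p-distance (simple mismatch proportion) backs the
Tajima-K summary — the mean number of substitutions per nucleotide over
all sequence pairs — which is conventionally quoted on the per-nucleotide
scale, not model-corrected, so `tajima_K()` deliberately consumes a
p-distance matrix.

`build_distance_matrix()` computes all pairs at once from per-base
indicator matrices (a handful of matrix cross-products), which keeps
bootstrap replication cheap; `count_site_patterns()` + `k2p_distance()`
give the same numbers one pair at a time and serve as the reference path
in the test suite.

## Barcode-gap analysis

`partition_distances()` splits the unordered non-missing pairs into
intra- and interspecific sets; `wilcoxon_rank_sum()` (exact for small
untied samples, tie-corrected normal approximation otherwise) tests
whether interspecific distances exceed intraspecific ones. Because
summaries of these skewed distributions are reported inconsistently
across studies — some quote means, some medians — `summarize_locus()`
emits both, plus ranges and SDs.

The per-individual gap (`individual_gaps()`) compares each record's
*furthest conspecific* with its *closest heterospecific*; the gap holds
when the latter is larger. Records of singleton species have no
conspecifics, so their `max_intra` and `has_gap` are undefined (NA)
rather than silently zero or dropped; they are counted separately so
either convention can be reproduced downstream.

## Threshold optimization

`optimize_threshold()` scans a candidate grid (default 0.1%–5% in 0.01%
steps, bracketing the 1% cutoff conventional in barcoding databases) and
scores each candidate $t$ by a cumulative error with two terms:

* **false negatives** — records whose furthest conspecific exceeds $t$
  (their species' variation overflows the cutoff);
* **false positives** — records with at least one heterospecific within
  $t$ (another species intrudes into the cutoff).

This is the standard threshold-optimization criterion for barcode
libraries: its minimum lies inside the barcode gap whenever one exists,
because only there do both terms vanish. Ties are broken toward the
smallest candidate, i.e. the most stringent threshold achieving the
minimum. An alternative error based directly on the fixed-cutoff
identifier's verdicts (incorrect + no-ID counts) was considered and
rejected: a record escapes "no ID" as soon as its *nearest* conspecific
is within $t$, so that error is already zero below the maximum
intraspecific distance and its smallest-tie minimizer systematically
undershoots the gap.

## Identification estimators

All three estimators are **leave-one-out**: the focal record is removed
from the library while being identified, the standard convention for
library self-evaluation (otherwise every record trivially matches
itself).

* `near_neighbour()` — true iff any nearest neighbour (all records tied
  at the minimum distance) is conspecific.
* `best_close_match()` — no neighbour within the threshold → `no_id`;
  otherwise the tied nearest neighbours decide: all conspecific →
  `correct`, all heterospecific → `incorrect`, mixed → `ambiguous`.
* `threshold_id()` — the BOLD-style rule: the verdict comes from *all*
  neighbours within a fixed cutoff (default 1%), with the same four-way
  verdict domain.

Tie handling is exact (floating-point equality): ties arise in practice
from duplicated haplotypes, which compare exactly equal, not from
numerical coincidence. Singleton-species records are retained and
necessarily score false/incorrect/no-ID — they cannot match a conspecific
— and their count is reported so users preferring to exclude them can
re-derive those percentages. `efficacy_table()` runs all three methods
per locus and reports percentages both at full precision and rounded to
whole numbers for report tables.

## Query matching and adjudication

Degraded market queries are matched by semi-global (free-end-gap)
alignment — match +1, mismatch −1, gap −2, terminal overhangs free — so a
truncated query aligns against the homologous stretch of each full-length
reference without penalty. The headline statistic is percent identity
over the aligned columns; hits below `min_identity` (default 90, low
enough to keep marginal but interpretable hits visible while suppressing
cross-family noise) are dropped, and ranking is by identity, then aligned
length, then hit id. E-values are deliberately not computed: they are
database-size statistics that have no meaning for a local library scan,
and percent identity is the quantity practitioners read first anyway.

`adjudicate()` compares the best-hit species against the species expected
from the query's vernacular name (exact string match against any listed
synonym; no fuzzy name matching). A vernacular with no known scientific
name yields the distinct status `mismatch_unverifiable` rather than a
plain mismatch, since the claim cannot actually be checked.
`market_summary()` reports the match percentage over *all* queries,
amplification failures included in the denominator — the bookkeeping
under which a 16-of-18-sequenced survey with 11 matches scores
11/18 ≈ 61%.

The packaged fixture (`market_fixture()`) is an 18-query survey table in
exactly this shape and is used by the tests as a fixed bookkeeping
reference: 2 amplification failures, 11 matches (61% of 18), and 4
queries of Vulnerable conservation status (22% of 18).

## Trees and query placement

`nj_build()` produces a neighbour-joining tree from the K2P matrix.
Neighbour joining was chosen over parsimony or likelihood search because
the tree's role here is corroborative — showing where queries attach
relative to reference species — and NJ answers that deterministically in
seconds; labels are sorted before agglomeration so the result is
independent of record input order. Support comes from a column bootstrap
(`bootstrap_support()`): alignment columns resampled with replacement,
matrix and tree rebuilt per replicate, support = percentage of replicates
containing each original bipartition. Replicate $r$ seeds its RNG with
`seed + r`, so any replicate can be reproduced alone. Supports of 50–74
are conventionally read as weak and 75–100 as strong (`support_class()`).

`annotate_queries()` reports each query's sister-group species set and
the support of the smallest clade joining it to a reference tip. Sister
groups need a root; midpoint rooting is used as a deterministic
convention that needs no outgroup declaration. When a query's immediate
sibling subtree contains only other queries, the clade is widened until
it captures a reference tip.

## The synthetic generator

`generate_library()` draws a uniform-random root sequence and evolves it
under the K80 process with transition/transversion rate ratio `kappa`
(default 2.0, a typical plastid value): each species ancestor sits at
expected K2P distance `inter_target/2` from the root on a **star
phylogeny**, each individual at `intra_target/2` from its ancestor, so
conspecific pairs diverge by ≈ `intra_target` and heterospecific pairs by
≈ `inter_target`. The star keeps expected distances analytically
controllable and matches the analysis's own assumptions (no rate
heterogeneity, no deep phylogenetic structure). Defaults emulate a
medicinal-plant reference library: 108 species × 1–3 individuals, with
per-locus lengths and divergence scales of 552 bp / inter 0.08 / intra
0.0002 (rbcLa-like) and 915 bp / inter 0.22 / intra 0.0008 (matK-like).

`degrade_query()` emulates market material: a contiguous terminal
fraction of the alignment is lost (replaced by gaps, preserving
coordinates so queries remain usable in alignment-based stages) and a
fraction of surviving bases is masked to N. A query retaining fewer than
50 bases is marked an amplification failure — the simplest mechanism
reproducing the empirical phenomenon that some processed samples yield no
usable sequence. `generate_lookup()` invents one vernacular name per
species and deliberately mislabels a chosen fraction of queries (drawn
among the sequenced ones, and as an exact count rather than a Bernoulli
rate, so panel compositions are reproducible by construction).

What the generator does **not** emulate — and hence what passing tests do
not certify about real data: non-star phylogenetic structure and closely
related congeners, rate variation across sites and lineages, indels and
alignment error, chimeric or mixed-species samples, and real vernacular
synonymy. In particular, real libraries dense in congeneric species will
show narrower gaps and lower identification success than the synthetic
panels.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic data
at desk scale, chosen to exercise every code path while keeping a full
run in minutes on one CPU: oracle comparisons use 200 random 20-record
matrices; parameter-recovery panels use 20 species × 3 individuals at
600 bp over 50 seeds; bootstrap checks use 100 replicates on the same
panels; the end-to-end pipeline default is the 108-species two-locus
study emulation with 18 queries. Exact-Wilcoxon validation enumerates all
rank permutations for every sample split with $n_1 + n_2 \le 8$.

Identification percentages on the default 1–3-individuals-per-species
panel are bounded above by the singleton share of records — singletons
cannot match a conspecific under leave-one-out — so ~86% "true" on the
synthetic default reflects the sampling structure, not estimator error;
panels with ≥2 individuals per species score 100% under the same
divergence targets.

## Known limitations

* Distances are K2P or p only; no Jukes–Cantor, F84 or GTR, and no
  maximum-likelihood distances.
* The aligner assumes inputs are alignable barcodes; there is no indel
  model in the generator, so gap handling in the semi-global matcher is
  exercised only by truncation in the tests.
* Tree support is bipartition-based NJ bootstrap; it is not a posterior
  probability and should be read with the usual conservatism.
* Vernacular adjudication is exact-string; orthographic variants of the
  same name count as absent from the lookup.
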