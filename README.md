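# barcodekit

Distance-based DNA barcoding analysis for species identification.

`barcodekit` is for researchers who maintain a reference library of
plant DNA barcodes (e.g. the plastid loci rbcLa and matK) and need to
answer two questions: *how well do these barcodes discriminate the
species in my library?* and *what species is this degraded, unidentifiable
sample?* The motivating use case is traditional-medicine ("muthi") market
surveys, where material is sold dried, powdered or processed, carries
only a vernacular name, and can only be identified molecularly — but the
toolkit applies to any barcode library with degraded queries.

## What it computes

**Distances.** Pairwise Kimura two-parameter distances under pairwise
deletion: with *P* and *Q* the transition and transversion proportions
over the sites comparable in a pair,

> d = −½ · ln[(1 − 2P − Q) · √(1 − 2Q)]

Pairs overlapping on fewer than `min_overlap` sites, or saturated pairs,
are missing (NA), never infinite. Uncorrected p-distances back the
Tajima-K mean-divergence summary.

**Barcode gap.** Partition of distances into intra- vs interspecific
sets, Wilcoxon rank-sum comparison, per-locus summary statistics, and the
per-individual gap (furthest conspecific vs closest heterospecific).

**Threshold optimization.** Grid search minimizing cumulative error =
false negatives (records whose furthest conspecific exceeds the cutoff)
+ false positives (records with a heterospecific inside it); ties break
toward the most stringent cutoff.

**Identification estimators** (all leave-one-out): near neighbour
(true/false), best close match (correct / incorrect / ambiguous / no ID
from the tied nearest neighbours within a threshold), and BOLD-style
fixed-cutoff identification (same verdicts from *all* neighbours within
1%).

**Query matching.** Semi-global (free-end-gap) alignment of degraded
queries against every reference, ranked by percent identity;
adjudication of the best hit against the species expected from the
query's vernacular name, with amplification failures and unverifiable
names tracked explicitly.

**Trees.** Neighbour-joining on the K2P matrix with column bootstrap
(supports of 50–74 read as weak, 75–100 as strong) and a query-placement
report (sister-group species and supporting clade).

**Synthetic data.** A seeded generator producing reference libraries
(star phylogeny, K80 substitution process with transition/transversion
ratio kappa), degraded queries with known truth, and vernacular lookups
with deliberate mislabels — so the whole pipeline is testable offline.

## Worked example

```r
library(barcodekit)

cfg <- synthetic_config(n_species = 20, individuals = 3, seq_length = 600,
                        inter_target = 0.10, intra_target = 0.003, seed = 42)
gen <- generate_library(cfg)
gen$library
#> Reference library [rbcLa]: 60 records, 20 species, 600 aligned columns

m  <- build_distance_matrix(gen$library, model = "k2p")
sp <- species_map(gen$library)
summarize_locus(gen$library, m)[, c("tajima_K", "inter_mean",
                                    "intra_mean", "threshold_pct")]
#>   tajima_K inter_mean intra_mean threshold_pct
#> 1    0.093     0.1033     0.0033          0.84
```

The realized divergences sit on the generator's targets (mean
interspecific K2P 0.103 ≈ 0.10, intraspecific 0.0033 ≈ 0.003), and the
optimized threshold (0.84%) falls inside the barcode gap — above every
intraspecific distance, below every interspecific one. Identification at
that threshold is perfect:

```r
opt <- optimize_threshold(m, sp)
best_close_match(m, sp, opt$threshold)$summary
#>     verdict  n pct
#> 1   correct 60 100
#> 2 incorrect  0   0
#> 3 ambiguous  0   0
#> 4     no_id  0   0
```

Market-style queries — truncated to 60% length, 2% of bases masked —
still match their source species:

```r
qs <- generate_queries(gen$library, n_queries = 6, truncate_frac = 0.4,
                       n_mask_frac = 0.02, seed = 7)
lk <- generate_lookup(qs$truth, species_pool = unique(sp), seed = 8)
qs$queries$vernacular <- lk$assignments$vernacular
rep <- market_report(qs$queries, gen$library, lk$lookup)
rep[1, c("query", "best_species", "percent_identity", "status")]
#>      query best_species percent_identity status
#> 1 query_01  species_014         98.05556  match
unlist(market_summary(rep)[c("n_match", "pct_match")])
#>   n_match pct_match
#>         6       100
```

(98.06% identity = 353 identical of 360 surviving aligned bases; the 7
masked Ns count as mismatches.)

The full pipeline — both loci plus their concatenation, gap summaries,
efficacy tables, market report, bootstrapped tree — runs from one
configuration:

```r
run_pipeline(run_config(seed = 1), "out/")   # writes table1.tsv,
# table2.tsv, table3.tsv, gaps.tsv, tree.nwk, placements.tsv, run.log
```

or from a shell via the bundled script `inst/exec/barcodekit`
(`barcodekit run --seed 1 --out out/`).

## Documentation

The methods vignette
(`vignettes/barcode-gap-identification.Rmd`) explains the model, the
estimators, the threshold-optimization criterion, what the synthetic
generator does and does not emulate, and the package's numerical
conventions.
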