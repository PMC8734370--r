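# circaloop

Analysis toolkit linking **rhythmic RNA polymerase II occupancy** to
**diurnal chromatin interactions**. It is written for regulatory genomicists
working with time-course ChIP-seq/RNA-seq plus RNAPII ChIA-PET loop calls at
a morning and an evening time point, who need the downstream statistics of
such a study as reproducible, tested building blocks rather than one-off
scripts.

## What it computes

* **Rhythm and phase calls** by cosinor harmonic regression: for each
  feature, `y(t) = m + a·cos(2πt/T) + b·sin(2πt/T)` is fitted over a period
  grid T ∈ [20, 28] h (step 0.5), amplitude `√(a²+b²)`, phase
  `(T/2π)·atan2(b,a) mod T` mapped to clock time, F-test p-value with
  Benjamini–Hochberg correction, rhythmic at q < 0.05. Row normalization is
  `Ei/M − 1` (each sample over the row mean, minus one).
* **Gene/peak annotation**: summit-in-gene-body (+500 bp promoter-side)
  assignment with FPKM tie-breaking; RG/NG/NEG gene classes; loop-anchor vs
  basal peak classes (peaks ±10%); tissue expression breadth (FPKM > 1).
* **Loop statistics**: filtering (FDR < 0.05, PET ≥ 5, intra-span > 8 kb),
  unique interacting gene pairs with RR/RN/NN/NEG-associated classes,
  common vs time-specific loops, pair coexpression and circular phase
  spans against distance-matched random pair controls (KS tests).
* **Chromatin spatial clusters**: node genes of degree ≥ 3 with their
  linked genes, classified AM-specific / PM-specific / static by a >3
  degree ratio between time points; composition, static-cluster linked-gene
  overlap, and a seeded permutation test for phase enrichment.
* **Connectivity networks**: igraph-backed gene networks, one/two-hop
  expansion from clock-gene seeds (hand-written BFS with induced edges),
  core nodes (degree ≥ 32), AM−PM network differencing, GraphML export.
* **Contact maps**: binned symmetric matrices at any resolution, iterative
  correction (ICE), and strand-aware TSS-centered aggregate interaction
  profiles over ±50 gene ranks.
* **A seeded synthetic-data generator** with ground-truth labels (gene
  classes, phases, the occupancy→expression lag, designed cluster classes)
  so the whole pipeline validates end to end offline.

## Worked example

```r
library(circaloop)

ds    <- simulate_dataset(sim_config(), seed = 1)   # 2000 genes, 2x3000 loops
norm  <- normalize_diurnal(ds$counts)
calls <- detect_rhythms(norm)
head(calls[calls$is_rhythmic, c("feature_id", "q_value", "period_h", "phase_h", "amplitude")], 3)
#>   feature_id      q_value period_h   phase_h amplitude
#> 1     g00001 2.526528e-06       27  2.679394 0.7919944
#> 4     g00004 3.058021e-06       25 23.989362 0.5165796
#> 7     g00007 1.494425e-05       22  8.362622 0.9589762

labels <- classify_gene_expression(ds$counts, calls)
table(labels$expression_class)
#> NEG  NG  RG
#> 601 642 757

calls_occ <- detect_rhythms(ds$occupancy$signal)
pairing   <- data.frame(feature_a = ds$occupancy$peak_gene$peak_id,
                        feature_b = ds$occupancy$peak_gene$gene_id)
lag <- mean_phase_lag(calls_occ, calls, pairing)
sprintf("mean occupancy -> expression lead: %.2f h over %d pairs",
        lag$mean_lag_h, lag$n_pairs)
#> "mean occupancy -> expression lead: 2.05 h over 729 pairs"
```

757 of the 2000 genes are classified rhythmically expressed (RG; the
generator plants ~37%), 601 are non-expressed (NEG), and the recovered mean
phase lead of polymerase occupancy over transcript accumulation is 2.05 h
against a simulated 2 h. Continuing into loops and clusters:

```r
loops_am <- filter_loops(subset(ds$loops, time_label == "t08"))
pairs_am <- loops_to_gene_pairs(loops_am, ds$occupancy$peaks,
                                ds$occupancy$peak_gene, labels, ds$genes)
round(100 * prop.table(table(pairs_am$pair_class)), 1)
#>   NN   RN   RR
#> 22.8 36.2 41.0

loops_pm <- filter_loops(subset(ds$loops, time_label == "t20"))
pairs_pm <- loops_to_gene_pairs(loops_pm, ds$occupancy$peaks,
                                ds$occupancy$peak_gene, labels, ds$genes)
cscs <- classify_cscs(build_cscs(pairs_am, pairs_pm))
table(cscs$csc_class)
#> AM-specific PM-specific      static
#>         145         144        1042
```

Rhythmic–rhythmic (RR) pairs dominate because phase-coherent rhythmic genes
are preferentially looped in the generator, and the cluster classifier
recovers the designed AM/PM/static node genes (the ~1000 static clusters
are background hubs whose degrees balance across the day).
`run_all(sim_config(), circa_config(), out_dir = "run1", seed = 1)` chains
every stage, writes per-stage TSV/BEDPE/GraphML outputs plus `report.md`
and a JSON manifest, and `validate_against_truth()` scores the run against
the generator's labels. A thin CLI over these functions is in
`inst/scripts/circaloop.R`.

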