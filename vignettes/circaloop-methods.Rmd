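---
title: "circaloop: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circaloop: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What the package models

Plant transcriptomes oscillate over the day, and a sizable fraction of that
oscillation is set up at the level of RNA polymerase II (RNAPII): the
polymerase is recruited rhythmically to promoters, a couple of hours before
the corresponding transcripts peak, and the loops it tethers between gene
promoters (measured by RNAPII ChIA-PET at a morning and an evening time
point) reorganize over the same cycle. `circaloop` implements the analysis
layer of such a study as reusable, tested components:

1. **Rhythm detection** on diurnal time courses (six clock times x two
   replicate days),
2. **Annotation** of genes (rhythmic RG / non-rhythmic NG / non-expressed
   NEG) and of RNAPII peaks (loop anchor vs basal promoter),
3. **Loop analysis**: filtering, interacting gene-pair classification,
   time-point comparison, coexpression and phase-span statistics against
   distance-matched random controls,
4. **Chromatin spatial clusters (CSCs)**: star-shaped node-gene
   neighborhoods classified AM-specific / PM-specific / static by a degree
   ratio, with a permutation test for phase enrichment,
5. **Connectivity networks** seeded at clock genes, with one- and two-hop
   expansion and AM/PM differencing,
6. **Contact maps**: binned matrices with iterative correction and
   TSS-centered aggregate profiles in gene-rank space,
7. A **synthetic-data generator** that emulates the statistical structure of
   the real study and carries ground-truth labels, so every stage above is
   testable end to end without any sequencing data.

## Rhythm detection by cosinor regression

Upstream studies of this kind often call rhythms with trained detectors
(deep-learning classifiers) or algorithm ensembles. Those are not
deterministic, parameter-transparent components, so `circaloop` uses
single-component cosinor harmonic regression, which preserves the decision
surface that matters (a q-value threshold, a bounded period window, a phase
and an amplitude per feature) while being exactly reproducible:

$$ y(t) = m + a\cos(2\pi t/T) + b\sin(2\pi t/T) + \varepsilon $$

fitted by least squares at every grid period \(T \in \{20, 20.5, \dots,
28\}\) h. The best-\(R^2\) period is retained; amplitude is
\(\sqrt{a^2+b^2}\); phase is the clock time of the fitted peak,
\((T/2\pi)\,\mathrm{atan2}(b,a) \bmod T\), mapped into \([0, 24)\) h; the
p-value is the F-test of \((a,b)=(0,0)\) on \((2, n-3)\) degrees of freedom.
Q-values are Benjamini–Hochberg adjusted across features and a feature is
rhythmic when \(q < 0.05\). Both sampling days are fitted jointly at clock
time mod 24, i.e. treated as biological replicates of one diurnal cycle.

Numerical conventions: a constant series has \(F = 0\), \(p = 1\), amplitude
0; rows with zero mean cannot be `Ei/M - 1` normalized and are dropped with
a warning before fitting; rows with fewer than six finite samples are
skipped. The period grid is the closed grid including both endpoints; the
selection maximizes \(R^2\) with ties going to the shorter period. No
selection correction is applied to the best-grid-period p-value — with 12
samples and a 17-point grid the selection effect is small, and the null
calibration is verified empirically in the acceptance suite (the false-call
fraction of 2000 truly flat noisy series is far below the 5% bound).

Phase relationships between paired signal sets (occupancy vs expression) use
the circular difference \(\min(|a-b|, 24-|a-b|)\); the mean lag keeps the
pairs where expression genuinely trails occupancy (signed lag in \((0,12]\)
h) and averages them, which recovers the simulated 2 h lead to within a few
hundredths of an hour at the default noise level.

## Thresholds and where they come from

All operating points sit in one `circa_config()` object:

| parameter | default | meaning |
|---|---|---|
| `q_threshold` | 0.05 | BH q below which a feature is rhythmic |
| `period_min`, `period_max` | 20, 28 h | cosinor period window |
| `fdr_max`, `min_pet` | 0.05, 5 | loop retention thresholds |
| `min_intra_span` | 8000 bp | minimum intra-chromosomal anchor span |
| `anchor_extension_frac` | 0.10 | peak widening for anchor overlap |
| `gene_extension` | 500 bp | promoter-side window for summit assignment |
| `node_min_degree` | 3 | CSC node qualification degree |
| `csc_ratio` | 3 | degree fold-change separating time-specific CSCs |
| `core_min_degree` | 32 | core network node threshold |
| `breadth_fpkm_min` | 1 FPKM | tissue-expression threshold for breadth |
| `n_perm` | 1000 | permutations for empirical p-values |
| `expressed_min` | 10 counts | summed-count threshold for "expressed" |

`expressed_min` deserves a note: the rule "expressed = total counts above a
given value" leaves the value unspecified in the source methodology, so the
package exposes it with a deliberately small default (10 summed raw counts
over 12 samples) that cleanly separates the generator's near-zero
non-expressed genes from everything else.

Two genuinely open reading choices are resolved as documented defaults
rather than hidden constants:

* **Direction of the 500 bp gene extension.** Whether the assignment window
  extends upstream, downstream, or both ways is not recoverable from the
  methodology text. The default is 500 bp upstream of the TSS,
  strand-aware, because peaks of a pre-initiation-complex antibody
  concentrate at promoters; `extension_direction` switches to
  `"downstream"` or `"both"`.
* **Common-loop criterion.** Whether two loops at different time points are
  "the same" is defined here as overlap of both corresponding anchors by at
  least 1 bp after canonical anchor ordering — the most permissive
  reproducible rule; no reciprocal-fraction requirement is imposed.

In the CSC enrichment test, the target set ("genes whose phase is around a
center, with high amplitude") is operationalized as: rhythmic genes with
amplitude at or above the median rhythmic amplitude
(`amplitude_quantile = 0.5`) and circular phase within `phase_halfwidth = 2`
h (one sampling interval) of the center. The statistic counts node plus
linked genes (`include_node = TRUE`); both choices are arguments. The
empirical p-value uses the add-one estimator
\((1 + \#\{\text{null} \ge \text{obs}\})/(n_{perm}+1)\), so it is never
zero and is near-uniform under an exchangeable null (verified over 200 null
runs in the acceptance suite).

Loader conventions: everything internal is 0-based half-open (BED); GFF3 is
converted at the boundary, and the loop reader exposes `one_based = TRUE`
for interaction tables whose coordinate convention is undeclared.

## The synthetic-data generator

The generator defines the study conditions the tests run under; its defaults
are fixed, not tuning knobs:

* 2000 genes on 4 chromosomes, lengths 1–10 kb, gaps 1–20 kb;
* 37% of genes truly rhythmic — the published fraction of rhythmic
  transcripts — with phases drawn from a von Mises distribution centered at
  08:00 (concentration 2), mirroring the morning-clustered rose plots, and
  relative amplitudes uniform on 0.4–0.9;
* 30% non-expressed genes (near-zero counts);
* multiplicative lognormal noise with CV 0.15 on a cosine mean — the
  analysis fits normalized continuous signals, so count-level
  negative-binomial noise would add realism the decision surface never
  sees, while the lognormal keeps the F-test assumptions approximately
  valid and makes the signal-to-noise ratio a single dial;
* one promoter peak per expressed gene whose intensity trace runs at the
  gene's phase minus a 2 h lag — the published lead of polymerase
  recruitment over mRNA accumulation; both days share the true phase, so
  replicate disagreement is pure noise;
* 3000 loops per time point (08:00 and 20:00): designed star clusters for
  60 AM-specific, 60 PM-specific and 60 static node genes (time-specific
  nodes have degree 4–9 at their time and 0–1 at the other; static nodes
  keep equal degrees with ~10% of linked genes shared between times,
  matching the reported overlap of static-cluster linked genes), and
  background pairs among the remaining expressed genes in which
  rhythmic–rhythmic pairs are drawn phase-coherent (span ≤ 4 h) with
  probability 0.7. Half of each star's spokes are drawn within 20 gene
  ranks of the node so aggregate TSS-centered profiles have the distance
  decay real loop sets show. All loops satisfy the downstream filter by
  construction (PET ≥ 5, FDR < 0.05, intra-span > 8 kb);
* a small fraction (5%) of background loops anchor at a non-expressed gene.
  Whether such anchors reflect real occupancy or annotation artifacts is
  left open by the source data, so the generator exposes the rate
  (`neg_loop_frac`) without committing to a mechanism — and since
  non-expressed genes carry no peak, these loops deliberately map to no
  gene pair through the peak-mediated assignment path;
* a 20-tissue FPKM panel in which rhythmic genes are broadly expressed and
  non-rhythmic genes span narrow breadths, reproducing the direction of the
  published breadth contrast.

Everything is deterministic given a seed, and each dataset ships truth
labels (per-gene class, phase, amplitude; per-loop gene pair and origin;
per-node designed CSC class) that `validate_against_truth()` scores against
pipeline output.

What the generator does **not** emulate: read-level noise, peak-calling
uncertainty, interchromosomal loop biology beyond uniform background pairs,
phase-dependent wiring of designed clusters, trans effects, or dampening
and period drift. Passing tests therefore demonstrate that the analysis
logic is correct and calibrated under the stated statistical structure, not
that it would be robust to artifacts upstream tools introduce in real data.

## Problem sizes and runtime choices

The test suite exercises the generator at two scales: a 400-gene / 600-loop
dataset for module-level properties, and the full default 2000-gene /
3000-loop dataset for the acceptance checks (null calibration of the rhythm
caller at 2000 series; phase-lag recovery; class and CSC recovery;
permutation calibration over 200 null runs at 199 permutations each). These
sizes keep the whole suite under a minute of simulation time while leaving
every statistical check adequately powered; the enrichment permutation
count is reduced from the analysis default of 1000 only inside the
calibration loops, where the add-one estimator's resolution (1/200) is
already finer than the tolerance being checked.

## Known limitations

* Hop expansion works in gene space; an anchor-region mode (merging
  overlapping anchors into non-gene nodes first) is noted as future work.
* Contact-map normalization implements iterative correction only; the
  eigenvector/compartment step some pipelines add is out of scope because
  no downstream result here consumes it.
* The cosinor detector assumes a single harmonic; sharply peaked or
  biphasic wave shapes lose power relative to ensemble detectors.
* `matched_random_pairs` widens empty log-distance bins rather than
  failing, which slightly blurs the matched distribution when the candidate
  pool is sparse at extreme distances.
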