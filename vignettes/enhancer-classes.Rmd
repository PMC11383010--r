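---
title: "Discovering embryonic enhancer classes from CUT&RUN profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering embryonic enhancer classes from CUT&RUN profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerclass)
```

## The problem

At zygotic genome activation, thousands of accessible chromatin regions
appear across the embryonic genome. Distal (TSS-distant) accessible
regions are putative enhancers, but they are heterogeneous: some carry
only H3K4me1 with acetylation (typical enhancers), while a distinct
subset additionally carries H3K4me2 and looks, by its histone-mark
profile, like a promoter. These two classes differ in DNA methylation,
pioneer-factor dependence and gamete history, so separating them
reliably matters for understanding how the embryonic regulatory program
is launched. This package implements that separation as a reusable,
testable pipeline, together with the downstream analyses that
characterize the two classes.

## The model and its assumptions

The classifier operates on a region × feature matrix built from CUT&RUN
fragment coverage. For each accessible region and each histone mark we
record three numbers — coverage in the 500-bp upstream flank, the open
interval, and the 500-bp downstream flank — normalized as
`log2(count / (len/500) / (total/1e6) + 1)`, i.e. log2 "RPKM/2" (reads
per 500 bp per million mapped) with a pseudocount of 1 so empty
intervals map to exactly 0. Ten marks give 30 features. The underlying
assumptions:

* fragment counts are proportional to local chromatin occupancy after
  restricting to mononucleosome-sized fragments (140–250 bp, inclusive)
  and trimming each to its central 73 bp, which sharpens positional
  signal to the nucleosome dyad;
* flank asymmetry is biologically meaningful but its genomic direction
  is not, so each region is oriented by total signal ("downstream" is
  the higher-coverage flank, summed over all marks);
* a radial-kernel SVM on the first three principal components of the
  centered (not variance-scaled) feature matrix captures the
  promoter/enhancer distinction well enough that distal regions
  predicted "promoter" are exactly the promoter-like candidates.

The SVM is trained only on positionally unambiguous regions — promoters
(contain a CAGE-selected TSS) versus distal elements (≥ 2 kb from every
isoform TSS) — and then applied to all regions. Disagreements between
the positional annotation and the prediction define the four mismatch
groups (typical/promoter-like enhancers, typical/enhancer-like
promoters).

Because the SVM decision is relative to the training mixture, the final
class calls use absolute fold-enrichment thresholds against the IgG
control, measured as mean linear RPKM/2 over the center + downstream
interval with a pseudocount of 0.1 in both numerator and denominator:

| class | H3K4me1 | H3K27ac | H3K4me2 | H3K4me3 |
|---|---|---|---|---|
| H3K4me2 enhancer (distal) | ≥ 2 | ≥ 1.5 | ≥ 2 | — |
| H3K4me1 enhancer (distal) | ≥ 2 | ≥ 1.5 | < 1.25 | — |
| poised enhancer (distal) | ≥ 2 | ≤ 1.5 | — | — |
| proximal potential enhancer | — | — | (≥ 2 flags H3K4me2) | < 1.25 |

Distal regions with H3K4me2 fold in the 1.25–2 gray zone are left
`unclassified`: they belong to neither class and excluding them keeps
both groups clean. A separate strict H3K4me2 flag (fold > 3) supports
the distance analyses that need a high-confidence H3K4me2 set.

## Parameters that matter

All thresholds live in one validated object, `pipeline_params()`:

* fragment bounds 140/250 bp (inclusive — the size range is a closed
  interval) and trim width 73 bp;
* flank width 500 bp; proximal cut 2000 bp (distance ≥ 2 kb ⇒ distal);
* CAGE support > 20 tags (strict), argmax per gene, ties broken at the
  smallest coordinate;
* normalization unit 500 bp with pseudocount 1; fold pseudocount 0.1
  (0.01 in log2 mode, matching the convention of ratio tracks);
* SVM γ = 1, cost = 1, PCs 1–3; PCA centered, unscaled (exposed via
  `pca_scale`);
* KDE bandwidth h = 3 on a 125 × 125 grid;
* directional transcription: 100-bp windows, ≥ 1 RPKM, ≥ 2-fold,
  ≥ 2 samples;
* methylation: window 200 bp, CpG depth ≥ 10, strata at 20 %/80 %
  (strict inequalities: exactly 20 % or 80 % is "medium");
* coverage matrices: ± 2500 bp at 25-bp bins (200 bins); adaptive color
  scale from the leftmost 20 bins (mean ⇒ `zmin`) and central 8 bins
  (90th percentile ⇒ `zmax`).

## Numerical choices

Several conventions are under-determined by the procedure itself; the
package fixes them as follows and exposes the consequential ones:

* **Coordinates** are 0-based half-open throughout (BED). The distance
  from an interval to a point is 0 inside the interval and otherwise
  `max(start − p, p − end)` — the gap measured from the region edge.
* **Trim arithmetic**: the trim center is the midpoint *base* of the
  fragment, `floor((start + end − 1)/2)`, and the 73-bp interval is
  `[center − 36, center + 37)`. This is deterministic for even and odd
  fragment lengths.
* **Orientation** sums are taken on linear (pre-log) RPKM, so a single
  strong mark cannot be out-voted by many empty ones after log
  compression; exact ties stay unflipped for stability on symmetric
  data.
* **Fold enrichment** of an exactly 0/0 pair is defined as 1 (no
  evidence either way), mirroring the skip-zero-over-zero convention of
  ratio tracks.
* **Percentiles** for the adaptive scale use the linear-interpolation
  definition (R type 7); if a degenerate matrix yields `zmax < zmin`,
  `zmax` is clamped to `zmin`.
* **KDE bandwidth** follows the classical 2-D routine in which the
  bandwidth argument is four Gaussian standard deviations per axis
  (sd = h/4); the package's grid agrees with that routine to machine
  precision and with direct kernel sums in the tests.
* **PCA signs** are fixed by making the largest-magnitude loading of
  each component positive, so scores are reproducible across BLAS
  builds.
* **Rank tests** switch between exact enumeration (pooled n ≤ 12 and no
  ties) and the tie- and continuity-corrected normal approximation; an
  all-tied input returns p = 1 rather than NaN. Kruskal–Wallis group
  comparisons use the chi-squared approximation only — exact
  small-sample Kruskal–Wallis is a documented omission.
* **qPCR fold decrease** is the ratio of arithmetic group means of
  control-normalized `2^−ΔCt` values (geometric means are available via
  `mean_type`); because normalization divides by the control mean, the
  control group mean is exactly 1 by construction.
* **Chi-squared motif test** bins per-region hits as {0, 1, ≥ 2},
  giving the 2 × 3 table with 2 degrees of freedom; the binning is an
  interpretation and other binnings can be supplied as a pre-built
  table.
* **"Equivalently hypomethylated"** in the gamete-overlap analysis is
  operationalized as the same < 20 % cut in embryo, egg and sperm; the
  cut is an exposed argument.
* **PWM hits** are log-odds scores at ≥ 60 % of each motif's maximum
  achievable score by default (thresholds can be set explicitly);
  scanning covers both strands of a window of 200 bp + motif length − 1
  so every footprint touching the core window is seen, and zero-cells
  are stabilized with a 10⁻³ pseudo-probability.

## What the synthetic data emulate — and what they do not

`make_truth_catalog()` lays out a small genome (two 4-Mb chromosomes by
default) with genes, isoform TSSs, CAGE tags, exons and planted region
classes; generators then emulate each data type the pipeline consumes:

* `simulate_cutrun_library()` draws fragments from a uniform background
  plus Gaussian enrichment (sd 150 bp) at region centers, with
  per-(class, mark) multipliers. The default archetype encodes the
  qualitative biology — promoters high in H3K4me3/H3K4me2/acetylation;
  H3K4me2 enhancers high in H3K4me1/H3K4me2/H3K27ac/H2A.Z but flat in
  H3K4me3; H3K4me1 enhancers with H3K4me2 at background; poised
  enhancers H3K4me1-only — with called marks at ≥ 4× their detection
  thresholds so that recovery failures indicate pipeline defects, not
  marginal effect sizes. Fragment lengths come from a three-component
  mixture including sub-140 and over-250 bp fragments so the size
  filter does real work.
* `simulate_rnaseq()` plants directional strand-specific signal at a
  chosen fraction of enhancers (5 RPKM by default, oriented by the
  region's planted orientation) over sub-threshold background noise
  (< 0.4 RPKM), plus exonic gene-body coverage.
* `simulate_methylomes()` draws binomial per-CpG counts around
  class-specific means (H3K4me2 enhancers and promoters hypomethylated
  in the embryo; H3K4me1/poised/background hypermethylated), with a
  seeded fraction of H3K4me2 enhancers hypomethylated in both gametes
  (0.69 by default) and a low-depth site fraction to exercise the
  depth-10 filter.
* `simulate_expression_and_qpcr()` gives the two gene groups logistic
  activations with different onsets (3.3 vs 2.5 h.p.f.) and draws
  technical-triplicate Ct values with a planted crispant knockdown.

Every generator is a pure function of (configuration, seed); per-library
streams are derived by hashing the master seed with the library name, so
adding a library never perturbs the others.

What the simulations deliberately do **not** model: mappability and
repeat structure, GC and fragmentation bias, realistic PCR-duplicate
families, bisulfite conversion error, spatial autocorrelation of
methylation, overdispersed biological replicates, or linked
enhancer–gene regulatory effects. Passing tests therefore demonstrate
that the pipeline's logic is correct under its stated model of the data,
not that the thresholds are optimal for any particular real dataset.

## Problem sizes

The test suite and the acceptance script size their simulations for a
single CPU: the recovery analysis plants 100 regions per class
(500 regions) on a 10-Mb genome with 1–2 M fragments per mark across
10 marks plus IgG; calibration uses 1000 replicate confidence intervals
and 5000 null rank tests; all other checks run on a shared 78-region
catalog. At these sizes the whole suite completes in about two minutes
and the acceptance script in about one.

## Known limitations

* The SVM mismatch groups depend on the composition of the training
  mixture; with synthetic classes that are perfectly separable in PC
  space, "promoter-like enhancers" only arise when the planted H3K4me2
  class genuinely overlaps the promoter cloud (the test suite
  constructs this case explicitly).
* Region-level fold enrichment reuses the 0.1 ratio pseudocount; on
  very shallow libraries the ratio is noisy and the 1.25-fold gate for
  H3K4me1 enhancers is the first to blur (visible in the worked example
  at 200 k fragments).
* Replicate handling is pooling by concatenation; no per-replicate
  dispersion model is fitted.
* Secondary-source peaks are assumed to be in the primary assembly
  already; genome lift-over is out of scope.
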