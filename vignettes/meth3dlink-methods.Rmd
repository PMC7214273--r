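---
title: "Methods: methylation dynamics and long-range regulatory linkage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation dynamics and long-range regulatory linkage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meth3dlink)
```

## The analysis problem

When a leukemic B-cell precursor is driven to transdifferentiate into a
macrophage-like cell, its DNA methylome is remodelled. An EPIC-style
methylation array sampled over a timecourse (0, 3, 12, 24, 48, 72 and 168
hours in this package's sample model) yields a probes × samples matrix of
beta values — per-CpG methylation fractions in [0, 1]. The questions this
package answers, stage by stage, are:

1. **Which CpGs change?** A CpG is called differentially methylated (DMC)
   when the endpoint beta change is large *and* statistically supported:
   \(p < 0.05\) (strict) and \(|\Delta\beta| \ge 0.66\) (inclusive), with
   \(\Delta\beta = \bar\beta(168\,h) - \bar\beta(0\,h)\).
2. **Does the endpoint mimic the target cell type?** Each passing DMC's
   168 h methylation is compared against positive-control (macrophage-like)
   and negative-control (parental-line) profiles.
3. **Which changes act locally?** Gene-annotated DMCs are correlated with
   their gene's expression; demethylation tracking expression gain is
   classified *activation*, tracking loss *repression*.
4. **Which act at a distance?** DMCs falling into the other-end fragments of
   promoter-capture Hi-C (PCHi-C) interactions are correlated with the
   looped target gene's expression and classified *enhancer* or candidate
   *silencer*.
5. **Is a specific loop gained?** UMI-4C contact profiles for two conditions
   are compared by a chi-square test on UMI counts inside vs outside a
   target fragment window, visualised with a smoothed trend line and a
   multi-scale domainogram.

## Statistical choices and their rationale

### The per-probe test

The thresholds above pair a significance filter with an endpoint
effect-size filter, but the test statistic itself is a free choice. The
default is a two-sided Welch t-test between the 0 h and 168 h replicate
groups — the simplest test matching the endpoint semantics of the
\(\Delta\beta\) filter — with a one-way F-test across all seven timepoints
(`method = "anova_f"`) as an alternative that uses the full trajectory.
Tests run on beta values directly; a logit (M-value) transform is available
for the test stage only, never for the \(\Delta\beta\) filter. Degenerate
probes (zero variance, equal means) get \(p = 1\); a zero-variance shift
yields the smallest positive double rather than 0, keeping p in (0, 1].

A caveat worth stating plainly: with 3 replicates per group the
Welch–Satterthwaite approximation is *conservative* — simulation with
`stats::t.test` on ideal Gaussian data shows a true size near 0.032 at
nominal 0.05. The package's type-I calibration checks therefore assert the
two-sided nominal band for the F-test (exact under normality, and
empirically on target at 2000 null probes) and assert one-sided
conservatism for the Welch default. Users wanting nominal-level error
control across the trajectory should prefer `anova_f`; users mirroring the
endpoint-contrast design should keep `welch_t` and accept its conservatism.

The filter is read literally: strict `<` on p, inclusive `>=` on
\(|\Delta\beta|\), and the p filter applies to the *raw* p-value by default
(BH-adjusted filtering is available with `adjust = "bh"` but off, since the
design pairs an unadjusted p with a strong effect-size gate).

### Permutation correlation for seven timepoints

Methylation–expression linkage correlates n = 7 per-timepoint means. At
that sample size the t-approximation for a Pearson r is unreliable, so
significance comes from the exact permutation distribution: the two-sided p
is the fraction of all \(n! = 5040\) pairings (identity included) whose
\(|r|\) reaches the observed \(|r|\). Enumeration is exact and cheap up to
n = 8; beyond that a seeded Monte-Carlo sample of 10,000 pairings with an
add-one estimator is used. The smallest attainable p at n = 7 is
\(2/5040 \approx 4\times10^{-4}\) (the two perfectly monotone pairings).
Spearman correlation is available as a config option; expression is taken
as provided on a log2 scale, with no re-normalisation.

Link classes are defined relative to the direction of the methylation
change: for a hypomethylated probe, \(r < 0\) (expression rises as beta
falls) is activation / enhancer and \(r > 0\) repression / silencer; signs
invert for hypermethylated probes. Each (probe, gene) pair is tested
independently, mirroring per-gene treatment; BH across links is optional.
When a gene accrues several classified distal links, its enhancer/silencer
label is taken from the strongest link (smallest permutation p, ties broken
by larger \(|r|\)), so the enhancer + silencer gene counts always partition
the distinct correlated target genes.

### Enrichment

TF category enrichment uses the upper-tail hypergeometric probability
\(P(X \ge k)\) computed through `stats::phyper`'s stable log-space tail,
with BH adjustment across the tested categories. The universe is the TF set
present in the supplied binding-site track (configurable); the category map
is a plain TSV input, keeping the package hermetic — no live ontology
queries.

### Coordinate conventions

Interval files (BED, bedGraph, ibed) are 0-based half-open; probe manifest
positions are 1-based single-bp. The two dialects meet in exactly one rule:
a manifest position \(p\) lies inside \([start, end)\) iff
\(start \le p-1 < end\). Internally intervals become `GRanges` and all
containment runs through `GenomicRanges::findOverlaps`; strand is parsed
but ignored (CpG methylation is strand-symmetric). Every overlap stage is
tested against a naive all-pairs containment oracle.

### UMI-4C

Contact quantification is restricted to fragments whose midpoint lies
between 500 bp and 1 Mb from the bait (inclusive at both ends) — the band
in which this assay quantifies reliably. Counts are depth-normalised by the
profile's total UMIs before smoothing or differencing; this is the minimal
normalisation that makes two conditions comparable and is applied uniformly.
The trend line is a centred moving average (odd window, truncated at the
edges); the domainogram evaluates the windowed mean difference
(condition B − condition A) over a series of odd scales, so its scale-1 row
equals the raw normalised difference. The contact test is a Pearson
chi-square (df = 1, no continuity correction by default — counts are large;
Yates correction by flag) on the 2×2 table of UMIs inside/outside the
target window. "Adjusted p" is BH across the windows tested in one call; a
single-window run reports adjusted = raw.

## The synthetic study generator

`generate_dataset()` emulates the deposited-data shapes of such a study so
every stage is testable without any download. Its defaults *are* the study
conditions used throughout the tests:

- 2000 probes, 100 planted hypomethylated and 1 hypermethylated (the
  direction skew of this conversion is overwhelmingly demethylation), 3
  replicates per timepoint, beta noise sd 0.03 (truncated Gaussian;
  Beta-distributed noise by flag), expression noise sd 0.2 on log2 scale.
- Planted probes follow a **logistic** (not linear) trajectory between a
  high plateau drawn in [0.70, 0.95] and a low plateau in [0.05, 0.25],
  midpoint drawn in [12, 72] h with scale midpoint/6 — a gradual sigmoid
  transition without asserting specific kinetics. The plateau pair is drawn
  jointly, conditioned on a difference of at least 0.67, so the expected
  endpoint \(|\Delta\beta|\) of every planted probe clears the 0.66 call
  threshold; null probes have constant expected beta.
- The positive control equals the planted 168 h expectation and the
  negative control the 0 h expectation, each with replicates.
- Planted links are fixed proportions of the planted hypomethylated set —
  20% local activation, 5% local repression, 12% distal enhancer, 8% distal
  silencer — echoing the roughly 80:20 and 60:40 splits such analyses
  report. Activation-linked expression increases affinely with
  \(1-\beta\) of its probe; repression-linked decreases; one probe per
  link, so ground truth is unambiguous.
- The genome model is a single synthetic chromosome tiled by equal 4 kb
  restriction fragments with baits at gene promoters — simplicity over
  realism. Planted distal probes are placed in distinct other-end fragments
  of interactions whose bait carries the target gene; background
  interactions avoid planted probes so the truth table is exact.
- One planted enhancer doubles as the UMI-4C loop target; its bait is
  seated 50 fragments (200 kb) away so the loop sits inside the reliable
  distance band. Per-fragment counts are Poisson with mean
  \(depth \cdot k^{-\alpha}\) (k = distance in fragments, depth 2000,
  \(\alpha = 1\)), times a gain factor of 5 at the loop fragment in the
  boosted condition only.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: array probe chemistry and normalisation
artifacts, cross-reactive/SNP probes, batch effects, realistic human
coordinates and interaction topology, cell-composition mixtures, and
replicate-level expression (expression is one value per timepoint, as from
a summarised array series).

## Problem sizes and determinism

All randomness is fixed by a single seed per generated study
(`sim_config(seed = )`), with the Monte-Carlo permutation path separately
seeded, so end-to-end runs are bit-identical under a fixed seed. The test
suite works at reduced scale chosen for statistical adequacy: 2000-probe
studies for calibration and recovery (20 seeds for the F1 experiment),
1000 simulations for contact-test null calibration, 50 seeds for loop
detection, and 300-500-probe studies for end-to-end property checks. The
methods themselves are size-agnostic.

## Known limitations

- The Welch default's small-sample conservatism, discussed above.
- Permutation p-values at n = 7 cannot fall below \(2/5040\); family-wise
  adjustment across many links (off by default) is therefore coarse.
- Multi-gene probes contribute one link per gene with no shared-probe
  dependence modelling.
- The enhancer/silencer label is correlational; no causal claim is made.
- The chi-square contact test conditions on the realised sequencing depths;
  replicate-level biological variance in contact profiles is not modelled.

## A worked run

```{r, eval = FALSE}
library(meth3dlink)
study <- generate_dataset(sim_config(seed = 1))
report <- run_pipeline(study = study, out_dir = "results/run1")
print(report)
```

The report's counts (significant CpGs, direction split, gene/non-gene
partition, link classes, TF enrichment, distal chain, multiplicity
histogram, CTCF overlap, and the loop test) are each reproducible from the
stage outputs written to `out_dir`, and every percentage is printed to one
decimal place.
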