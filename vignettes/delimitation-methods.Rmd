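---
title: "Methods: integrative species delimitation with tolerance intervals and climate envelopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative species delimitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delimitax)
```

## The problem

A species complex — here modelled on the Andean lizard *Liolaemus
walkeri* complex, with three candidate populations (Ancash, Ayacucho,
Cusco) and two named species (*L. tacnae*, *L. walkeri*) — often hides
distinct lineages behind nearly identical external morphology. The
pipeline implements a discovery-then-validation workflow:

1. **Discovery**: exclusive (monophyletic) haplotype clades on a supplied
   gene tree flag candidate species.
2. **Validation**: three independent lines of evidence are scored for
   every pair of candidates — fixed differences in binary characters,
   gaps in continuous characters, and non-identity of climatic niches.
3. **Integration**: a transparent decision rule converts the per-pair
   evidence into verdicts (`delimited`, `not-delimited`, `insufficient`).

The package does not infer trees, align sequences, or fit
maximum-entropy niche models; those stages are consumed as inputs or
replaced by a simpler engine (below).

## Tolerance statistics

Both morphological criteria are phrased as *statistical tolerance*
statements about the population, not about means: a diagnostic gap must
persist for 95% of each population, not merely between sample averages.
Throughout, P = 0.95 is the population content and 0.95 the confidence
(`tolerance_config()`).

**Continuous characters.** A two-sided normal tolerance interval is
computed with the Howe factor

$$k = z_{(1+P)/2}\sqrt{\frac{(n-1)(1+1/n)}{\chi^2_{\alpha,\,n-1}}},$$

so the interval is $\bar x \pm k s$. The plain $k_2$ formula (no small-n
correction term) is used: it reproduces the published meristic table of
the study system to one decimal on every verified cell, so any
correction factor would have to preserve that surface. Quantiles come
from exact numerical inversion (base R `qnorm`/`qchisq`), never a
series approximation; the tests cross-check against an independent
`uniroot` inversion of the chi-square CDF. Two taxa show a
*morphological gap* in a character when their closed tolerance intervals
are disjoint; intervals sharing an endpoint count as overlapping (the
conservative tie-break).

**Binary characters.** A character is a *fixed difference* when the two
observed state sets are disjoint and non-empty. Because small samples
can easily miss a rare alternative state, every fixed difference carries
a caveat: a one-sided Wilson score bound at 95% confidence on the
alternative-state proportion (one-sided $\alpha$ used directly, not
$\alpha/2$), propagated through the binomial quantile of a future sample
of size $m$ to a *count bound* — how many individuals out of $m$ could
still carry the unseen state in 95% of such samples. The future-sample
size $m$ defaults to the observed $n$; the choice is exposed in
`decision_config(m_future=)` because published accounts of this
procedure rarely state it. The caveat is reported alongside the fixed
difference but never vetoes a verdict: fixation is judged on the
observed sample.

Sex and age stratification happens at the data layer: characters carry
an applicability flag (`all`, `adults-only`, `adult-males-only`) and
out-of-scope individuals are treated as missing before any counting, so
the statistics never see a female scored for a male-only trait.

**Sample sizes are explicit.** The descriptive and tolerance-interval
tables of the study system disagree by one individual for two taxa
(n = 41 vs 42, 78 vs 79); the packaged summary fixtures therefore carry
an explicit `n` column at the tolerance-stage values, and readers never
infer n.

## Climate envelopes and niche comparison

The niche line of evidence needs only a *relative* suitability surface
per taxon, so the engine is a percentile-clamped climate envelope
(BIOCLIM-style): per layer, a cell scores 1 inside the (5th, 95th)
percentile band of the training values, decays linearly to 0 at the
training minimum/maximum, and is 0 beyond; cell suitability is the mean
of layer scores. The engine is deliberately simple and deterministic —
the comparative statistics built on top are engine-agnostic, and a
different engine could be slotted behind the same surface. Consequently
the published per-variable contribution tables and AUC values of the
original MAXENT models are not reproduction targets here.

Comparisons use surfaces normalized to sum to 1 over the shared valid
mask (the intersection of the two masks — normalization must happen on
a common domain for the overlap metric to be well defined):

* **Schoener's D** $= 1 - \tfrac12\sum_i |a_i - b_i| \in [0, 1]$.
* **Niche identity test**: records of both taxa are pooled (one record
  per cell within a pseudo-taxon, so duplicated cells across taxa are
  collapsed), repartitioned at random into the observed sample sizes,
  envelopes refit, and D recorded; 100 pseudoreplicates by default. The
  test is one-tailed (identity rejected when the observed D is *low*)
  with the add-one convention $p = (1 + \#\{D_{null} \le D_{obs}\})/(reps+1)$,
  so the smallest attainable p at 100 reps is 1/101. The rejection
  threshold defaults to $\alpha = 0.05$ (the source account does not
  state one).
* **Range maps**: a surface is binarized at the minimum training
  presence threshold averaged over 10 cross-validation folds (folds
  assigned in record order; folds with fewer than two presences merge
  into the previous fold); two taxa are *mutually exclusive* when no
  cell is suitable in both maps.
* **AUC and importance**: rank-based AUC against a seeded background
  sample of up to 10,000 valid cells, and permutation importance (drop
  in AUC when one layer's values are shuffled, truncated at zero and
  normalized to 100) — descriptive diagnostics, not decision inputs.

Occurrences are deduplicated to one record per raster cell before any
model fitting, and records outside the extent or on nodata cells are
dropped with a warning.

## The decision rule

The verbal synthesis of multiple evidence lines is formalized as
*candidate-plus-corroboration*: a pair is delimited when

* both taxa are exclusive on the tree (the gate passes automatically
  when monophyly was not assessed, or when `require_monophyly = FALSE`;
  an assessed non-exclusive taxon blocks the pair), **and**
* at least `min_corroborating_lines` (default 1) of the three lines
  hold: ≥ 1 fixed discrete difference, ≥ 1 continuous gap, identity
  test rejected at `alpha_identity`.

A pair with every line unassessed is `insufficient`, not a verdict.
The default of one corroborating line matches the conservative
"count the fixed differences" reading of the study system. One open
choice is flagged here explicitly: under the default rule a rejected
niche-identity test *alone* can delimit a pair with no morphological
input; whether niche evidence should suffice unaccompanied is a
taxonomic judgement, and the `min_corroborating_lines` knob exists so
users can demand more congruence. The rule is a pure function of the
evidence row, so verdicts are invariant to pair order, and adding a
corroborating line can never flip `delimited` to `not-delimited`.

## The synthetic-data generator

Every stage is testable without downloads because the generator
produces complete virtual datasets with known truth:

* **Characters**: independent Bernoulli states at per-taxon frequencies;
  continuous characters Normal($\mu$, $\sigma$), meristic ones rounded.
  Default 15 individuals per sex per taxon — comparable to the male
  sample sizes of the study system.
* **World**: each layer is a linear gradient in a random direction plus
  a sinusoidal term plus Gaussian noise, scaled to roughly 0–100 (the
  scale of a temperature-like bioclimatic variable), with 2% nodata.
  There is no explicit spatial autocorrelation model beyond the smooth
  terms; that suffices to exercise the envelope machinery but does not
  emulate the strong collinearity of real bioclimatic layers.
* **Occurrences**: cells drawn without replacement with probability
  proportional to a Gaussian suitability surface
  $\prod_\ell \exp(-(v_\ell-\mathrm{opt}_\ell)^2/2\,\mathrm{breadth}_\ell^2)$;
  coordinates are cell centers, so deduplication is a no-op by
  construction.
* **Trees**: balanced per-taxon clades on a ladder; each tip is
  regrafted into another clade with probability `discordance`, breaking
  exclusivity.

What passing tests on these worlds *do* show: the statistics recover
known fixed differences, 8-sigma continuous separations, and separated
niches, and the identity test holds its nominal type-I error under the
null. What they do *not* show: robustness to spatially autocorrelated
sampling bias, collinear layers, or non-normal measurement error — all
present in real data.

## Numerical and design choices

* Exact quantile inversion everywhere; the Wilson bound is closed-form
  and test-verified against a root-finding oracle on the score
  inequality.
* Touching tolerance intervals are "no gap"; ties in AUC count half.
* A constant training layer scores 1 within machine tolerance of its
  single value (no division by zero).
* All stochastic operations (world, occurrences, tree, identity test,
  background, permutations) take explicit seeds and are exactly
  reproducible; `build_evidence()` derives per-pair seeds from one
  master seed, so a fixed config + seed yields byte-identical reports.
* Report tables round half-away-from-zero to one decimal, mirroring the
  conventions of the study system's published tables.
* Monophyly is evaluated on the tree as supplied (rooted on an
  outgroup upstream); there is no unrooted bipartition fallback.
  Support labels are auto-detected as proportions or percentages.

## Problem sizes used in the checks

The packaged test suite runs the coverage simulation at 2,000
replicates of n = 20; identity-test calibration on 200 null datasets
and 100 separated datasets (100 pseudoreplicates each) over a 20 x 20
two-layer world; the exhaustive binomial-bound check for all
x ≤ n ≤ 25; the monophyly oracle on 50 random ≤ 12-tip trees; and
end-to-end recovery on 100 seeded three-taxon worlds. These sizes give
Monte-Carlo standard errors well below the margins being asserted while
keeping a full run in about a minute.

## Known limitations

* The envelope engine ignores interactions between layers and will
  overfit narrow niches at very small sample sizes (fits require ≥ 5
  records).
* The identity test conditions on the pooled *cells*; with heavy cell
  sharing between taxa the pseudo-samples shrink, making the test
  conservative.
* Binomial caveat bounds depend on the unstated future-sample
  convention; published caveat percentages computed with other
  conventions will not match exactly (the package reports its own,
  documented bounds).
* Verdicts are only as good as the candidate set: lineages absent from
  the tree, or sources sharing no taxa, are reported as errors or
  `insufficient`, never guessed.

## A worked example

```{r, eval = FALSE}
fx <- load_walkeri_fixtures()

# morphology: tolerance intervals, gaps, fixed differences
tis <- ti_table(rbind(fx$meristic, fx$morphometric))
any(gap_scan(tis)$gap)                       # FALSE: no gaps anywhere
males <- subset_matrix(fx$matrix, sex = "male", age_class = "adult")
diagnose_discrete(males, "Ancash", "Ayacucho", "precloacal_pores")

# discovery on the packaged topology
discover_candidates(fx$tree, min_support = 0.95)

# full integration with a synthetic niche world
w <- gen_world(world_spec(ncols = 40, nrows = 40, n_layers = 3), seed = 1)
```

The numbered drivers under `analysis/` run exactly this workflow and
write their tables under `results/`.
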