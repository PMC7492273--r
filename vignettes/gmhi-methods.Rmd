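---
title: "Methods: the Gut Microbiome Health Index and its implementation choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Gut Microbiome Health Index and its implementation choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmhi)
```

## The model

The Gut Microbiome Health Index (GMHI) summarizes a species-level stool
metagenome profile as the log-ratio of two "collective abundances": one over
a set of health-prevalent species $M_H$, one over a set of health-scarce
species $M_N$. For a sample with relative abundances $n_j$ (proportions
summing to 1),

$$\psi_M \;=\; \frac{R_M}{|M|'} \sum_{j \in M,\; n_j \ge t} \lvert n_j \ln n_j \rvert,
\qquad
h \;=\; \log_{10}\!\frac{\psi_{M_H} + \varepsilon}{\psi_{M_N} + \varepsilon},$$

where $R_M$ is the number of set species present at or above the presence
threshold $t$, $|M|'$ is an effective set size (below), and $\varepsilon$ is
a pseudo-count. The $\lvert n \ln n \rvert$ weight is the per-species term
of the Shannon entropy: it acts as a log-scale (geometric-mean-like) summary
of abundances, appropriate because microbiome relative abundances span
several orders of magnitude. The classifier is the sign of $h$: positive is
called healthy, negative nonhealthy, and exactly zero "neither" (an equal
balance of the two sets).

Natural log is used inside $\psi$ and base-10 log for $h$; these follow the
definitions of the quantities, not convenience.

### Assumptions

- Abundances are *proportions*; all ingest paths convert percent-scale
  MetaPhlAn output (detected by a column sum near 100) by dividing by 100,
  and feature filtering renormalizes retained rows so each sample sums to 1.
- The discriminating signal is carried by *presence frequency* (prevalence),
  not by mean abundance differences. This is what makes the approach robust
  to between-study heterogeneity: only a per-sample present/absent call at
  $t = 10^{-5}$ crosses study boundaries.
- Species are treated independently: no compositional correlation, no
  phylogenetic structure.

## Signature discovery

For each species $m$, let $p_{H,m}$ and $p_{N,m}$ be its prevalence
(fraction of samples with abundance $\ge 10^{-5}$, inclusive) in the healthy
and nonhealthy group. The species joins $M_H$ iff

$$p_{H,m}/p_{N,m} \ge \theta_f \quad\text{and}\quad p_{H,m} - p_{N,m} \ge \theta_d,$$

and joins $M_N$ under the mirrored criteria. Two conventions matter at the
boundary:

- **Zero denominators.** If $p_{N,m} = 0 < p_{H,m}$ the fold change is
  $+\infty$ and passes any finite $\theta_f$ (the limiting behavior of the
  criterion); $0/0$ is `NaN` and the species is ineligible in that
  direction.
- **Disjointness.** For any $\theta_d > 0$ the two sets cannot overlap. At
  $\theta_d = 0$ a species with exactly equal prevalences would satisfy both
  directions; the signature constructor rejects that, so callers must keep
  $\theta_d$ positive (the smallest default grid value is 0.025).

### Threshold grid search

Every $(\theta_f, \theta_d)$ pair yields different sets and hence a
different balanced accuracy
$\chi = \tfrac12\left[P(h>0 \mid H) + P(h<0 \mid N)\right]$, with $h = 0$
counted incorrect for both groups. `gmhi_grid_search()` evaluates the full
grid (cells with an empty set record `NA` rather than aborting) and returns
the argmax. The exact grid used for the published model is not public; the
defaults here are $\theta_f \in \{1.1, 1.2, \ldots, 2.0\}$ and
$\theta_d \in \{0.025, 0.05, \ldots, 0.20\}$, declared choices that contain
the published optimum $(1.4, 0.10)$. Ties are broken deterministically
toward larger $\theta_f$, then larger $\theta_d$ — preferring the more
stringent, more parsimonious signature.

### Effective set sizes

Using the nominal cardinalities $|M_H| = 7$, $|M_N| = 43$ in $\psi$ would
penalize the larger set, because full within-set richness is rarely
observed. The replacement $|M|'$ is estimated from data:

1. compute $(R_{M_H}, R_{M_N})$ for every sample;
2. sort all samples by $R_{M_N}$ ascending, then $R_{M_H}$ descending
   (a stable two-key sort; residual ties keep input order, documented
   because the medians over $k$ samples can depend on it in pathological
   data);
3. let $k_H$ be the closest integer to 1% of the healthy-group size
   (half-away-from-zero, floored at 1; 2636 → 26, 1711 → 17), $k_N$
   analogously;
4. $|M_H|'$ is the median $R_{M_H}$ of the top $k_H$ samples, $|M_N|'$ the
   median $R_{M_N}$ of the bottom $k_N$.

A median of zero means the data cannot support the estimate; this errors
with advice rather than silently producing an infinite index, and
`fallback_to_nominal = TRUE` substitutes the nominal cardinality (used by
default inside cross-validation, where small training folds make degenerate
medians more likely).

**Published model caveat.** The effective sizes of the published 50-species
model were never reported. `load_packaged_signature()` therefore defaults to
the nominal cardinalities and says so with a message; they are a
configuration input, not a guess. Relative comparisons between samples are
unaffected by this choice (it shifts $h$ by a constant
$\log_{10}$ offset, up to pseudo-count effects); absolute thresholds at 0
are affected.

### The pseudo-count

The literal log-ratio is undefined when $\psi_{M_N} = 0$. A symmetric
pseudo-count $\varepsilon = 10^{-5}$ (matching the presence threshold's
scale) is added to both numerator and denominator: symmetry preserves the
antisymmetry of $h$ under exchanging the two sets, and $\varepsilon = 0$
restores the literal formula, returning $\pm\infty$ with a warning when one
set is absent. The sample where both sets are absent scores 0 ("neither")
with a warning.

## Quality control

The filters run in pipeline order in `run_qc()`:

1. **BMI reclassification** — healthy-labeled subjects with reported BMI in
   the underweight (<18.5), overweight ([25, 30)) or obese (≥30) range move
   to the nonhealthy group with the matching phenotype; missing BMI leaves a
   sample unchanged.
2. **Unclassified-sample filter** — samples whose unclassified fraction
   strictly exceeds 5% are removed (a sample at exactly 5% is retained, per
   the strict ">" wording of the rule).
3. **Outlier fence** — within each phenotype, a hypothetical reference
   sample is built from feature-wise medians and deliberately *not*
   renormalized (it is a reference point, not a composition; rescaling it
   would change all distances). Samples whose Bray-Curtis distance to it
   lies more than 1.5 IQR above Q3 or below Q1 are removed. Quartiles use
   linear interpolation (the common type-7 default). Phenotypes with fewer
   than 4 samples are skipped with a warning — a fence over 3 points is
   meaningless.
4. **Feature filters** — viral-kingdom features, unknown/unclassified
   entities, and features present in fewer than 1% of samples are removed.
   Presence for the prevalence floor reuses the $10^{-5}$ threshold for
   consistency with discovery (whether the original rule used "> 0" is
   unknowable from the text; the threshold is configurable via
   `presence_threshold = 0`). Retained rows are renormalized to sum to 1 —
   the $\psi$ formula assumes it — and this too is switchable
   (`renormalize = FALSE`) since the original procedure is silent on the
   point.

Read-count-based exclusions (samples with fewer than a million reads) are
out of scope: this package operates on profiles, not reads.

## Companion statistics

Shannon diversity uses natural log (the ecology convention; base
configurable). The 80% abundance coverage uses an inclusive cumulative
comparison ("at least 80%", so ten species at 0.1 give 8). The Mann-Whitney
U test uses midranks; for a smaller sample of at most 8 it computes an exact
p-value (closed-form U distribution when tie-free, full enumeration of
label assignments when tied and the enumeration is feasible), otherwise the
tie-corrected normal approximation without continuity correction. Cliff's
Delta is computed from the midrank U statistic,
$d = (2U - n_x n_y)/(n_x n_y)$, algebraically identical to pair
enumeration. Spearman correlation uses average ranks, a $t$-distribution
p-value with $n-2$ degrees of freedom, and a Fisher-z confidence interval.

## The synthetic world

`generate_cohort()` emulates exactly the structure the discovery procedure
assumes: each species is present in a sample with a group-specific
probability — planted health-prevalent species at base + gap in the healthy
group and base in the nonhealthy group, planted health-scarce species
mirrored, background species at base in both — and present species draw
abundances from a log-normal law (location −7, scale 1.5 before closure),
giving the orders-of-magnitude abundance spread that motivates the
$\lvert n \ln n \rvert$ weighting. Each sample is closed to sum 1. Defaults
are the stated validation world: 500 samples per group, base prevalence 0.3,
gap 0.25, 10 planted species per set; 200 total species is a package choice
(neither source states one) in the realistic range of post-filter species
counts for stool metagenome cohorts (a few hundred), keeping tests at desk
scale. Nonhealthy samples are evenly assigned to 3 pseudo-phenotypes so
phenotype-stratified code paths are exercised.

What the generator deliberately does **not** model: compositional or
phylogenetic correlation between species, study batch effects, abundance
(rather than prevalence) effects, and unequal group sizes' interaction with
study origin. A green recovery test therefore establishes that the
selection machinery is correct under its own assumptions — not that GMHI
achieves any particular accuracy on real cohorts, where the published
balanced accuracies (69.7% discovery, 73.7% validation on thousands of
metagenomes) are far below the clean synthetic values produced here.

In the recovery acceptance test, precision and recall are evaluated pooled
over the 20 planted species of both sets: with only 10 species per set, a
single false positive quantizes per-set precision to 0.909, so a 0.95
criterion is only meaningful on the pooled sets. The permutation null for
the end-to-end check re-labels the scored samples: the balanced accuracy of
fixed scores against shuffled labels concentrates at 0.5, and its spread
across seeds provides the Monte-Carlo standard error used in the
comparison.

## Numerical conventions

- Presence comparisons are inclusive (`>= 1e-5`), matching the definition
  of prevalence.
- "Closest integer" for $k_H$/$k_N$ rounds halves away from zero with a
  floor of 1 (both published counts, 26 and 17, are insensitive to the half
  rule).
- Species names are matched across conventions by normalizing lineage
  prefixes, `s__` markers, underscores, slashes and periods to a canonical
  spaced form, which maps MetaPhlAn's
  `s__Streptococcus_mitis_oralis_pneumoniae` onto the composite name
  "Streptococcus mitis/oralis/pneumoniae" without a special-case table.
- The packaged signature table transcribes published prevalences at
  1-decimal precision. A minority of the printed difference/fold cells are
  inconsistent at the last decimal with their own printed prevalences
  (the published table was evidently rounded from unrounded internal
  values); integrity tests assert recomputed arithmetic only on the rows
  that are self-consistent.

## Known limitations

- Strain-level scoring is not supported; rank extraction stops at species.
- The packaged model cannot reproduce published absolute index values
  exactly without the unpublished effective set sizes (see above).
- `read_metaphlan_profile()` handles the classic two-column profile
  dialect; BIOM and newer multi-column formats are out of scope.
- Pathway or other generic feature tables are accepted by all discovery and
  scoring operations unchanged; no pathway-specific handling exists or is
  needed.
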