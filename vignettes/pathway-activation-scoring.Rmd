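---
title: "Pathway activation scoring and correlation screens: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway activation scoring and correlation screens: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paslab)
```

## The model

`paslab` implements the analysis chain used to characterize a driver gene
(the motivating case is the receptor tyrosine kinase *KIT* in
neuroblastoma) through molecular pathway activity. The core statistic is
the **pathway activation level** (PAL, often reported as pathway
activation strength, PAS). For a pathway $p$ with member genes $n$:

$$
\mathrm{PAL}_p \;=\;
\frac{\sum_n \mathrm{NII}_{np}\,\mathrm{ARR}_{np}\,\log \mathrm{CNR}_n}
     {\sum_n \mathrm{NII}_{np}\,\lvert \mathrm{ARR}_{np}\rvert}
$$

where

* $\mathrm{CNR}_n$ (case-to-normal ratio) is gene $n$'s mean expression in
  the case samples divided by its mean in the control ("norm") samples;
* $\mathrm{NII}_{np}$ indicates pathway membership (1 if $n \in p$, else
  0);
* $\mathrm{ARR}_{np}$ is the gene's discrete activator/repressor role in
  the pathway: $-1$ (repressor), $-0.5$ (likely repressor), $0$
  (ambivalent/neutral), $0.5$ (likely activator), $1$ (activator).

A positive PAL means the case condition pushes the pathway's output up —
activators rise and/or repressors fall; a negative PAL means suppression.
The denominator normalizes by the total absolute role weight so that PAL
is comparable across pathways of different sizes: a coherent ten-fold
shift of every (weighted) activator gives $\mathrm{PAL} = 1$ in log base
10 regardless of how many members the pathway has.

The model's assumptions are worth stating plainly. PAL is a *linear*
aggregate of log ratios: it assumes member genes contribute independently
and additively with fixed signs, ignores pathway topology and saturation,
and treats transcript abundance as a proxy for signaling output. These
are the standard trade-offs of role-weighted expression scoring; they buy
interpretability and closed-form behavior (antisymmetry under
case/control swap, invariance to global rescaling) at the cost of
mechanistic detail.

### Conventions and edge cases

* **Unmeasured members** are removed from numerator *and* denominator.
  Imputing $\mathrm{CNR} = 1$ for them would shrink every score toward 0
  by an arbitrary, coverage-dependent amount; dropping them treats the
  measured members as the available evidence. A pathway with no measured
  members is reported as *unmeasured*; one whose measured members are all
  neutral ($\mathrm{ARR}=0$) is *unscorable*. Both are listed with
  reasons rather than silently dropped.
* **Flooring**: means entering a CNR are floored at `eps = 1e-8` before
  division (zero intensities are real in array data); floored genes are
  recorded on the returned object.
* **Norm definition**: "average value in the control group" is read as
  the arithmetic mean (`control_arith_mean`, the default); a geometric
  mean option exists because log-scale averaging is also defensible for
  intensity data. Per-sample PAS supports either an explicit control set
  or the cohort mean profile as the norm — when correlating per-tumor PAS
  with a driver gene across a cohort, both definitions are in circulation
  and the choice is a recorded parameter, not a hidden default.
* **Log base 10** by default; every property of the score is
  base-invariant up to a global scale, and base 10 makes a ten-fold
  coherent shift score exactly 1.

## Preprocessing

Custom-array intensity data arrive as replicate probes. `aggregate_probes()`
collapses replicate groups by the **geometric mean** (the natural average
for multiplicative intensity noise), flooring zeros at `eps` first and
counting the flooring events. `quantile_normalize()` then forces every
sample column onto the common reference distribution defined by the row
means of the column-sorted matrix. Ties within a column receive the
arithmetic mean of the reference values their sorted positions span — the
convention that keeps the procedure exactly idempotent on tie-free data.
Where several replicate groups map to one gene, the package collapses
duplicate gene rows by arithmetic mean *after* normalization
(`collapse_duplicate_genes()`); collapsing first would mix probe sets with
different affinities before their distributions are aligned. The collapse
count is reported.

## Cohort distributions and the high-expressor fraction

Pan-cancer comparisons of a single gene work on per-cohort distribution
shapes rather than means. Values are placed on the analysis scale
$\log_2(x + 1)$ and binned on a shared grid; by default 64 equal-width
bins spanning the pooled 0.5th–99.5th percentile range (the trim keeps a
handful of extreme samples from stretching the grid; out-of-range values
are clipped into the terminal bins and counted). Neither the bin count
nor the scale is canonical — both are parameters and both are recorded in
the output.

Cohorts are clustered with **Ward.D2** linkage (squared-Euclidean update,
square-root heights, as in Murtagh & Legendre) on the Euclidean distance
between frequency vectors. Cohorts are sorted by label before
clustering, which makes the dendrogram invariant to input order with a
deterministic tie-break.

The **high-expressor fraction** asks a different question than the mean:
what share of a cohort's samples exceed the *mean* expression of a
reference cohort (the AML cohort, in the motivating analysis, computed on
the same analysis scale)? Cohorts with a fraction strictly above 5% are
flagged. The flag is strict: a fraction of exactly 0.05 is not flagged,
0.06 is.

## Correlation screens and two-stage FDR

Immune-infiltration signatures are scored per sample as the **mean
squared expression** of the signature's measured genes. That phrase is
implemented literally (mean of squares); a root-mean-square option is
provided because the literal and RMS readings differ only by a monotone
transform and some users will expect the latter. Squaring weights
high-expressing members more heavily than a plain mean — the score is
dominated by the genes that are actually on.

Associations use the sample Pearson coefficient with the two-sided
p-value from $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom,
with pairwise-complete deletion and a minimum of 3 complete pairs.
Constant vectors have no defined correlation; such features are excluded
from a screen with a log entry rather than scored as zero.

Multiplicity is handled by the **two-stage adaptive FDR** procedure of
Benjamini, Krieger and Yekutieli: stage 1 runs the linear step-up at
$\alpha' = \alpha/(1+\alpha)$, the rejection count estimates the number
of true nulls $m_0 = m - r_1$, and stage 2 re-runs the step-up at
$\alpha' m/m_0$ (rejecting everything if $m_0 = 0$). Reported q-values
are rescaled by $(1+\alpha)\,m_0/m$ so that $q \le \alpha$ reproduces the
rejection rule exactly — the convention statsmodels users will recognize.
p-values of exactly 0 are kept as 0; only rank order matters to a step-up
procedure. The correction family is *within cohort, across features*:
per-cancer-type counts of significant correlations are the screen's
output, so each cohort is corrected on its own. Whether a joint
correction across cohorts would be preferable is not decidable from the
motivating analysis; the family is therefore an explicit, recorded
parameter of `correlation_screen()` rather than something configured
implicitly.

Two screens share this machinery with different effect-size gates: the
signature screen calls significance at $q < \alpha$ **and**
$\lvert r\rvert > 0.2$ (a large-cohort screen needs an effect-size floor,
otherwise trivially small correlations reach significance on thousands of
samples), while the PAS-vs-driver association uses the FDR condition
alone by default, with `r_min` available.

## Dependency panels and drug-target deconvolution

Gene-dependency scores (RNAi/DEMETER2-style and CRISPR/Chronos-style;
negative = the line depends on the gene — no sign flip is applied
anywhere) are summarized per tumor type with median and quartiles,
keeping only types represented by **strictly more than** `min_lines`
cell lines (default 5; a type with exactly 5 lines is excluded).

For drug-sensitivity deconvolution, each drug's AUC is Pearson-correlated
with each candidate target's dependency score separately per channel over
the shared cell lines (pairwise-complete, at least 3 pairs), and the
available channel correlations are averaged. A pair computable in only
one channel contributes that channel's value alone — averaging over
available channels rather than zero-filling, flagged per cell in the
detail table, since a missing screen is absence of evidence, not evidence
of zero correlation. Targets are ranked by the mean of their available
cells; drugs are clustered with Ward.D2, with missing cells mean-imputed
*for the clustering distance only* (correlations themselves are never
imputed) and the imputation count reported.

## Synthetic data: what it emulates, and what it does not

The generators produce data with exactly the structure each stage
assumes, so every claim the tests make is a claim about the method, not
about a particular dataset:

* `gen_cohort_expression()` — per-cohort log2-normal expression with an
  optional upward-shifted mixture component ("high expressors", fraction
  $\pi$, shift in log2 units). This emulates the shape contrast that
  distribution clustering groups on.
* `gen_pathway_dataset()` — controls at per-gene log10 baselines; cases
  with activator members shifted $+\delta$ and repressors $-\delta$ plus
  Gaussian log-noise $\sigma$. With $\sigma = 0$ the planted pathway's
  PAL equals $\delta$ *exactly* and disjoint pathways score 0, so
  recovery targets are closed-form.
* `gen_signature_dataset()` — a latent factor drives the driver gene;
  signature members load on it with per-gene loading
  $w^2 = \rho^2 / (K(1-\rho^2) + \rho^2)$, calibrated so the K-gene
  score's latent correlation with the driver is $\rho$ after averaging.
  Log-scale SDs are kept moderate (0.5 log2 units) so the lognormal
  transform and the squaring in the score perturb the realized
  correlation only slightly.
* `gen_pharm_panel()` — i.i.d. normal dependency scores per channel,
  except the true target, whose dependency is shared between channels
  (one biology, measured twice); AUC is a linear function of it plus
  noise at a set signal-to-noise ratio.

All generators are seeded, platform-stable, and restore the caller's RNG
state. What they do **not** emulate: gene–gene covariance beyond the
planted structure, batch and platform effects across cohorts,
heavy-tailed or zero-inflated expression, overlapping pathway membership,
and dose–response curve fitting. Passing tests therefore demonstrate
correctness and calibration of the *methods* under their stated
assumptions, not robustness to everything real data will do.

## Operating conditions used in the test suite

The property-based checks run at sizes chosen to make their statistical
assertions sharp while keeping the suite fast: 100 random
pathway/matrix instances for oracle equivalence (agreement within
1e-10); null calibration with 2000 uniform p-values over 200 replicates
(observed any-rejection rate is compared against 0.07, i.e. the nominal
0.05 plus sampling slack); screen operating characteristics with 200
null features plus one planted $\rho = 0.9$ feature at $n = 100$ over
50 seeds; distribution-clustering recovery with two 10-cohort families
separated by 4 noise SDs over 100 seeds; and target ranking with 60
cell lines at noise ratio 0.5 over 100 seeds. `scripts/acceptance.R`
recomputes the same quantities from scratch at an arbitrary seed.

## Known limitations

* Role-weighted linear scoring cannot express pathway logic (AND gates,
  feedback); two pathways sharing members are scored independently.
* The pathway file format ("GMTX": `id<TAB>class<TAB>gene:role…`) is this
  package's own role-extended GMT dialect; curated role-annotated
  collections must be converted to it, and a plain GMT import (all roles
  +1) is provided only as a degraded fallback.
* Counting "regulated" pathways requires a threshold on PAL; there is no
  canonical value, so `count_regulated()` makes it a required argument
  and reports it alongside the counts.
* The two-stage FDR q-values are calibrated to the rejection rule at the
  given $\alpha$; unlike BH q-values they are not level-free quantities.
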