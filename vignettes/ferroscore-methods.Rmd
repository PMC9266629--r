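---
title: "Scoring relative ferroptosis levels: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring relative ferroptosis levels: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The statistic

Ferroptosis activity in a tumor sample is inferred from two curated gene
signatures: drivers (genes promoting ferroptosis) and suppressors (genes
preventing it). For each sample the package computes a single-sample gene
set enrichment score (ssGSEA) of each signature and defines the relative
ferroptosis level as their ratio,

$$\mathrm{RFL}_s = \frac{ES(\text{drivers};\, x_s)}{ES(\text{suppressors};\, x_s)}.$$

The enrichment score walks the genes of a sample in order of decreasing
within-sample rank $r_g$ and accumulates the difference between a weighted
in-set cumulative fraction and the out-of-set cumulative fraction:

$$ES = \sum_{i=1}^{N}\Big[ \frac{\sum_{j \le i,\, g_j \in S} r_{g_j}^{\alpha}}
 {\sum_{g \in S} r_g^{\alpha}} - \frac{\#\{j \le i: g_j \notin S\}}{N - |S|} \Big].$$

Two properties follow directly and are enforced by tests:

* **Rank invariance.** The score depends on expression only through
  within-sample ranks, so any strictly increasing per-sample transform
  (log, exponentiation, affine scaling) leaves all scores — and hence the
  RFL — unchanged. This is what makes the ratio comparable across
  differently normalized cohorts.
* **Scale invariance of the ratio.** Dividing all scores of a cohort by a
  common positive constant (the optional cohort-range normalization)
  cancels in the ratio.

### Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.25 | rank-weighting exponent of the running sum; 0.25 is the conventional ssGSEA choice, 0 gives the unweighted KS walk. Unit-free. |
| `normalize` | off | divide all scores of one call by their range; the RFL is provably invariant to it, so it exists only for cross-cohort display. |
| `tie_method` | average | rank ties; average ranks are deterministic and standard. |

Genes of a signature that are not measured in a cohort are intersected out
with a logged count; a signature with no measured gene is an error, as is a
signature covering every measured gene (the out-of-set fraction would be
undefined). Equal ranks are walked in lexicographic gene-id order (radix,
locale-independent) so results are bit-reproducible across platforms.

### Undefined RFL

Raw enrichment scores can be non-positive. A ratio over a non-positive
suppress activity has no "relative level" interpretation, so such samples
are flagged undefined, excluded from every downstream stage, and counted in
the log. The cohort-level validity check requires Pearson
r(RFL, drive) > +0.2 and r(RFL, suppress) < −0.2; cohorts failing either
bound are not stratified (mirroring the practice of excluding cohorts whose
score does not track its own components).

## Survival analysis

Kaplan–Meier estimation, the two-group log-rank test and Cox
proportional-hazards fits are delegated to the `survival` package
(`survfit`, `survdiff`, `coxph` with Breslow ties — the simplest
deterministic tie rule). The package's own contributions are:

* **Minimum-P cutoff scan.** Every *observed* RFL value between the 10th
  and 90th linear-interpolation percentiles is tried as a cutoff
  (`rfl > cutoff` → high; the strict boundary makes scanning over observed
  values deterministic); the lowest log-rank P wins, ties broken toward the
  cutoff nearest the median. Minimum-P selection inflates type I error;
  `scan_cutoff(n_perm = ...)` offers a label-permutation adjusted P that is
  reported alongside, never silently substituted. It defaults to off.
* **Centered risk score.** RS is the Cox linear predictor centered at the
  fitting cohort's covariate means, so RS > 0 reads "above-average modeled
  risk" and the RS > 0 / RS < 0 grouping has a defined zero point.
* **ROC AUC** via the Mann–Whitney rank identity (ties count ½), using the
  end-of-follow-up event indicator as the binary label. A fixed-horizon
  time-dependent AUC would be a reasonable alternative; it is out of scope
  here and the plain ROC is what the package reports.

## Gene screening

Per-gene Pearson correlation against the RFL with two-sided P from
$t = r\sqrt{n-2}/\sqrt{1-r^2}$; a gene is markedly correlated when
r > |0.3| and P < 0.05, both strict. No multiple-testing correction is
applied by default — the screen reproduces a fixed-threshold convention —
but Benjamini–Hochberg adjustment is one argument away
(`select_correlated(adjust = "BH")`). Recurrence across cohorts demands a
*consistent sign*: a gene counted positive in some cohorts and negative in
others is never selected, whatever the totals. Jaccard overlap matrices are
computed separately for the positive and negative selections; a pair of
empty sets yields 0 with a warning rather than NaN.

## The synthetic cohort generator

The generator exists so that every stage of the pipeline can be exercised,
with known ground truth, in seconds. Its model:

* latent per-sample ferroptosis activity $f_s \sim N(0,1)$;
* log-scale expression $x_{gs} = b_g + \beta_g f_s + \varepsilon_{gs}$,
  $\varepsilon \sim N(0, \sigma^2)$ with $\sigma = 0.5$;
  $\beta_g = +1$ (drivers), $-1$ (suppressors), $\pm\sigma/\sqrt{3}$
  (planted correlates, giving population $r = 0.5$ with $f$), 0
  (background);
* per-gene baselines $b_g \sim N(5, 2^2)$, with drivers and suppressors
  shifted +4 higher;
* survival $T_s \sim \mathrm{Exp}\{0.1\,e^{-\gamma f_s}\}$ with
  $\gamma = 1$, so high ferroptosis is favorable; independent exponential
  censoring tuned to a 30% baseline censoring fraction;
* treatment experiments shift the treated arm's latent activity by
  $\delta = \pm 1.5$ (inducer/inhibitor analogue); single-cell data draw
  per-patient activities and add cell-level noise around the patient
  profile, so pseudobulk averages converge to the patient profile.

Two baseline choices deserve their rationale. The **signature shift** (+4)
reflects that curated signatures are *expressed* gene sets sitting well
above the median of a whole transcriptome; it keeps both activities
positive over the realistic activity range (|f| ≲ 3.5), so the RFL is
defined for essentially every sample. A smaller shift makes the suppress
score cross zero for moderately high-activity samples, and the resulting
exclusions truncate exactly the samples a treatment experiment shifts
upward — an informative-missingness artifact the emulated data do not
have. The **baseline spread** (sd 2) emulates the wide dynamic range of
real transcriptomes; with a flat background baseline the rank walk
saturates in the low-noise (e.g. pseudobulk) limit — signature genes
occupy exactly the top ranks for every sample and the scores tie — which
no real cohort exhibits.

What the generator does **not** emulate: negative-binomial count noise and
library-size effects (expression is Gaussian on the log scale), batch
effects, correlated background genes, non-proportional hazards, and
informative censoring. Tests passing on these cohorts therefore establish
the correctness and statistical behavior of the *methods*, not the
biological validity of any particular signature on real data.

All generators are pure functions of `(params, seed)`: each call seeds the
RNG once and draws in a fixed order, so outputs are bitwise reproducible.

## Numerical and degenerate-input conventions

* Quantiles: R type 7 (linear interpolation).
* Cutoffs at or outside the observed RFL range are errors; candidates in
  the scan are restricted to values that leave both groups non-empty.
* Constant covariates are dropped from Cox fits with a warning; fewer than
  two events is an error; unestimable coefficients abort with the
  iteration count.
* Constant genes or features yield NA correlations, class `none`, never a
  crash.
* Pipeline logs carry no timestamps, so reruns are byte-identical — the
  determinism check compares raw bytes of every output file.

## Problem sizes used by the test suite

The suite validates the engine against a brute-force oracle on 200 random
matrices (≤ 20 genes, ≤ 5 samples), runs nine reference cohorts
(300 samples × 2000 genes) for RFL validity, ten treatment experiments
(20 samples/arm), ten survival cohorts for the scan direction, twenty
400-sample two-arm Cox simulations, and a nine-cohort demo pipeline
(100 × 600) twice for the byte-identity check. These sizes give stable
statistical behavior at interactive runtimes; the generator scales to
larger cohorts unchanged.

## Known limitations

* The minimum-P cutoff is reported as-is (with the optional permutation
  adjustment); confidence intervals for the selected cutoff are not
  provided.
* The ROC is not time-dependent.
* Pseudobulk is an unweighted gene-wise mean of a patient's cells; no
  per-cell quality weighting or normalization is applied.
* The screen's per-cohort P-values are marginal; dependence between genes
  is not modeled.
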