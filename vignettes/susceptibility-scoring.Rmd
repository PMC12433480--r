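---
title: "Scoring tumor cell-line susceptibility to oncolytic viruses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring tumor cell-line susceptibility to oncolytic viruses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viroscore)
```

Oncolytic viruses kill some tumor cell lines at vanishingly small doses and
leave others untouched. When a panel of lines is screened by live-cell
imaging — confluence read every couple of hours across a ladder of
multiplicities of infection (MOI) — the resulting curves must be reduced to
a single, comparable number per line before anything can be correlated with
the lines' molecular make-up. `viroscore` implements that reduction, the
composite susceptibility score built on it, and the downstream correlation
of the ranking with gene expression.

## The scoring procedure

For each well, confluence is first normalized to its own baseline (the
first timepoint), giving a unitless fold-change curve that starts at 1.
Normalization is division, not subtraction: a well that was seeded a bit
denser should not look like it grew more, and division makes every
downstream summary invariant to the absolute confluence scale of a well.
(Subtraction is available via `baseline_mode = "subtract"` for users who
want the instrument-style view.)

The fold-change curve is summarized by its trapezoidal area under the
curve (AUC) on the observed grid — no smoothing, no interpolation, no
model fitting. Technical replicate wells are averaged per condition, and
each treated mean AUC is divided by the same biological repeat's untreated
mean AUC. This ratio (`auc_norm`) is 1 for no growth inhibition and falls
toward 0 as the virus suppresses growth.

Per cell line, the dose response over the MOI grid is tested with a
one-way ANOVA and Dunnett's many-to-one comparisons of every MOI against
untreated. The *rank multiplier* encodes the onset of significance: 1 if
the lowest MOI (0.001 PFU/cell on the standard grid) already differs from
untreated at `p <= 0.05`, through 5 if only MOI 10 does, and 6 if nothing
is significant. The composite score is

> score = (sum of `auc_norm` over the treated MOIs) x rank multiplier,

so a line that is both strongly inhibited (small AUC sum) and sensitive at
low dose (small multiplier) gets a small score. Lines are ranked 1 (most
susceptible) to N by ascending score; ties break by smaller AUC sum, then
by name, so the ranking is deterministic.

The significance threshold is inclusive (`p <= 0.05` counts), matching the
usual asterisk convention in the field.

### Which values enter the Dunnett test

The replication unit entering the test is the biological repeat (the
technical triplicate is averaged away first). Two reasonable choices exist
for the tested quantity: the per-repeat mean AUCs themselves, or the
untreated-normalized ratios. We default to the ratios
(`test_on = "auc_norm"`), the same quantity displayed and summed by the
score; because each repeat is normalized by its own untreated mean, the
untreated group is then identically 1 and contributes no replicate
variance. Both variants are implemented, and in null simulations (no true
kill effect, 300 runs) both kept the family-wise fraction of false
rank-multiplier calls near or below the nominal 5%.

### Dunnett's adjustment by quadrature

The adjusted p-value for comparison *i* is
`P(max_j |T_j| >= |t_i|)` under the joint multivariate-t null with the
many-to-one correlation structure
`rho_ij = sqrt(n_i n_j / ((n_i + n0)(n_j + n0)))`. `pdunnett()` evaluates
the family-wise distribution by conditioning on the shared control variate
and the pooled scale, reducing the k-dimensional probability to a smooth
double integral: Gauss–Hermite quadrature (128 nodes) over the control
variate crossed with Gauss–Legendre quadrature (256 nodes) on the
quantile-transformed chi distribution of the pooled standard deviation.
This node configuration keeps the absolute error below 1e-6 over degrees
of freedom from 1 to several thousand — verified against the univariate t
distribution (the k = 1 identity) and against `mvtnorm::pmvt` reference
values at k = 3 with unbalanced group sizes. A zero observed difference
returns p = 1; identical constant groups return p = 1.

### Factorial analyses

`two_way_anova_type3()` provides the fixed-effects analog of the
mixed-model time x MOI tables produced by commercial software: sum-to-zero
contrasts with type-III (marginal) tests, computed as the Wald quadratic
form of each coefficient block. For complete balanced data this equals the
classical decomposition exactly (sums of squares add to the total). A
restricted-maximum-likelihood mixed model is deliberately *not* fitted:
repeated-measures pairing is ignored, which is a documented deviation from
the mixed-effects analyses those tables come from, exact only in the
balanced fixed-effects sense. `pairwise_adjust()` covers the Šidák,
Tukey (via the studentized-range distribution) and unprotected Fisher-LSD
conventions used for the accompanying cytokine and viability panels.

## Expression correlation

Raw counts are normalized with the median-of-ratios size-factor estimator:
the reference is the per-gene geometric mean over samples, genes with any
zero count are excluded from the reference, and each sample's factor is
the median count-to-reference ratio. The estimator is implemented in the
package itself (and agrees with the DESeq2 reference implementation to
numerical precision in the test suite, which uses DESeq2 purely as an
independent oracle). Expression is then `log2(count / factor + 1)` — base
and pseudocount are configurable, since upstream reports rarely state
them — and per-gene z-scaling (`scale_rows()`) produces the matrix one
would plot in a heatmap.

Per gene, replicate samples are aggregated by the arithmetic mean of
log-normalized expression per cell line, and the aggregate is correlated
against the integer susceptibility rank (1 = most susceptible) by Spearman
(and optionally Pearson). Correlating against the raw score instead gives
identical Spearman output, since the score and its rank induce the same
ordering. For untied data the Spearman estimate is computed by the exact
closed form `1 - 6 sum(d^2) / (n (n^2 - 1))` and the integer `sum(d^2)` is
reported alongside; with ties, midranks and Pearson-on-ranks are used and
the closed form does not apply.

Small-panel p-values deserve care: with 11 or 12 lines the t
approximation is crude. `spearman_p()` therefore offers full enumeration
of all n! permutations (exact, allowed up to n = 8, i.e. 40,320
permutations), seeded Monte-Carlo permutation sampling with a standard
error, and the t approximation; `correlate_with_susceptibility()` picks
enumeration automatically when the panel is small enough. Published
correlation p-values from point-and-click software use unspecified
small-sample approximations, so identical p-values should not be expected
across tools — the estimates, which are exact rank functionals, should
match to the printed precision. Gene-level p-values are reported
unadjusted, as is conventional for small targeted panels, with an optional
Benjamini–Hochberg column.

## Assay calibration

`fit_standard_curve()` fits the four-parameter logistic
`y = d + (a - d) / (1 + (x/c)^b)` (ELISA, electrochemiluminescence) or the
hyperbolic saturation curve `y = Bmax x / (Kd + x)` (ATP luminescence) by
Levenberg–Marquardt least squares, unweighted by default with optional
`1/y^2` weighting. Starting values come from the extreme responses, the
geometric mid concentration and slope 1, with three perturbed restarts,
keeping the best residual sum of squares. Inversion is analytic, and
responses outside the fitted span are flagged rather than extrapolated;
`substitute_out_of_range()` then applies the standard detection-limit
rules (below range: lower limit / sqrt(2); above range: upper limit).
Blank subtraction before fitting is off by default (a config switch, since
protocols differ). `plaque_titer()` applies the countable-window rule —
only wells with 5–50 isolated plaques enter the mean — and the formula
PFU/mL = mean count x dilution factor / infection volume.

## What the synthetic data emulate

The generator exists so every stage is testable with known ground truth.
Each line follows logistic growth minus a delayed Hill-type kill term:

> C'(t) = g C (1 - C/K) - k(m) C 1[t > tau],  k(m) = kmax m^h / (m^h + m50^h)

the simplest mechanism that produces dose- and time-dependent confluence
suppression with an onset delay. Dead-cell density and secreted FLT3L are
both proportional to the accumulated killed biomass
(`int k(m) C ds`), with the area-conversion constant fixed at 1 (its scale
cancels in normalization). The default design mirrors the screening
layout: sampling every 2 h to 170 h, MOI grid {0, 0.001, 0.01, 0.1, 1,
10}, triplicate wells, three biological repeats, and an 11-line default
panel spanning strong killers to a complete null (`kmax = 0`).

Numerical choices: trajectories are Euler-integrated with 10 substeps per
2 h sampling interval (configurable); at the default refinement the
noise-free null trajectory matches the closed-form logistic solution to
0.5% relative, and at no refinement to about 5%. Noise is multiplicative
lognormal per timepoint (confluence is positive and heteroskedastic in
practice); the default SD of 0.05 is a plausible well-to-well figure for
imaging-based confluence, chosen once as a working value — instrument
reports do not publish well-level variance, so it is a modeling choice,
not a measured quantity. Counts are negative binomial (dispersion 0.1,
typical for cell-line RNA-seq) with planted "receptor" genes whose log2
mean decreases with the standardized susceptibility score and lognormal
per-sample depth factors so size-factor estimation is genuinely exercised.

What the simulation does *not* emulate: intracellular virus replication,
spatial plate effects, batch structure, library-composition bias, or
immune components. Passing tests therefore demonstrate that the pipeline
recovers the truth under its own mechanistic assumptions, not that those
assumptions describe any particular real assay. One consequence worth
knowing: cumulative dead-cell density is pointwise monotone in MOI only
while killing is weak relative to growth — under strong killing the
high-MOI well is cleared early and its cumulative death plateaus below
that of a slowly dying, still-growing well.

## Test and simulation scale

The test suite checks the exact identities at full precision and the
stochastic guarantees at sizes chosen to keep the whole suite in a few
minutes on one core: family-wise error of the scoring test on 500
simulated null lines (observed fraction of false calls must stay within
Monte-Carlo slack of the nominal 5%, i.e. at most 8%), planted-effect
recovery across 50 seeded replicates of a 12-line study, Dunnett's k = 2
tail against a 200,000-draw Monte-Carlo oracle, and exact Spearman
enumeration at n = 7 against a million permutation draws.

## Known limitations

* Repeated-measures structure is ignored throughout (fixed-effects
  analyses only).
* The exact enumeration p-value is limited to n <= 8; larger panels use
  Monte Carlo or the t approximation.
* Wells are assumed independent; plate-position effects are neither
  modeled nor corrected.
* The 4PL fit reports the best of four starts; pathological standards
  (non-monotone, narrow span) are rejected rather than rescued.
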