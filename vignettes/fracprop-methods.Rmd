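---
title: "Compositional correction of fractionated RNA-seq: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional correction of fractionated RNA-seq: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracprop)
```

## The compositional model

A fractionation experiment splits one lysate into physical fractions
(light/heavy polysomes, nuclear/cytoplasmic, ...) and sequences each as its
own library, alongside an un-fractionated **Total** library from the same
condition and replicate.  Write $\tilde Y_i^f$ for the true (unobserved)
number of molecules of transcript $i$ in fraction $f$, $\tilde Y_i$ for the
whole sample, and assume each library observes every molecule independently
with a library-specific recovery rate: $s$ for the Total, $s^f$ for
fraction $f$.  Recovery subsumes both material loss and sequencing depth;
its defining assumption is uniformity across transcripts within a library.

Because the whole sample is the sum of its fractions plus unrecovered
("lost") material,

$$\mathrm{E}[Y_i] \;=\; \sum_{f} \frac{s}{s^f}\,\mathrm{E}[Y_i^f]
  \;+\; s\,\tilde Y_i^{u},$$

where $Y$ denotes observed counts and $u$ the lost fraction.  Regressing
the Total counts on the fraction counts with **non-negative least squares**
(no intercept — the model has none, and depth ratios cannot be negative)
yields coefficients $\alpha_f$ estimating $s/s^f$.  The package uses the
Lawson–Hanson active-set solver from `pracma`; an independent
subset-enumeration least-squares oracle in the test suite confirms the
solutions to $10^{-8}$ in residual sum of squares.

Three quantities follow:

* **Global fraction weights.** The share of whole-sample RNA in fraction
  $f$ is $w_f = \alpha_f \sum_i Y_i^f / \sum_i Y_i$, with library sums over
  all transcripts; the lost weight is $1 - \sum_f w_f$.
* **Per-transcript proportions.**
  $p_i^f = \alpha_f Y_i^f / \max(Y_i, \sum_f \alpha_f Y_i^f)$ and
  $p_i^u = 1 - \sum_f p_i^f$.  The max-clamp guarantees $p \in [0,1]$ when
  sampling noise makes the rescaled fraction counts exceed the observed
  total; a transcript with reads in fractions but none in the Total gets
  proportions summing to 1 with zero lost mass.  Transcripts with no reads
  anywhere are undefined and reported as `NA`.
* **Corrected counts** $\alpha_f Y_i^f$: fraction counts on the
  whole-library scale, returned alongside the proportions.

Each (condition, replicate) group is fitted independently — recovery rates
are properties of individual libraries, so neither coefficients nor
weights can be pooled across replicates.  `summary()` reports both
per-replicate and condition-mean weights.

## Transcript selection for the regression

The regression set excludes transcripts that carry no information or too
much: defaults are Total count ≥ 10 (`min_total`), at least one read
across the fraction libraries, and Total count not above the 99.5th
percentile of the surviving totals (`max_total_quantile`), a leverage
guard against a handful of extreme transcripts dominating the
least-squares objective under the heavy-tailed abundance distributions
typical of transcriptomes.  Fewer than $10F$ survivors ($F$ = number of
fractions) is an error rather than a silent low-quality fit.  Both
thresholds are exposed as arguments of `fracprop()`.  Proportions are
computed for **all** transcripts afterwards, not only the regression set.

When the observable weights already exceed 1 — NNLS does not enforce the
compositional bound $\sum_f w_f \le 1$ — the lost weight is clamped to 0
and the observable weights renormalized, with a warning.  Deviations
smaller than $10^{-9}$ are treated as floating-point dust and clamped
silently.

## Differential proportion testing

To compare the share of a transcript residing in a fraction set $T$
between two conditions, each replicate contributes trials $n = Y_i$ (Total
count) and successes $k = \mathrm{round}(\sum_{f\in T} \alpha_f Y_i^f)$,
rounded half-up (the binomial likelihood needs integers; half-even
rounding would bias systematically toward even counts) and clamped to
$[0, n]$.  The replicate's own $\alpha$ is used throughout.  $\alpha$ is
treated as known (plug-in): its estimation error is ignored by the tests,
which understates the variance slightly; with the regression pooling
thousands of transcripts the coefficient uncertainty is an order of
magnitude below the per-transcript binomial noise.

Three tests are provided:

* **GLM** (default): binomial GLM with logit link and a condition factor;
  likelihood-ratio statistic against the intercept-only model,
  $\chi^2_1$ p-value.  Degenerate cases — all-zero or all-$n$ successes,
  non-convergence, quasi-separation (|log-odds coefficient| > 15) — fall
  back to the logit test and are flagged, avoiding infinite estimates.
* **Logit**: continuity-corrected empirical logit
  $\log\frac{k+0.5}{n-k+0.5}$ with variance
  $\frac{1}{k+0.5}+\frac{1}{n-k+0.5}$, inverse-variance pooled per
  condition, two-sided z test.  Fast, finite at boundaries, slightly less
  powerful.
* **BetaBin**: beta-binomial with per-condition means and a shared
  overdispersion $\rho$ (shared because 2–3 replicates cannot support
  separate dispersions), jointly maximized by L-BFGS-B on logit scales
  with $\rho$ bounded in $[10^{-6}, 0.9]$; Wald statistic from the
  observed information (delta method back from the logit scale).  With a
  single replicate per condition it degenerates to a pooled binomial Wald
  test, as it should when $\rho$ is not estimable.  As $\rho \to 0$ it
  reproduces the pooled two-proportion Wald test (verified to $10^{-3}$
  in the tests).

Transcripts are testable when summed trials reach `min_count` (default 10)
in both conditions; below that, binomial asymptotics are meaningless and
the transcript is reported untested with missing statistics.
Benjamini–Hochberg adjustment runs over the tested transcripts only, so
discovery counts are reproducible from the reported `tested` flag.
Reported `prop1`/`prop2` are pooled corrected proportions
$\sum_r k_r / \sum_r n_r$ per condition and do not depend on the chosen
test.  Per-transcript tests are mutually independent and order-invariant,
so they may be parallelized freely.

## The simulator and what it emulates

`scenario_config()` / `simulate_truth()` / `subsample_libraries()` build
fully known ground truth in three stages:

1. **Base abundances**: log-normal (meanlog 2, sdlog 1.6), realized as
   integer counts by a multinomial draw at `total_reads` (default 1.8e6,
   the scale of the long-read count profile the defaults are calibrated
   to).  The log-normal reproduces the heavy tail of real transcriptomes —
   a few transcripts carry percent-level shares.  An empirical count
   vector can be supplied instead (`base_counts`).
2. **Allocation**: each transcript's split across fractions + lost is
   Dirichlet with parameter vector
   `allocation_concentration * global_weights`.  The total concentration
   (default 0.2) is the single knob for biological heterogeneity: values
   below 1 concentrate allocations near the simplex corners, i.e. most
   transcripts predominantly in one compartment — matching real
   fractionation data, where for instance the majority of transcripts are
   essentially absent from polysomes while ribosomal-protein mRNAs are
   almost entirely polysome-bound.  `Inf` gives every transcript the
   global mix.  Molecules are then split multinomially, so conservation
   $\sum_f \tilde Y_i^f = \tilde Y_i$ holds exactly.
3. **Thinning**: every observed library is an independent per-transcript
   binomial subsample of its true counts at the configured recovery rate;
   the lost fraction is never emitted.  Replicates are independent
   thinnings of one shared truth.

What the simulator does **not** model: transcript-specific capture biases
(violating the uniform-recovery assumption), positional/length effects,
mapping ambiguity, and batch structure between replicates.  Passing
validation therefore demonstrates correctness of the estimator under its
own assumptions, not robustness to assumption violations in real
libraries.

`evaluate_recovery()` scores a fit against its truth: weight errors and
correlation pooled over replicate groups, and per-transcript Pearson,
RMSE, and *dispersion* — defined here as the standard deviation of
(estimated − true) proportions — over transcripts with true whole count
≥ 10 (below that, true proportions are themselves noise).

## Validation design and problem sizes

`benchmark_recovery()` runs the grid used by the acceptance checks:
3 weight layouts {(0.4, 0.4, 0.2 lost), (0.25, 0.15, 0.6 lost),
(0.6, 0.1, 0.3 lost)} × 3 recovery layouts {all 1.0; Total 0.3;
fractions 0.2} × 3 seeds, at $G = 5000$ transcripts and 1.8M-read ground
truth — the depth the base abundance profile represents.  The package's
figures of merit on this grid are a pooled true-vs-estimated weight
correlation above 0.85 and per-transcript RMSE below 0.17 and dispersion
below 0.15 in every scenario.  Transcript-level accuracy is driven by the
sequencing depth of the fraction libraries: a fraction thinned to 0.2
leaves low-count transcripts with single-digit fraction counts whose
proportion estimates carry irreducible binomial noise, which is why the
validation is defined at the full base depth rather than a scaled-down
one.  Weight estimates, by contrast, pool the whole library and are
insensitive to recovery layout (the depth-invariance check bounds the
mean shift between recovery 0.2 and 1.0 at 0.01).

Two caveats the grid makes visible.  First, weight identifiability rests
on allocation heterogeneity: if every transcript carried exactly the
global mix, the regression could not separate the lost fraction from a
rescaling of $\alpha$, and the lost weight shrinks toward its
corner-solution value as `allocation_concentration` grows.  Second, the
grid is the package's own stand-in for a fuller published scenario sweep;
it spans imbalanced weights, dominant lost fractions and uneven recovery,
but it is not exhaustive.

## Numerical choices

* NNLS per replicate, never pooled; no intercept.
* All-zero predictor columns get $\alpha_f = 0$ with a warning instead of
  failing the whole replicate.
* $R^2$ is computed about the mean of the response on the selected set and
  clipped to $[0, 1]$.
* Fraction ordering is lexicographic by fraction type everywhere, making
  coefficient vectors deterministic.
* Replicate labels are nested within condition; replicates are never
  matched across conditions.
* Ties in the success rounding go half-up; successes clamp to the trials
  with a counted warning.
* Seeds: every stochastic entry point takes an explicit seed;
  `subsample_libraries()` derives a distinct stream from the scenario seed
  so truth and libraries are separately reproducible.

## Limitations

No uncertainty intervals on $\alpha_f$ or the weights; no shrinkage of
weights across replicates; two-condition contrasts only (no omnibus or
paired designs); counts must be precomputed (no BAM/FASTQ handling, no
transcript-to-gene aggregation).  The lost fraction is a modeling
complement — it cannot distinguish unrecovered RNA from RNA absent for
biological reasons.
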