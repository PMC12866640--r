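# fracprop

Compositional correction and differential proportion testing for
fractionated RNA-seq.

## The problem

Fractionation experiments — polysome profiling, nuclear/cytoplasmic
separation, membrane association, RNA-granule enrichment — physically split
a lysate into fractions and sequence each fraction as its own library.
Library preparation and sequencing depth then erase the original
proportions of the fractions: a fraction holding 10% of the RNA and a
fraction holding 60% can both come back as 20 million reads.  On top of
that, part of the material (unbound RNA, discarded gradient zones, losses
during extraction) is never sequenced at all.  Ratios of library-normalized
counts are therefore biased, and the unrecovered "lost" fraction is
invisible to standard differential expression tooling.

`fracprop` reconstructs the original composition from a whole-lysate
(Total) library plus its fraction libraries, per condition and replicate.

## The model

Let Y<sub>i</sub> be the observed Total count for transcript i, and
Y<sub>i</sub><sup>f</sup> its observed count in fraction f.  Each library
observes every true molecule with its own recovery rate s (Total) and
s<sup>f</sup> (fraction f), uniformly across transcripts, so

E\[Y<sub>i</sub>] = Σ<sub>f</sub> (s / s<sup>f</sup>) E\[Y<sub>i</sub><sup>f</sup>] + (lost material).

A non-negative least squares regression of the Total counts on the
fraction counts, over a selected transcript set (minimum Total count,
presence in at least one fraction, extreme-count leverage guard),
estimates the normalization coefficients α<sub>f</sub> = s / s<sup>f</sup>.
From these:

* **global fraction weights** w<sub>f</sub> = α<sub>f</sub> ·
  ΣY<sup>f</sup> / ΣY, with the lost fraction as the complement
  1 − Σ<sub>f</sub> w<sub>f</sub>;
* **corrected per-transcript proportions**
  p<sub>i</sub><sup>f</sup> = α<sub>f</sub> Y<sub>i</sub><sup>f</sup> /
  max(Y<sub>i</sub>, Σ<sub>f</sub> α<sub>f</sub> Y<sub>i</sub><sup>f</sup>),
  with lost complement p<sub>i</sub><sup>u</sup> = 1 − Σ<sub>f</sub>
  p<sub>i</sub><sup>f</sup> (the max keeps proportions in \[0, 1]);
* **differential proportion tests** between two conditions on any fraction
  set, modelling corrected successes k = round(Σ α<sub>f</sub>
  Y<sup>f</sup>) out of n = Y trials: a binomial GLM likelihood-ratio test,
  an empirical-logit z test, or a beta-binomial Wald test with shared
  overdispersion, all with Benjamini–Hochberg correction.

A ground-truth simulator (log-normal abundances, Dirichlet-multinomial
allocation across fractions plus lost, binomial library thinning) supports
validation entirely offline.

## Worked example

```r
library(fracprop)

cfg <- scenario_config(G = 2000, total_reads = 2e5,
                       global_weights = c(Frac1 = 0.25, Frac2 = 0.15, Lost = 0.6),
                       recovery = c(Total = 0.6, Frac1 = 0.8, Frac2 = 0.5),
                       n_replicates = 2, seed = 42)
sim <- simulate_fractionation(cfg)
fit <- fracprop(sim$counts, sim$design)
summary(fit)
#> Per-replicate global fraction weights:
#>             Frac1  Frac2   Lost
#> cond1.rep1 0.2730 0.1363 0.5907
#> cond1.rep2 0.2629 0.1365 0.6007
#>
#> Mean weights per condition:
#>        Frac1  Frac2   Lost
#> cond1 0.2679 0.1364 0.5957
#>
#> Normalization coefficients (alpha = s_total / s_fraction):
#>             Frac1  Frac2
#> cond1.rep1 0.8581 1.2742
#> cond1.rep2 0.8277 1.2625
#>
#> Regression diagnostics:
#>            r_squared n_selected
#> cond1.rep1    0.6752        724
#> cond1.rep2    0.6730        730

evaluate_recovery(sim$truth, fit)
#> Recovery of simulation ground truth
#>   weights: max abs error 0.0426, Pearson 0.9971
#>   transcripts (true count >= 10, n = 1479): Pearson 0.9901, RMSE 0.0614, dispersion 0.0614
```

The scenario placed 25% / 15% of the RNA in the two fractions and lost
60%; the fit recovers (0.27, 0.14, 0.59) despite the three libraries being
sequenced at unrelated depths (recovery 0.6 / 0.8 / 0.5).  The
coefficients α track the depth ratios s<sub>Total</sub>/s<sub>f</sub>, and
per-transcript proportions correlate with the truth at r ≈ 0.99.

For real data the entry point is the same two calls:

```r
counts <- read_count_matrix("counts.tsv")    # transcript_id + one column per library
design <- read_design("annotation.csv")      # Sample,Condition,Replicate,Type; one "Total" per replicate
fit    <- fracprop(counts, design)
res    <- diff_prop_test(fit, c("Condition1", "Condition2"),
                         types = "Fraction1", method = "GLM")
```

Input formats (3-line examples):

```
transcript_id<TAB>S1<TAB>S2<TAB>S3        Sample,Condition,Replicate,Type
tx1<TAB>5<TAB>3<TAB>2                     S1,A,r1,Total
tx2<TAB>0<TAB>1<TAB>4                     S2,A,r1,LP
                                          S3,A,r1,HP
```

A command-line wrapper with subcommands `fit`, `test`, `simulate` and
`evaluate` ships in `inst/cli/fracprop.R` (see `?fracprop_cli`).

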