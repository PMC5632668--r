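# changescope

Analysis pipeline for **change-blindness flicker experiments**: an original
and a manipulated photograph alternate (600 ms each, separated by a 100 ms
blank) until the observer detects the change, and the reaction time (RT) to
detection is the dependent measure. The scientific question the pipeline
serves: is change detection driven only by the *interpretation* of a scene
(its subjectively important content), or also by the stimulus-driven image
statistic that dominates early visual cortex — **contrast energy** — and do
the two interact beyond what two independent detection channels could
produce?

It is written for visual-psychophysics researchers who want a reproducible,
tested version of this analysis with every knob documented, plus a
synthetic-data module (the original stimuli and RT data are not
redistributable) that generates all inputs with known ground truth.

## What it computes

**Local contrast energy.** Per pixel, the Gaussian-weighted RMS contrast of
luminance in a spatial window
`w(dx, dy) = exp(-(dx^2 + dy^2) / (2 sigma^2))` (default sigma = 19.4 px =
0.75 deg on the 481 x 321 px, 18.6 x 12.4 deg grid):

```
CE = sqrt( sum_i w_i (L_i - Lbar)^2 / Lbar^2  /  sum_i w_i )
```

The change score of a manipulation is the absolute difference of the mean
CE over the changed region between original and manipulated image.
**Subjective importance** change is the sum over the changed region of the
5-observer average label map (values in {0, 0.2, ..., 1}).

**Design.** Median splits of both scores cross into a 2x2 low/high design;
a seeded greedy search selects 108 pairs (27 per cell) balanced on size,
eccentricity, mean/max/min contrast, luminance change and spatial-frequency
change (ANOVA + Kruskal-Wallis all p > 0.05), then builds 6 subsets of 36
(9 per condition, no source image repeated within a subset).

**RT analysis.** Hits (clicks within 0.75 deg of the change) are kept;
outcome proportions get a per-condition ANOVA; RTs get an
**inverse-Gaussian GLM** `rt ~ CE + SI + CE:SI` (split or ranked coding)
and per-condition inverse-Gaussian CDF fits.

**Race model.** Miller's bound `F_12(t) <= F_1(t) + F_2(t)` is tested at
the deciles 0.1..0.9 with a subject-level bootstrap and Bonferroni
correction (0.05/9); a positive violation means the high/high condition is
faster than any race of independent channels — evidence for coactivation.

## Worked example

Simulate a full experiment under a *coactivation* architecture (one
accumulator with summed drifts in the redundant condition) and analyze it:

```r
library(changescope)
pool   <- generate_stimulus_pool(stimulus_gen_config(seed = 42))
design <- build_subsets(select_balanced_set(pool$scores, seed = 42), seed = 42)
trials <- simulate_rts(design, rt_gen_config(architecture = "coactivation", seed = 42))
filt   <- exclusion_filter(trials)
round(tapply(filt$trials$rt_s, filt$trials$condition, median), 2)
fit_rt_glm(filt$trials, coding = "split")
race_test(filt$trials, n_boot = 10000, seed = 42)
```

which prints (abridged):

```
retained 2080 of 2160 trials
highCE-highSI  highCE-lowSI  lowCE-highSI   lowCE-lowSI
         3.36          5.69          5.45          7.25

<rt_glm> inverse-Gaussian family, link=log, coding=split, n=2080, residual df=2076
           estimate        se       t         p
intercept  2.206787  0.028642 77.0481 < 2.2e-16 ***
ce        -0.337198  0.037449 -9.0041 < 2.2e-16 ***
si        -0.350501  0.037317 -9.3925 < 2.2e-16 ***
ce_si     -0.250548  0.047913 -5.2292 1.873e-07 ***

<race_test_result> domain=quantile, 9 quantiles, corrected alpha=0.005556
 quantile observed_rt bound_rt violation   ci_lo  ci_hi      p
      0.1      2.1258   2.5460    0.4202  0.2566 0.5755 0.0000
      ...
      0.9      5.2430   5.1889   -0.0541 -0.4071 0.2152 0.7281
significant: 0.1 0.2 0.3 0.4 0.5 0.6 0.7 0.8
max corrected-significant violation: 0.61 s
```

Reading: median RTs order as low/low slowest (7.25 s), single-high
conditions intermediate, high/high fastest (3.36 s); all three GLM effects
are negative (high change shortens RT) and significant; and the redundant
condition beats the race bound by up to ~0.6 s at the lower deciles —
the signature of coactivation. Rerunning with
`architecture = "race"` produces no corrected-significant violation.

## Layout

- `R/` — geometry and image metrics, design balancer, RT analysis,
  race-model test, synthetic data, I/O and CLI.
- `vignettes/changescope-methods.Rmd` — models, assumptions, parameter
  defaults, numerical choices and limitations.
- `tests/testthat/` — unit, property and acceptance suites (oracle
  double-sum contrast energy, null-calibration and power simulations,
  end-to-end determinism).
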