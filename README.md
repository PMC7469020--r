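# foodcoda

Compositional data analysis of 24-hour time-use diaries, built around a
concrete epidemiological question: how do people's daily time budgets
differ across levels of *foodwork* (food shopping, food preparation and
management, washing dishes)?

A diary day collapsed into seven activity parts — personal care, sleep,
eating, physical activity, leisure screen time, work (paid and unpaid,
including foodwork), socialising & hobbies — is a composition closed to
1440 min. Because only the ratios between parts are informative, the
package analyses pivot isometric log-ratio (ilr) coordinates

$$ z_k = \sqrt{\tfrac{k}{k+1}}\;\ln\frac{x_{k+1}}{\mathrm{gm}(x_1,\dots,x_k)},\qquad k = 1,\dots,6, $$

so that $z_1$ is the sleep : personal-care contrast and the last
coordinate contrasts socialising & hobbies with everything else.

The toolkit covers the full survey-analysis chain:

* **Diary handling** — wide-CSV parsing, quality flags (missing time >
  90 min, < 7 episodes, ≥ 2 of 4 basic activities absent, incomplete
  24 h, zero sleep), one random diary per participant, activity-taxonomy
  mapping with the travel rule (active travel → physical activity,
  passive travel inherits the part of the activity it enabled), foodwork
  minutes and the none / some / more categorisation at the engager
  median.
* **Rounded zeros** — zeros below the 10-min grid limit replaced either
  by the deterministic multiplicative fill (6.5 min, ratios of observed
  parts preserved) or by a log-space data-augmentation MCMC that
  estimates sub-limit values from the correlation structure.
* **Inference on the simplex** — MANOVA (Wilks/Pillai) and pairwise
  Hotelling's $T^2$ on ilr coordinates, interaction tests in a
  multivariate linear model, Mardia and Box's M assumption checks,
  Bonferroni critical level 0.05/3 ≈ 0.017.
* **Adjusted compositional means** — per-coordinate OLS with the full
  covariate set, least-squares-means-style reference-grid averaging,
  back-transformation to min/day; stratified reruns when an interaction
  is significant.
* **Bootstrap log-ratio differences** — per-part
  $\ln(\text{adjusted min in A} / \text{adjusted min in B})$ with
  stratified case-resampling percentile intervals at level 0.983.
* **A synthetic survey generator** — logistic-normal compositions with
  covariate structure and retained ground truth, rounded-zero injection,
  and full 144-slot diary expansion, so the entire pipeline is testable
  without restricted survey data.

## Worked example

```r
library(foodcoda)
cfg <- list(simulate = list(n_per_category = list(none = 500, some = 500,
                                                  more = 500)),
            analysis = list(B = 1999), seed = 42)
res <- run_pipeline(cfg)
res$adjusted
```

```
Adjusted compositional means (min/day):
     personal_care sleep eating physical_activity screen_time  work social_hobbies
none          50.1 531.6   74.9              47.2       216.1 308.8          211.3
some          51.8 515.8   79.0              51.0       198.5 347.5          196.4
more          44.0 505.4   78.5              51.8       188.7 402.2          169.4
```

Each row is a covariate-adjusted compositional mean: the model-predicted
day of a participant in that foodwork category at a balanced covariate
profile, in minutes summing to 1440. The omnibus and pairwise tests:

```
MANOVA Wilks = 0.769  F = 34.9  p = 1.44e-76
none_vs_some : T2 = 85.03  p = 1.88e-15
some_vs_more : T2 = 182.2  p = 2.13e-33
```

and the per-part bootstrap log-ratio differences for more vs some
(`^` marks intervals at level 0.983 that exclude zero):

```
              part estimate  ci_low  ci_high marker
     personal_care -0.16287 -0.2080 -0.12057      ^
             sleep -0.02032 -0.0491  0.00712
            eating -0.00745 -0.0451  0.02903
 physical_activity  0.01616 -0.0218  0.05388
       screen_time -0.05062 -0.0870 -0.01426      ^
              work  0.14609  0.1150  0.17987      ^
    social_hobbies -0.14763 -0.1859 -0.11187      ^
```

Here participants in the 'more' category spend
$e^{0.146} \approx 16\%$ more adjusted time on work and significantly
less on personal care, screens and socialising — the generator was
configured with exactly this pattern, and the pipeline recovers it.

A config-file CLI wraps the same chain
(`Rscript inst/cli/foodcoda.R {simulate|run|report} --config cfg.yaml
--out DIR --seed N`).

## Layout

`R/` geometry (`aitchison.R`), diaries (`diary.R`), zero replacement
(`zeros.R`), multivariate tests (`inference.R`), adjusted means
(`adjusted_means.R`), bootstrap (`bootstrap.R`), generator
(`simulate.R`), orchestration (`pipeline.R`); `inst/extdata/` plain-text
fixtures (taxonomy, published counts); `vignettes/methods.Rmd` the
methods notes; `tests/testthat/` the suite including
`test-acceptance.R`.
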