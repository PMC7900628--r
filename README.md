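# contourgaze

Simulation and analysis tools for contour-integration psychophysics
with added orientation noise, aimed at researchers studying perceptual
grouping and internal noise in clinical and developmental populations.
The package covers the complete computational path of such a study:

* **Stimulus/design generation** — Gabor displays on a 39 × 25
  hexagonal grid (975 elements, 1.044° spacing), a 12-element straight
  contour at 60°, balanced orientation jitter ±δ at six external-noise
  levels (0–60°), blocked yes/no sessions, and double-pass repeats
  (identical stimulus order) at 10° and 45°.
* **A synthetic observer cohort** — two groups (n = 24 and n = 32) of
  linear-amplifier observers with additive plus stimulus-dependent
  internal noise, shifted-gamma reaction times, and per-trial gaze
  positions, replacing the unavailable participant data so every
  analysis runs end to end from code.
* **Double-pass internal-noise estimation** — the fixed-point relation
  `pc = m·log10(pa/100) + 100` fitted through (100, 100), and a
  bivariate-normal linear-amplifier model whose inversion turns one
  (percent correct, percent agreement) pair into an estimate of the
  internal-to-external noise ratio `r = σᵢ/σₑ`:
  single-pass yes rate `Φ(a)` with `a = (μ − γ)/√(1+r²)`, both-pass
  agreement from the orthant probability `Φ₂(a, a; ρ)`,
  `ρ = 1/(1+r²)`.
* **Behavioural statistics** — signal-detection categorization (hits /
  misses / false alarms / correct rejections), the 0.25–4.0 s RT
  outlier rule, Bayesian-bootstrap group comparisons (Dirichlet
  weights, 4000 draws), Pearson correlations with Fisher-z intervals.
* **Gaze point-pattern analysis** — screen-window clipping, 5 × 5
  quadrat χ² tests, inhomogeneous Poisson intensity models with
  log-quadratic trend fitted by Berman–Turner quadrature,
  likelihood-ratio tests for noise/group/mark effects, border-corrected
  inhomogeneous K with simulation envelopes, variance ellipses and
  per-subject dispersion summaries.

See `vignettes/contour-noise-methods.Rmd` for the models, assumptions,
parameter meanings and design decisions.

## Worked example

Estimate the internal-to-external noise ratio from a double-pass
performance pair, then run the full synthetic study:

```r
library(contourgaze)

# forward model: an observer with signal strength d = 1.5 and
# internal/external noise ratio r = 0.8
p <- lam_predict(lam_model(d = 1.5, r = 0.8))
#> pc = 72.1, pa = 75.8            # percent correct / percent agreement

# inverse: recover the ratio from that performance pair
estimate_sigma_ratio(p$expected_pc, p$expected_pa)
#> r_hat = 0.800, d_hat = 1.500

# full pipeline on the default 56-subject synthetic cohort
res <- run_pipeline(run_config(master_seed = 1))
print(res)
#> Pipeline result (master seed 1)
#> Synthetic cohort: 56 subjects ( ASD n=24, TD n=32 )
#>   26880 trial rows, 26880 gaze points
#> Slope comparisons (groupA - groupB):
#>  noise_level   t_ratio       df        p
#>           10 -1.134494 53.70191 0.261626
#>           45 -2.606005 53.96012 0.011816
#> Median pairwise distance of mean gaze positions:
#>  group    median        q1        q3
#>    ASD 0.2324770 0.1410475 0.3361296
#>     TD 0.1473184 0.0981554 0.2031470
```

Reading the output: the two groups' double-pass slopes are
statistically indistinguishable at the low noise level (10°, p = 0.26)
but differ at the high level (45°, p = 0.012) with the ASD-labelled
group lower — the signature of stimulus-dependent (not additive)
internal-noise differences. The median pairwise distance between
subjects' mean gaze positions is larger in the ASD-labelled group
(0.23° vs 0.15°), i.e. larger individual differences in fixation
placement. `res` also carries accuracy and RT summaries with bootstrap
intervals, per-subject noise-ratio estimates, quadrat and
intensity-model χ² tests, and gaze-area correlations; with
`out_dir` set, everything is written as CSV/JSON plus a PDF report.

A command-line wrapper is included:

```sh
Rscript inst/scripts/pipeline.R run-all --seed 1 --out-dir out/
```

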