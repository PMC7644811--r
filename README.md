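# synlab

Modular analysis of lower-limb surface EMG recorded during walking and
running, overground and on a treadmill — for movement scientists who want
to ask whether two locomotion conditions are controlled with the same
neuromotor strategy, not just whether the signals look alike.

The central object is the muscle synergy: the envelope matrix
`V` (13 muscles × 200·n_cycles normalized time points) is factorized as

    V ≈ M P,    M ≥ 0 (13 × r),  P ≥ 0 (r × n)

by non-negative matrix factorization with Gaussian multiplicative updates,

    P ← P ∘ (MᵀV) ⁄ (MᵀM P),    M ← M ∘ (V Pᵀ) ⁄ (M P Pᵀ),

where the columns of `M` are motor modules (muscle weightings) and the rows
of `P` motor primitives (time-dependent activation coefficients).
Convergence is declared when the reconstruction R² changes by less than
0.01% over 20 iterations; each rank 1–10 is fitted from 10 random restarts,
and the factorization rank is selected where the R²-vs-rank curve becomes
linear (iterated drop-and-refit linear fit, MSE < 10⁻⁴).

Downstream of the factorization the package provides:

* functional classification of primitives into the four fundamental
  locomotor synergies (weight acceptance, propulsion, early swing, late
  swing) or "combined", by NMF clustering into principal shapes;
* motor primitive geometrics: circular center of activity (CoA) and full
  width at half maximum (FWHM), with half-maximum heat maps;
* rescaled-range (R/S) Hurst exponent of each primitive (window halving
  down to the 200-point cycle period), H < 0.5 flagging anti-persistence;
* gait spatiotemporal parameters (stance, swing, cadence) and their
  step-to-step coefficients of variation;
* statistics: two-way repeated-measures ANOVA (environment × locomotion
  type) with Levene/Shapiro gating, a rank-transform fallback and
  FDR-adjusted post hoc tests, plus one-dimensional SPM over primitives
  with permutation cluster inference and gait-cycle-order resampling;
* a synthetic-trial generator (ground-truth modules and wrapped-Gaussian
  primitives, gait events, raw-like 2 kHz EMG, exact fractional Gaussian
  noise) that makes every stage testable without recorded data.

The methods, their assumptions, and every numerical choice are documented
in `vignettes/muscle-synergy-pipeline.Rmd`.

## Worked example

```r
library(synlab)

# a ground-truth trial: 4 synergies, 30 gait cycles, 5% envelope noise
trial <- generate_trial(r = 4, n_cycles = 30, noise_sd = 0.05, seed = 11)

# raw-like EMG -> linear envelope -> amplitude & time normalization
env <- normalize_amplitude(emg_envelope(trial$raw))
V   <- time_normalize(env, trial$events)

# synergy extraction and rank selection
fit <- extract_synergies(V, ranks = 1:10, n_restarts = 10, seed = 11)
round(fit$curve, 3)
#>     1     2     3     4     5     6     7     8     9    10
#> 0.295 0.644 0.857 0.968 0.972 0.977 0.981 0.984 0.988 0.991
select_rank(fit)
#> [1] 4

model <- fit$models[[select_rank(fit)]]
model
#> synergy_model: rank 4, R2 = 0.9676, 74 iterations

# recovered modules vs ground truth (greedy cosine matching)
round(match_modules(model$M, trial$truth$modules_true)$cosine, 3)
#> [1] 0.995 0.988 0.970 0.967
```

The R² curve shows the knee at rank 4 (0.857 → 0.968, then ~flat), the
drop-and-refit rule returns 4, and the four extracted modules match the
generator's ground truth with cosine similarity ≥ 0.967 despite the noise
and the full filtering chain. Geometrics, fractal and gait measures:

```r
geo  <- apply(model$P, 1, primitive_geometrics)
coas <- sapply(geo, `[[`, "coa_points")
round(coas, 1)                     # one primitive per phase of the cycle
#> [1]  25.0 175.9 128.8  71.9
prop <- which(coas >= 50 & coas < 100)   # the propulsion primitive
round(c(coa_points = geo[[prop]]$coa_points, fwhm = geo[[prop]]$fwhm), 1)
#> coa_points       fwhm
#>       71.9       27.5

round(trial_hurst(model)$h_mean, 3)      # i.i.d. cycle noise -> H << 0.5
#> [1] 0.117
gs <- gait_summary(trial$events)
round(c(stance_cv = gs$stance_cv, cadence_cv = gs$cadence_cv), 2)
#>  stance_cv cadence_cv
#>       2.81       1.46
```

The propulsion primitive peaks at normalized point ~72 (late stance) and is
active for ~27 of 200 points per cycle; the trial Hurst mean far below 0.5
reflects the generator's i.i.d. cycle-to-cycle variation (see the vignette
for why recorded data sit higher).

## The analysis workflow

The numbered scripts under `analysis/` run the full study pipeline on a
synthetic cohort (6 participants × overground/treadmill ×
walking/running) and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # cohort of raw-EMG trials (CSV)
Rscript analysis/02_preprocess.R        # envelopes, normalized cycles
Rscript analysis/03_synergies.R         # NMF, rank table
Rscript analysis/04_classify_metrics.R  # labels, CoA/FWHM, heat maps
Rscript analysis/05_fractal_gait.R      # Hurst table, gait CV summary
Rscript analysis/06_stats.R             # RM-ANOVAs, SPM cluster tables
```

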