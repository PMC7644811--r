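---
title: "Muscle synergies, motor primitive geometrics and fractal analysis: methods"
author: "synlab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle synergies, motor primitive geometrics and fractal analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`synlab` implements a complete analysis chain for multi-muscle surface EMG
recorded during locomotion in a two-by-two design: locomotion type (walking
or running) crossed with environment (overground or treadmill). The chain
runs from raw 13-channel EMG to statistical comparisons of the modular
organization of muscle activity: linear-envelope preprocessing, gait-cycle
time normalization, muscle synergy extraction by non-negative matrix
factorization (NMF), functional classification of the extracted motor
primitives, primitive geometrics (center of activity and full width at half
maximum), rescaled-range fractal analysis, gait spatiotemporal variability,
and scalar plus one-dimensional statistics. A synthetic-data module
generates ground-truth trials so every stage is testable without recorded
data. The numbered scripts under `analysis/` run the whole chain on a
synthetic cohort and write their tables under `results/`.

# The model

Muscle activity is modeled as a low-dimensional modular decomposition. For
a trial, the preprocessed envelopes of the $m = 13$ muscles over
$n = 200 \cdot n_{\text{cycles}}$ normalized time points form a non-negative
matrix $V \in \mathbb{R}^{m \times n}$, approximated as

$$V \approx V_R = M P,$$

where the columns of $M \in \mathbb{R}^{m \times r}_{\ge 0}$ are the *motor
modules* (time-invariant muscle weightings) and the rows of
$P \in \mathbb{R}^{r \times n}_{\ge 0}$ the *motor primitives*
(time-dependent activation coefficients). The rank $r$ is the number of
muscle synergies.

## Preprocessing

Raw EMG (2 kHz; the 10–500 Hz acquisition band-pass is assumed applied at
the device and is emulated, not re-applied) is processed per channel as:

1. zero-phase Butterworth high-pass, 50 Hz cut-off;
2. full-wave rectification;
3. zero-phase Butterworth low-pass, 20 Hz cut-off (the linear envelope);
4. channel minimum subtraction, then division by the channel maximum, per
   trial;
5. time normalization: each gait cycle resampled by linear interpolation to
   200 points, 100 for stance and 100 for swing.

"4th-order zero-phase Butterworth" is read the conventional way for
movement-science pipelines: the filter is designed at order 2 and applied
forward–backward, which doubles the effective order and cancels the phase.
The design order is a parameter (`design_order`) for users who prefer the
other reading. Linear interpolation is used for resampling because it is
shape-preserving and cannot produce negative envelope values.

Phase boundaries are half-open: stance covers $[\text{touchdown},
\text{lift-off})$ and swing $[\text{lift-off}, \text{next touchdown})$, so
no sample is shared between phases. Event tables list one row per cycle
(touchdown time, stance duration); the last listed cycle has no following
touchdown, so its end boundary is estimated as its touchdown plus the
median cycle duration, and the cycle is dropped when the recording ends
first. At most the first 30 cycles enter the analysis.

## NMF and convergence

Factorization uses the classical Gaussian (Frobenius) multiplicative
updates, each iteration updating first the primitives and then the modules:

$$P_{i+1} = P_i \circ \frac{M_i^{\mathsf T} V}{M_i^{\mathsf T} M_i P_i},
\qquad
M_{i+1} = M_i \circ \frac{V P_{i+1}^{\mathsf T}}
                          {M_i P_{i+1} P_{i+1}^{\mathsf T}},$$

with elementwise products and divisions and a guard $\varepsilon =
10^{-12}$ added to denominators (multiplicative updates are
division-by-zero-prone; the value is configurable and far below any
envelope scale). Initial entries of $M$ and $P$ are i.i.d. uniform on
$(0, 1)$. Reconstruction quality is the coefficient of determination

$$R^2 = 1 - \frac{\lVert V - MP \rVert_F^2}
                 {\lVert V - \bar V \rVert_F^2},$$

with $\bar V$ the grand mean of $V$ (the standard definition; stated here
because several variants circulate). $R^2$ is evaluated every iteration
and convergence is declared when its change over the last 20 iterations is
smaller than 0.01% — interpreted as *relative* change, the natural reading
of a percentage; an absolute mode is available via `conv = "absolute"`. A
cap of `max_iter = 2000` guards against pathological inputs. The updates
never decrease $R^2$; the test suite checks this monotonicity on every
trace it draws. The inner loop is compiled (RcppArmadillo), and the
residual is evaluated through the Gram identity
$\lVert V - MP\rVert^2 = \lVert V\rVert^2 - 2\,\mathrm{tr}(M^{\mathsf T}VP^{\mathsf T}) + \mathrm{tr}((M^{\mathsf T}M)(PP^{\mathsf T}))$,
reusing the update's own products rather than forming the $m \times n$
reconstruction each iteration.

For each rank $1 \le r \le 10$ the factorization is repeated from 10 fresh
random initializations and the best-$R^2$ solution kept; restart seeds
derive deterministically from a master seed (`seed + 100 r + restart`), so
a whole extraction is reproducible from one integer.

## Rank selection

The $R^2$-versus-rank curve is scanned for its most linear tail: an
ordinary least-squares line is fitted to the current curve and the mean
squared error computed in raw $R^2$ units; if it is below $10^{-4}$ the
first rank of the tail is selected, otherwise the first point is dropped
and the fit repeated, stopping at two remaining points. The MSE is computed
on the $[0, 1]$ scale of $R^2$ (not percent), the reading consistent with
the $10^{-4}$ threshold producing ranks near 4–5 on locomotor data.

## Functional classification

Per condition, the per-trial mean cycles (200 points) of all extracted
primitives are stacked and factorized with the same NMF engine into
$k = (\text{maximum factorization rank}) + 1$ *principal shapes*. Mean
cycles, rather than full 6000-point primitives, carry the shape information
that defines function, and the spare $+1$ shape gives non-conforming
primitives somewhere to go.

Two implementation choices here were genuinely open and are worth
recording:

* **Clustering initialization.** The clustering factorization is
  initialized deterministically — evenly spaced single-bell shapes for the
  primitive factors and a constant weight matrix — rather than randomly.
  With this initialization the multiplicative updates are exactly
  equivariant under permutation of the stacked primitives, so labels
  cannot depend on trial order; a random initialization (even seed-fixed)
  breaks that invariance, because initial rows stay attached to matrix
  positions, not to primitives.
* **Shape-agreement $R^2$.** A primitive is provisionally assigned to the
  shape holding its largest clustering weight if that weight reaches the
  mean of the whole weight matrix; the assignment is confirmed when the
  $R^2$ between primitive and shape reaches 25% of the average $R^2$ of
  the other assigned primitives against their own shapes (four times the
  average when it is negative). The $R^2$ compares the two curves after
  normalizing each to unit area. Area normalization compares activation
  *distributions*: a primitive blending two bells retains only about half
  of its mass near the single-bell shape and scores near or below zero,
  while max-normalization leaves such blends with $R^2 \approx 0.3$ —
  enough to slip past the 25% rule and be mislabeled fundamental. Unit-area
  comparison is also consistent with the center-of-activity statistic,
  which likewise treats the primitive as a mass distribution over the
  cycle.

Confirmed primitives are *fundamental* and labeled by the phase of their
shape's peak on the 0-based 200-point cycle — weight acceptance $[0, 50)$,
propulsion $[50, 100)$, early swing $[100, 150)$, late swing $[150, 200)$;
the windows are configurable since functional definitions, not point
boundaries, are what is agreed in the field. Everything else is *combined*
(blends or splits of fundamentals), excluded from geometric comparisons.

## Motor primitive geometrics

The **center of activity** (CoA) maps one 200-point cycle onto the unit
circle, $\theta_t = 2\pi (t - 1) / 200$ for $t = 1 \dots 200$ (the first
point sits at angle 0), and takes the quadrant-correct angle of the
resultant vector:

$$A = \sum_t \cos\theta_t \, P_t, \quad
  B = \sum_t \sin\theta_t \, P_t, \quad
  \mathrm{CoA} = \operatorname{atan2}(B, A) \bmod 2\pi.$$

The two-argument arctangent is used because the single-argument form is
ambiguous when $A < 0$. A uniform cycle has zero resultant and an undefined
CoA; the function returns `NA` with a warning. Trial-level CoA is the
*circular* mean of per-cycle CoAs (resultant of unit vectors), which
respects wrap-around near the cycle boundary where late-swing activity
lives; an arithmetic mean would average points 5 and 195 to mid-cycle.

The **FWHM** of a cycle is the number of points strictly exceeding half of
the min-subtracted cycle's maximum; strictness is configurable in effect
only at exact ties, and a constant cycle scores 0. Trial FWHM is the
arithmetic mean over cycles. The **half-maximum heat map** gives, per
normalized time point, the fraction of cycles exceeding their own half
maximum; summing its 200 values reproduces the trial mean FWHM exactly,
an identity the tests assert.

## Fractal analysis

The Hurst exponent of each motor primitive (full-trial series, length
$n = 200 \cdot n_{\text{cycles}}$) is estimated by rescaled-range (R/S)
analysis. For a segment: subtract the mean, cumulate, take the range $R$
of the cumulative sum, divide by the segment's standard deviation $S$.
Window sizes are $N = n, n/2, n/4, \dots$ (integer floor), stopping before
any window would drop below 200 points — the normalized cycle period, below
which "long range" has no meaning for these series; the full-length window
is included as the first point. Per window size the series is cut into
consecutive non-overlapping segments (trailing remainder discarded,
classical R/S practice), R/S averaged across segments, and $H$ obtained as
the OLS slope of $\log(R/S)$ on $\log(N)$. $S$ is the population (divisor
$n$) standard deviation; at these lengths the slope is insensitive to the
choice, which is configurable. The base of the logarithm cancels in the
slope; natural log is used. A fit $R^2$ below 0.9 triggers a warning rather
than an error. $H \approx 0.5$ indicates a memoryless series, $H > 0.5$
persistence, $H < 0.5$ anti-persistence; quasi-periodic locomotor
primitives land below 0.5. Trial-level $H$ averages *all* primitives of
the trial, combined synergies included (a flag restricts to fundamentals).

The estimator is calibrated against exact fractional Gaussian noise
generated by circulant embedding (`generate_fgn`), which is unbiased by
construction; across 100 seeds at $n = 6000$ the mean estimate stays
within $\pm 0.15$ of the true $H$ over $\{0.3, 0.5, 0.7\}$ and is strictly
increasing — small-sample R/S bias (upward at low $H$, downward at high
$H$) is visible but bounded.

## Gait parameters

From per-cycle touchdown and stance times: cycle duration is the difference
of consecutive touchdowns (the last listed cycle, without a successor, is
dropped); swing is duration minus stance; cadence is $120 / \text{duration}$
steps per minute — only one limb's events are available, so symmetric
stepping (two steps per cycle) is assumed and documented. Variability is
the step-to-step percent coefficient of variation, $100 \cdot
\mathrm{sd}/\mathrm{mean}$ with the sample ($n-1$) standard deviation.

## Statistics

**Scalar outcomes** (rank, $R^2$, CoA, FWHM, $H$, gait parameters) are
analyzed with a two-way repeated-measures ANOVA, environment × locomotion
type. Homogeneity is reported via Levene's test; normality of the Gaussian
linear-model residuals is gated by Shapiro–Wilk at $\alpha = 0.05$ (the
gate's test statistic is a package choice; the procedure requires only
*a* normality check). In the balanced 2×2 within design every effect
reduces to a squared paired $t$ on its within-participant contrast, and
type I/II/III sums of squares coincide; the implementation computes these
contrasts directly and the tests verify equality with `aov()`'s
multistratum decomposition to $10^{-8}$. When the gate fails, the same
engine runs on the pooled ranks of the data — a rank-transform ANOVA,
documented as an approximation to dedicated rank-based RM-ANOVA estimators.
Post hoc comparisons are least-significant-difference paired tests over the
six condition pairs with Benjamini–Hochberg adjustment.

**One-dimensional curves** are compared by statistical parametric mapping
over the 200 normalized time points. The pointwise statistic is the
repeated-measures $F$ for the environment effect computed from participant
× environment cell means (cycles averaged within the cell). Cluster
inference is nonparametric: environment labels are sign-flipped within
participants (`n_perm` permutations), the $(1-\alpha)$ quantile of the
permuted curve-maximum $F$ gives the critical value, and each
suprathreshold cluster receives $p = (1 + \#\{F^{*}_{\max} \ge
F_{\text{cluster max}}\}) / (n_{\text{perm}} + 1)$. This replaces
random-field-theory thresholds deliberately: permutation inference needs no
smoothness estimation, is exact under exchangeability, and its validity is
itself testable (the suite checks the null cluster rate). Cluster
*locations* from the two approaches are therefore compared by overlap, not
point-for-point. To remove any influence of gait-cycle ordering, cycle
order is re-randomized within each participant and environment
(`n_resamples` times, 10,000 by default) and the $F$ curve averaged across
resamples; the gait-cycle factor is treated as within-participant and
fixed. Because the environment $F$ depends on cycles only through their
cell means, it is mathematically invariant to this randomization — the
averaging is retained for fidelity to the stated procedure and costs
little.

# The synthetic generator

`generate_trial` builds ground-truth trials: non-negative modules (for
$r = 4$, physiological templates of the four fundamental locomotor
synergies — knee/hip extensors for weight acceptance, plantarflexors for
propulsion, dorsiflexors for early swing, hamstrings for late swing),
wrapped-Gaussian single-bell primitives with per-cycle peak jitter
(wrapping keeps late-swing activity circularly continuous into the next
cycle), envelope noise as zero-clipped additive Gaussian scaled to the
noiseless maximum, gait events with Gaussian step-to-step variability, and
a raw-like signal obtained by amplitude-modulating a 10–500 Hz band-limited
Gaussian carrier at 2 kHz so the filtering chain has realistic spectral
content to work on. Defaults (30 cycles, 13 muscles, noise 0.05, jitter 3
points, bell width 12 points, peaks at 25/75/125/175, stance 0.6 s of a
1.0 s cycle, stance CV 3%, cycle CV 2%) are chosen once as representative
of comfortable adult walking and are the conditions under which the
pipeline's recovery properties are asserted.

What the generator does **not** emulate — and hence what passing tests do
not show about recorded data: electrode-level artifacts (motion artifact,
crosstalk), treadmill-belt speed fluctuation, amplitude non-stationarity
across a trial, and, importantly, temporally structured cycle-to-cycle
dependence. Because its cycle-to-cycle variation is i.i.d., synthetic
primitives are far more anti-persistent ($H$ near 0) than recorded
locomotor primitives (typically 0.2–0.5): the generator supports *ordering*
and *calibration* tests of the Hurst machinery, not absolute-level
comparisons. The envelope-noise model (truncated Gaussian) is likewise a
stand-in; the statistics of real EMG envelope noise are not characterized
here.

# Numerical choices and degenerate inputs

* Division guard in NMF updates: $10^{-12}$, configurable.
* `select_rank` regression: OLS, MSE in raw $R^2$ units, threshold
  $10^{-4}$.
* Constant envelope channels normalize to all-zeros with a warning rather
  than erroring — dead channels occur in practice.
* Constant R/S segments (zero SD) are excluded from the window average.
* Uniform cycles have undefined CoA (`NA` + warning), zero FWHM.
* Zero-variance ANOVA contrasts give $F = 0$, $p = 1$ (no evidence) rather
  than NaN; zero-variance residuals count as passing the normality gate.
* All random stages (inits, restarts, permutations, resamples, generators)
  consume explicit integer seeds; derived seeds stay below $2^{31}$.

# Problem sizes

The test suite asserts the pipeline's properties at these sizes, chosen to
bound each check within minutes on a single core while keeping Monte-Carlo
error well inside the asserted margins: exact recovery on 10 noiseless
rank-4 trials (13 × 6000, best of 10 restarts); rank recovery on 50 noisy
trials at the full 10-rank × 10-restart protocol; CoA/FWHM oracle
equivalence on 1000 random cycles; Hurst calibration on 100 fGn seeds per
$H \in \{0.3, 0.5, 0.7\}$ at $n = 6000$; SPM validity over 200 null
replicates at 500 resamples and 500 permutations; scalar-ANOVA type-I
calibration over 10,000 null replicates at $n = 30$. The `analysis/`
cohort uses 6 participants × 4 conditions × 30 cycles. `scripts/acceptance.R`
recomputes headline quantities at comparable sizes (20 noisy trials, 30
fGn seeds per $H$, 2,000/100 calibration replicates).

# Known limitations

* The rank-transform fallback approximates dedicated rank-based RM-ANOVA
  fitters; exact agreement with those estimators is not claimed.
* Permutation SPM and RFT-based SPM agree on detection but not on exact
  thresholds; cluster bounds are comparable only by overlap.
* The deposit reader (`read_deposit`) expects the published RData layout
  and is exercised against synthetic miniatures of that layout; it is
  optional plumbing, and no analysis in this package requires the
  download.
* Strike-index computation requires kinetic data and is out of scope.
* Cadence from one limb assumes step symmetry.
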