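---
title: "Methods: left-right phenotype statistics and organizer-flow tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: left-right phenotype statistics and organizer-flow tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrflow)
```

This vignette explains the statistical models and algorithmic choices
behind `lrflow`, which quantifies zebrafish left-right (L-R) patterning
experiments: multinomial phenotype scoring (heart looping, visceral organ
position, gene-expression pattern classes), dorsal forerunner cell (DFC)
clustering and migration, and microbead velocimetry of the fluid flow in
the Kupffer's vesicle (KV), the organ that breaks L-R symmetry.

## 1. The multinomial permutation test

Phenotype scoring experiments yield, per condition, counts over m mutually
exclusive outcome categories — for heart looping the categories are D-loop
(normal dextral), mild/no-loop, and S-loop (reversed). For two conditions
with counts $(k_{a,1},\dots,k_{a,m})$, $N_a = \sum_c k_{a,c}$ and likewise
$b$, the dissimilarity is

$$\delta = \sum_{c=1}^{m} \left| \frac{k_{a,c}}{N_a} - \frac{k_{b,c}}{N_b} \right|,$$

twice the total-variation distance between the two empirical
distributions, so $\delta \in [0, 2]$. The null hypothesis — both
conditions share one multinomial — is tested by pooling all $N_a + N_b$
observations and re-splitting them at random into groups of the original
sizes, K = 100,000 times by default; the p-value is the frequency of
re-splits with $\delta' \ge \delta$.

Implementation notes:

* Re-splitting pooled categorical observations without replacement makes
  the group-a counts multivariate hypergeometric; `permutation_test()`
  samples that law directly with sequential conditional `rhyper()` draws,
  vectorised across all K resamples. This is the exact permutation null,
  not an approximation, and runs K = 100,000 in well under a second.
* Ties $\delta' = \delta$ count as exceedances, which makes the test valid
  (never anti-conservative) on discrete data; the identical-table case
  correctly returns p = 1.
* When no resample reaches $\delta$ the function reports
  `is_lower_bound = TRUE`: the honest summary is p < 1/K, not p = 0.
* All randomness flows through one explicit integer `seed`; results are
  bit-reproducible.

Because a p-value estimated by K draws is itself binomial, calibration and
oracle checks in the test suite compare Monte-Carlo results with exact
enumeration over all splits (small tables) and verify that the type-I
error at $\alpha = 0.05$ on 1,000 null table pairs (m = 3, N = 100 per
group, K = 2,000) stays inside [0.03, 0.07].

## 2. Reconstructing counts from printed percentages

Published tables often print per-category percentages to two decimals
without raw counts. `reconstruct_counts()` inverts the printing: it finds
the smallest total N (or validates a stated one) such that non-negative
integers reproduce every printed percentage to half a unit in the last
decimal ($|100 k_c / N - p_c| < 0.005$). For two-decimal percentages this
pin-points N sharply; it is how all count vectors used by the analysis
scripts are obtained.

Two published-table pathologies are handled explicitly:

* **Complement-derived last column** (`complement_last = TRUE`): some rows
  print the last category as 100 minus the other *rounded* percentages
  rather than rounding its own frequency, so it absorbs their rounding
  error. The last category then gets a widened window
  ($0.005\,m$) while the others stay strict. Diagnostic: the printed row
  sums to exactly 100.00 while the strict search only succeeds at an
  implausibly large N.
* **Header/percentage disagreement**: several rows of the source tables
  carry header Ns that contradict their own percentages (two rows appear
  swapped; one is consistent only with a different N; one was divided by
  the wrong denominator so its percentages sum to 98.5). The package
  trusts percentages over header Ns, and the analysis driver
  `analysis/01_phenotype_stats.R` prints every disagreement it finds
  rather than silently adopting either number.

This matters for inference: the permutation p-value depends on the group
sizes, so reconstructing with a wrong N changes the test's power, not just
cosmetics. One caption p-value in the source could not be reconciled under
any count vector consistent with its percentages (see the README's
reproduction notes); the package reports what the stated method computes
on the percentage-consistent counts.

## 3. Uniform-prior binomial posterior

For binary malformation scoring (e.g. DFC clustering defective vs normal),
each embryo is a Bernoulli trial with condition-specific probability q.
With a uniform prior, k malformed among n gives posterior
$q \sim \mathrm{Beta}(k+1,\, n-k+1)$; the maximum-likelihood estimate is
the empirical frequency k/n, the posterior standard deviation

$$\sigma = \sqrt{\frac{\alpha\beta}{(\alpha+\beta)^2(\alpha+\beta+1)}},
\qquad \alpha = k+1,\ \beta = n-k+1$$

supplies the uncertainty interval (mean ± sd, clipped to [0, 1]). The
posterior mean shrinks toward 1/2 by at most $1/(n+2)$, so MLE and
posterior mean agree closely at the study's sample sizes (n of order 100).

## 4. Fisher exact test convention

`fisher_exact_two_sided()` conditions on the margins and sums
hypergeometric point probabilities of all tables no more probable than the
observed one (the point-probability, or "minimum-likelihood", two-sided
convention — the default in most statistical software). The source work
does not state its convention; this choice reproduced one of its caption
p-values to the printed precision (7.9e-15), which we take as
confirmation. Probabilities are accumulated on the log scale so extreme
tables (p ~ 1e-40) remain accurate. The implementation is validated in the
tests against full enumeration of every 2x2 table with total at most 12 and
against `stats::fisher.test`.

## 5. Bead detection, linking, and speed

Imaging conditions emulated and assumed: single-plane time lapse at 4 Hz,
0.25 um pixels, sub-micron fluorescent beads appearing as ~1 um spots.

**Detection** (`detect_spots()`) is multi-scale blob detection: per frame,
a geometric ladder of Gaussian blurs; normalised difference-of-Gaussians
(DoG, a Laplacian-of-Gaussian approximation) responses; strict local
maxima in position x scale space. Three gates follow:

* *response significance*: the blob response must exceed 5 robust standard
  deviations (MAD) of the frame's response at that scale. This is what
  keeps pure-noise frames empty (validated: at most 1 false positive per
  100 noise-only frames) — a brightness quantile alone cannot, since some
  noise pixels always sit in the top percentile.
* *size*: apparent diameter (FWHM) inside 0.75-1.25 um. The scale ladder
  deliberately extends beyond the gate so oversized structures are
  measured at their true scale and rejected, not mis-assigned to the
  ladder edge. The DoG response of a Gaussian spot with sd s peaks at
  $\sigma = s/\sqrt{k}$ (k the ladder ratio); the estimator corrects for
  this, giving ~0.9-1.1 um estimates for true 1.0 um spots.
* *brightness*: peak intensity above a whole-stack quantile, default 0.99
  (the brightest 1% of intensities). The source protocol's wording
  ("brightness superior to the 0.01 percentile") is ambiguous — read
  literally, a 0.0001 quantile excludes essentially nothing — so the
  quantile is an explicit argument and the complementary reading is the
  default.

Sub-pixel localisation uses separable three-point parabolic interpolation
of the response; on SNR-10 renders the residual localisation error is
~0.1 px, well below the one-pixel recovery tolerance asserted in tests.

**Linking** (`link_detections()`) is frame-to-frame greedy assignment:
candidate (track end, next detection) pairs closer than the gate
(2.5 um, strict) are matched in increasing distance order, one use per
endpoint, ties broken by detection index. Objects jumping farther start
new trajectories; there is no gap closing, merging, or splitting. Greedy
distance-ordered matching is optimal whenever inter-bead spacing exceeds
twice the per-frame motion, which the simulator's default bead density
respects by construction.

**Speed** (`mean_bead_speed()`): per-track mean step displacement divided
by the frame interval, then an unweighted mean across tracks (each
trajectory counts once; pooling all steps would over-weight long tracks —
the per-track convention is adopted and documented since the source does
not state one). Note the estimator measures total motion: with diffusion
D > 0 the expected step length exceeds the advective contribution, so
recovery of an imposed flow speed from raw steps is only exact in the
low-diffusion regime; the directed-model MSD fit's v is the
diffusion-corrected speed estimate.

## 6. MSD analysis and motion classification

`compute_track_msd()` uses the time-averaged (overlapping-pair)
definition: $\mathrm{MSD}(n\Delta) = \mathrm{mean}_i\,
\lVert r_{i+n} - r_i\rVert^2$. For a noise-free constant-velocity track
this equals $v^2 \Delta t^2$ exactly at every lag (asserted to machine
precision in the tests); for free 2D diffusion its expectation is
$4D\Delta t$. `ensemble_msd()` averages per-track curves with equal
weight, restricted to tracks lasting 1-8 s: shorter tracks carry almost no
displacement information, longer ones are rare (< 1% in the emulated
acquisitions) and would dominate long lags.

`classify_motion()` fits three canonical models — directed
$4D\Delta t + v^2\Delta t^2$, confined $L^2(1 - e^{-\Delta t/\tau})$ with
$D = L^2/4\tau$, and free $4D\Delta t$ — all constrained non-negative
(non-negative least squares for the linear models; bounded
Levenberg-Marquardt with a grid fallback for the confined one), and picks
the lowest small-sample corrected Akaike score computed from the Gaussian
residual sum of squares; the free model is the nested 1-parameter
alternative, so a linear curve is called diffusive rather than directed
with v = 0. The log-log slope alpha is reported as a model-free
diagnostic (≈2 directed, ≈1 diffusive, falling below 1 under
confinement).

Numerical notes: an exactly ballistic curve gives zero residuals, which
the score handles by flooring the RSS; the confined fit is seeded from the
curve's plateau and initial slope. On the simulator's study conditions
(200 beads, 8 s tracks), 20/20 directed and 20/20 confined seeded
replicates classify correctly; the acceptance tests require at least 95%.

## 7. DFC kinematics

Cell tracks are minute-stamped (t, x, y) with +y toward the vegetal pole.

* `convergence_ratio()`: y-extent (max - min over cells) at the first
  recorded timepoint divided by the extent at the last. Orientation
  (initial over final) is a package convention chosen so convergence
  scores above 1 — the source does not state one. Extent is the plain
  range, the simplest reading of the group's "stretch" along the axis;
  cells missing at either endpoint are excluded (manual tracks are
  ragged), at least two must remain, and a fully collapsed final extent
  returns a flagged infinite result rather than dividing by zero.
* `migration_speed()`: per-cell mean of step displacement over step
  duration, averaged without weights across cells. Positional noise
  inflates this estimator (each step adds measurement jitter in
  quadrature); at zero noise a uniform drift is recovered exactly.
* `migration_index()`: position along the animal-vegetal axis as a
  percentage of embryo length, 100 * position / length.

## 8. What the synthetic data emulate — and what they do not

The generators exist so that every pipeline stage is testable offline with
known ground truth; their defaults are fixed study conditions, not tuning
knobs.

* `simulate_bead_tracks()`: directed mode advects beads in a
  counter-clockwise vortex — rigid rotation at each bead's radius with the
  default tangential speed 0.96 um/s (the wild-type mean bead speed scale)
  plus residual diffusion D = 0.02 um^2/s; the advection step is an exact
  rotation so zero-diffusion beads trace exact circles. Confined mode is
  Brownian motion (D = 1.1 um^2/s, the Stokes-Einstein scale for a 0.5 um
  sphere in a ~0.8 mPa s medium) reflected at a 5 um disc boundary.
  Defaults: 4 Hz, 8 s tracks so whole trajectories sit in the 1-8 s
  analysis window; directed beads start at radii 8-36 um, spacing chosen
  so 200 beads remain optically resolvable when rendered. For a disc the
  long-lag MSD plateau is $R^2$ (mean squared distance between two
  uniform points), reached on the slowest-mode timescale
  $R^2/(\lambda_1^2 D)$ with $\lambda_1 \approx 1.84$ — about 7 s at the
  defaults, so plateau-level assertions in the tests use 40 s simulations
  while classification runs use the 8 s study window.
* `render_image_stack()`: isotropic Gaussian spots (default FWHM 1.0 um),
  constant background, additive Gaussian noise, default SNR 10. It does
  not model Poisson shot statistics by default, uneven illumination,
  out-of-focus light, or bead blinking.
* `simulate_dfc_tracks()`: group centroid drifts vegetally (default
  1 um/min over 3 h at 3 min sampling, a ~180 um journey on a ~1 mm
  embryo) while each cell's deviation from the centroid decays as
  $e^{-ct}$ (default c = 0.004/min, a roughly two-fold convergence);
  the per-step decay is exact, so at zero noise the convergence ratio
  equals $e^{cT}$ identically and recovery tests have a closed-form
  target. Real DFC motion adds cell-cell contact dynamics, ragged manual
  tracking, and anisotropic noise that this linear relaxation ignores.

Passing tests on these simulations therefore demonstrate that the
estimators recover known kinematic and statistical structure through the
full pipeline (rendering included); they do not certify performance on
real microscopy, where PSF anisotropy, density fluctuations and photon
noise are harsher.

## 9. Problem sizes and runtime choices

Test-suite simulations use 200-500 beads, 33-161 frames and image fields
of ~300 px so the whole suite runs in about two minutes; the permutation
calibration uses 1,000 table pairs at K = 2,000, and printed-table
reproductions use the study's own K = 100,000 (sub-second each). These
sizes were chosen as the smallest at which the asserted tolerances are
comfortably non-marginal.

## 10. Known limitations

* Strictly 2D, single-channel, uniform frame interval; no gap closing, so
  a single missed detection splits a trajectory (harmless for speed and
  ensemble-MSD statistics, which are per-track-unweighted).
* The permutation test assumes exchangeable independent outcomes; batch
  structure in pooled experiments is not modelled (and is the likely
  origin of the caption p-values we could not reproduce).
* `reconstruct_counts()` assumes round-half printing to exactly two
  decimals; other printing conventions need the complement-aware mode or
  a denominator search.
* The confined-motion model is a single exponential; real corralled
  diffusion has a mode spectrum, so fitted tau is an effective timescale.
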