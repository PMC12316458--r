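# lrflow

Quantitative analyses for zebrafish left–right (L–R) patterning studies.
During early development a transient ciliated organ — the Kupffer's
vesicle (KV), built by migrating dorsal forerunner cells (DFCs) — drives a
counter-clockwise fluid flow that breaks L–R symmetry; downstream readouts
include heart looping direction and visceral organ placement. `lrflow`
implements the statistics and image-analysis steps such studies need, with
synthetic-data generators so every stage runs and is tested fully offline:

* **Phenotype statistics** — a permutation test for multinomial outcome
  distributions, count reconstruction from printed percentages, a
  uniform-prior Beta-binomial malformation-probability estimator, and an
  exact two-sided Fisher test.
* **KV bead velocimetry** — spot detection in time-lapse stacks, gated
  nearest-neighbour linking, time-averaged mean-square displacement
  (MSD), directed/confined/diffusive motion classification, and mean bead
  speed.
* **DFC kinematics** — convergence ratio, migration speed, and the
  migration index along the animal–vegetal axis.
* **Synthetic data** — multinomial tables, vortex/confined/Brownian bead
  trajectories, rendered fluorescence spot stacks with ground truth, and
  converging cell tracks.

## The core statistic

For two conditions with category counts $(k_{a,c})$, $(k_{b,c})$ and
totals $N_a$, $N_b$, the dissimilarity between their outcome
distributions is

$$\delta = \sum_c \left| \tfrac{k_{a,c}}{N_a} - \tfrac{k_{b,c}}{N_b} \right|
  \in [0, 2],$$

twice the total-variation distance between the empirical distributions.
Significance comes from the pooled-resplit permutation null: all
$N_a+N_b$ observations are pooled and randomly re-split into groups of
the original sizes K = 100,000 times; the p-value is the frequency of
re-splits with $\delta' \ge \delta$, reported as the bound $p < 1/K$
when no re-split reaches $\delta$. Binary malformation rates are
summarised by the uniform-prior posterior
$\mathrm{Beta}(k{+}1,\, n{-}k{+}1)$, whose sd gives the error bar.
Motion regimes are told apart by MSD shape: $v^2\Delta t^2$ growth for
directed transport, $4D\Delta t$ for free diffusion, a plateau
$L^2(1 - e^{-\Delta t/\tau})$ under confinement.

## Worked example

Compare wild-type and triple-mutant heart-looping outcomes, estimate a
malformation probability, and classify simulated organizer flow:

```r
library(lrflow)

wt  <- outcome_table("WT",       c("D-loop", "mild/no-loop", "S-loop"), c(107, 14, 0))
mut <- outcome_table("triplMut", c("D-loop", "mild/no-loop", "S-loop"), c(50, 34, 47))
permutation_test(wt, mut, n_resamples = 100000, seed = 1)
#> Pooled-resplit permutation test
#>   conditions: WT vs triplMut
#>   delta = 1.0052,  K = 100000,  exceedances = 0
#>   p < 1e-05

binomial_posterior(119, 182)
#> Beta-binomial posterior: k = 119 / n = 182
#>   MLE = 0.6538 (65.38%)
#>   posterior Beta(120, 64): mean = 0.6522, sd = 0.0350
#>   interval (mean +/- sd): [0.6172, 0.6872]

tr <- simulate_bead_tracks("directed", n_beads = 200, tangential_speed = 0.96, seed = 1)
classify_motion(ensemble_msd(tr))
#> Motion classification: directed
#>   directed fit: v = 0.9455 um/s; confined fit: L = 956.5 um, tau = 1.617e+05 s
#>   D (directed model) = 0.05299 um^2/s; log-log exponent alpha = 1.938
#>   AICc: directed -126.9, confined 128.1, diffusive 125.6
```

The permutation test finds the two looping distributions maximally
incompatible at the resampling resolution (no re-split among 100,000
reached the observed dissimilarity of 1.005); the posterior says a 65.4%
malformation frequency in 182 embryos is known to about ±3.5 points; and
the MSD of simulated vortex flow is quadratic (alpha ≈ 1.9), classified
as directed transport with the imposed ~0.96 µm/s tangential speed
recovered by the fit.

## Analysis workflow

Numbered drivers under `analysis/` run the package end to end and write
tables under `results/`:

1. `01_phenotype_stats.R` — reconstructs integer counts from the published
   percentage tables (reporting every header/percentage inconsistency it
   finds), runs all permutation tests, and computes clustering posteriors
   and Fisher tests.
2. `02_bead_flow.R` — simulates directed and confined bead regimes,
   renders the directed one into a fluorescence stack, re-tracks it
   (detect → link), and summarises MSD classification and speeds.
3. `03_dfc_kinematics.R` — simulates control-like and mutant-like DFC
   recordings and quantifies convergence, speed, and migration index.

```sh
Rscript analysis/01_phenotype_stats.R
Rscript analysis/02_bead_flow.R
Rscript analysis/03_dfc_kinematics.R
```

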