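---
title: "Models and methods behind volatilearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind volatilearn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(volatilearn)
library(dplyr)
```

`volatilearn` analyses implicit probabilistic visual learning experiments in
head-fixed mice: a cue-outcome task whose contingencies move from a stable to
a volatile regime, trial-aligned calcium-imaging population recordings from
the superior colliculus (or retinal / corticotectal axon terminals),
pupillometry, and receptive-field mapping. This vignette is the package's own
account of the models it implements, the tunable parameters that matter, what
the synthetic-data generator does and does not emulate, and the numerical and
design choices that were genuinely open.

## The task

Each trial pairs an oriented-grating cue (vertical or horizontal, 1 s) with an
outcome after a 0.5-s gap: either one of six aversive visual stimuli
(sweeping discs and looming discs, 2 s) or an omitted outcome (gray screen).
The *expected* pairings are vertical→aversive and horizontal→omitted. Three
72-trial stable blocks run at an expected-contingency probability of 5/6
(83.4%); a following volatile epoch changes the probability every 24 trials
(1/6, 1/2, 5/6). The first stable block absorbs early movement artifacts and
is flagged `excluded`; the analysis sees 216 trials in three 72-trial epochs —
early-stable (ES), late-stable (LS) and volatile (VL) — with 108 aversive
outcomes, 36 per epoch, six per aversive subtype per epoch.

`generate_session()` realizes counts *exactly* (`round(p * n)` expected trials
per block) and balances cues, outcomes and subtypes within every analysis
epoch, permuting the fixed label multiset with one seed per block. This is a
design choice rather than i.i.d. sampling: it is the only construction under
which every simulated subject sees identical contingency totals, and it makes
the printed design counts invariants rather than expectations. Whether
unexpected trials should also be balanced across the two cue types is not
determined by the task description; the generator balances them by default
and exposes `balance_unexpected_across_cues` to turn that off (which requires
no extra divisibility).

```{r session}
sess <- generate_session(design_config())
table(analyzed_trials(sess)$epoch, analyzed_trials(sess)$outcome)
```

## The ideal observer

The observer is a three-level binary hierarchical Gaussian filter (HGF).
Level 1 tracks the trial's contingency bit $u_k \in \{0, 1\}$ (1 =
unexpected pairing), level 2 the contingency probability on a logit scale
($\mu_2$, with $\hat\mu_1 = s(\mu_2)$ for the logistic $s$), and level 3 the
log-volatility of the environment ($\mu_3$). One trial's update:

$$
\hat\sigma_2 = \sigma_2^{(k-1)} + e^{\mu_3^{(k-1)} + \omega_2}, \qquad
\sigma_2 = \left(\hat\sigma_1 + 1/\hat\sigma_2\right)^{-1}, \qquad
\mu_2 = \mu_2^{(k-1)} + \sigma_2\,\delta_1,
$$

with $\delta_1 = u_k - s(\mu_2^{(k-1)})$ and
$\hat\sigma_1 = \hat\mu_1(1 - \hat\mu_1)$; level 3 moves by the
volatility-weighted level-2 prediction error
($\mu_3 = \mu_3^{(k-1)} + \sigma_3 w_2 \delta_2 / 2$). Thirteen per-trial
quantities in five classes are exposed as trajectories: learning rates
$\alpha_{1..3}$, prior predictions $\hat\mu_{1..3}$, belief variances
$\hat\sigma_{2..3}$, uncertainties $\mathrm{unc}_{1..3}$ (outcome,
informational, environmental) and precision-weighted prediction errors
$\varepsilon_{2..3}$.

Three points were open and are resolved as follows:

* **Priors and tonic volatilities.** $\omega_2, \omega_3$ and the initial
  state are not pinned down by the analysis they feed (the trajectories are
  used as correlation regressors, and Pearson correlation is invariant to
  affine rescaling). The defaults are the canonical binary-HGF choices
  $\mu_2^{(0)} = 0$, $\sigma_2^{(0)} = 1$, $\mu_3^{(0)} = 1$,
  $\sigma_3^{(0)} = 1$, $\omega_2 = -2$, $\omega_3 = -6$; all are fields of
  `hgf_config()`.
* **$\varepsilon_3$.** The implemented default is
  $\varepsilon_3 = \hat\sigma_2\,\delta_3/\sigma_3$, built from the generic
  level-3 prediction error $\delta_3$. The canonical precision-weighted form
  uses the level-2 prediction error instead; it is available via
  `hgf_config(epsilon3_canonical = TRUE)` and changes only that one column.
* **$\alpha_1$.** The level-1 learning rate is the prediction-update /
  prediction-error ratio
  $(s(\mu_2^{k}) - s(\mu_2^{(k-1)}))/\delta_1$. Its denominator can come
  arbitrarily close to zero; below `alpha1_guard` (default $10^{-12}$) the
  trial's $\alpha_1$ is returned as `NA` and carried as missing downstream
  (pairwise-dropped in correlations) rather than clamped. Likewise a
  non-positive $\sigma_3$ aborts with the trial index instead of being
  silently clamped — clamped trajectories would corrupt the regressors.

The forward pass starts from the configured state with no burn-in, and
`subset_aversive()` restricts trajectories to the 108 aversive-outcome trials
so they can be compared with neuronal trajectories, which only exist for
aversive responses.

## Contextual response modulation

Deconvolved activity is z-scored per cell *within each analysis epoch*
(mean 0, SD 1 over the epoch's frames). The alternative — whole-recording
moments — is available via the `scope` argument of `zscore_epoch()`;
within-epoch is the default because slow drifts (photobleaching) would
otherwise leak epoch-level offsets into every comparison. Trial-averaged
responses $z(t)$ exclude trials whose mean platform excursion exceeds
0.25 mm. A cell is *responsive* when $z(t)$ exceeds a threshold in at least
one epoch: 1 for collicular somata, 0.75 for axonal boutons (smaller
structures carry noisier signals, hence the lower bar).

The modulation statistic is
$\Delta z = \bar z - \langle \bar z\rangle_\mathrm{epochs}$, where $\bar z$
averages $z(t)$ over the 2-s outcome window; $\Delta z$ sums to zero across
epochs per cell by construction. The window early/late split sits at the
window midpoint (1 s) — the component analyses name no boundary, so the
midpoint is the symmetric choice, adjustable through the generator's
`late_component_weight` on the simulation side.

**Group inference.** `compare_epochs()` fits value ~ Group × Epoch + Mouse
within Group and reports Tukey–Kramer pairwise epoch contrasts per group via
estimated marginal means. By default cells are first aggregated to
mouse-by-epoch means. This is deliberate: cells recorded in the same animal
share the trial sequence and the same excursion-excluded trial set, which
behaves as a mouse × epoch random component. Treating cells as independent
replicates makes the interaction test badly miscalibrated in both directions
(near-zero type-I on $\bar z$, where unmodeled per-cell main effects inflate
the residual; severalfold inflation on $\Delta z$). Aggregation tests
group-level effects against mouse-level variation — the split-plot error
stratum — and simulation under the generator's flat preset puts the
interaction type-I error at its nominal 5%. The cell-level model remains
available (`unit = "cell"`) for descriptive use.

Orientation bias of baseline cue responses follows the same logic at the
animal level: per-cell vertical−horizontal ES response differences, per-animal
medians, a two-sample Kolmogorov–Smirnov test between genotypes, and
per-animal χ² tests of the vertical/horizontal preference split with
Bonferroni correction. "Orientation-selective" has no canonical definition at
the single-cell level here; the package uses a two-sided Wilcoxon rank-sum
test between vertical- and horizontal-cue trial responses at α = 0.05, which
is a documented, configurable choice.

## Neuronal trajectories and decay removal

For correlation with the observer, each cell's per-trial aversive response
$\bar z_k$ is normalized in two steps:

1. **Stimulus-type normalization.** Subtract, per aversive subtype, the mean
   over that subtype's 18 trials across the three epochs:
   $\Delta z_{k|\mathrm{type}} = \bar z_{k|\mathrm{type}} -
   \langle\bar z_{k|\mathrm{type}}\rangle$. The concatenated 108-trial series
   is independent of which stimulus was shown on each trial.
2. **Non-stationarity elimination.** A power function
   $f(j) = a\,j^{b} + c$ is fitted to the population mean of all
   trajectories, averaged across epochs onto the within-epoch aversive-trial
   index $j = 1..36$ ("averaged across epochs" implies a single 36-point
   curve; a global 108-point index is available by refitting on `k_av`).
   Each cell then loses a *single* scaled copy:
   $\Delta z^\mathrm{res}_k = \Delta z_k - d\,f(j)$, with $f$ tiled per
   epoch and one $d$ per cell shared across epochs so the epoch contrast —
   the scientific signal — is untouched.

The scalar $d$ is the OLS projection coefficient
$\mathrm{cov}(\Delta z, f)/\mathrm{var}(f)$: the residual's Pearson
correlation with the tiled decay is then exactly zero, which satisfies the
±0.05 requirement by construction rather than by tuning. The requirement
states a constraint, not a selection rule; OLS is the unique scale that
optimally satisfies it.

Numerically, the power fit profiles the SSE over the exponent $b$ (the model
is linear in $a, c$ for fixed $b$) on a grid over $[-3, 3]$, refines the best
bracket by 1-D optimization and polishes the triple with
Levenberg–Marquardt. Power-law fits are initialization-sensitive, and the
degenerate flat-population case ($a \approx 0$, $b$ unidentifiable) defeats
plain multi-start nonlinear least squares; the profile handles both.

## Correlation inference

Every cell's residual trajectory is Pearson-correlated with each of the 13
HGF parameter trajectories over the 108 aversive trials (missing guarded
values pairwise-dropped). p-values are pooled across cells *and* parameters
before Storey's q-value conversion (the per-parameter alternative is the
`pool` argument): the decision threshold q < 0.05 is shared across the whole
table, so pooling is the consistent default. The Storey implementation
estimates $\pi_0$ on a λ-grid with a cubic smoothing spline, evaluated at
the largest λ; below 100 p-values the spline is unstable and the estimator
falls back to the conservative $\pi_0 = 1$ (Benjamini–Hochberg). A fixed-λ
variant exists for verification against hand computation.

The polarity bias test permutes *each cell's trajectory independently across
trials* (10,000 repetitions by default), recomputing the full
correlation–significance pipeline per repetition, with the signed count of
positive- minus negative-significant cells as statistic. The permutation unit
was an open choice; permuting trials within cells preserves every cell's
marginal distribution and the parameter trajectories exactly while destroying
only the temporal alignment, which is the quantity under test. FDR across the
13 parameters uses Benjamini–Hochberg (Storey's $\pi_0$ estimate is not
meaningful at m = 13). Between-group comparisons of significant-cell counts
use Pearson's χ² without continuity correction, FDR-corrected across the
comparison family.

Several HGF parameters are strongly collinear (e.g. $\alpha_2 = \sigma_2$
enters $\mathrm{unc}_2$); the correlation table therefore carries the
13 × 13 parameter correlation matrix as an attribute, and coupling-recovery
claims should be read per level rather than per single parameter. No
decorrelation is applied — the procedure is deliberately univariate.

## Pupillometry

The long-axis pupil diameter is converted to area as
$A = \pi (D/2)^2 / \mathrm{calibration}$ (default $6 \times 10^3$ px² per
mm²); the long axis is invariant to eye position for a circular pupil on a
spherical eyeball. Evoked analysis normalizes each aversive trial by its
10-frame pre-onset baseline, averages the proportional change over trials
($a(t)$), time-averages over the 2-s outcome window ($\bar a$) and centers
across epochs ($\Delta a$, zero-sum). Trials missing more than 20% of
baseline or window frames are dropped — the handling of missing frames was
unspecified, and this conservative default is configurable. The session
median area is taken over all frames (rather than stimulus periods only;
also an undetermined detail, chosen once). Group statistics: Mann–Whitney on
per-animal median areas, two-way ANOVA Group × Epoch on $\Delta a$ (already
one value per animal and epoch, so no aggregation question arises), and
Tukey–Kramer pairwise epochs.

## Receptive fields

The checkerboard stimulus is a grid of 3.7° × 2.9° fields, each independently
modulated by binary white noise at 4 Hz; values are coded {0, 1} and
mean-subtracted at analysis time (the coding convention was unspecified; with
mean subtraction the two natural codings differ only by scale). The
response-weighted average over a 0.5-s trailing window at 16.7-ms bins gives
a space–time kernel; peak latency is the lag maximizing the spatially summed
absolute kernel; the spatial slice at that latency is fitted with an
elliptical 2-D Gaussian (nonlinear least squares, moment-based
initialization, sign-flipped if the dominant lobe is negative), and RF size
is twice the mean of the long- and short-axis SDs. Non-convergent fits are
flagged with a missing size rather than guessed.

The synthetic RF unit is linear–Gaussian: a spatially Gaussian-weighted,
temporally filtered function of the stimulus, optionally plus noise, and
deliberately *not* rectified — the noiseless linear unit makes recovery
errors attributable to the estimator alone (with a 10-min stimulus: center
error < 0.5 field, size error < 10% across random RFs).

## What the generator emulates — and what it does not

`simulate_recording()` produces deconvolved-activity-space data directly (the
analysis consumes that representation; no calcium-kernel forward model or
CNMF is simulated) with: stimulus-type-specific Gaussian temporal kernels
with randomized latency (emulating the timing spread that retinotopy imposes
on moving stimuli), per-epoch response multipliers per preset, a shared
power-law photobleaching decay $g(k) = a k^b + c$ over the presented trial
index, truncated-at-zero Gaussian trial-amplitude noise plus half-truncated
Gaussian frame shot noise, occasional platform excursions above the 0.25-mm
threshold (5% of trials), and — for a labeled cell subset — trial gain
linked to a standardized HGF parameter. The eight cohort presets encode the
qualitative sign patterns of the study groups (late-stable adaptation with
volatile recovery in wild-type colliculus; elevated volatile responses in
the mutant; flat profiles under corticotectal block and in retinal inputs),
with effect sizes chosen once as plausible, not fitted to any dataset.

Not emulated: imaging-frame pixel data, motion artifacts, neuropil
contamination, spike-to-fluorescence dynamics, correlated noise between
cells beyond the shared trial structure, eye movements, and any behavioral
feedback loop. Passing recovery tests on this generator therefore
demonstrates that the *analysis* is correct and calibrated under its own
assumptions — not that those assumptions exhaust real recordings.

## Problem sizes and reproducibility

Simulations in the test suite run at reduced but representative sizes chosen
by the package: the decay-constraint check uses the full 1000-cell cohort;
pattern-recovery cohorts use 4 mice × 40 cells (recovery) and 2 mice × 20
cells over 50 seeds (type-I control); the ANOVA calibration uses 200 seeds of
two identical flat cohorts (2 mice × 12 cells each) at the 15.5-Hz
acquisition rate; polarity-test calibration uses 100 null cohorts of 40
cells at 200 permutations; RF recovery uses 50 noiseless units on the
10-minute stimulus. Every stochastic step takes an explicit seed, and
`run_pipeline()` derives per-stage seeds from one master seed, so identical
configurations reproduce identical outputs.

```{r pipeline, eval = FALSE}
run <- run_pipeline(presets = c("WT_SC", "SCN2A_SC"), n_mice = 4,
                    n_cells = 100, seed = 1)
tidy(run$modulation_stats)          # Tukey-Kramer epoch contrasts per group
autoplot(run$cohorts$WT_SC$correlations)   # parameter-representation bubbles
```

## Known limitations

* The HGF is run as a forward ideal observer only; no inversion against
  behavior, and no response model mapping beliefs to actions.
* The univariate correlation procedure cannot attribute coupling to a single
  parameter within a collinear cluster; detections should be read per level.
* The mouse-aggregated group test trades power for calibration; with very few
  animals the Tukey contrasts have few denominator degrees of freedom.
* The generator's noise model is stationary within a session apart from the
  power-law decay; slow state changes (arousal drift) are not modeled, and
  pupil–neural coupling is absent.
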