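---
title: "Methods: spectral DCM for resting-state effective connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral DCM for resting-state effective connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`restdcm` infers directed (effective) connectivity between brain regions
from resting-state BOLD time series. The generative model has three layers.

**Neural dynamics.** Regional neural states $x(t)$ follow a linear
stochastic differential equation

$$\dot x = A x + v(t),$$

where $A$ (in Hz) is the effective-connectivity matrix: $A_{ij}$ is the
rate at which activity in region $j$ drives region $i$; diagonal entries
are self-inhibition, constrained negative, and the whole system must be
stable (all eigenvalues of $A$ in the left half-plane). The endogenous
fluctuations $v(t)$ are stationary with power-law spectra
$g_v(f) = \alpha_v f^{-\beta_v}$, the usual assumption for slow
resting-state dynamics.

**Haemodynamics.** Each region's neural state drives the balloon model: a
vasodilatory signal $s$, inflow $f$, venous volume $v$ and
deoxyhaemoglobin content $q$,

$$\dot s = x - \kappa s - \gamma(f - 1), \quad \dot f = s, \quad
\tau \dot v = f - v^{1/\alpha}, \quad
\tau \dot q = f \frac{1 - (1 - E_0)^{1/f}}{E_0} - v^{1/\alpha} \frac{q}{v},$$

with BOLD read-out
$y = V_0 (k_1 (1 - q) + k_2 (1 - q/v) + k_3 (1 - v))$.
The constants are the standard values $\kappa = 0.64\,s^{-1}$,
$\gamma = 0.32\,s^{-1}$, $\tau = 2\,s$, $\alpha = 0.32$, $E_0 = 0.4$,
$V_0 = 0.04$, $k_1 = 7E_0$, $k_2 = 2$, $k_3 = 2E_0 - 0.2$
(`default_hemo()`); the transit time $\tau$ is a free (log-scale)
parameter per region during inversion, the rest are fixed.

**Observation.** Measured spectra include power-law observation noise
$g_e(f) = \alpha_e f^{-\beta_e}$.

Because the model is linear in $x$ and the haemodynamic step is linearised
about its fixed point for inversion, the predicted cross-spectral density
(CSD) of the data has the closed form

$$S(f) = T(f)\, G_v(f)\, T(f)^{H} + G_e(f), \qquad
T(f) = \operatorname{diag}(K(f))\, (i 2\pi f I - A)^{-1},$$

where $K_r(f)$ is the transfer function of the balloon cascade linearised
at its fixed point (`hemo_transfer()`). Spectral DCM fits this prediction
to an empirical CSD estimate rather than to the time series themselves.

# Data features

Subject data enter as ROI time series (one column per region; the package
ships the six default-mode regions mPFC, PCC, LIPC, RIPC, LHIP, RHIP with
their MNI centres, `dmn_rois()`). `principal_eigenvariate()` summarises a
voxel sphere by its first singular variate; `residualize()` projects out
confounds; `dct_basis()` provides the discrete cosine set spanning
0.0078–0.1 Hz (400 functions for 1000 scans at TR 2 s) used to model
resting-state fluctuations at the GLM stage.

The empirical CSD is estimated either parametrically, from an OLS
multivariate autoregressive fit (`fit_mar()` + `csd_from_mar()`), or
nonparametrically by Welch averaging (`csd_welch()`). Published analyses
of this kind rarely state which estimator produced their spectra; both are
first-class here and cross-validated against each other in the test suite.

## Numerical choices that matter

* **Frequency grid.** 12 log-spaced points over 0.0078–0.1 Hz
  (`default_freq_grid()`). Two choices here are deliberate. The lower edge
  is the canonical resting-state band edge rather than the fundamental
  frequency 1/(N·TR): below ~0.008 Hz the MAR spectrum of a 1000-scan
  series is pure extrapolation, and because spectral power grows as
  $f^{-1}$ those points would otherwise dominate the likelihood (coupling
  recovery collapses from r ≈ 0.8 to r ≈ 0.3 if they are included). The
  grid is kept small because CSD values at neighbouring grid points are
  strongly dependent (the MAR fit has limited degrees of freedom); an
  over-dense grid double-counts evidence and biases model comparison
  toward richer models.
* **Inverse-power whitening.** The sampling variance of a spectral
  estimate scales with the square of its expectation, so the inversion
  weights each frequency by the inverse of its mean diagonal power before
  applying a single shared noise precision $e^\lambda$. The weights are a
  fixed function of the subject's data, identical across candidate
  models, so free-energy differences between models are unaffected.
* **MAR order.** `fit_mar()` defaults to the conventional p = 8; the
  analysis pipeline uses p = 12, which measurably reduces the smoothing
  bias that otherwise lets over-parameterised coupling patterns absorb
  systematic feature error in model comparison.

# Inversion: variational Laplace

`spdcm_invert()` maximises a free-energy bound $F$ on log model evidence
under a Gaussian (Laplace) posterior approximation:

* Parameters: free couplings (only those allowed by the model mask; masked
  couplings are removed from the parameter vector entirely), self-connection
  log-scales ($a_{ii} = -0.5 e^{\theta}$), per-region transit-time
  log-scales, shared log noise amplitudes and spectral exponents.
* Priors: couplings $N(0, 1/64)$ Hz; self and transit log-scales
  $N(0, 1/256)$; log amplitudes $N(0, 1/64)$ around data-calibrated
  reference values (80% endogenous / 20% observation share of the mean
  observed power); exponents $N(1, 1/64)$; log observation precision
  $\lambda \sim N(4, 1)$.
* Optimisation: damped Gauss–Newton steps on the parameters with
  Levenberg–Marquardt damping (×8 on rejection, ÷2 on acceptance) and a
  coarse line search along each step direction, alternating with guarded
  Newton updates of $\lambda$; a step is accepted only if $F$ increases,
  so the recorded trace is non-decreasing by construction. Convergence at
  $|\Delta F| < 0.01$ nats or 64 iterations. Jacobians are forward finite
  differences of the spectral prediction, computed in compiled code.
* $F$ is the standard Laplace quantity: log joint density at the posterior
  mode plus the Gaussian entropy correction, i.e. accuracy minus a
  complexity penalty that grows with the number of informed parameters.
  Absolute $F$ values are implementation-relative; only differences and
  ranks across models are used downstream.

When a whole model space is scored (`model_evidence_table()`), an optional
warm start fits the fully connected model once per subject and restarts
every candidate from its posterior projected onto the candidate's
parameterisation, keeping the better of cold- and warm-started solutions.
Constrained masks occasionally trap a cold start in a poor basin, deflating
that model's evidence by tens of nats; the warm start removes this at about
twice the cost and never lowers a model's recorded evidence.

# Model space

`base_families()` enumerates eight topologies over the four core DMN
nodes: the complete digraph (a), three driver-dominant variants in which
all connections *into* the driver set are removed (mPFC; PCC; the
bilateral parietal pair, which keeps its mutual pair), and the same four
without the LIPC–RIPC reciprocal pair (e–h). `inclusion_patterns()` wires
one additional (hippocampal) region into the base set in 12 ways —
reciprocal, disconnected, efferent-only, afferent-only, and
parietal/medial-specific mixtures. The cross product gives 96 five-node
models per hemisphere (`full_space()`); removing PCC collapses the base
families to six distinct topologies (c into a, g into e — the package
verifies this deduplication as a self-check) and yields the 72-model
reduced space (`reduced_space()`). `combine_best()` builds the six-node
model joining the best LHIP inclusion (afferents from the parietal pair,
efferents to all) with the best RHIP inclusion (fully reciprocal); both
inter-hippocampal directions are included a priori, so shrinkage rather
than structure decides the unsupported direction.

# Group inference

`ffx_bms()` performs fixed-effects Bayesian model selection (column sums
of $F$, softmax); `family_posteriors()` aggregates evidence over model
families by log-sum-exp with a member-count correction so large families
cannot win by size; `count_wins()` reports per-subject best models.
`bma()` averages couplings across models with per-subject posterior model
weights (optionally within an Occam window) and flags group-level
significance by one-sample t-tests, uncorrected and Bonferroni.
`bpa()` fuses single-subject posteriors for one model by precision
weighting, subtracting the $(S-1)$-fold over-counted prior.
`stability_matrix()` reports Pearson correlations between subjects'
evidence profiles. `lateralization_contrast()` runs paired t-tests of
LHIP→target versus RHIP→target couplings on the six-node model.
`fc_subject()`/`fc_group()` provide Fisher-z functional connectivity with
Benjamini–Hochberg control over the 15 unique region pairs.

# The synthetic-data generator

No reference dataset ships with the package; every inference stage is
exercised on synthetic groups with known ground truth:

* `random_couplings()` fills a model mask with magnitudes uniform in
  0.1–0.3 Hz (the scale of published group coupling tables), 20%
  inhibitory, self-inhibition −0.5 Hz, and requires a spectral abscissa
  below −0.15 Hz. The margin matters: near-unstable draws amplify latent
  fluctuations beyond the balloon model's physiological regime.
  `dmn_couplings()` instead fills the mask with published group-mean
  estimates for the DMN region sets, giving a ground truth on the
  empirically observed scale and sign pattern (including the strong
  0.44 Hz left-to-right inter-hippocampal coupling in the six-node model).
* `make_group_truth()` jitters the free couplings per subject
  (SD 0.05 Hz by default) and re-checks stability.
* `simulate_bold()` synthesises power-law fluctuations in the frequency
  domain (exact for the spectral family the inversion assumes), integrates
  the neural and balloon equations by fixed-step Euler (dt = 0.125 s,
  64 s burn-in), samples at TR and adds power-law observation noise. The
  positive haemodynamic states are integrated in log space with a
  $|\log z| \le 4$ guard: sustained neural drive below $-\gamma$ would
  otherwise push the flow equilibrium negative. The default endogenous
  amplitude ($\alpha_v = 10^{-5}$, pink) keeps latent excursions inside
  that regime, giving latent SD ≈ 0.05–0.1 and BOLD fluctuations of a few
  percent of baseline; the default observation noise
  ($\alpha_e = 1.5 \times 10^{-6}$, pink) is ~0.4% of baseline, so
  per-region SNR (mean/SD of the raw series) is of order 25–60 — far
  above the floor of 2.4 reported for real acquisitions of this kind.
* The default group emulates a typical resting-state cohort for this
  design: 26 subjects × 1000 scans at TR 2 s over the six DMN regions.

What the generator does *not* emulate: head motion, physiological
confounds, scanner drift beyond the power-law term, spatial smoothing,
inter-regional haemodynamic variability beyond transit time, or nonlinear
neural interactions. Passing recovery tests on these data therefore
demonstrates correctness of the estimation machinery under the model's
own assumptions, not robustness to the full mess of real fMRI.

# Problem sizes in the tests and acceptance script

Single inversions use 1000-scan subjects (a standard long resting-state
acquisition at TR 2 s).
Batch bookkeeping over the 96- and 72-model spaces runs with iteration-
capped inversions, which preserves the combinatorial structure being
checked. Recovery and identification experiments use 4–8 subjects per
group and 10 seeded replicates; functional-connectivity calibration uses
26 subjects × 1000 scans and 400–1000 replicates for the FDR property.
These sizes were chosen so the full suite completes comfortably on one
CPU while leaving the statistical conclusions stable across seeds.

# Known limitations

* Absolute free energies are not comparable across packages or feature
  choices; only within-subject model comparisons are meaningful.
* The forward simulator and the inversion share the same structural model
  family; tests quantify estimation error, not model misspecification on
  real data.
* BPA can behave counterintuitively at high SNR because it trusts the
  posterior covariance structure; the package reports both BMA and BPA and
  the tests assert only BPA's algebraic properties.
* FFX BMS assumes every subject expresses the same model; no
  random-effects BMS is provided.
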