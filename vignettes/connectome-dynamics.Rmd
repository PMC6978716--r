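---
title: "Connectome-constrained neural mass dynamics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-constrained neural mass dynamics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`corticodyn` simulates whole-brain resting-state activity with a
Larter-Breakspear neural mass model coupled through a structural connectome,
and evaluates how well a parameter point reproduces two empirical summaries
observed at very different time scales: slow BOLD co-fluctuation
(resting-state functional connectivity, rsFC) and fast EEG topography
switching (microstates). This vignette is the package's own account of the
models it implements, the tunable parameters that matter, the numerical
choices, and what the synthetic data generators do and do not emulate.

## The neural mass model

Each cortical region is described by three state variables: the mean
excitatory membrane potential $V$, the mean inhibitory membrane potential
$Z$, and the fraction of open potassium channels $W$ (all in dimensionless
model units). Voltage-gated calcium, sodium and potassium channels open
according to sigmoid gating curves
$m_{ion} = \tfrac12\!\left(1 + \tanh\frac{V - T_{ion}}{\delta_{ion}}\right)$,
and population firing rates follow the same sigmoid form with maximum rates
$Q_V^{max}, Q_Z^{max}$. The excitatory equation balances calcium, potassium,
sodium and leak currents, local recurrent excitation, inhibitory feedback
and a constant subcortical drive $I$; the inhibitory population integrates
slowly (time scale factor `b_time = 0.1`); the potassium gate relaxes as
$\dot W = \phi\,(m_K - W)/\tau_K$.

Two parameters are swept; everything else keeps its standard published
value (see `neural_mass_params()`):

* **Global coupling `C`** $\in [0,1]$ mixes local excitatory feedback with
  the connectivity-weighted mean firing rate of the other regions,
  $\langle Q_V \rangle_i = \sum_j u_{ij} Q_{V_j} / \sum_j u_{ij}$, a convex
  combination of the neighbours' rates.
* **Threshold variance `delta_V`** (the inverse gain of the firing
  sigmoid); the inhibitory threshold variance `delta_Z` is tied to it, and
  the sweep range of interest is roughly $[0.55, 0.75]$.

Two readings of the potassium relaxation equation circulate because the
equation is typeset ambiguously in parts of the literature; with
$\tau_K = 1$ they differ only by the placement of $\phi$. The package
implements the standard relaxation form $\dot W = \phi (m_K - W)/\tau_K$
(see the comment in `lb_rhs()`).

One model time unit is interpreted as **1 millisecond**. This makes the
model's fast oscillation land in the physiological EEG range and makes the
10-15 Hz analysis band meaningful. Simulated trajectories are emitted at
1000 Hz by default, matching the sampling rate from which EEG is
conventionally decimated to 100 Hz.

**Initial states.** Repeated simulations with "different initial values"
need a concrete distribution: `random_initial_state()` draws
$V, Z \sim U(-0.1, 0.1)$ and $W \sim U(0.3, 0.4)$ per region — membrane
potentials in a small neighbourhood of rest, the gating variable near its
operating range. Every simulation is reproducible from its seed.

**Subcortical input noise.** The random modulation of the subcortical input
defaults to 0 (constant $I$), so simulations are deterministic. A non-zero
`delta_subcortical` adds a seeded per-region constant perturbation of that
scale; fluctuating input noise is intentionally out of scope.

## Numerical integration

The solver is deSolve's Bogacki-Shampine embedded Runge-Kutta 2(3) pair
(`rk23bs`) — the same method family as MATLAB's `ode23`, which chooses its
own step size under error control. Defaults are `rtol = 1e-3`,
`atol = 1e-6`, both configurable. Two facts matter for interpretation:

* The coupled system is **sensitive to initial conditions** in parts of the
  parameter plane. At production tolerances the *trajectory* therefore
  accumulates phase error relative to the exact solution; the *statistics*
  (FC, PLV, microstate structure) are the meaningful output, which is
  standard practice for chaotic whole-brain models.
* Integrator correctness is checked against an independently coded
  fixed-step RK4 oracle at $dt = 10^{-4}$ s in the test suite, in a regular
  (periodic) regime and at tight tolerances (`rtol = 1e-10`), where
  trajectory-level agreement (RMS $< 10^{-3}$ over 1 s) is a meaningful
  criterion.

A solver failure (non-finite state, step underflow) raises an error that
names the parameter point; the sweep records such repeats as missing and
continues.

## Hemodynamics and the rsFC branch

The neuronal drive of the Balloon-Windkessel model is the absolute value of
the time derivative of the excitatory membrane potential, $z = |\dot V|$
(units: model units per second, by central finite differences). The four
hemodynamic states per region — vasodilatory signal $s$, inflow $f$, blood
volume $v$, deoxyhemoglobin $q$ — follow the canonical equations with
$\kappa = 0.65\,\mathrm{s^{-1}}$, $\tau = 0.98$ s, $\alpha = 0.32$,
$\rho = 0.34$, $V_0 = 0.02$. The flow-induction rate $\gamma$ is not part
of that printed set; the canonical value $\gamma = 0.41\,\mathrm{s^{-1}}$
from the standard hemodynamic-model literature is adopted and is
configurable. The readout
$y = V_0\,(7\rho(1-q) + 2(1 - q/v) + (2\rho - 0.2)(1 - v))$ is exactly zero
at the resting fixed point $(s,f,v,q) = (0,1,1,1)$, which is preserved under
zero drive. Integration starts at that fixed point and uses the same
adaptive RK 2(3) scheme (with a step-size cap so that rapidly fluctuating
drive is never stepped over).

BOLD is emitted at 0.4 Hz by default — the repetition time of 2.5 s typical
of resting-state fMRI — and then: optional zero-phase Butterworth band-pass
0.008-0.1 Hz (`bandpass_bold()`), global-signal regression by least squares
with intercept (`regress_global()`), Pearson correlation at zero lag
(`compute_fc()`). The similarity between two FC matrices is the Pearson
correlation of their strictly-lower-triangle entries (`fc_similarity()`);
the phrase "averaging the cross-correlation coefficients of the lower
triangular components" is read as this correlation-of-triangles score, the
convention of the FC-fitting literature — a literal mean of elementwise
products would not be scale-free.

Only the global regressor is applied to simulated BOLD: white-matter and
CSF regressors belong to the empirical preprocessing pipeline and have no
simulated counterpart.

## The EEG branch

Membrane potentials are projected to channel space by a region-resolution
lead field, `data = gain %*% V` (`project_sources()`), then common-average
referenced, band-pass filtered 10-15 Hz (zero phase), and decimated to
100 Hz with an anti-alias low-pass — exactly in that order
(`preprocess_simulated_eeg()`).

**Lead-field reduction.** A dense channels-by-sources gain is reduced to one
column per region by `reduce_leadfield()`: per ROI, an SVD of the ROI block,
keeping the leading components whose *cumulative singular-value sum* first
reaches `energy_fraction` (default 0.8), reconstructing the block and
averaging its columns. "Accumulation of singular values" is taken literally
(not squared singular values); with a rank-1 block or `energy_fraction = 1`
the reduction is exactly the plain column mean, and for spatially smooth
lead fields the two correlate above 0.99, so the interpretation is
inconsequential — which the reduction-fidelity test makes explicit.

## Microstates

`fit_microstates()` implements the basic N-microstate algorithm (modified,
polarity-invariant k-means) on unit-normalised topographies at GFP local
maxima:

1. GFP is the per-sample across-channel population standard deviation;
   peaks are strict interior local maxima (plateaus yield their first
   sample).
2. k-means++ initialisation with squared-correlation distance
   $1 - r^2$, so initial templates are probabilistically spread.
3. Alternating assignment (each peak map to the template with maximal
   squared spatial correlation — sign-free) and template update (the
   principal eigenvector of the assigned maps' outer-product sum, via SVD).
4. Convergence when the explained variance changes by less than
   $\epsilon = 10^{-6}$ (relative); best of `n_restarts = 20` seeded
   restarts; a cluster that loses all members is reseeded from the
   worst-explained peak.
5. Templates with mutual $|r| \ge 0.9$ describe the same state: the fit is
   rerun with $K-1$ classes until no pair exceeds the threshold.

`segment_smooth()` assigns every sample by the segmentation-smoothing
iteration: starting from the per-sample argmax of squared correlation,
labels minimise the noise-normalised squared residual
$(x_t^\top x_t - a_{kt}^2) / (2e(N_s - 1))$ minus
$\lambda\,N_{bkt}$, the count of same-label neighbours within $\pm b$
samples, with $b = 3$, $\lambda = 5$, $\epsilon = 10^{-6}$, and $e$ the
current mean residual noise variance. With $\lambda = 0$ the labelling is
exactly the unsmoothed argmax. The penalty deliberately suppresses
one-sample segments; consequently it lengthens mean dwell times relative to
a memoryless generator, which is why parameter-recovery checks against the
geometric ground-truth process use the unsmoothed labelling.

Statistics (`microstate_stats()`): occupation ratio (assigned samples per
state over all assigned samples); **mean transition time**, implemented as
the mean contiguous run length per state in ms — the dwell-time reading of
"time required to transition from one microstate to another", consistent
with empirical values near 100 ms; the run-to-run transition probability
matrix (rows of never-exited states are `NA`, visited rows sum to 1); and
GEV, the GFP²-weighted mean squared spatial correlation between each sample
and its assigned template. GEV is computed over **all** assigned samples by
default (a GFP-peaks-only variant sits behind `peaks_only = TRUE`).
Unassigned samples are representable (`NA` labels) but nothing is excluded
by default.

`match_microstates()` scores two models by exhaustively enumerating all
one-to-one assignments (exact for $K \le 6$), each scored by the mean
*absolute* spatial correlation of matched pairs — microstates are defined up
to polarity, so signed correlation would be ill-posed — with unmatched
states of the larger model contributing zero. When merging reduces a model
below four states, the missing-state-scores-zero rule applies unchanged.

## Synthetic data: what it emulates, what it does not

No empirical MRI/EEG inputs ship with the package, so `synthetic_data`
generators stand in for them. They are first-class, tested code.

* **Connectome** (`generate_connectome()`): symmetric, zero-diagonal,
  non-negative; edges present with probability `edge_density = 0.3`
  (non-homotopic pairs); log-normal weights, `sdlog = 1.5`. Tractography
  weight distributions are heavy-tailed over orders of magnitude, and at
  desk scale this heavy tail is also what keeps the coupled dynamics from
  collapsing into complete synchrony while preserving the qualitative
  regime contrast (globally synchronised at weak coupling/high gain,
  connectivity-structured at strong coupling/low gain). Homotopic pairs
  $(i, i+n/2)$ are always connected and scaled by
  `interhemispheric_scale = 2`, emulating the stronger interhemispheric
  connectivity of empirical matrices. `shuffle_connectome()` permutes the
  upper-triangle weights for the null control, preserving the weight
  multiset exactly.
* **Lead field** (`generate_leadfield()`): channels on a unit ring, ROI
  centres on an annulus (cortical patches lie near the scalp), sources
  jittered around their centre, gain = exponential spatial kernel
  $\exp(-d/\ell)$. The exponential (Matern-1/2) kernel is a deliberate
  choice over a squared-exponential: its slowly decaying spectrum keeps the
  gain matrix at full numerical row rank at realistic channel counts.
  Within-ROI columns are strongly correlated; `smoothness` controls the
  correlation length.
* **Ground-truth EEG** (`generate_microstate_eeg()`): a Markov dwell
  process over $K$ unit-norm average-referenced templates — geometric dwell
  with the requested mean, uniform switching to a *different* state, random
  per-segment polarity (states are sign-free), and a positive amplitude
  envelope built from rectified smoothed Gaussian noise so GFP has genuine
  local maxima. Channel noise is scaled to the requested RMS
  signal-to-noise ratio. Labels are returned, so recovery is measurable.

Not emulated: tractography and its biases, realistic volume conduction
(three-layer BEM), sensor noise spectra, ocular/cardiac artifacts, regional
parameter heterogeneity, conduction delays. Passing tests therefore show
that the *pipeline* is correct and self-consistent under known ground
truth — not that the model fits any particular empirical recording.

## Study sizes and degenerate regimes

The package's own end-to-end checks run at a desk scale chosen once
(`desk_sweep_config()`): 8 regions, 32 channels, 160 sources, 60 s
simulations with a 10 s transient, 2 repeats per grid point, BOLD at 2 Hz
with the slow band-pass disabled — 60 s cannot resolve 0.008 Hz — and a
2-by-2 grid bracketing the two regimes of interest, with targets generated
from a reference run with the intact connectome. Paper-scale settings
(78 regions, 63 channels, 600 s, 10 repeats, TR 2.5 s, full band-pass,
dense grids) are the function defaults and are documented throughout; they
are simply long-running.

At desk scale the coupled system is multistable: some initial states fall
into a fully synchronised attractor. Such runs yield rank-one EEG and BOLD
whose global-signal residuals carry no information; `compute_fc()` flags
the zero-variance regions and the FC similarity is undefined (`NA`). The
sweep aggregates with `na.rm`; in paired intact-versus-shuffled
comparisons an undefined similarity is scored as uninformative — it cannot
beat a defined one — and numeric summaries report it as zero similarity.
The reference run that generates scoring targets stands in for structured
empirical data, so a fully synchronised reference realisation is rejected
and the next connectome seed drawn. This mirrors the scientific reading:
dynamics that have lost all regional differentiation do not reproduce
structured rsFC.

## Known limitations

* Trajectories at production tolerances are statistically, not pathwise,
  accurate (see above).
* The segmentation smoother inflates dwell times by design; empirical
  comparisons should use identical smoothing settings on both sides.
* `match_microstates()` is exact but factorial; it is capped at $K \le 6$.
* The synthetic connectome is a stand-in: its weight distribution is a
  modelling choice, not an empirical claim.
* Process-level parallelism is left to the caller; `run_sweep()` evaluates
  grid points sequentially and is order-independent by construction.
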