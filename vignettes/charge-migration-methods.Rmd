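---
title: "Models and numerical methods in chargemig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in chargemig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When an extreme-ultraviolet (XUV) attosecond pulse suddenly removes an
inner-valence electron from a molecule such as adenine, the remaining
electrons are left in a correlated, non-stationary state. One relaxation
pathway is *shake-up*: the inner-valence hole is refilled by a valence
electron while, through the two-body Coulomb interaction, a second electron
is promoted to a bound excited orbital. If a delayed near-infrared (NIR)
pulse then removes that excited electron, an intact doubly charged parent
ion appears — and its yield as a function of pump–probe delay clocks the
shake-up process. `chargemig` implements, at desk scale, the full analysis
chain of such an experiment: synthetic delay-resolved ion data, kinetic
curve fitting, golden-rule rate estimation on few-orbital model molecules,
and many-body density-matrix propagation with an NIR depletion observable.

Nothing in this package attempts ab-initio adenine. The few-orbital model
molecules are *designed stand-ins* whose parameters are calibrated against
two experimentally anchored numbers: the characteristic shake-up time of
one special state (2.5 fs) and the number of NIR photons needed to ionise
it (two). Everything downstream — rates, dynamics, depletion — is computed,
not asserted.

## The experiment arm

### Curve models

Ion yields versus pump–probe delay are described by two rate-equation
solutions:

* **Step-decay (model A)** — a population created directly at time zero
  that decays exponentially:
  $y(t) = y_0 + A\,H(t-t_0)\,e^{-(t-t_0)/\tau_1}$.
  This describes the fragment cations.
* **Rise-decay (model B)** — opposing rates: a population that starts at
  zero, rises with lifetime $\tau_1$ and decays with the slower lifetime
  $\tau_2$:
  $y(t) = y_0 + A\,\frac{\tau_2}{\tau_2-\tau_1}\,H(s)\left(e^{-s/\tau_2} -
  e^{-s/\tau_1}\right)$, $s = t-t_0$.
  This describes the intact dication, whose risetime is the shake-up clock.

Both are convolved analytically with a Gaussian instrument response of
standard deviation $\sigma_{\mathrm{IRF}}$ (the pump–probe intensity
cross-correlation; for a 0.3 fs pump and 4 fs probe,
$\mathrm{FWHM}_{cc} = \sqrt{0.3^2 + 4^2} \approx 4.01$ fs). The convolution
is the exponentially modified Gaussian closed form, evaluated entirely in
log space,
$\mathrm{emg}(s) = \exp\!\big(\sigma^2/2\tau^2 - s/\tau +
\log\Phi(s/\sigma - \sigma/\tau)\big)$,
which is finite for arbitrarily large arguments (the textbook
$\tfrac12 e^{\sigma^2/2\tau^2 - s/\tau}\,\mathrm{erfc}(\cdot)$ form
overflows far before the Gaussian factor can rescue it). Brute-force
numerical convolution is retained only as a test oracle.

The unconvolved rise-decay curve peaks at
$t_0 + \tau_1\tau_2\ln(\tau_2/\tau_1)/(\tau_2-\tau_1)$ — about 6.0 fs for
$\tau_1 = 2.32$ fs, $\tau_2 = 24$ fs — which the tests verify against a
numerical maximiser.

### Fitting

`fit_ion_trace()` minimises the (SEM-weighted) sum of squares with the
lifetime ordering enforced smoothly by the reparameterisation
$\tau_2 = \tau_1 + e^{\vartheta}$; $\tau_1 = e^{\vartheta'}$ keeps both
positive. The optimiser is a Nelder–Mead / BFGS / Nelder–Mead cascade at
tight tolerances; noiseless traces are recovered to five decimal places.
68% confidence intervals come from a seeded residual-resampling bootstrap
(percentile method, 500 replicates by default). Residual resampling rather
than a parametric bootstrap because the synthetic noise is homoscedastic by
construction but real traces need not be.

Whether the original analysis fixed the time zero per channel or shared it
is not recorded; both modes are supported. The packaged pipeline anchors
$t_0$ by fitting the step-decay model (free $t_0$) to a prompt fragment
channel and then fixes that $t_0$ in the dication fit — the same logic as
anchoring time zero with a rare-gas double-ionisation reference. The
error-function step fit of `find_time_zero()` is provided for such
reference channels.

### Synthetic data

`simulate_pumpprobe_dataset()` evaluates each channel's response model on a
delay grid (default $-20$ to $60$ fs in 1 fs steps, covering both dication
time constants; the original grid is not recorded) and adds i.i.d. Gaussian
noise per scan and delay point, with standard deviation `noise_sigma`
(default 5%) times the channel's peak model yield. Seven scans are
simulated by default, so the scan-averaged SEM is
$\approx 0.05/\sqrt{7} \approx 1.9\%$ — chosen as a plausible match to the
published error bands, since the raw data are not deposited. The default
channels are: positive steps with slow (150–300 fs) decays at m/z 27, 38
and 53 u/e, a negative step at 108 u/e, and the rise-decay dication at
67.5 u/e with $\tau_1 = 2.32$ fs and $\tau_2 = 24$ fs — i.e. the generator
plants the reported values and the analysis chain must recover them.

What a green recovery test establishes: that the estimator is essentially
unbiased at the stated noise level. What it does not establish: anything
about real detector physics (saturation, correlated noise, drifting
overlap), which the generator deliberately omits.

Time-of-flight spectra are simulated with the standard law
$t = k\sqrt{m/z} + t_0$ and Gaussian peaks whose areas are the channel
yields; the 0.25 u/e half-width of the extraction window resolves the
half-integer dication mass from its integer neighbours. Calibration is a
linear fit in $\sqrt{m/z}$; the integration-window width of the original
instrument is not recorded, so 0.25 u/e is a configurable default.

### Photon counting

The dication yield's NIR-intensity dependence is summarised by the slope of
$\log y$ on $\log I$ over the explored $7\times10^{12}$–$1.4\times10^{13}$
W/cm² range; the rounded slope is the photon number (two for the intact
dication).

## The theory arm

### Model molecules

A `model_molecule` is a few-orbital electronic structure in a
spin-restricted basis: spatial orbital energies (eV), a real 4-index
two-electron table $\langle pq|v|rs\rangle$ (physicist convention, 8-fold
permutational symmetry), dipole elements (a.u.), a designated inner-valence
hole $h^\*$, a designated special virtual $a^\*$, XUV hole weights, and a
global coupling scale $\lambda$.

`make_adenine_like_molecule()` generates the packaged stand-in (defaults: 5
occupied + 3 virtual spatial orbitals, seed 1). Its design choices, all of
which are the generator's *stated world*:

* **One deep hole.** A single inner-valence orbital near $-20$ eV carries
  the full XUV weight, so the statistical golden-rule sum and the
  sudden-hole dynamics describe the same initial condition. (The ab-initio
  weights of the original study live in unpublished supplementary
  material; a uniform distribution over the inner-valence set — here one
  orbital — is the declared default.)
* **An engineered resonance band.** Shake-up conserves energy at Koopmans
  level when $\varepsilon_i + \varepsilon_j = \varepsilon_h +
  \varepsilon_a$. Three quasi-degenerate deep-valence orbitals near
  $(\varepsilon_h + \varepsilon_{a^\*})/2$ give the special state a small
  dense band of final two-hole configurations — irreversible,
  golden-rule-like decay rather than a two-level recurrence. Their fixed
  offsets (−0.4, −0.1, +0.3 eV on the pair sums) tile the Lorentzian
  broadening instead of clustering at exact resonance, which would make
  the broadened rate sum overestimate the dynamical decay.
* **Resonant non-special virtuals.** The remaining virtuals sit on
  (deep, shallow) valence-pair resonances, so every virtual has open
  channels for every seed; their couplings are not damped, so after
  calibration they relax several times faster than the special state
  (sub-femtosecond, emulating the few-hundred-attosecond typical values).
* **Scattering-only interactions.** Every two-electron element with a
  repeated orbital index is suppressed (factor 0.1). These elements carry
  the static Hartree/exchange shifts and density-coupled one-body terms,
  which a semi-empirical model should regard as already absorbed in its
  effective orbital energies; keeping them at full strength would detune
  the engineered Koopmans resonances by $\sim$1 eV in the interacting
  dynamics. The damped class is closed under the 8-fold symmetry group and
  disjoint from the all-distinct-index shake-up matrix elements.
* **Calibration.** $\lambda$ is adjusted so the golden-rule characteristic
  time of $a^\*$ equals 2.5 fs (bisection, then an exact polish using
  $\Gamma \propto \lambda^2$, which makes calibration idempotent to
  machine precision). The special state's binding energy (3.0 eV by
  default) lies strictly inside the two-NIR-photon window
  $(1.77, 3.54]$ eV.

### Golden-rule rates

For hole $h$ and virtual $a$,

$$\Gamma_{h\to a} = \frac{2\pi}{\hbar} \sum_{i<j}
\left|\langle h a|v|i j\rangle - \langle h a|v|j i\rangle\right|^2\,
\delta_\eta(\varepsilon_i + \varepsilon_j - \varepsilon_h - \varepsilon_a),$$

summed over distinct occupied spin-orbital pairs of the cation and the
promoted electron's spin, with a Lorentzian $\delta_\eta$ of half-width
$\eta$ (default 0.2 eV; the original lineshape and width are not recorded,
and the default is exposed and swept in the tests). Koopmans energies are
used in the energy balance — the simplest defensible reading, and the
generator's integral damping is what keeps that reading accurate.
Hole channels are statistically summed with the molecule's hole weights;
the characteristic time is the inverse total rate. Matrix elements follow
Slater–Condon rules with canonical-ordering phases, validated element by
element against an independent brute-force second-quantised oracle.

The implementation is validated dynamically in the regime where the
broadened golden rule is *exact*: weak coupling into final states that
carry a genuine Lorentzian width. The test fixture gives the special state
an absorbing width $\gamma = 2\eta$ and compares $\Gamma$ with the decay
rate of the many-body survival probability (the squared norm,
$N(t)/N(0)$) in exact-CI propagation, after the fast-pole transient and
with couplings weak enough that the overlapping-resonance correction
$\big(1-\sqrt{1-4V^2/\eta^2}\big)\eta/(2V^2/\eta)$ stays within a few
percent. A bound few-channel toy would instead sit in the quadratic,
pre-golden-rule regime, where no 20% agreement should be expected — that
physics, not implementation error, is why the validity window matters.

### Many-body propagation

Three propagators share one state representation (complex spin-block
density matrices in the molecule's orbital basis; Hartree atomic units
internally, fs/eV at the interfaces):

* **Mean field** — $\dot\rho = -i[h_{\mathrm{HF}}(t), \rho]$ with the full
  Hartree + exchange potential and dipole coupling, stepped by an
  exponential midpoint predictor–corrector (exactly unitary per step
  without absorbers, so particle number is conserved to integrator
  precision).
* **GKBA second Born** — adds the collision integral
  $I(t) = \int_{t-t_c}^{t} ds\,[\Sigma^>(t,s)G^<(s,t) -
  \Sigma^<(t,s)G^>(s,t)]$ with lesser/greater functions reconstructed from
  $\rho$ through the Generalised Kadanoff–Baym Ansatz with mean-field
  propagators, and the second-Born (direct + exchange) self-energy. The
  index convention is fixed in code and validated against exact CI on the
  Hubbard dimer (interaction quench at half filling, where the mean field
  is inert and *all* dynamics comes from the collision integral) and on
  shake-up toys. The memory integral uses trapezoidal quadrature on the
  propagation grid with a configurable history cutoff; a
  `collision_stride` option refreshes the integral every few steps for
  long scans. The compiled (RcppArmadillo) engine mirrors the R reference
  implementation step for step and is asserted equal to it at 1e-12.
* **Exact CI** — full propagation in a fixed particle-number determinant
  basis (at most $2^{10}$ determinants), by exact exponentials; the
  validation oracle.

Numerical stability deserves an honest note: at the packaged molecule's
calibrated coupling, HF-GKBA positivity violations grow secularly and the
propagation eventually diverges on long horizons. The packaged depletion
settings (dt 0.02 fs, memory cutoff 1.0 fs, stride 2) are chosen inside
the stable domain up to the 13 fs the depletion scan needs; the short
memory window also damps the instability. The price is a quantitative one:
with a truncated memory the correlation-induced feeding of the special
state is slower than the golden-rule rate (the kernel window is shorter
than $\hbar/\eta \approx 3.3$ fs). The transfer also has an S-shaped onset
from the collision-memory buildup, which makes a free two-parameter
exponential fit of the rise unidentifiable; the robust equivalent
timescale — the half-rise time towards the saturation plateau divided by
$\ln 2$ — agrees with the 2.5 fs golden-rule time within a factor of two,
and the depletion onset shifts late rather than early, conservative for
the onset bound the acceptance criterion checks.

### NIR ionisation surrogate and the depletion observable

The ionisation continuum is replaced by a quasi-continuum: one bridge level
one probe photon above $a^\*$ (so reaching the continuum from $a^\*$ takes
two NIR photons, matching the observed quadratic intensity scaling) and six
equally spaced absorbing levels from the ionisation threshold upward, each
with a diagonal width $-i\gamma/2$ ($\gamma = 0.5$ eV) so the
photo-electron leaves irreversibly. The added orbitals carry no
two-electron integrals — they are a one-body readout channel, which also
keeps the collision integral confined to the interacting sub-block.

`depletion_vs_delay()` runs, for each delay, the sudden-hole GKBA dynamics
with and without the NIR pulse centred at that delay, and reports the mean
population difference of $a^\*$ over a 1 fs window starting when the NIR
envelope ends. The definition as a difference against the NIR-free run is
declared, not asserted as the original one (an absolute-drop readout is
equally defensible). The attosecond pump is treated as sudden hole
creation; a finite pump can be emulated by birth-time averaging, which by
time-translation invariance is a convolution of the depletion curve with
the normalised pump intensity envelope (`birth_samples > 1`). The default
is a single birth time: a sub-300-as pump is effectively sudden on the
2.5 fs shake-up scale.

The summary statistic mirrors the experimental one: the earliest delay at
which the depletion exceeds half its 8 fs value, compared against the lower
edge of the reported 2–4 fs onset window as a one-sided bound.

## Out-of-plane density

`out_of_plane_density()` integrates
$Q(t) = \sum_k n_k(t) \int_{|d(\mathbf r)| > d_0} |\phi_k(\mathbf r)|^2\,dV$
with $d$ the signed distance to the molecular plane and both half-spaces
included (the published wording does not specify one-sided integration;
both-sided is declared here). Orbitals live on regular grids with Gaussian
cube I/O — the standard Bohr dialect on write, with the negative-voxel-count
Angstrom dialect honoured on read. Voxel membership is decided by the voxel
centre, with no partial-voxel weighting; the tests check sub-percent
stability under grid refinement and the closed-form
$\mathrm{erfc}(d_0/\sigma\sqrt2)$ fraction for Gaussian fixtures. The plane
defaults to the smallest principal axis of supplied atom coordinates.

## Tolerances and degenerate inputs

* Exact-multiple photon groups resolve to the *lower* group within 1e-9 eV.
* `fit_ion_trace()` refuses traces with fewer than twice as many points as
  free parameters; flat references raise a no-step error rather than a
  garbage time zero.
* Zero-intensity probes yield identically zero depletion; delays whose
  readout window precedes the hole's creation report zero.
* Single-scan averages set the undefined SEM to zero with a warning.
* GKBA occupations outside $[-0.05, 1.05]$ raise an ansatz-breakdown
  warning; non-finite propagation aborts with an error rather than
  returning numbers.

## Known limitations

* No nuclear motion and no non-adiabatic relaxation anywhere in the theory
  arm: the 24 fs decay of the dication signal is a *fitted* quantity of the
  experiment arm only, with no mechanistic model behind it (deliberately —
  the reference ab-initio treatment cannot reproduce it either, for the
  same reason).
* Auger decay is neglected, consistent with the moderate XUV energy range.
* HF-GKBA at the calibrated coupling is quantitatively soft: memory
  truncation slows correlation transfer, and positivity violations bound
  the usable horizon. The depletion observable is therefore read as a
  trend and an onset bound, not as absolute populations.
* The model molecules are calibrated, not derived: any agreement beyond
  the two anchored observables (2.5 fs, two photons) is structural, not
  predictive.
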