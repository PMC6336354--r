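---
title: "Quantifying transient helices: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transient helices: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrhelix)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters with their defaults
and units, what the synthetic-data generators do and do not emulate, and
the numerical choices made where the design was genuinely open.

## Secondary structure propensity from chemical shifts

Backbone chemical shifts deviate from their residue-type random-coil
values in a structure-dependent way. For a residue sampling a helix with
population $p$ and coil otherwise, the observed secondary shift of each
nucleus is, to first order, $\Delta\delta_{obs} = p\,\Delta\delta_\alpha$,
where $\Delta\delta_\alpha$ is the full-helix endpoint for that residue
type and nucleus. The SSP score combines the five backbone nuclei
(¹H^N, ¹⁵N, ¹³CO, ¹³CA, ¹³CB) into one residue-specific number:

- each secondary shift is projected onto the helix direction
  ($s = \mathrm{sign}(\Delta\delta_\alpha)\,\Delta\delta_{obs}$) and
  normalized by the full-helix endpoint when it points helix-ward, by the
  full-sheet endpoint otherwise;
- normalized propensities are averaged over a sliding window of $W$
  residues (default $W = 5$, odd, truncated at chain ends) and over all
  nuclei present, weighted by the squared magnitude of the relevant
  reference secondary shift, so nuclei that move more per unit structure
  count more;
- the result is $+1$ for a fully formed helix, $-1$ for a fully formed
  sheet, $0$ for coil, and — under the two-state assumption — equals the
  helical population in between. Scores with magnitude above 1.5 are
  flagged as implausible rather than clipped.

Re-referencing (`rereference = "on"`, the default) estimates a constant
chemical-shift referencing error in the carbon dimension as the
10%-trimmed mean of the raw CA and CB secondary shifts over the whole
chain and subtracts it. The trimmed mean is robust to the minority of
residues with genuine helical signal (two short helical segments in a
~140-residue chain perturb well under 20% of residues); other nuclei are
left untouched. This is a defined SSP *variant*: the endpoint and
linearity semantics above are its contract, and per-residue parity with
any external SSP implementation is not promised. Neighbor-residue
corrections to the random-coil values are deliberately omitted; the
shipped reference library uses standard published random-coil values with
per-nucleus consensus helix/sheet endpoints.

```{r ssp-demo}
chain <- paste(rep("AKLSEDVRQM", 4), collapse = "")
tb <- gen_idr_shifts(chain, rep(0.2, 40), noise_sd_ppm = 0, seed = 1)
prof <- ssp_profile(secondary_shifts(tb, chain, rereference = "off"))
range(prof$score)
```

## ¹⁵N relaxation

R₁ and R₁ρ intensity decays are fit per residue as
$I(t) = I_0 e^{-Rt}$ by Levenberg–Marquardt least squares with a
deterministic initializer ($I_0$ from the maximum intensity, $R$ from a
log-linear regression on positive intensities). The default sampling
grids are 40–992 ms (10 points) for R₁ and 30–210 ms (6 points) for R₁ρ.
A fitted negative rate is flagged, never clipped.

R₂ is derived from R₁ρ with the spin-lock tilt-angle correction
$$R_2 = R_{1\rho} + (R_{1\rho} - R_1)\tan^2\theta, \qquad
  \theta = \arctan(\Delta\nu/\nu_1),$$
with resonance offset $\Delta\nu$ (Hz) and spin-lock field strength
$\nu_1$ (Hz; default 1433). The convention is fixed by the on-resonance
identity $\Delta\nu = 0 \Rightarrow \theta = 0 \Rightarrow R_2 = R_{1\rho}$;
under it the correction is the exact algebraic inverse of
$R_{1\rho} = R_1\sin^2\theta + R_2\cos^2\theta$, which the test suite
verifies over randomized inputs. Offsets beyond $3\nu_1$ trigger a
warning (the correction amplifies noise quadratically in $\tan\theta$).

Monte Carlo rate errors refit 100 noise-perturbed copies of each decay
(Gaussian, per-intensity, sd equal to the spectral noise) and report the
standard deviation of the refit rates; the seed is an explicit argument.
Exchange-broadening corrections are not applied — the intended regime is
chains for which relaxation-dispersion experiments show no slow
micro–millisecond dynamics, so R₂/R₁ reflects reorientational motion
only. The effective rotational correlation time is then
$$\tau_c = \frac{1}{4\pi\nu_N}\sqrt{6R_2/R_1 - 7},$$
with $\nu_N$ the ¹⁵N Larmor frequency; a negative radicand
($R_2/R_1 < 7/6$, the fast limit) yields an absent value with a flag
rather than a complex number. Because it is not always stated whether a
published chain-average τc averages per-residue values or substitutes
chain-averaged rates (the two differ by roughly a percent),
`chain_tumbling_time()` exposes both conventions.

```{r relax-demo}
ctx <- spectrometer_context(700)
tumbling_time(1.2, 4.7, ctx)$tau_c * 1e9   # ns
```

## Titration quenching and binding segments

When a disordered chain binds a large partner, resonances of contact
residues broaden and their peak heights drop, often without chemical
shift changes. The quench profile is the raw ratio of bound to free peak
heights per residue; overlapped peaks, prolines and missing assignments
are carried through as flagged residues without a ratio. No cross-sample
normalization is applied by default (freshly prepared samples can differ
slightly in concentration; an optional normalization by the mean ratio of
a user-declared unaffected region is available, off by default, so that
the default output is auditable raw data).

Binding segments are maximal runs of at least `min_length` (default 3)
consecutive ok-residues with ratio at or below `threshold` (default 0.5).
A single flagged residue inside a run is bridged; two or more consecutive
non-qualifying residues end it. The defaults were chosen so that a
Fig-2-like synthetic profile — a ~11-residue segment quenched to ~0.2
against a ~0.9 background — yields exactly one call; both parameters are
configurable, and the linear-scan caller is tested against an
independent interval-enumeration oracle.

## 1:1 binding: kinetics, steady state, depletion isotherms

The Langmuir 1:1 model is
$R(t) = R_{eq}(1 - e^{-k_{obs}t})$ during association and
$R(t_a)e^{-k_d(t-t_a)}$ during dissociation, with
$k_{obs} = k_aC + k_d$ and $R_{eq} = CR_{max}/(C + K_D)$,
$K_D = k_d/k_a$. The global kinetic fit shares $k_a$, $k_d$ (and by
default one $R_{max}$ — a single immobilized surface per series) across
all concentrations, on log-scale parameters to enforce positivity, with
a deterministic initializer (dissociation-tail log-linear regression for
$k_d$; association half-rise times for per-curve $k_{obs}$; the
$k_{obs}$-versus-$C$ slope for $k_a$) refined from a small deterministic
multi-start factor grid to guard against local minima. Non-identifiable
designs (no dissociation decay; all concentrations far from $K_D$) attach
a warning to the fit instead of failing silently. Mass-transport
limitation, baseline drift and bulk refractive-index jumps are not
modeled; the residual standard deviation is reported so users can judge.

The steady-state route extracts $R_{eq}$ per curve as the mean response
over a plateau window (default the last 20 s of association, required to
vary by <5%) and fits the binding hyperbola; kinetic and steady-state
routes agree on $K_D$ within 1% on noiseless full-plateau data (tested).

Equilibrium isotherms at a fixed labeled-species concentration $L_0$
(default 10 nM, 16-point two-fold dilution ladder) use the exact
depletion-corrected fraction bound,
$$FB = \frac{(L_0 + T_0 + K_D) - \sqrt{(L_0 + T_0 + K_D)^2 - 4L_0T_0}}{2L_0},$$
fitting $(K_D, S_{free}, S_{bound})$; the signal-to-noise ratio is the
fitted amplitude over the residual sd, and fits with amplitude below 3
residual sd carry a low-confidence flag. Because $K_D$ is a scale
parameter, estimates across replicate experiments are aggregated by
geometric mean in the recovery tests. At a dose–response signal-to-noise
near 19 and a top concentration ~3× $K_D$, single-experiment estimates
are genuinely heavy-tailed — an honest property of the design, visible
in the tests.

## CD conversion

Molar ellipticity is $[\theta] = m°M/(10LC)$ in deg·cm²·dmol⁻¹ with
$m°$ in millidegrees, $M$ in g/mol, $L$ in cm and $C$ in g/L; a blank
(buffer) spectrum is subtracted pointwise first. A per-residue form
(dividing by the peptide-bond count) is available but off by default —
the molar form is the primary definition. Secondary-structure
deconvolution of CD spectra is out of scope.

## Transport, spatial, ROI and tilt quantification

**Track segmentation.** Tracks are 1-D positions along the axon axis,
increasing away from the cell body (anterograde). Per-frame velocities
are centered moving averages of frame displacements (default window 3
frames); frames are classed anterograde/retrograde/pause against a
motion threshold `v_min` (default 0.1 µm/s), same-state frames merge into
segments, and pauses shorter than `min_pause_frames` (default 2) flanked
by runs in the *same* direction are absorbed. A brief pause at a
reversal is kept — absorbing it into either flank would be arbitrary.
Segment statistics (duration, run length, signed velocity) always use
the raw positions. The published kymograph tools this mirrors do not
print their thresholds, so these defaults are explicit and configurable;
recovery tests on noiseless simulated tracks use window 1 and no pause
absorption, which is the exact per-frame state evaluation for data
without localization noise.

**Particle direction** is assigned from net start-to-end displacement
(threshold `d_min`, default 0.3 µm), so a net-anterograde particle may
contain retrograde segments and vice versa.

**Spatial distribution.** Relative positions are percentages of total
axon length (0% cell body, 100% tip, the axon length being the summed
inter-particle line segments); densities are particles per 100 µm.

**ROI intensities.** The inner region is expanded by `dilation_px`
(default 2, the smallest expansion that robustly yields a nonempty ring)
using binary box dilation; the per-pixel background is the
ring-intensity divided by ring area, and the final integrated signal is
the inner intensity minus background times inner area. This is exact for
a punctum wholly inside the inner mask on constant background and
unbiased (zero in expectation) on pure noise.

**Spindle tilt** is the axis angle between the centrosome–centrosome
vector and the embryo long axis, folded to [0°, 90°], with a 15°-bin
rose-diagram helper.

**Exact 2×2 test.** Point probabilities are hypergeometric over fixed
margins (evaluated in log space via `dhyper`); the two-sided p-value
sums tables no more probable than the observed one, with a $10^{-7}$
relative tolerance on the comparison to absorb floating-point ties. The
implementation is tested against exhaustive `choose()`-based enumeration
for every table with total ≤ 40 and against `stats::fisher.test`.

```{r fisher-demo}
fisher_exact_2x2(7, 14, 0, 13)
```

## Synthetic data: what it does and does not emulate

The generators produce data with the statistical structure each analysis
assumes: population-weighted two-state shifts with Gaussian per-nucleus
noise; monoexponential decays on the standard grids; noiseless-kinetics
Langmuir sensorgrams over the 5-point ladder (50, 11, 4.5, 1.8, 0.3 µM,
120 s association / 600 s dissociation) plus Gaussian noise; exact
depletion isotherms (16 two-fold dilutions from 42.5 µM against 10 nM
labeled species); three-state Markov motility (default per-frame
persistence 0.92 for runs, 0.90 for pauses at 0.2 s frame interval,
velocities +1.0/−1.2 µm/s, values typical of organelle transport in
mechanosensory axons); and Gaussian puncta on constant background.

They deliberately do **not** emulate: peak overlap or assignment
ambiguity in spectra; exchange broadening; mass-transport-limited SPR;
thermophoresis time traces (only the endpoint dose–response level);
localization noise, photobleaching, or particle crossing in tracks; or
camera noise statistics beyond additive Gaussian. Passing recovery tests
therefore demonstrates correctness of the estimators under their stated
models, not robustness to every artifact of real data.

All noise is Gaussian, matching the Monte-Carlo error model used in the
relaxation analysis, and every generator takes an explicit integer seed
with no hidden global state; identical seeds reproduce datasets
bit-exactly.

## Problem sizes and numerical choices

The test suite runs decays on the standard 10- and 6-point grids across
up to 50 residues, kinetic fits at 1–2 s sampling over 720 s, 20-seed
noise replicates for the kinetic and isotherm recoveries, 200-track
motility simulations of 30 s at 0.2 s frames, and the exhaustive ≤ 40
exact-test comparison — sizes chosen to exercise the estimators' working
regimes while keeping the whole suite under a minute. Nonlinear fits use
`minpack.lm` with tight tolerances (`ftol = ptol = 1e-14`) and log-scale
positivity transforms; standard errors come from the Jacobian-based
covariance with the delta method back to the natural scale. Degenerate
inputs (constant decays, empty masks, coincident points, zero columns in
contingency tables) are either handled exactly or rejected with a
specific error — never silently coerced.

## Known limitations

- The SSP variant is calibrated by its endpoint/linearity contract, not
  against any specific external implementation's per-residue output.
- Per-residue spin-lock offsets must be supplied (or default to zero);
  the package does not compute them from carrier frequencies.
- The kinetic model is strictly 1:1; bivalent or conformational-change
  schemes are out of scope.
- ROI quantification assumes a locally constant background across the
  dilation ring.
- Real-data kymograph reproduction depends on the upstream tracker's
  thresholds, which are outside this package's control.
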