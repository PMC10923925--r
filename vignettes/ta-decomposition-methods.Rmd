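---
title: "Isolating pure-species photodynamics from mixed transient-absorption data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isolating pure-species photodynamics from mixed transient-absorption data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadecomp)
```

## The decomposition problem

Femtosecond pump–probe spectroscopy of bacteriorhodopsin records a map
$\Delta OD(\lambda, t)$ of pump-induced absorbance changes. A dark-adapted
sample holds two retinal isomers — all-*trans* (AT, absorbing at 570 nm) and
13-*cis* (13C, 543 nm) — and pumping at their isosbestic point excites both
with equal probability. Likewise, re-exciting a sample 60 ps after an
actinic pulse probes a mixture of unreacted AT and the K$_{590}$
intermediate. In both cases the measurement is, assuming each species
contributes independently,

$$\Delta OD_{mix}(\lambda, t) = c \cdot \Delta OD_{A}(\lambda, t) +
  (1 - c) \cdot \Delta OD_{B}(\lambda, t),$$

and isolating species B reduces to estimating the single scalar $c$, the
excited-population fraction of the reference species A whose pure map is
measurable separately (light-adapted samples are pure AT). Every estimator
in this package is a scalar least-squares projection

$$\hat c = \frac{\langle m, p \rangle}{\langle p, p \rangle}$$

of a pure-species marker signal $p$ onto the corresponding mixture signal
$m$, restricted to a regime where only species A contributes to the marker.
The estimators differ in the marker.

## The signal model and its generator

Because the experimental maps are not redistributable, the package carries a
forward generator (`gen_species_map`, `gen_mixture`, `gen_double_pump`) that
realizes, per species,

$$\Delta OD(\lambda,t) = P(t)\,[\sigma_{ESA}(\lambda,t) -
  \sigma_{SE}(\lambda,t)]\,(1 + osc(\lambda,t)) - P(t)\,\sigma_{GS}(\lambda)
  + \phi\,(1 - P(t))\,[\sigma_{prod}(\lambda) - \sigma_{GS}(\lambda)]$$

with excited-state survival $P(t) = \sum_i A_i e^{-t/\tau_i}$
($\sum_i A_i = 1$), Gaussian bands in wavelength, optional exponential
relaxation of band centres
$c(t) = c_\infty + (c_0 - c_\infty)e^{-t/\tau_{shift}}$ emulating ballistic
isomerization, and multiplicative damped-cosine coherence
$osc = \sum_j a_j\, g_j(\lambda)\, e^{-t/d_j} \cos(2\pi c \tilde\nu_j t +
\varphi_j)$ confined by a Gaussian window $g_j$ near 520 nm. Noise is iid
Gaussian per pixel, seeded and reproducible.

The reference species encode the experimental picture:

| species | bleach | kinetics | yield | special |
|---|---|---|---|---|
| `species_at()`  | 570 nm | 0.5 ps | 0.65 | 180 cm$^{-1}$ mode at 520 nm, damping 0.5 ps |
| `species_13c()` | 543 nm | 0.15 ps | 0.55 | ESA 480→450 nm, SE 900→1000 nm shifts ($\tau$ 0.1 ps); product dipole strength 1.15× bleach |
| `species_k()`   | 590 nm | 1.7 / 11 ps, equal amplitude | 0.4 | none (coherence-free) |

The 13C lifetime of 0.15 ps makes its excited signal numerically extinct
(< 2 %) past 0.6 ps, the regime the dark-adapted decomposition uses. Its
band-shift magnitudes are free fixture parameters — the experiments
constrain their existence and direction, not their size. The K yield of 0.4
is a plausible placeholder: no stage of the analysis depends on it. Band
amplitudes put peak signals near 10 mOD so that the studied noise range
(10–100 µOD) corresponds to realistic signal-to-noise.

**What the generator does not emulate** — and what passing tests therefore
do not establish robustness against: probe-chirp/group-velocity dispersion,
coherent pump–probe artifacts (the generator starts clean at $t = 0$;
analyses still discard $t < 0.08$ ps as the experiments must), correlated
baseline noise, pump scatter, instrument-response convolution, and any
breakdown of the species-additivity assumption itself.

## Estimators and their tunable parameters

**Dynamic-difference factor** (`estimate_scale_factor_ddod`).
$\Delta\Delta OD = \Delta OD(t_2) - \Delta OD(t_1)$ cancels static signal
(the accumulated photoproduct plateau), so past the fast species' decay the
mixture's $\Delta\Delta OD$ is $c$ times the pure species'. Parameters:

- `t_min` (ps, default **0.6**): earliest delay entering the differences;
  the point past which dark-adapted dynamic difference spectra converge
  onto pure-AT shapes.
- `mask` (nm, default **440–500 and 850–1400**): wavelengths dominated by
  excited-state signal — the visible ESA band and the NIR SE band — where
  photoproduct and bleach contributions are minimal.
- Pair construction: differences stride one third of the post-`t_min` delay
  list rather than pairing neighbours. Long baselines suppress what little
  fast-species signal survives $t_{min}$ (the contamination of a difference
  scales with $\Delta P_{fast}/\Delta P_{slow}$, which falls as the baseline
  grows), while distinct endpoints keep pair noise uncorrelated — pairing
  everything against one late spectrum would share that spectrum's noise
  across all pairs.
- Uncertainty is a delete-one-pair jackknife: the experimental uncertainty
  derivation for this factor is not public, and the jackknife needs no
  distributional assumptions beyond pair exchangeability.

**Coherence factor** (`estimate_factor_from_oscillations`). Band-averaged
traces at `window_center` 520 nm (`window_width` 30 nm) are detrended by a
multiexponential fit (`n_exp` 3, enough for the superposed AT and K decays
plus plateau), and the oscillatory residuals are matched over `t_range`
0.08–1.5 ps — after the artifact window, within the coherence lifetime.
One numerical subtlety dominates the estimator's accuracy: a free
multiexponential fit can *absorb* part of the coherence it should expose,
by placing an ultrafast exponential along the first half-cycle, and the
absorbed fraction varies between the mixture and pure fits. Detrending
lifetimes are therefore bounded below by `detrend_tau_min` 0.3 ps — slower
than a 180 cm$^{-1}$ period (0.17 ps) — so the smooth model cannot track
the oscillation. The estimator assumes the coherence belongs exclusively to
the reference species; the test suite quantifies the upward bias a
coherent contaminant produces.

**NIR-SE factor** (`estimate_factor_from_se`): the same projection on raw
$\Delta OD$ over `nir_window` 900–1400 nm and `t_range` 0.6–5 ps, where only
surviving excited-state population emits. Using it *before* the fast
species has decayed biases the factor upward — a property the tests assert,
since it is the failure mode a practitioner must know.

**Late-spectrum factor** (`late_spectrum_match`): time-averaged spectra at
$t \ge$ `t_min` 50 ps, matching one experiment onto another once all
transients have settled.

**Steady-state decomposition** (`decompose_absorption`):
$A_{13C} = (A_{DA} - x_{AT} A_{LA})/x_{13C}$ with the composition defaulting
to 0.35 : 0.65. The peak is located by three-point parabolic interpolation;
ties between equal maxima break toward the longer wavelength, and an edge
maximum returns the grid point. Negative dips are reported with a warning,
never clipped — clipping would bias the located maximum.

**Kinetics** (`fit_multiexp`). Variable projection: for any trial lifetime
set the amplitudes and offset are the exact linear least-squares solution,
so the nonlinear search runs only over log-lifetimes. Because linear+log
delay axes create local minima, the search multistarts from 8 log-spaced
lifetime grids spanning 0.05–200 ps, bounded to [0.01, 1000] ps (a bound
hit raises a warning), and the best start is polished derivative-free
(Brent for one lifetime, Nelder–Mead otherwise). Standard errors come from
the full nonlinear Jacobian at the optimum. `t_start` defaults to 0.08 ps,
the artifact-window edge. For K-like decays with a minor initial phase, both
presets — (`n = 2`, `t_start = 0.3`) excluding it and (`n = 3`,
`t_start = 0.08`) modelling it — are expressible through the arguments; the
package fixes neither as canonical since the data decide.

**Coherence analysis** (`fit_oscillations`, `power_spectrum`). Damped
cosines are fitted with the quadrature trick (cosine/sine pair per mode,
amplitudes linear, variable projection again), initialized from
power-spectrum peaks and multistarted over damping guesses 0.2/0.5/2 ps.
Frequencies convert via $\tilde\nu = f / c$ with $c = 2.998 \times 10^{-2}$
cm ps$^{-1}$. Power spectra resample the nonuniform trace linearly onto the
minimum native spacing first; interpolation attenuates power near the
Nyquist limit, which is why the damped-cosine fit, not the FFT, is the
quantitative frequency estimator here.

**Quantum yield** (`estimate_qy`). Per excited molecule the long-delay
difference spectrum is $\phi(\epsilon_{prod} - \epsilon_{reac})$; its band
integral over the reactant absorption region equals
$\phi D_{reac}(r - 1)$ when the product carries $r$ times the reactant's
dipole strength ($r \approx 1.15$ for 13C→AT retinal pigments), while the
early-bleach integral measures $D_{reac}$. Hence
$\hat\phi = I_{long} / (|I_{bleach}|(r - 1))$. The exact experimental
formula is not public; this reconstruction is the minimal model consistent
with the described procedure, is flagged `formula = "reconstructed"` in the
result, and its correctness standard is round-trip recovery on the
generator (where it is exact by construction when the supplied bleach is
clean). Integrals are evaluated in wavenumber — dipole strengths are
energy-domain quantities — by trapezoid with interpolated window edges. How
a clean early bleach is obtained from data where ESA/SE overlap it is the
caller's responsibility (e.g. from a decomposed map); the package does not
guess.

## Numerical and interface choices

- Bands are Gaussian in wavelength, not wavenumber: generator realism is
  secondary to having closed forms the tests can pin down; integrals that
  care about energy weighting are taken in wavenumber regardless.
- Axes: wavelength in nm, delay in ps, signal in OD — everywhere, including
  files. The TSV formats are strict (decimal points only, monotone axes,
  rectangular bodies) and full-precision, so write→read is bit-exact;
  malformed files fail with the offending row/column named, never a silent
  misparse. Generator entry points require at least 8 points per axis;
  containers and readers accept 2, since downstream algebra is
  well-defined on small hand-written fixtures.
- All estimator identities (mix ≡ pure ⇒ $\hat c = 1$, noiseless
  subtraction exactness at $10^{-14}$) and every closed-form factor's
  agreement with a brute-force grid search on its own objective are asserted
  in the test suite.
- Degenerate inputs error early and specifically: a marker signal that is
  identically zero (factor unidentifiable), a coherence residual below
  3× the stated noise floor, a zero bleach integral, compositions not
  summing to one, out-of-range yields flagged rather than clipped.
- Problem sizes: the suite and the acceptance script run on 195-wavelength
  × 66-delay maps (5 nm / linear-0.02-ps-then-log sampling), 20-fixture
  recovery sweeps, and 50-replicate Monte-Carlo fits — sizes at which every
  estimator's error is far from its asserted tolerance yet the full run
  completes in seconds.

## Known limitations

- The equality of the excited-signal fraction with the ground-state isomer
  ratio rests on isosbestic pumping and equal emission dipoles; the package
  treats it as an assumption of the experiment design, not something it can
  verify from a single mixture map.
- The anisotropy-based confirmation of the two-pump factor is supported
  only by the standard $r(t)$ computation (`anisotropy`); the polarization
  bookkeeping of a specific instrument is out of scope.
- No global or target kinetic-scheme analysis: the decomposition's point is
  to stay free of kinetic-scheme assumptions, and the package keeps that
  property.
- No chirp correction, IRF deconvolution, or vendor binary formats.
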