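---
title: "Multiscale kinetics of salt-induced protein crystallization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale kinetics of salt-induced protein crystallization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crystkin)
```

# The problem

Trivalent salts such as LaCl3 can drive concentrated solutions of
globular proteins (serum albumin being the classic model) into
crystallization. The transformation takes days and involves several
populations at once: dissolved monomers, small clusters or precursors,
possibly a disordered dense phase, and growing crystals. No single
instrument sees all of them. Optical microscopy follows individual
crystal faces; dynamic light scattering (DLS) measures long-time
collective diffusion over milliseconds; neutron spin echo (NSE) and
neutron backscattering (NBS) measure nanosecond diffusion on ångström
length scales; diffraction recorded in situ watches lattice order emerge.
`crystkin` implements one analysis chain per probe and reduces each to
the same two numbers so the probes can be compared.

# The kinetic model

All pipelines end in the logistic growth law

$$f(t) = \frac{f_0}{1 + \exp(-(t - t_0)/\Delta t)},$$

with amplitude $f_0$ (negative for a decaying contribution), inflection
time $t_0$ (the moment of fastest growth) and characteristic time
$\Delta t$; the maximum rate is $f'(t_0) = f_0/(4\Delta t)$. Both
identities are verified to $10^{-9}$ (relative) in the tests. Processes
with intermediate steps are described by sums of such terms plus a
constant background; `fit_kinetics()` fits any number of components by
weighted Levenberg–Marquardt with analytic-scale normalization of the
observable, deterministic multi-start (inflection times scattered over
the window, sign flips for the first component, a coarse placement grid
for two-component fits), bounds $\Delta t \in (0, \mathrm{span}]$ and
$t_0$ within one span of the data, and uncertainties from the local
covariance $(J^\top W J)^{-1}$ scaled by the reduced chi-square.
Components are reported sorted by $t_0$. Degenerate inputs (constant
traces) and non-convergence are flagged, never silent.

# Per-technique models

## Dynamic light scattering

The normalized intensity correlation shows a clear shoulder, so the field
correlation is modelled as two exponentials and squared (Siegert):
$g_2 - 1 = \beta\,[a e^{-\Gamma_1\tau} + (1-a) e^{-\Gamma_2\tau}]^2$,
with the slow rate $\Gamma_1$ assigned to clusters/precursors and the
fast rate $\Gamma_2$ to dissolved proteins ($\Gamma_1 \le \Gamma_2$
enforced by label swapping, the weight flipped accordingly). An unsquared
variant is available (`squared = FALSE`) because correlator conventions
differ; the squared form is the default since $g_2-1$ is what is
measured. Repeats are averaged after outlier rejection: a point is
dust if it deviates from the per-lag median by more than 5 scale units,
where the scale is the stated instrument error when available (a MAD
across a handful of repeats underestimates the spread too often),
otherwise the MAD. Per sample age, $\Gamma_{1,2}(q) = D_{1,2} q^2$ fitted
through the origin (pure Fickian; an intercept is available for
diagnostics only) gives the collective diffusion coefficients. The
refractive index of D2O at 633 nm defaults to 1.333 and is configurable.

The monomer coefficient $D_2(t)$ needs two sigmoid steps. With the
default truth (steps at about 97 h and 108 h) a single sigmoid reproduces
the curve to better than the 1% noise when it carries a free offset, so
"one sigmoid is not enough" is demonstrated two ways: across the full
duration the one-component fit fails a Wald–Wolfowitz runs test on the
residual signs while the two-component fit passes, and a one-component
fit to data truncated at 80 h mispredicts the observed end level badly.

## Neutron spin echo

The normalized intermediate scattering function mixes coherent and
incoherent contributions with opposite signs (spin-flip polarization):
$I(\tau) = a_\mathrm{coh} I_\mathrm{coh}(\tau) - a_\mathrm{inc}
e^{-\gamma_\mathrm{inc}\tau}$. The minus sign is what makes the signal
*rise* at Fourier times below a few hundred picoseconds wherever the
incoherent part is appreciable — the model reproduces this signature and
the tests require it. Since the curves may have partially decayed before
the first measured $\tau$, the amplitudes cannot be fixed from theory;
instead $a_\mathrm{coh} - a_\mathrm{inc}$ is pinned to the measured value
at $\tau < 15$ ps. All admissible points below the cut are averaged: the
constraint error propagates into the immobile fraction with a gain of
roughly four, so using one noisy point would dominate the error budget.
(A sum convention $a_\mathrm{coh} + a_\mathrm{inc}$ is available behind
`constraint_mode = "sum"` because the two wordings circulate; with the
minus sign in the model the difference convention is the consistent one
and is the default.)

At the Bragg position the coherent part carries an immobile fraction:
$I_\mathrm{coh} = s + (1-s) e^{-\gamma_\mathrm{free}\tau}$, crystals
being static on the accessible 10 ns. Both rates are held fixed there —
$\gamma_\mathrm{free}$ from a weighted Fickian fit
$\gamma = D q^2$ over the neighbouring q values, and the incoherent rate
from the same construction — because co-fitting either with $s$ is
degenerate when $\gamma_\mathrm{free}\tau_\mathrm{max} \lesssim 1$. Two
further estimator choices matter and are deliberate:

* **Two-pass rate estimation.** At low q the slow incoherent decay is
  degenerate with the coherent one, biasing first-pass coherent rates.
  The incoherent (self) rate is therefore pinned at high q first and the
  free curves refitted with it fixed.
* **Pooling across ages** (`pool_rates = TRUE`). The free-protein rates
  vary slowly compared with crystallization, while $s$ responds to the
  fixed rate with a gain near ten; the median over ages removes most of
  the per-age interpolation noise.
* **Relaxed estimator bounds.** The physical $s$ lies in $[0,1]$, but
  truncating the per-age estimates at those bounds biases the ends of the
  $s(t)$ series (early points can only err upward, late points downward),
  which propagates into $\Delta t$. The chain therefore fits $s$ within
  $[-0.5, 1.5]$ and leaves interpretation to the series level; standalone
  `fit_isf()` keeps the physical bounds by default.

The series $s(t)$ is referenced to its first point, scaled so the maximum
is 1, and fitted with a free amplitude *and* free offset — the subtracted
reference is itself noisy and already contains a small part of the growth
curve, and a fixed-zero baseline would distort the time constants.

## Neutron backscattering fixed window scans

Elastic (0 µeV) and inelastic (1 and 3 µeV) windows are recorded over
0.2–1.9 Å⁻¹. Under a single-Lorentzian assumption the intensity ratio
$R = I_1/I_3$ inverts in closed form,
$\gamma = \sqrt{(\omega_3^2 - R\,\omega_1^2)/(R-1)}$, valid for
$1 < R < (\omega_3/\omega_1)^2$; outside the window the motion is too
slow or too fast for the chosen offsets and the point is masked. The
closed form neglects the instrument resolution (the offsets sit outside
it); a numerically inverted resolution-convolved ratio is provided both
as the reference oracle and as an optional analysis mode, and the tests
quantify the closed form's bias on convolved data. The resolution is a
unit-area Gaussian of 0.9 µeV FWHM (only the width is specified by the
instrument; the shape is a modelling choice). The Lorentzian–Gaussian
convolution is evaluated by fixed-node Gaussian quadrature —
Gauss–Legendre in the arctangent variable for $\gamma < 1$ µeV,
Gauss–Hermite above — accurate to better than $10^{-9}$ against adaptive
quadrature over $\gamma \in [0.05, 20]$ µeV, and fully vectorized.

$\gamma(q) = \hbar D q^2 + c$ fitted over $0.4 < q < 1.4$ Å⁻¹
($\hbar = 0.6582$ µeV·ns) gives the effective short-time diffusion
coefficient; the offset $c$ absorbs localized/jump-like internal motion.
A saturating jump-diffusion alternative is available behind
`model = "jump"`. The quasi-elastic scale $s_\mathrm{FWS}$ is the least
squares factor matching the convolved Lorentzian to both inelastic
windows, and the elastic weight is
$c_e = [I_0 - s_\mathrm{FWS}(L \otimes R)(0)]/R(0)$, clipped at zero with
a flag. Averaged over $1.1 < q < 1.8$ Å⁻¹, referenced to $t = 0$ (the
container contributes only elastically, so it cancels in the
subtraction), normalized to the final value and fitted with a free
offset, this yields $c_\mathrm{NBS}(t)$. Solvent subtraction
(`subtract_solvent`) takes a measured solvent frame and a scale factor
defaulting to the solvent volume fraction (0.945 at 75 mg/ml protein).

## In situ diffraction

The dissolved-protein signal under the Bragg peak is estimated per frame
by linear interpolation across an exclusion window (half-width defaulting
to about three peak sigmas) from the mean of three flanking points per
side; the integrated excess above it is the crystal signal. Integrated
excess is preferred over peak height for robustness to wavelength
smearing; height is available behind `quantity = "height"`. Because the
interpolation is per frame, any baseline shared by all frames — or
drifting smoothly in time — cancels exactly, which the tests assert.
Assuming no crystals at the start and full crystallization at the end,
the series is referenced to $t = 0$ and normalized by the final frame.
The low-q channel is simply $I(q_0, t)/I(q_0, 0)$ at the lowest recorded
momentum transfer (0.096 Å⁻¹), fitted with a sigmoid plus constant
background; it works whether or not a Bragg peak is in range. Peak
location uses a robust linear baseline through the sub-median window
points, a 3σ prominence requirement and quadratic vertex refinement.

## Microscopy

Each crystal's 2D-projected area is fitted individually; crystals whose
fits fail to converge are excluded and counted. Population summaries are
Freedman–Diaconis histograms and error-weighted means
$m = \sum x_i/\sigma_i^2 / \sum 1/\sigma_i^2$ (reducing to the arithmetic
mean for equal errors). A trace censored before its inflection keeps a
very uncertain $t_0$ and is automatically down-weighted. Cubic
crystallites give $V = A^{3/2}$; refitting the volume trace sharpens
$\Delta t$, and this conversion is offered as a documented default — the
full surface-to-volume correction used for published volume-corrected
parameters involves additional detail not reproducible here, so no
equivalence is claimed. The segmenter (threshold, connected components
via EBImage, centroid tracking, merge flagging) is intended for the
synthetic square-crystal stacks only, not for real micrographs.

# The synthetic-data generators

The generators define the study conditions; every analysis stage is
validated by `analyze(generate(θ)) ≈ θ`. Defaults, chosen once:

* **Kinetic truths** use the published cross-technique parameters:
  microscopy population $t_0 \sim N(31.92, 5)$ h,
  $\Delta t \sim N(7.08, 1)$ h, log-normal maximum areas; DLS monomer
  steps at (96.93, 3.21) and (108.19, 14.65) h; NSE immobile fraction
  at (45.24, 11.65) h with plateau 0.75; Bragg-peak area at
  (48.98, 7.15) h; low-q baseline amplitude at (74.20, 13.47) h; NBS
  elastic fraction at (40.0, 11.48) h over a 0.25 container constant.
* **Noise models**: multiplicative Gaussian 1% (DLS), additive Gaussian
  3% (NSE), Poisson at 10^4 mean counts per unit spectral density (NBS),
  multiplicative 3% (diffraction, microscopy areas).
* **Cadences** follow the instruments: 2 h per NSE spectrum, half an hour
  for NBS, DLS and microscopy. Observation windows are 80 h
  (microscopy, NSE, NBS), 160 h (DLS, whose second process is late), and
  100 h for the diffraction movie so that the slow low-q process is
  actually seen saturating.
* **NSE specifics**: the incoherent relaxation constant defaults to
  80 Å²/ns — an effective value well above the centre-of-mass diffusion
  (3 Å²/ns coherent), standing in for the combined self, rotational and
  internal relaxation that makes the incoherent signal die on
  subnanosecond scales; it is what produces the observed short-τ rise.
  Amplitudes interpolate from coherent-dominated at low q to
  incoherent-dominated above 0.3 Å⁻¹, with the coherent fraction
  re-enhanced at the Bragg position by the reflection itself. The
  Fourier-time grid is log-spaced from 5 ps (several points below the
  15 ps constraint cut) to 10 ns.
* **NBS specifics**: the spectrum per (q, t) is an elastic line of weight
  $c_e(t)$ plus a convolved Lorentzian of weight $1 - c_e(t)$ with
  $\gamma = \hbar D(t) q^2 + 0.3$ µeV. The inelastic windows contain only
  the quasi-elastic term: the offsets are treated as fully outside the
  resolution, consistent with how the ratio method is constructed. For a
  true Gaussian resolution the elastic leak at 1 µeV would be about 3% of
  the elastic line; real analyses neglect it and so does the generator.
  This is the main idealization to keep in mind when transferring
  conclusions to real data.

What passing recovery tests shows — and what it does not: the chains are
unbiased and precise *under these forward models*. Real data add
multiple scattering at early times (DLS), imperfect buffer subtraction
(NSE), non-Gaussian resolution wings (NBS), sedimentation of crystals out
of the beam (diffraction; the non-monotonic artefacts this causes are not
modelled) and interface-preferring nucleation (microscopy). None of these
are emulated.

# Numerical choices and diagnostics

* Fit engine: `minpack.lm::nls.lm` with bounds everywhere; covariances
  from the scaled inverse Hessian, pseudo-inverse fallback.
* The observable is normalized to unit scale inside `fit_kinetics` so
  that amplitudes of order $10^{-11}$ (diffusion coefficients in m²/s)
  do not wreck the conditioning of the covariance.
* Voigt evaluations: 800-node Gauss–Legendre / 96-node Gauss–Hermite
  hybrid, cached nodes; reference adaptive quadrature at $10^{-12}$.
* Ratio inversion root-finding in $\log\gamma$ with `uniroot` at
  $10^{-13}$ tolerance.
* Ties and degeneracies: DLS labels swapped to keep $\Gamma_1 \le
  \Gamma_2$; kinetic components sorted by $t_0$; weights at the $s$
  bounds replaced by the worst regular point's uncertainty in the NSE
  series; all-zero or constant series flagged as degenerate rather than
  fitted silently.
* Problem sizes in the validation suite are scaled to the structure of
  each question: recovery envelopes use 100 seeds per modality at 1–4 h
  cadences and a reduced DLS angle set (five angles), which reproduce the
  full-cadence estimator medians while keeping each run below a second.

# Known limitations

* The NSE immobile-fraction series carries the information floor set by
  3% curve noise and the shallow free-protein decay at the Bragg q
  ($\gamma_\mathrm{free}\tau_\mathrm{max} \approx 0.7$): per-age
  $s$ estimates scatter by about 0.06 even with everything else known,
  so individual-seed kinetic parameters scatter by 1–3 h; the estimator
  is unbiased (median over seeds within 0.3 h) but not sharp.
* The closed-form ratio inversion is biased for linewidths comparable to
  the resolution width and undefined where the broadened ratio leaves the
  Lorentzian window; the convolved inversion handles both at ~7x cost.
* The cubic area-to-volume conversion is a stated approximation, not a
  validated reproduction of published volume-corrected parameters.
* No mechanistic nucleation model is fitted anywhere — the package
  describes kinetics, it does not explain them.

# Orchestration

The package is organised as an analysis workflow: the numbered scripts
under `analysis/` are thin narrative drivers over the package functions,
and `run_crystallization_study()` performs the whole
simulate-then-analyze sweep from one seed, writing per-modality outputs,
the resolved run configuration and the cross-technique comparison table.
Configuration is by function arguments; there is deliberately no shell
CLI layer beyond `Rscript` on the analysis and acceptance scripts.
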