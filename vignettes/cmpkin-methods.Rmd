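---
title: "Modelling casein microparticle size kinetics in simulated gastric fluid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling casein microparticle size kinetics in simulated gastric fluid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmpkin)
```

## The system and the modelling idea

Casein microparticles (CMPs) are spherical, sponge-like protein particles of
10–50 µm made from casein micelles. Exposed to simulated gastric fluid (SGF)
at pH 2 with pepsin, a single particle observed in a flow cell shows a
characteristic three-phase size response:

* **Phase I** — a two-step *shrinkage* during acidification. Casein
  solubility passes through two minima (near pH 6 and at the isoelectric
  point, pH 4.2); at each insolubility peak the gel network contracts and
  squeezes solvent out.
* **Phase II** — an anomalous *swelling* that starts abruptly once the
  isoelectric point is crossed: the caseins charge positively, repulsion
  returns, and solvent flows back in, first fast and then progressively
  slower.
* **Phase III** — with pepsin present, an *exponential decay* of the
  particle volume to a stable plateau once the enzyme has penetrated the
  network.

Because the particle stays spherical until disintegration, the measured
circular projection area $A$ determines the volume $V$ through the
spherical approximation $A = 3V/(4R)$, i.e.
$A = \pi^{1/3}(3V/4)^{2/3}$ (`volume_to_area()`, `area_to_volume()`).
The whole kinetic description is a single volume balance
$$\frac{dV}{dt} = \sum_i I_{V,i},$$
with all structural detail pushed into the time dependence of the gated
in/out flows $I_{V,i}$. Sources and sinks of volume other than transport
across the particle surface (e.g. changes in water binding) are neglected;
this is an explicit model assumption, not a finding.

## Kernels

Each insolubility-driven outflow is a Gaussian pulse
$g(t) = n\,e^{-(t-t^+)^2/(2\sigma^2)}$ (`gaussian_pulse()`). Two
conventions coexist in the source material: a normalized density prefactor
in the rate definition, and a closed form whose exponent carries
$\tfrac{\sqrt{2\pi}}{2} n \sigma\,\mathrm{erf}(\cdot)$ — which is the
integral of the *unnormalized* kernel. The package adopts the unnormalized
kernel everywhere, because it makes the rate equation, its integral and the
fitted closed form mutually consistent; the amplitude $n$ simply absorbs
the normalization. For the same reason $\sigma$ is treated as a standard
deviation in seconds (the erf argument $(t-t^+)/(\sqrt2\sigma)$ is only
dimensionless then), even though the parameter tables label its unit
"s²".

Event chronology is expressed with binary gates (`gate_schedule()`): a step
is on from $t^*$ (closed left boundary), a pulse is on over the half-open
window $[start, end)$, and a ramp — whose slope is never specified by the
model chronology, only its activation time — is treated as a held unit
activation. The half-open convention ensures back-to-back windows sharing
a boundary (the swelling pulse ends exactly when degradation starts) never
double-activate.

The linear time→pH map (`time_to_ph()`) anchored at the two insolubility
peaks (pH 6.2 and 4.2) is provided for axis annotation only. Extrapolated
beyond its anchors it quickly reaches non-physical values (pH < 0 within
the experimental window), so no model dynamics depend on it; all
chronology uses times directly.

## Closed-form phase models

**Phase I.** Integrating $dV/dt = -V(g_1 + g_2)$ gives
$$V(t) = V_0\, e^{-\frac{\sqrt{2\pi}}{2} n_1 \sigma_1
  \mathrm{erf}\frac{t-t_1^+}{\sqrt2\sigma_1}
  -\frac{\sqrt{2\pi}}{2} n_2 \sigma_2
  \mathrm{erf}\frac{t-t_2^+}{\sqrt2\sigma_2}}$$
(`eval_phase1()`). The erf terms omit integration constants, so $V_0$ is a
mid-curve reference — the value where the erf terms vanish — not the
volume at $t=0$: early on both erf terms are near $-1$ and
$V(0) \approx V_0 e^{+\frac{\sqrt{2\pi}}{2}(n_1\sigma_1 + n_2\sigma_2)}$.
The package therefore exposes the reference-free total shrinkage
$V(\infty)/V(-\infty)$ as `phase1_shrink_factor()` and leaves $V_0$ as a
fit constant. Volume *ratios* are reference-free, which is what the
quadrature-oracle tests check.

**Phase III.** For pre-acidified particles,
$$V(t) = \begin{cases}
V_0\,e^{-\frac{\sqrt{2\pi}}{2} n_3 \sigma_3
  \mathrm{erf}\frac{t-t_3^+}{\sqrt2\sigma_3}} & t < 147\ \mathrm{s}\\
V_4 e^{-t/t_4} + V_\infty & t \ge 147\ \mathrm{s}
\end{cases}$$
(`eval_phase3()`). The breakpoint default is 147 s (the body-text figure;
a figure caption rounds it to 150 s) and is configurable. The two branches
are fitted independently, mirroring the published segment fit; no
continuity is enforced and the branch jump at the breakpoint is reported
as a diagnostic. With the tabulated parameters that jump is large
(≈ 230 pL), an honest property of the printed parameter set rather than
an artifact of this implementation.

A known ambiguity: the plateau $V_\infty = 55.5$ pL has been quoted as
"16% of the initial volume", but it is 28% of the fit constant $V_0$ and
≈ 15% of the model's own $t=0$ value. No reference choice reproduces 16%,
so `phase3_plateau_fraction()` requires an explicit reference volume and
the package never asserts the 16% figure.

## The stock-and-flow simulator

`simulate_system()` integrates
$dV/dt = -I_{V1} + I_{V2} - I_{V3}$ by fixed-step Euler (default
$dt = 0.25$ s, every step recorded, areas derived per step). The flows:

* $I_{V1} = V(g_1 + g_2)$ until $t_2^+ = 300$ s — Phase I outflow.
* $I_{V2} = V g_2 + s(V) - \mathrm{pulse2}(t)\,V g_3$ on
  $[300, Degt = 536)$ s — at the shrinkage minimum the solvent flow
  reverses, so the tail of $g_2$ re-enters as inflow; $s(V)$ is a
  sustained swelling term; from $t(\mathrm{pH}2.8) = 424$ s the pepsin
  surface contraction $g_3$ throttles the swelling.
* $I_{V3} = RC_2 V - RC_3$ from $Degt$ — linear decay whose fixed point
  $V_\infty = RC_3/RC_2$ sets the final area
  $A_\infty = \pi^{1/3}(\tfrac34 RC_3/RC_2)^{2/3}$
  (`steady_state_area()`).

The Phase II flow is a *reconstruction*: the original simulation-software
equations are not published, only the qualitative description and the
parameter table (which lists $RC_1 = 0.0032$ s⁻¹ and an exponent
$nx = 1.5$ next to it). Two choices were genuinely open:

* **Form of the sustained swelling term.** The literal power law
  $RC_1 V^{nx}$ with $V$ in fL is superlinear and, at the tabulated
  coefficients, reaches a finite-time blow-up near $t \approx 343$ s —
  before the degradation onset — so a simulation of the tabulated
  configuration could never reach its steady state. The default is
  therefore the relative-volume power law
  $s(V) = RC_1 V_0 (V/V_0)^{nx}$, which keeps $RC_1$ in s⁻¹, reduces to
  the simple first-order swelling $RC_1 V$ at $nx = 1$, and stays finite
  through Phase II. The kernel is pluggable
  (`phase2_kernel = "absolute"` gives the literal form), and the
  steady-state results are kernel-independent by construction: after
  $Degt$ only $I_{V3}$ is active.
* **Ramp semantics.** Only the activation time of the degradation ramp is
  specified; it is implemented as a unit step, since the magnitude of
  $I_{V3}$ is fully determined by $RC_2$ and $RC_3$.

Euler positivity is guarded by a configurable floor (default $10^{-6}$ fL)
with a warning, and non-finite states abort with the offending step —
silent failure is never the contract. At the default rates the Euler error
is far below the model's own uncertainty: halving $dt$ moves the final
area by well under 0.1%, and against the analytic solution of the pure
linear-decay configuration the trajectory is accurate to better than 0.1%
at $dt = 0.25$ s.

Note on amplitudes: the Phase I amplitudes of the simulator table
($n_1 = 4.23\times10^{-4}$, $n_2 = 1.7\times10^{-4}$) are two orders of
magnitude below the closed-form fit values. The two parameterizations
serve different model structures (relative-volume closed form vs
absolute-volume flow model) and are deliberately not reconciled; the
simulator always uses its own table.

## Fitting

`fit_phase1()` follows the published protocol: residuals on relative
volume (areas → volumes → normalized to the fitting-window start, with the
free $V_0$ absorbing the normalization), $\sigma_1$ fixed, $t_2^+$ fixed
at the observed shrinkage minimum. The by-eye choice of that minimum is
replaced by a reproducible surrogate, the argmin of a 5-point moving
average (`detect_shrinkage_minimum()`), overridable. The optimizer is
bounded Levenberg–Marquardt least squares (via minpack.lm) with a
deterministic multi-start over a small set of $t_1^+$ candidates and
data-driven scale starts ($V_0$ from the geometric mean of the window
endpoints, amplitudes from the total log-drop split across the two
pulses); a single generic start can land in a merged-step local optimum
when the second shrinkage step dominates.

`fit_phase3()` fits the two branches independently ($\sigma_3$ and the
breakpoint fixed; the exponential branch seeded by a log-linear
regression) and reports the branch discontinuity.

`fit_system()` estimates named simulator parameters by a classic
differential-evolution (rand/1/bin) global search, written in-package,
with reflection at the bounds and an early stop when the population loss
spread collapses; the loss is the sum of squared *area* residuals with
observation times matched to the nearest Euler grid point. Runs are
bit-reproducible for a given seed. Defaults (population 15 per free
parameter, up to 1000 generations) are package choices; the published
protocol names the method but not its settings.

## Synthetic data

`generate_kinetics()` emulates the microscope series for the three
experimental conditions at 2 frames per second with multiplicative
lognormal noise (default CV 1%; multiplicative because segmentation error
scales with particle size, lognormal with `meanlog = 0`, i.e.
median-unbiased — the mean exceeds the noiseless curve by
$e^{\log(1+cv^2)/2}$, about $5\times10^{-5}$ at 1%). Ground truths are the
tabulated parameter sets shipped as JSON under `inst/extdata`. Durations
are emulation choices matched to the published kinetics: 1800 s for the
SGF + pepsin run (stable final value after ≈ 30 min), 900 s for the two
control conditions.

Two synthetic features are deliberately *not* claims about the system:
the water-pH 2 scenario appends a configurable exponential expansion
segment (default rate 0.003 s⁻¹ from $t_2^+ + 3\sigma_2$) purely to give
detection and windowing code something realistic to work on — the real
dissolution process has no published fitted model — and the pre-acidified
scenario inherits the branch discontinuity of the printed Phase III
parameters.

What passing the recovery tests shows, and what it does not: noiseless
recovery to ≤ 0.1% and noisy-replicate medians below 5% demonstrate that
the fitting machinery is consistent and well-conditioned *under the
generator's assumptions* (iid multiplicative noise, exact model family,
exact frame grid). Real microscopy series add segmentation drift,
correlated noise, focus changes and model misspecification, none of which
the generator emulates.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the full simulator grid
(9601 Euler steps for 2400 s at $dt = 0.25$ s), 100-draw quadrature-oracle
comparisons at 1e-8 relative tolerance, 20 noisy-replicate fits, and a
differential-evolution recovery with population 20 on the two
steady-state rate coefficients — sizes chosen so the whole suite completes
in well under a minute on one core while still exercising every code
path at the published operating point. Least-squares tolerances are
1e-12 on cost and parameter change; tie-breaks (gate boundaries) follow
the closed-left convention stated above; degenerate inputs (constant
series, empty free-parameter sets, zero rate coefficients) return defined
results or informative errors rather than NaNs.

## Known limitations

* The Phase II flow is a reconstruction constrained by qualitative
  description only; point-by-point agreement with the published simulated
  trajectory is out of reach without the original model code, and only
  steady-state and phase-structure properties are asserted.
* The closed-form Phase I total shrinkage implied by the tabulated pepsin
  parameters (to ≈ 44% of $V(0)$ in volume) is hard to reconcile with the
  reported "three quarters of the initial area"; the normalization
  convention of the underlying relative-volume figure is not fully
  specified, so the package asserts curve anchors and ratios, not that
  headline fraction.
* The solubility-curve module implements the two-Gaussian functional form
  only; re-fitting the historical solubility measurements it summarizes
  is out of scope (the data exist only graphically, in third-party work).
* No uncertainty quantification: the source protocol reports point
  estimates, and so does the package.
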