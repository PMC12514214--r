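# cmpkin

Kinetic modelling of casein microparticle (CMP) size changes under
simulated gastric conditions.

CMPs are spherical, sponge-like casein particles (10–50 µm) studied as
protective capsules for bioactives during gastric transit. Observed one
particle at a time in a flow cell, their projected area responds to SGF
(simulated gastric fluid, pH 2) with pepsin in three phases: a two-step
acid-induced shrinkage, an anomalous fast-then-slow swelling after the
isoelectric point is crossed, and a pepsin-driven exponential decay to a
stable plateau. `cmpkin` implements the kinetic description of that
response for researchers modelling protein-particle digestion and
controlled release.

## The model

Because the particle stays spherical, the measured projection area A and
volume V are linked by the spherical approximation A = 3V/(4R), i.e.
A = π^(1/3)·(3V/4)^(2/3). Everything else is a single volume balance,

    dV/dt = −I_V1 + I_V2 − I_V3,

with gated flows: Phase I outflow I_V1 = V·(g1 + g2) driven by two
Gaussian insolubility pulses g_i(t) = n_i·exp(−(t−t_i⁺)²/(2σ_i²));
Phase II inflow I_V2 (reversed g2 tail plus a sustained swelling term,
throttled late by the pepsin surface contraction g3); Phase III outflow
I_V3 = RC2·V − RC3, whose fixed point sets the final area
A∞ = π^(1/3)·(3/4·RC3/RC2)^(2/3). Closed forms are available for the
pure phases: the erf solution of the Gaussian-outflow balance
(`eval_phase1()`) and the piecewise erf/exponential-to-plateau decay
(`eval_phase3()`). The full model is integrated by fixed-step Euler
(`simulate_system()`, dt = 0.25 s), and parameters are estimated by
bounded Levenberg–Marquardt least squares (phase models) or an
in-package differential-evolution global search (full model). A
synthetic-data generator (`generate_kinetics()`) emulates the microscope
series (2 frames/s, multiplicative lognormal noise) for all three
experimental scenarios with the tabulated parameter sets as ground truth.

## Worked example

```r
library(cmpkin)

cfg <- system_config()            # tabulated SGF + pepsin parameter set
steady_state_area(cfg)
#> [1] 11.84329                    # final area A-inf, µm²

traj <- simulate_system(cfg)      # full three-phase Euler trajectory
traj
#> <cmp_trajectory> 9601 steps, t = [0, 2400] s, final A = 11.85 um2
tail(traj$area_um2, 1) / traj$area_um2[1]
#> [1] 0.2709831                   # particle ends at 27% of initial area

# pepsin-induced decay (pre-acidified particles), tabulated parameters
tab2 <- read_phase3_params(system.file("extdata", "table2.json",
                                       package = "cmpkin"))
phase3_rate(tab2)
#> [1] 0.007057163                 # decay rate 1/t4, rounds to 7e-3 s^-1

# synthetic series with known ground truth -> segment fit recovers it
s <- generate_kinetics(scenario_spec("preacidified_pepsin", noise_cv = 0))
fit <- fit_phase3(s, fit_spec("phase3"))
fit$estimates[c("t4", "V_inf")]
#>    t4  V_inf
#> 141.7   55.5                    # decay time constant (s), plateau (pL)
```

The numbers mean: with the tabulated rate coefficients (RC2 = 0.005 s⁻¹,
RC3 = 0.1533 fL·s⁻¹) the particle settles at A∞ ≈ 11.8 µm², 27% of its
initial area (14% of its initial volume); pepsin degrades a pre-acidified
particle with rate ≈ 7·10⁻³ s⁻¹ down to a 55.5 pL plateau, and the
fitting pipeline recovers those generating parameters from synthetic
microscope data.

A command-line wrapper ships at
`system.file("cli", "cmpkin.R", package = "cmpkin")` with `generate`,
`simulate`, `fit` and `convert` subcommands.

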