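---
title: "A minimal phase-ring Markov model of the KaiABC circadian oscillator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A minimal phase-ring Markov model of the KaiABC circadian oscillator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kairing)
```

## The model

The KaiABC system of *S. elongatus* is a post-translational oscillator: the
phosphorylation level of KaiC hexamers cycles with a near-24 h period, driven
by KaiA (which stimulates phosphorylation) and KaiB (which sequesters KaiA
during the dephosphorylation phase). `kairing` implements a deliberately
minimal Markov-state abstraction of this cycle on a phase ring.

A hexamer's progress through the cycle is a phase `phi` on `[0, 2*pi]`:
`phi = 0` is fully dephosphorylated, `phi = pi` fully phosphorylated, and the
arc `(pi, 2*pi)` is the return through the inactive, dephosphorylating
conformation. The half-ring `[0, pi]` is discretized into `N` intervals and
carried by three rungs:

* **P1(j)** — active conformation, KaiA-free, at `phi_j = j*pi/N`;
* **P3(j)** — active conformation, KaiA-bound, same phases;
* **P2(k)** — inactive (KaiB-bound, KaiA-sequestering) states on the return
  arc, `P2(2N - j)` at phase `2*pi - phi_j`.

The edges and their rate laws (see `build_state_space()`):

| transition | rate | meaning |
|---|---|---|
| `P3(j) -> P3(j+1)` | `k3_fwd` (back `gamma1*k3_fwd`) | KaiA-assisted phosphorylation |
| `P1(j) -> P1(j-1)` | `k1` (back `gamma*k1`) | autodephosphorylation; the ultrasensitivity knob |
| `P2(k) -> P2(k+1)` | `k2_fwd` (back `gamma2*k2_fwd`) | dephosphorylation of the inactive form |
| `P1(j) -> P3(j)` | `k_Af * A_f` | KaiA binding |
| `P3(j) -> P1(j)` | `k_Ab0 * alpha^(phi_j - pi)` | unbinding; `alpha > 1` = differential affinity |
| `P1(j) <-> P2(2N-j)`, `phi_j >= phi0` | `omega` | conformational switch |
| `P2(2N) -> P1(0)` | `omega1` | complex dissociation, cycle reset |

The hydrolysis-driven rungs are biased (`gamma`, `gamma1`, `gamma2 <= 1`)
because phosphotransfer is coupled to ATP turnover. `K_d0 = k_Ab0 / k_Af` is
the dissociation constant at full phosphorylation and doubles as the
nutrient proxy: raising `K_d0` mimics lowering %ATP.

Free KaiA closes the loop nonlinearly:
`A_f = max(0, A_T - sum(P3) - eps_seq * sum(P2))` — every P3 state holds one
KaiA and every P2 state sequesters `eps_seq` of them. The ensemble evolves by
the nonlinear master equation `dP/dt = W(P) P` (`rate_matrix()`,
`integrate_clock()`), whose only state dependence is the scalar `A_f`, so the
generator splits as `W = W0 + A_f * B`.

Two structural readings were genuinely open and were resolved as follows.
The P1 rung moves in the *dephosphorylation* direction at rate `k1` with
hydrolysis-ratio reverse `gamma * k1`; `k1 = 0` switches the rung off
entirely. This is what makes the `k1 = 0` model exactly solvable (below) and
what creates the antagonism — phosphorylation in P3 against
dephosphorylation in P1 — that generates ultrasensitivity. `omega1` is
assigned to the reset edge `P2(2pi) -> P1(0)`; the switch `omega` acts both
ways on the `P1`–`P2` rungs at `phi >= phi0`.

## Time-independent solutions

With `k1 = 0`, `eps_seq = 0` and `phi0 = pi`, the stationary state has a
closed form (`fixed_point_exact()`). Interior P1 nodes then touch only their
vertical binding edges, so `k_Af * A_f * P1 = k_Ab0 * alpha^(phi-pi) * P3`
holds exactly node by node, and the P3 and P2 rungs are constant-current
birth–death chains: geometric profiles in `1/gamma1` (resp. `1/gamma2`) plus
an offset proportional to the cycle current `J`. Anchoring the chains at
their top ends keeps the algebra numerically stable (the bottom-anchored
form cancels catastrophically at `gamma^-N ~ 1e14`). A single scalar — the
free-KaiA level, equivalently `b = P3(0)` — remains, fixed by the
self-consistency `A_f = A_T - sum(P3)` and found by a bracketed root solve
on `(0, A_T]`.

For `k1 > 0` (`fixed_point_approx()`) the same vertical-equilibrium relation
is imposed as an ansatz for `phi <= phi0`, with occupancies truncated to
zero above `phi0` (truncation index `j0 = ceiling(N*phi0/pi)`). Summing the
paired P1/P3 balances cancels the vertical fluxes exactly and leaves a small
reduced network whose kernel is the profile; the construction degenerates to
the exact one at `k1 = 0`, `phi0 = pi`. The general-purpose solver
(`fixed_point_numeric()`) is a damped Newton iteration on `W(p) p = 0` with
the analytic rank-one free-KaiA feedback in its Jacobian, seeded from the
analytic constructions; it also recovers the *unstable* stationary state
inside the oscillatory regime, which simulation cannot reach.

```{r fixed-points}
aff <- kai_preset("affinity", alpha = 6)
fe <- fixed_point_exact(aff)
fn <- fixed_point_numeric(aff)
c(residual = fe$residual, agreement = max(abs(fe$p - fn$p)), b = fe$b)
```

## Linear stability and the onset of oscillations

Around a fixed point `p*`, perturbations evolve under
`M = W(p*) + (B p*) (dA_f/dp)^T` — the generator plus the rank-one feedback
of free KaiA (`linearized_operator()`). One eigenvalue is always 0 (mass
conservation) and is excluded; the oscillation onset is the crossing of the
remaining leading eigenvalue into the right half-plane with nonzero
imaginary part, and `2*pi/|Im|` predicts the emerging period
(`stability_report()`, `critical_parameter()`). Gershgorin discs of `M`
(`gershgorin_discs()`) show how the feedback columns push a finite disc area
into the positive half-plane; note that for the bare rate matrix every disc
touches zero exactly, so any instability is carried by the KaiA feedback.

```{r stability}
rep <- stability_report(kai_preset("affinity", alpha = 35))
c(oscillating = rep$oscillating, period = rep$predicted_period)
```

## Study presets

The package ships two calibrated study conditions (`kai_preset()`); all
quantities are in dimensionless model units, with time interpreted in hours
and concentrations relative to total KaiC = 1.

* **`affinity`** — differential-affinity study: `k1 = 0`, `eps_seq = 0`,
  `phi0 = pi`, `A_T = 0.4`, fast strong binding (`k_Af = 250 /h`),
  `k3_fwd = 4 /h`, `k2_fwd = 2.5 /h`, `gamma1 = gamma2 = 0.1`,
  `omega = omega1 = 16 /h`. Substoichiometric KaiA plus strong differential
  affinity produce a limit cycle with a ~24 h period; at `K_d0 = 5` the
  onset sits at `alpha ~ 27`, and the critical `alpha` grows monotonically
  with `K_d0` (oscillations need stronger differential affinity when ATP is
  scarce).
* **`ultrasensitivity`** — ultrasensitivity study at fixed `alpha = 10`:
  sequestration on (`eps_seq = 6`, one KaiA per KaiB-bound monomer of the
  hexamer; `A_T = 0.8`), early switching (`phi0 = 0.8*pi`),
  `gamma = 0.8`, `k_Af = 150 /h`, `omega = 3 /h`, `omega1 = 30 /h`. At
  `K_d0 = 8` the stationary state destabilizes as `k1` crosses ~1.2 /h; the
  oscillatory band closes again above `k1 ~ 3 /h` and disappears entirely
  beyond `K_d0 ~ 13`.

These numbers are this package's own calibration: they were chosen once to
put the model in the regime the biology demands — circadian-scale periods,
onset at moderate differential affinity, ultrasensitivity-rescued
oscillations at low %ATP — and are not fitted to any external dataset. The
phenomenology they reproduce is structural, not numerical: monotone onset
boundaries in `K_d0`, metabolic compensation, near-linear entropy production
in `k1`, plateauing entropy production in `alpha`, and Hill coefficients
that grow with `k1`.

Metabolic compensation emerges without tuning: across the oscillatory
`K_d0` range of the `ultrasensitivity` preset the period changes by only a
few percent while the amplitude and the area of the angle–angular-velocity
orbit (`wavepacket_velocity()`) shrink several-fold. Smaller `K_d0` (more
ATP) speeds the wavepacket but also lengthens its orbit; the two effects
nearly cancel in the period.

## Ultrasensitivity without KaiB

Removing KaiB (`omega = omega1 = 0`, `kaib_free_response()`) confines the
dynamics to the active rungs, which always settle into a steady state. The
stationary phosphorylation versus total KaiA is switch-like: KaiA acts as a
saturated kinase (every KaiA molecule is engaged while phosphorylation
demand exceeds supply) against KaiC's own zero-order dephosphorylation
(`k1`). `hill_coefficient()` quantifies the steepness as
`n_eff = log(81)/log(EC90/EC10)` on the curve's own dynamic range — exact on
ideal Hill curves — with a maximum local log–log slope as the secondary
estimator; the global estimator is the default because amplification-based
definitions in the enzymology literature are global measures, and the two
differ on asymmetric curves.

In this model the Hill coefficient grows with `k1` when `k1` is comparable
to or larger than the phosphorylation rate `k3_fwd` and the P1 ladder ratio
`gamma` is close to 1; for `k1 << k3_fwd` differential affinity dominates
and *grades* the response (unbinding sweeps across `alpha^pi`-fold over the
ring), so the trend reverses. The presets sit in the former regime.

```{r hill}
grid <- exp(seq(log(0.002), log(30), length.out = 60))
u10 <- kai_preset("ultrasensitivity", K_d0 = 10)
vapply(c(2, 18), function(k) {
  hill_coefficient(kaib_free_response(kai_set(u10, k1 = k), grid))
}, numeric(1))
```

## Entropy production

Each reversible edge carries fluxes `J+ = k_f p_source`, `J- = k_b p_target`
and contributes `(J+ - J-) log(J+/J-) >= 0` to the total entropy production
rate (k_B per hour; `entropy_production_stationary()`,
`entropy_production_cycle()` time-averages over an integer number of
detected cycles). Because the ring coarse-grains the full reaction network,
this underestimates the true dissipation; no correction is applied. The rate
is exactly zero on the detailed-balance reference
(`kai_equilibrium_params()`), varies continuously through the oscillation
onset, grows nearly linearly with `k1`, and saturates in `alpha`.

Two numerical guards matter here. Nominally irreversible edges (the reset,
and KaiA binding while the free pool is depleted to zero) receive a floor
rate `reverse_floor` (default 1e-8 /h) so that no flux ratio is infinite.
The floor is orders of magnitude below every physical rate and its effect
on trajectories and fixed points is below the solver tolerances. The
*cycle-averaged* entropy rate is a different matter wherever the limit
cycle spends time with the KaiA pool fully sequestered (`A_f` clamped to
0): the binding edges then run at the floor rate and contribute like
`log(1/reverse_floor)`, so sigma-dot inherits a logarithmic floor
sensitivity of about 4% per decade at the `ultrasensitivity` preset
(1.792, 1.729, 1.665 k_B/h at floors 1e-10, 1e-8, 1e-6). This is the
price of idealizing sequestration as a hard clamp; stationary-state rates
away from the clamp are floor-insensitive. Edges whose both fluxes fall
below 1e-300 contribute zero (the `x log x` limit).

## The stochastic oracle

`gillespie_run()` simulates `n_copies` hexamers on the same network with a
shared discrete KaiA pool (direct-method SSA in compiled code, reproducible
from a seed). It is the independent check that the mean-field master
equation is the right `n -> Inf` limit: from a common initial condition the
empirical occupancies track the deterministic trajectory with deviations
shrinking like `1/sqrt(n)` over `n = 1e2, 1e3, 1e4`. Sequestered KaiA is
tracked as a real-valued pool debit (`eps_seq` per P2 copy), rounded only
when evaluating binding propensities. One caveat the tests respect: over
long windows a large-`n` ensemble stays phase-coherent with a slightly
size-shifted period, so *time-averaged* occupancies do not decrease
monotonically in `n`; trajectory-level deviations do.

## Numerical choices and limitations

* Default grid `N = 20` (63 states). Rung hop rates are defined on this
  reference grid and scale with `N` so the phase-drift velocity is
  grid-independent; at a fixed parameter point deep in the oscillatory
  regime the period then changes by only a few percent between `N = 20` and
  `N = 40`. `N` is nevertheless a *structural* parameter, not a mesh: the
  hydrolysis ratios `gamma*` act per step, so diffusion along the ring
  scales as `1/N`, and the oscillation onset — which is a competition
  between feedback and diffusive decoherence — shifts appreciably with `N`
  (e.g. the critical `alpha` at the `affinity` preset drops from ~27 at
  `N = 20` to ~10 at `N = 40`). Physically `N` stands for the finite number
  of coarse-grained phosphorylation steps of the hexamer; all preset
  calibrations fix `N = 20`.
* Integration: `deSolve::lsoda`, relative tolerance 1e-8, analytic Jacobian
  supplied; mass drift is renormalized beyond 1e-9 and an error beyond 1e-6.
* Period detection: local maxima of the phosphorylation signal with
  quadratic sub-sample interpolation after discarding a 30% transient;
  flat signals (span < 1e-4) are stationary, and cycle-to-cycle spacing
  drift above 5% raises "not converged" rather than returning a number.
  Near onset the linear growth rate can be ~1e-3 /h, so trajectories are
  extended to ~12 growth times before measuring, capped at `t_max`.
* Fixed-point root selection: the admissible free-KaiA root lies in
  `(0, A_T]` and is unique in all parameterizations explored; the bracket
  endpoints have opposite signs by construction.
* The `phi0 = pi` limit makes the exact solution available but also places
  the whole switch at full phosphorylation; the `ultrasensitivity` preset
  uses `phi0 = 0.8*pi`, for which all analytic profiles are truncated
  approximations (`method = "analytic-truncated"`).
* The model has no site-resolved hexamer states, no explicit KaiB binding
  kinetics, and no entrainment input; synthetic-preset numbers (onset
  values, entropy costs) characterize this abstraction, not measured
  KaiABC rate constants. Passing tests demonstrate internal consistency of
  the mean-field/stochastic/analytic routes, not agreement with wet-lab
  kinetics.
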