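---
title: "The Coulomb-force channel-hopping model of unmyelinated conduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Coulomb-force channel-hopping model of unmyelinated conduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonhop)
```

## The model and its assumptions

Classical cable theory treats the axon as a distributed RC line. The model
implemented here starts from a different observation: at typical NaV channel
densities (5–50 channels/µm²) and conduction velocities (~1 m/s), conduction
can spend less than a microsecond per channel, while generating an action
potential at a channel takes a hundred microseconds or more. Whatever
propagates must therefore run ahead of the action potential. The model's
candidate is the Coulomb force of the sodium charge accumulating at the last
opened channel, acting on the ions crowded around the next channel and
triggering its conformational opening once a threshold force is crossed.

The assumptions, each visible in the code:

* **Ring lattice.** Channels sit on evenly spaced rings ("channel lines")
  around the axon. With density $C_d$ the rings are $C_d^{-1/2}$ µm apart
  and a ring on a diameter-$D$ axon carries $\pi D \sqrt{C_d}$ channels, so
  count × central angle closes the ring at exactly $2\pi$
  (`channel_lattice()`). Density is constant along one axon; no clustering,
  no hard-core exclusion.
* **Uniform hop angle.** The line to the next channel makes an angle
  $\theta$ with the longitudinal direction, uniform on $[-\pi/6, \pi/6)$
  (density $3/\pi$); the hop covers
  $r(\theta) = (\sqrt{C_d}\cos\theta)^{-1}$, bounded between the ring
  spacing and $2/\sqrt{3}$ times it. The interval is half-open exactly as
  defined; the endpoint has measure zero, so samplers and validators simply
  share the convention.
* **Constant influx window.** The sodium inflow rate through an open channel
  is constant within the first 1.0 µs, so the accumulated charge is
  $Q_1 t$ and the Coulomb force at distance $r$ is
  $k\,Q_1 t\,e/r^2$ — linear in $t$, inverse-square in $r$, equal in
  magnitude for cations (repulsive) and anions (attractive). The window is
  a hard model-validity bound: `hop_time()` and `simulate_conduction()`
  refuse hops that would outlast it rather than extrapolating the linear
  law beyond its stated domain.
* **Threshold semantics.** The next channel opens when the instantaneous
  force reaches `threshold_force`. Because the force is linear in $t$, a
  threshold on time-accumulated force would differ only by a constant
  factor, which the calibration would absorb; the instantaneous convention
  reproduces the inverse-density hop-time law verbatim.

## The mean hop distance, and a discrepancy

Averaging $r(\theta)$ over the uniform angle gives

$$\langle r\rangle \;=\; \int_0^1 \frac{dx}{\sqrt{C_d}\,\cos(\pi x/6)}
\;=\; \frac{3\ln 3}{\pi}\,C_d^{-1/2} \;\approx\; 1.0492\,C_d^{-1/2}.$$

The package evaluates this integral three independent ways —
`mean_hop_distance_closed()`, the defining Riemann sum
(`mean_hop_distance_riemann()`, a right-endpoint sum of an increasing
integrand, hence monotone from above), and Monte Carlo
(`mean_hop_distance_mc()`) — and the tests require them to agree
(quadrature to $10^{-9}$ relative, sampling within 3 standard errors).

The original publication of this model reports the constant as
$\pi\ln 3/12 \approx 0.2875$ instead. That value cannot be right: no hop is
shorter than the ring spacing $C_d^{-1/2}$ itself, and the substitution step
that produced it multiplies by $\pi/6$ where the change of variables
requires $6/\pi$. The package exposes the reported value through
`reported_mean_hop_constant()` for comparison but never uses it; every
downstream conclusion rests only on the $C_d^{-1/2}$ proportionality, which
both constants share.

```{r}
c(correct = mean_hop_distance_closed(1), reported = reported_mean_hop_constant())
```

## Units, calibration and the diameter–density coupling

Lengths are µm, times ns, angles radians throughout. Forces and charges use
**reduced units**: the Coulomb constant and the elementary charge default
to 1, so the model's proportionalities hold verbatim without unit
bookkeeping; `coulomb_field(physical = TRUE)` switches to
$k = 1/(4\pi\varepsilon_0\varepsilon_r)$ with $\varepsilon_r = 80$ as an
extension. The charge-budget functions, which produce physical particle
counts, use the physical constants (capacitance $10^{-14}$ C/(V µm²),
$e = 1.602\times10^{-19}$ C, $N_A = 6.02\times10^{23}$).

Neither the threshold force nor $Q_1$ is known absolutely, so the model
fixes only ratios; `calibrate_reference()` pins the time scale by scaling
the threshold so the expected velocity hits a target (default 1 m/s) at a
reference diameter. Two deliberate conventions:

* **Reference at $D = 0.2$ µm.** Anchoring 1 m/s at the *smallest* typical
  fibre keeps every hop across the full density range 5–50 channels/µm²
  inside the 1 µs validity window. An anchor at mid-range ($D = 0.6$) would
  put the slowest fibres ($C_d = 5$) at 0.45 m/s, i.e. mean hop times of
  exactly 1000 ns with sampled hops beyond it — the simulator would
  (correctly) refuse to run at the low end of its own stated parameter
  range. With the small-fibre anchor, mid-range fibres conduct at
  $\sqrt{3} \approx 1.7$ m/s, still the order of magnitude observed for
  unmyelinated fibres. Calibration is idempotent and a pure scale
  transformation; the tests verify both.
* **$C_d = \alpha D$ with $\alpha = 50/1.2$.** The importation/breakdown
  equilibrium argument yields proportionality only; the default maps the
  top of the typical diameter range (1.2 µm) to the top of the typical
  density range (50 channels/µm²). A convention, overridable, not a
  measured value.

## The simulator

`simulate_conduction()` is a discrete-event walk over
$\lfloor L\sqrt{C_d}\rfloor$ ring transitions. The default geometry mode is
`"sampled"`: each hop draws its own $\theta$, and since hop time grows as
$r^2$, the mean hop time exceeds the nominal-spacing hop time by
$\mathbb{E}[\sec^2\theta] = 2\sqrt{3}/\pi \approx 1.1027$. `"nominal"` mode
uses the ring spacing for every hop — the degenerate deterministic case that
reproduces the inverse-density hop-time law exactly and is used as an exact
oracle in the tests. Both modes share the closed-form expectation
`expected_velocity_closed()`, and both scale as $\sqrt{C_d}$; only the
constant differs. Velocity is computed over the span of *completed* hops
(count × ring spacing) divided by the summed hop times; expectation-level
quantities stay real-valued while event counts floor (minimum one ring or
channel), since the model itself never discretizes.

In `"superposed"` force mode, all previously opened rings at 1, 2, 3, …
spacings contribute force in the ratio $1, 1/4, 1/9, \dots$; hop times
shrink by exactly the partial sum of $\sum 1/n^2$ (`superposition_factor()`,
$\pi^2/6$ in the infinite-ring default, finite `n_lines` available for axon
ends). Since the factor is a constant, no scaling exponent moves — the tests
check the hop-time ratio to machine precision and the sweep slopes across
modes.

`scaling_sweep()` runs replicate simulations over a grid of densities or
diameters and regresses log mean velocity on the log of the variable. The
slope's standard error is obtained by propagating the per-point Monte-Carlo
standard errors through the least-squares weights rather than from the
regression residuals: with only a handful of grid points the residual-based
estimate has too few degrees of freedom to be well calibrated, while the
per-point errors rest on the full replicate count. Every stochastic
function takes an explicit seed, restores the global RNG state, and records
the seed in its output.

### Problem sizes

The shipped verification uses desk-scale runs chosen to make the Monte-Carlo
error budgets meaningful: $10^6$ draws for distribution moments and mean-hop
estimates, 200 replicates × 1 mm axons (2200–7100 hops each) per grid point
for the scaling sweeps, $10^5$ hops for mean-hop-time checks. At these sizes
the whole suite runs in seconds and slope standard errors land near
$10^{-4}$, far inside the 0.02 budget the sweep contract promises.

## The membrane side

`ghk_voltage()` evaluates the GHK equation with chloride's in/out terms
swapped relative to the cations — the standard convention for a monovalent
anion, implemented exactly as written. It reduces to each ion's Nernst
potential as the other permeabilities vanish, is zero for a symmetric
milieu, and negates under a full in/out swap; the tests pin all three
properties plus hand-evaluated oracles (−89.06 mV for the potassium limit at
140/5 mEq/l and 310.15 K). Temperature defaults to 310.15 K (mammalian);
concentrations are mEq/l, identical to mmol/l for the monovalent species
modelled. Potentials are computed in volts and reported in mV.

The charge budgets implement the worked arithmetic: $\pi DL/1.602\times
10^{-4}$ ions transferred per action potential,
$2.33\times10^7\,\pi D^2 L$ resident cations, and their ratio
$\approx 3.73\times10^3 D$ — resident cations outnumber the influx more than
a thousandfold over nearly the whole diameter range, which justifies
treating the axoplasm composition as fixed and considering only
adjacent-ring Coulomb interactions. (The package computes the ratio's
coefficient exactly, 3737 per µm; the rounder 3730 arises when the cation
coefficient is rounded to three figures first.) `feasibility_report()`
packages the time-budget argument that motivates the model.

## What the stochastic verification does and does not show

The only randomness in the model is the hop angle; the generator draws it
from exactly the uniform law the model postulates. Agreement between the
simulator and the closed forms therefore verifies the implementation and
the internal consistency of the model — it cannot, and does not claim to,
validate the uniform-angle postulate, the ring-lattice idealization, or the
$C_d \propto D$ equilibrium against real axons. Real channel placement is
irregular, densities vary along the axon (especially near the hillock), and
the "next channel" selection rule (uniform within one sector) is a
modelling choice the source leaves implicit.

## Known limitations

* Proportionality only: absolute velocities exist solely through the
  calibration anchor; the model predicts exponents, not intercepts.
* No refractoriness, wavefront collisions, branch points, or myelinated
  (saltatory) conduction; no channel gating kinetics; the bare Coulomb force
  is used without Debye screening or hydration-shell effects.
* The GHK flux equation, time-dependent membrane charging and pump/leak
  kinetics are out of scope; only the steady-state voltage and static charge
  budgets are implemented.
* The 1 µs validity window is enforced, not modelled: parameter choices
  whose hops approach it are near the edge of the model's own domain, and
  the default calibration is chosen to stay away from that edge.
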