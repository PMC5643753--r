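# axonhop

Conduction of the action potential along an unmyelinated axon, modelled not
as a cable of distributed resistors and capacitors but as a chain of
threshold-crossing **hops** between rings of voltage-gated sodium (NaV)
channels. When one channel opens, sodium influx builds a growing point
charge; the Coulomb force from that charge rearranges the ions around the
next channel ring until a threshold is crossed and the next channel opens.
`axonhop` implements this model as a tested simulator and library for
computational neurophysiologists who want to explore its geometry, charge
budgets and scaling laws.

## The model

With channel surface density *C<sub>d</sub>* (channels/µm²), channels sit on
rings spaced *C<sub>d</sub>*<sup>−1/2</sup> µm apart; a ring on an axon of
diameter *D* carries *πD√C<sub>d</sub>* channels. The hop to the next ring
leaves at an angle θ uniform on [−π/6, π/6), covering the distance
*r*(θ) = (√C<sub>d</sub> cos θ)<sup>−1</sup>, whose mean is
(3 ln 3)/π · *C<sub>d</sub>*<sup>−1/2</sup> ≈ 1.0492 · *C<sub>d</sub>*<sup>−1/2</sup>.
The sodium influx is constant within the first microsecond, so the Coulomb
force at distance *r* grows linearly in time and the threshold is crossed at

> *t*(r) = threshold · *r*² / (k Q₁ e S),

with *S* the multi-ring superposition factor (partial sums of Σ 1/n²,
converging to π²/6). A length *L* spans *L√C<sub>d</sub>* rings, so the
conduction velocity scales as

> CV ∝ √C<sub>d</sub> ∝ √D,

the second step via the importation/breakdown equilibrium *C<sub>d</sub>* ∝ *D*.
The absolute time scale is not determined by the model (neither the
threshold force nor Q₁ is known absolutely); the package pins it by
calibrating to 1 m/s for the smallest typical fibre, a pure scale factor
that leaves every exponent untouched.

The membrane side of the model is covered too: the Goldman–Hodgkin–Katz
(GHK) voltage, the ~πDL/1.602×10⁻⁴ sodium ions needed per action potential,
the 2.33×10⁷·πD²L resident intracellular cations, their ratio
(~3.73×10³·D), and the per-channel time budget showing each channel gets
well under a microsecond during conduction.

## Worked example

```r
library(axonhop)

# How long does conduction spend at each channel? (10 cm axon, Cd = 5, 1 m/s)
feasibility_report()
#>   axon_length_um density_per_um2 ... total_travel_time_s per_channel_time_s within_budget
#> 1         100000               5 ...                 0.1           4.47e-07          TRUE
```

The whole axon is crossed in 0.1 s; divided over the 2.24×10⁵ channels on a
longitudinal line, each channel gets 4.5×10⁻⁷ s — under the 10⁻⁶ s budget,
and far less than action-potential generation itself takes, which is the
point of the model: conduction runs ahead of the action potential.

```r
mod <- propagation_model(diameter_um = 0.6) # Cd = alpha * D = 25 channels/um^2
glance(simulate_conduction(mod, length_um = 1000, seed = 1))
#>   density_per_um2 diameter_um n_lines span_um total_time_ns conduction_velocity_m_per_s
#> 1              25         0.6    5000    1000      579381.3                    1.725979

fit <- scaling_sweep(mod, "density", c(5, 10, 20, 50), reps = 50, length_um = 500, seed = 1)
fit
#> <scaling_fit>
#>   log(velocity) ~ log(density), 4 grid points x 50 reps
#>   slope: 0.5001 +/- 0.0002 (r^2 = 1.0000); model prediction 0.5
```

A 1 mm conduction at mid-range parameters crosses 5000 rings in 0.58 ms
(1.73 m/s: √3 times the 1 m/s calibrated for the smallest fibre, since
velocity grows as √D). The log–log sweep over the reported density range
recovers the square-root law: slope 0.5001 ± 0.0002. `autoplot(fit)` draws
the fit; `tidy()`/`glance()` return the results as tibbles.

A thin CLI wraps the same functions (`inst/cli/axonhop`):

```sh
Rscript inst/cli/axonhop feasibility
Rscript inst/cli/axonhop geometry --density 25 --format csv
Rscript inst/cli/axonhop sweep --grid 5:50:4 --log --reps 50 --seed 1 --out sweep
```

## Further reading

The methods vignette (`vignettes/conduction-model.Rmd`) documents the model
assumptions, the unit system, the calibration and coupling conventions, a
known discrepancy in the originally reported mean-hop-distance constant,
and what the simulator does and does not capture about real axons. Run
`Rscript inst/cli/axonhop --cite` for the model's source reference.
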