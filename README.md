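# entropore

Stochastic simulation of substrate translocation through membrane
transporters modeled as periodically breathing entropic channels.

## The problem

Membrane transporters (ABC exporters, secondary active transporters)
move nutrients, ions and drugs across the plasma membrane by
*alternating access*: the protein cavity cyclically opens to one side
of the membrane and then the other. Their turnover rates span
10⁻¹–10³ s⁻¹, versus ~10⁶ s⁻¹ for ion channels. `entropore` is for
biophysicists and modelers who want a minimal, quantitative model of
this cycle: it represents the transporter as a conical channel of
length *L* whose radius breathes between *h*<sub>min</sub> and
*h*<sub>max</sub> at angular frequency ω,

&nbsp;&nbsp;&nbsp;&nbsp;*h*(*x*,*t*) = (*h*<sub>max</sub> −
*h*<sub>min</sub>)(*x*/*L* − ½) sin ω*t* +
(*h*<sub>max</sub> + *h*<sub>min</sub>)/2,

and integrates the Langevin dynamics of a substrate particle under
three forces:

&nbsp;&nbsp;&nbsp;&nbsp;γ*v* = *F*<sub>ent</sub> + *F*<sub>μ</sub> + *F*<sub>r</sub>,

where *F*<sub>ent</sub> = *k*<sub>B</sub>*T* ∂<sub>x</sub> ln *A*(*x*,*t*)
is the entropic (Fick–Jacobs) force of the varying cross-section
*A* = π*h*², *F*<sub>μ</sub> = *f*<sub>μ</sub>*k*<sub>B</sub>*T*/*L* a
constant chemical-gradient force, and *F*<sub>r</sub> thermal noise
with ⟨*F*<sub>r</sub>(*t*)*F*<sub>r</sub>(*t*′)⟩ =
2*k*<sub>B</sub>*T*γ δ(*t*−*t*′). Trajectories start at the entrance
with Boltzmann velocities (*T* = 300 K) and a uniformly drawn
oscillation phase, and end at the absorbing exit (no re-entry). The
transport rate is

&nbsp;&nbsp;&nbsp;&nbsp;Γ = *V*/*L* = ⟨1/τ⟩,

the ensemble mean of per-trajectory time-averaged velocities over the
first-passage times τ. Sweeping the dimensionless frequency
Ω = ω*L*²/*D* — the ratio of the diffusion time to the conformational
cycle time — locates the optimal breathing frequency, and
`to_physical_rate()` maps Γ back to turnover rates in s⁻¹.

The integrator is the Grønbech-Jensen–Farago stochastic
Velocity-Verlet with a Brownian-bridge absorption correction, and the
package ships an exact mean-first-passage-time quadrature oracle that
validates the simulator in every static (frozen-channel) limit.

## Worked example

```r
library(entropore)

# a transporter: L = 10 nm, D = 1e-2 um^2/s, breathing at 3000 /s
# (Omega = 30), moderate chemical force
cfg <- run_config(omega = 3000, f_mu = 0.5, n_particles = 2000, seed = 42)
est <- estimate_rate(simulate_ensemble(cfg), cfg)
est
#> <rate_estimate> Gamma = 4.437 +/- 0.081 (dimensionless), 2000/2000 successes

to_physical_rate(est$gamma_dimless, D = cfg$D, L = cfg$L)
#> [1] 443.7492
```

A dimensionless rate of 4.44 means a substrate translocates in roughly
0.23 diffusion times; at transporter scales (one diffusion time
*L*²/*D* = 10 ms) that is ≈ 440 turnovers per second — inside the
measured 10⁻¹–10³ s⁻¹ range. The same dimensionless rate at ion-channel
diffusivities (*D* = 10³ µm²/s) gives ≈ 4.4 × 10⁷ s⁻¹.

Sweeping the breathing frequency and locating the resonance:

```r
sw <- sweep_frequency(default_omega_grid(12, c(3, 100)), c(0.1, 1), cfg)
find_peak(sw, f_mu = 1)$omega_peak    # 18.7
find_peak(sw, f_mu = 0.1)$omega_peak  # 15.8
plot(sw)
```

The rate is maximal at intermediate breathing frequencies
(a broad optimum around Ω ~ 10–30: slower breathing wastes time in
unfavourable conformations, faster breathing reverses the expelling
force mid-transit) and the peak grows with *f*<sub>μ</sub> — rates
increase with substrate concentration. The peak *location* is flat
enough that its interpolated position moves by a factor ~2 between
seeds at this sampling depth; see the methods vignette.

The oracle suite cross-validates the simulator against closed forms
(Einstein relation, equipartition, Boltzmann sampling, and exact
static-channel first-passage quadrature at three frozen phases × three
chemical forces):

```r
validate_simulator(seed = 1)
#>                         check observed expected pass
#> 1  free diffusion: MSD slope = 2D  1.998    2.000 TRUE
#> 2   free diffusion: <v^2> = kBT/m  1000.1  1000.0 TRUE
#> ...                                                TRUE
```

A YAML config loader (`load_config()`) and a thin CLI
(`inst/cli/entropore` with subcommands `simulate`, `sweep`, `peak`,
`validate`, `geometry-dump`) wrap the same functions for shell use.

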