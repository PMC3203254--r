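# rta — receptor–toxin–antibody kinetics around a single cell

`rta` simulates how well a neutralizing antibody protects a cell from a
receptor-binding toxin when the competition between receptor binding,
antibody complexation and *diffusion* of all species is taken into account.
It is aimed at modellers and experimentalists doing in-vitro antibody
selection who need a mechanistic estimate of the protection an antibody
affords, and of the time window during which applying it matters most.

## The model

A spherical cell of radius ρ_c sits at the centre of an extracellular
shell ρ ∈ [ρ_c, ρ_e] filled with toxin T, antibody A and their complex C.
In nondimensional form the species obey reaction–diffusion equations

    ∂t uT = −k₁ uT uA + k₋₁ uC + κ_T Δ uT
    ∂t uA = −k₁ uT uA + k₋₁ uC + κ_A Δ uA
    ∂t uC = +k₁ uT uA − k₋₁ uC + κ_C Δ uC

with Dirichlet conditions (uT⁰, uA⁰, 0) on the outer surface, zero flux for
A and C at the cell wall, and a reactive (Robin) wall condition for toxin
coupled to the surface receptor occupancy θ(t):

    κ_T ∂ρ uT |ρc = r₀ (k₂(1−θ) uT − k₋₂ θ),
    dθ/dt = k₂(1−θ) uT − k₋₂ θ − k₃ θ,

where r₀ is the surface receptor concentration and k₃ the internalization
rate of receptor-bound toxin. The figure of merit is the antibody
protection factor

    ψ(t) = θ(t; uA⁰ > 0) / θ(t; uA⁰ = 0),

the relative reduction of receptor-bound toxin due to the antibody (lower
is better). The package provides:

* an implicit finite-difference solver for the full PDE system
  (`simulate_rd()`, compiled core, backward Euler or Crank–Nicolson, with
  grid-convergence certification via `grid_convergence_study()`);
* the well-mixed-solution (WMS) ODE reduction with depletion
  (`integrate_wms()`, stiff-capable via deSolve);
* five estimators of the saturation value ψ^sat: the steady-state root and
  closed-form estimators and the long-time ODE ratio (`psi_sat_wms()`),
  plus the long-time occupancy ratio and the wall-concentration isotherm
  from the PDE (`psi_sat_pde()`);
* closed-form transport diagnostics — conductance/flux, bioavailability
  number L = K\*k₃ρ_c/κ\*, effective mean diffusivity, and the asymptotic
  prefactor ψ\* = (1+L₀)/(1+L₀/p) — for classifying diffusion-limited vs
  internalization-limited uptake (`transport_diagnostics()`).

## Worked example

```r
library(rta)
p <- default_params()        # canonical nondimensional parameter set
derived_constants(p)
#> Derived constants:
#>   K1     = 0.0107692
#>   K2     = 0.0416
#>   eps    = 3.86286
#>   b      = 0.00264
#>   k4     = 0.00375047
#>   R0     = 7.93224e-06
#>   K_star = 0.000736023

## WMS saturation estimators
p0 <- p; p0$rates$k3 <- 0
psi_sat_wms(p0, "root")          # 0.215523
psi_sat_wms(p0, "closed_form")   # 0.215524
psi_sat_wms(p,  "long_time")     # 0.206474  (with internalization)

## full reaction-diffusion run, paired with and without antibody
st <- rd_settings(N = 201, dt = 1)
sA <- simulate_rd(p, st, 1e4, detect_steady = FALSE)
s0 <- simulate_rd(p, st, 1e4, uA0 = 0, detect_steady = FALSE)
psi_timecourse(sA, s0)
#> Protection curve psi(t): 10001 points on [0, 10000]
#>   estimator: theta ratio (reaction-diffusion model)
#>   final psi = 0.933883, min psi = 0.723762 at t = 137
```

At the default diffusivities the protection curve is non-monotonic: the
antibody sequesters free toxin early (ψ dips to 0.72 at t ≈ 137), after
which diffusion replenishes the wall and ψ relaxes to its saturation value
0.934 — the dip is the "window of opportunity" during which the antibody
is most effective. Lowering κ_T to 1e-4 removes the dip and drives ψ
monotonically to a far smaller saturation value (strong protection).

`psi_saturation_report("wms")` / `psi_saturation_report("pde")` recompute
every estimator across the shipped rate and diffusivity sweeps and compare
them side by side with the stored published reference values.

A JSON configuration interface (`parse_config()`, see
`inst/extdata/default_params.json`) and a thin command-line front end
(`inst/cli/rta.R`, subcommands `simulate-wms`, `simulate-pde`, `psi-sat`,
`transport-diagnostics`, `reproduce`) cover scripted use.

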