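# sflt1sim

Mechanistic kinetic modeling of sFLT1 (sVEGFR1) secretion by endothelial
cells.

sFLT1 is a secreted splice isoform of VEGF receptor 1 that traps
VEGF-family ligands without signaling; it patterns blood-vessel growth
and, when dysregulated, drives preeclampsia. Quantitative time courses of
sFLT1 in conditioned media and in cell lysates (ELISA, quantitative
Western blots, pulse-chase labeling) contain enough information to
constrain a compartmental model of its production, maturation, secretion
and degradation — this package provides that model family and everything
needed to exercise it: simulation of the two standard experimental
protocols, multistart fitting, model selection, flux and sensitivity
analysis, inhibition simulation, and a synthetic-data generator. It is
aimed at quantitative cell biologists and systems-biology modelers
working on protein trafficking or the VEGF axis.

## The model

Intracellular sFLT1 `I` and extracellular sFLT1 `X` (both #/cell) evolve
by mass-action kinetics:

    dI/dt = α − β·I(t−τ) − γ·I(t−τ)  [+ ε·X]
    dX/dt = β·I(t−τ) − δ·X           [− ε·X]

with production α (#/cell/h), secretion β, intracellular degradation γ,
extracellular degradation δ (1/h), and three optional processes that
define eight candidate structures M1–M8: a maturation delay τ (h) that
makes the system a delay differential equation (M2 = delay only),
first-order internalization ε, and exponential production decay κ during
the chase phase of pulse-chase experiments. Useful closed forms:

    I_SS = α/(β+γ)        X_SS = αβ/(δ(β+γ))
    T50_I = ln2/(β+γ)     T50_X = ln2/δ
    c1 = αβ               c2 = β+γ

The compound constants c1, c2 are what extracellular-only data actually
pin down: with δ and τ they leave exactly one free direction in (α, β,
γ), which a single absolute intracellular measurement closes.

## Worked example

```r
library(sflt1sim)

p <- reference_params()          # packaged ensemble-median parameters
steady_state(p)
#> $I_SS  821513.3   $X_SS  732824.8   $T50_I  4.0129   $T50_X  12.069
compound_constants(p)
#> $c1  7269.537     $c2  0.17273

# constitutive secretion: equilibrate, media change at t = 0, 72 h
traj <- simulate_constitutive(p)
trajectory_values(traj, c(24, 72), "X")
#> [1] 548151.3 721097.2

# +10% parameter bumps: fractional output change per fractional change
local_sensitivity(p)
#>    parameter output   sensitivity
#> 1      alpha   X72h  1.000000e+00
#> 2      alpha   I72h  1.000000e+00
#> ...
#> 10     delta   X72h -8.590188e-01
#> 11     delta   I72h  8.502503e-15
#> 13       tau   X72h  4.366499e-07
```

`steady_state()` says a cell at the reference parameters holds ~8.2×10⁵
sFLT1 molecules and exports at most ~17% of the mature pool per hour;
`local_sensitivity()` shows both 72 h outputs scale one-for-one with
production (sensitivity 1), while δ shapes only the extracellular pool
and the maturation delay is invisible in constitutive culture.

Fitting and recovery on synthetic data emulating the three published
experimental designs:

```r
designs <- list(synthetic_design("hornig_like", noise_cv = 0),
                synthetic_design("kinghorn_like", noise_cv = 0),
                synthetic_design("jung_like", noise_cv = 0))
rec <- recovery_experiment(p, designs, fit_config(n_starts = 50, seed = 1))
rec$errors   # delta, tau, c1, c2 recovered to <1%; alpha/beta/gamma spread
```

A thin command-line wrapper over the same functions ships in
`inst/cli/sflt1-tools.R` (subcommands `simulate`, `synth`, `fit`,
`compare-models`, `sensitivity`, `fluxes`, `inhibit`, `invert`,
`recover`; each writes tidy CSV/JSON plus a `manifest.json` echoing the
config and seed).

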