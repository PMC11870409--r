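---
title: "Modeling sFLT1 secretion: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling sFLT1 secretion: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sflt1sim)
```

## The biological problem

Soluble FLT1 (sFLT1, also called sVEGFR1) is a secreted splice isoform of
VEGF receptor 1. It binds VEGF-family ligands without signaling and so
acts as a ligand trap that shapes VEGF gradients during blood-vessel
growth; its dysregulation is central to preeclampsia. Endothelial cells
secrete sFLT1 constitutively, and recent quantitative experiments track
both the protein exported into conditioned media and the surprisingly
large pool retained inside cells. This package provides the mechanistic
machinery to interpret such time courses: a family of compartmental
kinetic models, the simulation protocols matching the two standard
experimental designs, and the estimation and perturbation analyses built
on top of them.

## The model family

Two well-mixed pools are tracked in units of molecules per cell:
intracellular sFLT1 $I$ (all endomembrane compartments pooled) and
extracellular sFLT1 $X$ (conditioned media). The core skeleton has four
processes with mass-action kinetics:

$$\frac{dI}{dt} = \alpha - \beta I - \gamma I, \qquad
  \frac{dX}{dt} = \beta I - \delta X,$$

with zeroth-order production $\alpha$ (#/cell/h), first-order secretion
$\beta$, intracellular degradation $\gamma$, and extracellular
degradation $\delta$ (all 1/h). Three optional processes generate a
family of eight candidate structures (M1–M8):

* **maturation delay** $\tau$ (h): secretion and intracellular
  degradation act on $I(t-\tau)$, representing transit of newly made
  protein through the secretory pathway — this turns the system into a
  delay differential equation (M2 is the skeleton plus this delay);
* **internalization** $\varepsilon$ (1/h): first-order uptake
  $X \to I$;
* **production decay** $\kappa$ (1/h): during the chase phase of a
  pulse-chase experiment, production decays as $\alpha e^{-\kappa t}$
  instead of stopping instantly, representing gradual depletion of
  labeled amino acids.

Absent processes are stored as exact zero rate constants so one
right-hand side (compiled in C, solved with `deSolve`'s stiff ODE and
delay solvers) serves all eight structures. One subtlety: a model
*without* production decay has chase production 0, which is the
$\kappa \to \infty$ limit of the decay term, not $\kappa = 0$ (at
$\kappa = 0$ production would continue at full rate). The fitting bounds
for $\kappa$ therefore extend to $10^4$/h so the no-decay boundary is
numerically reachable, and model comparison warm-starts added-$\kappa$
models at that upper bound.

Closed forms used throughout: the constitutive steady states
$I_{SS} = \alpha/(\beta+\gamma)$ and
$X_{SS} = \alpha\beta/(\delta(\beta+\gamma))$ (delay-independent, since
$I(t-\tau)=I(t)$ at steady state), the half-times
$T_{50,I} = \ln 2/(\beta+\gamma)$ and $T_{50,X} = \ln 2/\delta$, and the
compound constants $c_1 = \alpha\beta$, $c_2 = \beta+\gamma$ with the
bounds $I_{SS} \ge c_1/c_2^2$, $\alpha \ge c_1/c_2$,
$\beta,\gamma \le c_2$. With internalization the steady state
generalizes to $I_{SS} = \alpha(\delta+\varepsilon)/(\delta(\beta+\gamma)
+ \gamma\varepsilon)$, which the implementation uses; the reported
half-times keep their simple first-order forms.

## Simulation protocols

**Constitutive secretion.** Cells equilibrate before the measurement
window: starting from an empty system, the model is integrated until $I$
changes by less than 0.5% over a sliding 20 h window, evaluated on the
1-minute reporting grid with first-crossing semantics (capped at
2000 h). The media change at $t = 0$ then resets $X$ to 0 while $I$ and
its delay history carry over unchanged; the experiment runs 24–72 h.
Two implementation notes. First, the zero/zero guard of the convergence
criterion (needed when $\alpha = 0$) requires $I$ to be zero over the
*whole* window: strongly delayed parameter combinations
($(\beta+\gamma)\tau \gg 1$) oscillate through zero and would otherwise
satisfy an endpoint-only check spuriously. Second, very long delays
genuinely interfere with this equilibration recipe (the system may never
meet the criterion and the pre-simulation errors out at the cap); the
package treats such parameter sets as failed trial points rather than
special-casing them.

**Pulse-chase.** Only labeled (newly synthesized) protein is modeled, so
the system starts empty with zero history; production runs for a
20-minute pulse, then at $t = 0$ the media change resets $X$ and
production switches off (or decays with $\kappa$). The chase runs 10 h.
With the delay model, labeled protein cannot appear extracellularly
before $\tau$ minus the pulse length — the feature that makes $\tau$
identifiable from pulse-chase data and invisible in constitutive data.

Integration uses tolerances of $10^{-12}$ (absolute) / $10^{-8}$
(relative) for ODE models and $10^{-4}$ / $10^{-3}$ for delay models on
the reporting grid, with tiny solver-induced negative values clamped to
zero. Discontinuities (media change, production switch) are handled by
segmenting the integration at the known event times, with the delayed
argument served by an interpolant of the previous segment.

## Datasets and the cost function

Experiments come in two unit systems: absolute concentrations
(ELISA-like, ng/mL) and relative intensities (Western-blot-like,
normalized to an anchor time point). Datasets are tidy CSVs with a
metadata sidecar carrying the scenario, units, anchors, and — for
absolute data — the conversion constants (cells per volume of medium,
molar mass) that map #/cell to ng/mL. Preprocessing drops points flagged
as excluded and collapses replicates to per-time-point means.
Predictions are converted into each dataset's units (normalizing the
simulated series at the dataset's anchors for relative data), matched to
observation times by linear interpolation on the 1-minute grid, and
scored by unweighted squared relative error
$((\mathrm{sim}-\mathrm{obs})/\mathrm{obs})^2$. Because the residuals
are relative, the cost is invariant to any common rescaling of a
dataset's units. Observed zeros make the relative error undefined and
are rejected as a configuration error.

## Multistart fitting

Each start draws initial values log-uniformly per parameter
($\alpha \in [10^3, 10^7]$, $\beta,\gamma,\delta \in [10^{-4}, 10]$,
$\varepsilon \in [10^{-4}, 10]$, $\kappa \in [10^{-2}, 10^4]$; $\tau$
uniformly on $[0, 8]$ h since its range includes zero), all overridable
in `fit_config()`. Optimization is bounded Levenberg–Marquardt least
squares (`minpack.lm`) on the residual vector, with $\alpha, \beta,
\gamma, \delta$ optimized on a log10 scale and the optional-process
parameters on a linear scale so their zero boundary is reachable.
Simulations inside the optimizer run the full protocol (including the
pre-simulation, memoized per parameter point) but at tighter integration
tolerances (relative $10^{-6}$) than the reporting contract, and the
finite-difference jacobian uses an enlarged step (`epsfcn = 1e-6`,
i.e. about 0.1% of each transformed parameter): at the reporting
tolerances, solver noise swamps the numerical derivatives and every
start stalls. Failed trial simulations (unstable delayed feedback,
pre-simulation cap) map to a large finite penalty so the optimizer
retreats; starts whose entire neighborhood is pathological converge
"immediately" on the penalty plateau and are removed by the acceptance
filter.

Accepted fits are those with cost within 10% of the minimum. On
noiseless synthetic data the minimum is solver noise ($\sim 10^{-11}$),
where a purely relative filter is meaningless, so costs below an
absolute floor (`cost_floor = 1e-4`, one part in $10^2$ per observation
in relative error) count as ties at numerical zero. On noisy data
(cost of order 1) the floor is inert.

This design reproduces the practical identifiability structure of the
problem: with extracellular-only absolute data plus relative time
courses, $\delta$ and $\tau$ are pinned by curve shape, $c_1$ and $c_2$
by scale, while $\alpha$, $\beta$, $\gamma$ individually slide along a
one-dimensional ridge; a single absolute intracellular measurement
collapses the ridge.

## Model selection

Candidates are compared by the small-sample-corrected Akaike criterion
$AIC_c = n \ln(C/n) + 2k + 2k(k+1)/(n-k-1)$ with natural logarithm
(the base shifts all scores by a constant factor and cannot change the
ranking) and $k$ = number of active parameters + 1. Models are fitted in
order of increasing complexity, each warm-started from the best fits of
its sub-models (added $\tau$ or $\varepsilon$ at 0, added $\kappa$ at
its upper bound), which enforces cost nestedness up to optimizer
precision and the finite $\kappa$ bound (a sub-0.1% residual offset).

## Sensitivity, fluxes, perturbation

Local sensitivities are one-sided forward differences at +10% of each
parameter, reported as fractional output change per fractional parameter
change; $T_{50,X}$ is evaluated from its closed form $\ln 2/\delta$
(with the grid-crossing estimate available as a cross-check). Global
scans multiply one parameter at a time by 25 log-spaced factors from
0.01 to 100, tolerating simulation failures at extreme factors. Process
fluxes ($\Phi_{prod}, \Phi_{secr} = \beta I(t-\tau), \Phi_{ideg} =
\gamma I(t-\tau), \Phi_{xdeg} = \delta X$) are evaluated along stored
trajectories using the saved delay history.

Inhibition of a process multiplies its parameter by $(1-f)$: at the
media change only ("chemical", acute drug addition after baseline
equilibration) or throughout including the pre-simulation ("genetic",
chronic knockdown). For $\delta$ the two modes give identical
extracellular time courses exactly; for $\beta$ and $\gamma$ they differ
transiently only through the intracellular starting level and converge
at long times. Observed fold changes are inverted to an effective $f$ by
a 21-point monotonicity pre-scan followed by bisection to $10^{-3}$;
observations outside the attainable response range yield explicit
verdicts ("exceeds full inhibition" when even $f = 1$ falls short,
"wrong direction" when the observed change opposes the simulated
response, "insensitive" for targets like $\tau$ with no constitutive
response) rather than estimates. $\tau$ inhibition is implemented for
completeness even though constitutive outputs cannot respond to it.

## Synthetic data

The generator emulates the structure of three published experimental
designs: an ELISA-style constitutive time course of conditioned media
only, in ng/mL (grid 1–72 h, with the 3 h point pre-flagged excluded to
exercise the exclusion rule); a quantitative-Western-style constitutive
time course of both pools in relative units out to 72 h (X anchored at
24 h, I at 0 h); and a pulse-chase time course in relative units over a
10 h chase (X anchored at 8 h, I at 0 h, the 10 h X point pre-flagged
excluded). Exact published grids live in supplementary material we do
not reproduce; the defaults are plausible grids chosen to exercise every
preprocessing rule. Extracellular points are only sampled after the
media change (and, for pulse-chase, after secretion onset): with an
exact maturation delay the labeled extracellular pool is identically
zero earlier, and zero observations are incompatible with a
relative-error cost. Noise is multiplicative lognormal per observation
(mean-one, CV 0.10 by default, 3 replicates) — a standard model for
densitometry and immunoassay error; the conversion constants default to
$10^5$ cells/mL and 110 kDa, which place simulated media concentrations
in the ng/mL range typical of ELISA. What passing recovery tests show is
that the *estimation machinery* is faithful under the stated noise
model; they cannot certify the noise model itself, batch effects, blot
saturation, or detection limits of real assays.

```{r recovery-example, eval = FALSE}
p <- reference_params()
designs <- list(synthetic_design("hornig_like", noise_cv = 0),
                synthetic_design("kinghorn_like", noise_cv = 0),
                synthetic_design("jung_like", noise_cv = 0))
recovery_experiment(p, designs, fit_config(n_starts = 50, seed = 1))
```

## Problem sizes and numerical choices

The test-suite and acceptance experiments use 50 starts for the main
recovery fit, 16 for the absolute-intracellular variant, 12 per model
for the noisy eight-model comparison and 2 plus warm starts for the
noiseless nestedness check; these sizes give a comfortable margin of
multistart hits over the fraction of random starts that reach the
global basin while keeping a full run on one CPU in the tens of
minutes.
The reference parameter set shipped with the package is the
component-wise median of an accepted fit ensemble for HUVEC secretion
data; it satisfies the compound-constant constraints to better than
0.3% and is used as-is without re-projection.

## Known limitations

* A fixed maturation delay is a caricature of the graded, stochastic
  transit through the secretory pathway.
* Cell number, VEGF binding, matrix association, feedback on production,
  and stress responses (e.g. the unfolded protein response triggered by
  secretion inhibitors) are outside the model; observed fold changes
  that the model cannot reach at $f = 1$ are reported as infeasible
  rather than explained by added mechanisms.
* Very long delays conflict with the steady-state initialization recipe
  (see above); the package reports rather than repairs this regime.
* The accepted-fit filter depends on a numerical-zero floor on noiseless
  data; analyses of real (noisy) data are insensitive to it.
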