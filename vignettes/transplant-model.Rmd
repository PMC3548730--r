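---
title: "Modeling alloimmune dynamics under immunosuppression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling alloimmune dynamics under immunosuppression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(graftsim)
```

## The model

`graftsim` implements a mass-action ODE model of the cellular immune
response to a solid-organ allograft. Eleven state variables evolve in a
single well-mixed plasma/interstitial compartment:

* six antigen pools (μg/l): a generic **environmental antigen** $E$ that the
  immune system sees continuously; graft-derived **regenerating antigen** in
  unprocessed ($S$) and processed ($L$) form — the indirect presentation
  pathway, with $S$ proportional to viable graft mass; **directly presented
  antigen** $U$ carried by donor APCs, which does not regenerate; and
  non-regenerating, indirectly presented antigen in unprocessed ($Y$) and
  processed ($Z$) form;
* four specific T-cell populations ($C_e$, $C_l$, $C_u$, $C_z$, in
  $10^3$ cell/μl), one per activating antigen;
* the plasma concentration $F$ (ng/ml) of a single immunosuppressant
  (a calcineurin inhibitor such as cyclosporine).

Each antigen/T-cell block has the same skeleton. Antigen is produced (a
constant inflow for $E$, logistic regrowth $k_s S (1 - S/S^*)$ for the graft
antigen, processing inflow $k_{ls}S$ or $k_{zy}Y$ for the processed forms,
nothing for $U$ and $Y$), and eliminated by a first-order term and a
bilinear T-cell-dependent term. T-cells are produced at a basal rate $k_c$,
expand clonally on antigen contact via $k_{cac}(F)\,C\,A$, and die by
antigen-contact apoptosis and first-order apoptosis $k_{xc}C$. The drug
follows one-compartment linear kinetics $\dot F = k_f - k_{xf}F$ and acts by
suppressing clonal expansion exponentially,

$$k_{cac}(F) = k_{cacF}\, e^{-\lambda F},$$

identically for all four T-cell populations — immunosuppression is not
antigen-specific, which is exactly why protecting the graft also weakens the
response to infections.

Given $F$, the four blocks are mutually independent; this decoupling is
exploited throughout (it makes subsystem-wise equilibrium analysis exact and
gives sharp zero-effect predictions for the sensitivity analysis, both of
which are tested).

Transplantation at time $t_\tau$ is an impulsive event: the three
alloantigen pools jump by $S_\tau$, $U_\tau$, $Y_\tau$, and, when therapy
starts simultaneously with a loading dose, $F$ jumps by $\kappa_f/k_{xf}$ —
exactly the steady level that constant delivery at rate $\kappa_f$ sustains
thereafter.

## Parameters and units

All quantities are carried in the published table units — antigen μg/l,
T-cells $10^3$ cell/μl, drug ng/ml, time years — so every tabulated value is
used verbatim and all bilinear rate constants are dimensionally consistent
(e.g. $\lambda F$ is dimensionless). The time columns of the source table
are labelled "in days" but list 35 and 40 with the year unit; consistent
with the simulated 35–60-year axis, they are treated as years.

`default_parameters(scenario)` returns the published set; the three
scenarios differ only in the drug delivery rate $\kappa_f$:

| scenario | $\kappa_f$ (ng/ml/year) | steady drug level $\bar F = \kappa_f/k_{xf}$ |
|---|---|---|
| `none` | 0 | 0 |
| `moderate` | 36500 | 100 ng/ml |
| `high` | 127750 | 350 ng/ml |

Two naming notes. The parameter $S^*$ is called a carrying capacity here
(that is its mathematical role in the logistic term) although the source
table labels it a "maximum regeneration rate". And the clonal-expansion
equation groups $k_{cac}(F)\,C\,A - k_{xce}\,A\,C$ as two terms; this is
algebraically identical to the factored form $(k_{cac}(F)-k_{xce})\,A\,C$
used in the equilibrium algebra, so no separate branch exists. Whether the
experimentally derived $k_{cacF} = 2.92$ should be read as the gross
expansion coefficient or as the net coefficient observed in the MLR
(expansion minus contact apoptosis) is not decidable from the calibration
itself; it is used as the gross coefficient, as published.

## Numerical integration and impulses

Dirac impulses are realized as exact state jumps with integrator
stop/restart at every event and at every therapy-schedule discontinuity —
never as narrow smoothed pulses. This preserves impulse semantics exactly
and keeps the stiff solver stable. Between breakpoints the system is
integrated with `deSolve::lsoda` at `rtol = 1e-8`, `atol = 1e-10`
(configurable); the rates span 0.001–365 per year, so the problem is stiff
around the transplant and the tight tolerances are cheap insurance. The
default output grid is 0.01 year over a 35–60-year horizon — the grid only
controls reporting, not accuracy, and halving it changes trajectories by
less than $10^{-6}$ relative (tested).

Solver under/overshoot more negative than $-10\,\mathrm{atol}$ raises an
error; anything smaller is clipped to zero. Nonnegativity from nonnegative
initial conditions is a structural property of the equations (each
component's derivative is nonnegative on its zero face), and the clip only
removes floating-point noise.

Intermittent therapy is a square wave: on for `period` years starting at
$t_\tau$, then off for `period`, and so on. The loading impulse is applied
only at $t_\tau$ (the published drug equation has a single delta); with
$k_{xf} = 365$/year the drug re-equilibrates within days of each switch
either way, so re-loading at every on-phase would change little.

## Equilibria and bifurcation structure

At a fixed post-transplant drug level $\bar F$ the four subsystems are
analyzed separately:

* **Environmental**: $C_e^*$ is the unique positive root of a quadratic
  whose leading coefficient is positive and constant term negative, and
  $E^* = k_e/(k_{xec}C_e^* + k_{xe})$. The characteristic polynomial of the
  Jacobian has all-positive coefficients once the equilibrium relations are
  substituted, so this point is locally asymptotically stable at every drug
  level; raising $\bar F$ lowers $C_e^*$ and raises $E^*$ (immunosuppression
  trades infection control away).
* **Graft**: the rejection endpoint $(S, L, C_l) = (0, 0, k_c/k_{xc})$ is
  stable iff $k_s k_{xc} < k_{xsc} k_c$. The published parameters give
  $2 > 0.045$ — the condition fails, the endpoint is unstable in the $S$
  direction, and a positive equilibrium can persist. Positive equilibria
  solve a cubic in $C_l$ (coefficients in `graft_cubic()`), with $S$ and $L$
  recovered by back-substitution; only roots with the whole triple positive
  count. In the published regime exactly one positive triple exists for
  every $\bar F \in [0, 350]$ and it is locally asymptotically stable
  (verified on the full grid). `graft_equilibrium()` treats any other count
  as a structural change and raises a dedicated error rather than guessing —
  the published stability claim rests on numerics for one parameter set, so
  no extrapolation is hard-coded.
* **Non-regenerating blocks**: $(U, C_u) = (0, k_c/k_{xc})$ and
  $(Y, Z, C_z) = (0, 0, k_c/k_{xc})$, both stable for any $\bar F \ge 0$
  (triangular Jacobians with negative diagonals): antigen that cannot
  regenerate is always cleared completely.

Numerical choices: cubic roots come from the companion-matrix solver
(`polyroot`); a root is treated as real when $|\mathrm{Im}|
< 10^{-9}\max(1, |\mathrm{Re}|)$ and positive when $> 10^{-12}$ — robust to
floating-point noise at the scale of the published coefficients. Stability
is classified from the maximum real eigenvalue part with a $10^{-9}$
dead-band reported as `marginal`, never silently rounded to stable.

`bifurcation_sweep()` evaluates the graft equilibrium on an $\bar F$ grid
(default 0–350 ng/ml, step 1, the therapeutic range): $\bar S$ rises along
a saturation curve toward $S^*$ — more drug, more surviving graft — while
$\bar C_l$ falls. Each algebraic equilibrium is independently cross-checked
in the tests against long-horizon ODE relaxation (90–120 years, agreement
to $10^{-3}$ relative), including under random ±10% parameter perturbation.

## Sensitivity analysis

`tornado()` performs one-at-a-time local sensitivity: each rate parameter is
increased by 1% (default), the system is re-simulated, and the percent
change of a clinically relevant target ($C_e$, $S$ or $L$) at fixed
post-transplant times (defaults 41 and 50 years, i.e. one and ten years
after transplantation) is recorded and ranked by magnitude. A
finite-difference re-simulation is used instead of forward sensitivity ODEs:
at ~28 parameters and 11 states the simple approach costs a few seconds and
avoids extra machinery. The perturbed set covers the dynamical rate/shape
parameters; event times, impulse sizes and initial conditions are excluded
by default but can be passed explicitly.

The source analysis does not state the therapy scenario behind its
sensitivity figures; since the drug parameters ($\lambda$, $k_{xf}$,
$\kappa_f$) appear among the influential ones, some drug must be present,
and the documented default here is the moderate scenario. Parameters whose
baseline is zero in the active scenario (e.g. $\kappa_f$ without therapy)
are skipped with a warning — a 1% relative perturbation of zero is zero.

Reproduced findings (asserted in the tests): T-cell apoptosis $k_{xc}$
dominates the $C_e$ tornado at both times; the $E$-block rates matter at one
year but fade near equilibrium; and a faster $S\to L$ processing rate
*lowers* $L$ one year after transplantation (≈ −1.5% per +1%) — more
processed antigen means faster $C_l$ expansion, which consumes $L$.

## MLR calibration

`mlr_calibration()` reproduces the derivation of $k_{cacF}$ from a
CFSE-dilution mixed lymphocyte reaction. From gated percentages of divided
CD3+ cells (23.9% and 23.1% in the two reacting samples; the operation
accepts any number of samples, since whether a third stained sample
contributed is not stated), the chain is: mean divided fraction 23.5% →
undivided 76.5% → precursor fraction $23.5/2^3 \approx 2.94\%$ (halving once
per completed cycle, three cycles in three days) → day-0 count
$\approx 79.4$ per 100 final cells → exponential rate
$k_{max} = \ln(100/79)/3 \approx 0.08$/day. Dividing by the maximal antigen
concentration of the culture — $10^5$ MHC molecules/cell × $10^6$ cells/ml
× 60 kDa ≈ 10 μg/l — and annualizing gives $k_{cacF} = 2.92$ l/μg/year.

All percentages are relative to the **final** harvested cell count (CFSE
precursor-frequency conventions differ; this one makes
"undivided + precursor" the day-0 count per 100 final cells). The printed
source chain solves a decay-signed exponential yet reports a positive
growth rate; the implementation uses $k_{max} = \ln(y_3/y_0)/t$, which is
positive for growth, and documents rather than reproduces the sign slip.
Two rounding modes exist: `"exact"` carries full precision; `"paper"`
reproduces the printed intermediate roundings (precursor → 3, day-0 → 79,
rate → 0.08, Avogadro $6\times10^{23}$). The exact chain lands ~4% below
the rounded one at the rate stage — that is rounding propagation, not a
model discrepancy.

## The infection experiment

The source describes an infection two years after transplantation without
stating its entry mechanism. `infection_challenge()` implements it as an
additive impulse to $E$ (default 10 μg/l, configurable) — the simplest
mechanism consistent with an impulsive pathogen exposure; a transient rise
in $k_e$ would be the main alternative and is not implemented. The
qualitative result is mechanism-independent: without therapy $C_e$ surges
and $E$ returns to baseline quickly; under high-dose therapy clearance is
slower (tested as time-to-within-5%-of-baseline, monotone in dose).

## What the tests do and do not show

The test suite runs the model at the published study conditions:
transplantation at 40 years with impulses of 1000 μg/l per alloantigen
pool, horizons to 60 years (90–120 for equilibrium relaxation, where only
the asymptote matters), output steps 0.01–0.1 year, and the three therapy
scenarios. Passing them shows internal consistency — simulation, algebra
and calibration agree with each other and with the published anchors
(steady drug levels 100/350 ng/ml, pre-transplant T-cell total ≈
$2\times10^3$ cells/μl, instability of the rejection endpoint, tornado
rankings). It does not validate the biology: the model was calibrated for
plausible relative time-courses, not fitted to patient data; no parameter
uncertainty is propagated; CD4/CD8 subsets, APCs, B-cells, cytokines,
graft-versus-host dynamics and multi-drug pharmacology are all outside the
model, and the antigen concentration scale is an arbitrary proxy for graft
mass.
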