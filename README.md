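# graftsim

Simulation and analysis of the cellular immune response to a solid-organ
allograft under single-agent immunosuppression.

## The problem

After transplantation the recipient's T-cells recognize donor MHC–epitope
complexes and expand clonally, destroying the graft unless suppressed.
Immunosuppressants (calcineurin inhibitors such as cyclosporine) block that
expansion — but non-specifically, so every dose trades graft survival
against vulnerability to infection. `graftsim` provides a mechanistic
sandbox for that trade-off, aimed at modelers and quantitative
pharmacologists working on transplant immunology: it simulates the coupled
antigen/T-cell/drug dynamics, computes the equilibria that the long-term
outcomes (rejection, tolerance, tolerance at reduced graft mass) correspond
to, and quantifies which parameters the clinically relevant outputs are
sensitive to.

## The model

Eleven states in one well-mixed compartment: six antigen pools — the
environmental antigen *E*; graft-derived regenerating antigen, unprocessed
*S* (∝ viable graft mass) and processed *L*; directly presented donor-APC
antigen *U*; non-regenerating indirect antigen, unprocessed *Y* and
processed *Z* — four specific T-cell populations *C_e*, *C_l*, *C_u*, *C_z*,
and the drug *F*. Every block follows mass-action kinetics of the form

    dA/dt = production(A) − k_xAC · C · A − k_xA · A
    dC/dt = k_c + k_cac(F) · C · A − k_xCA · A · C − k_xc · C

with graft antigen regrowing logistically (rate `k_s`, carrying capacity
`S_star`) and the drug obeying `dF/dt = k_f − k_xf · F`. The drug
suppresses clonal expansion exponentially and identically for all T-cell
types:

    k_cac(F) = k_cacF · exp(−lambda · F)

Transplantation at `t_tau` = 40 years is an impulsive event (jumps `S_tau`,
`U_tau`, `Y_tau` = 1000 μg/l each, plus a drug loading dose
`kappa_f / k_xf`). Given *F*, the four antigen/T-cell blocks are fully
decoupled — the only coupling is through the shared drug, which is the
mathematical statement of why immunosuppression cannot protect the graft
without also blunting infection control.

## Worked example

Simulate the moderate-therapy scenario (continuous delivery at 36500
ng/ml/year, i.e. a steady 100 ng/ml plasma level) and compare the long-run
state against the algebraic graft equilibrium:

```r
library(graftsim)

params   <- default_parameters("moderate")
protocol <- scenario_protocol("moderate")
sim <- simulate_transplant(params, protocol, t_end = 60)

df <- as.data.frame(sim)
round(df[df$time %in% c(39, 41, 50, 60), c("time","E","S","L","C_e","C_l","F")], 4)
#>      time      E      S      L    C_e     C_l   F
#> 401    39 0.3660 0.0000 0.0000 1.1351  0.3000   0
#> 601    41 0.4625 1.7059 0.1914 0.6135 19.2287 100
#> 1501   50 0.6784 3.4915 0.9741 0.3159  6.6830 100
#> 2501   60 0.6785 3.4884 0.9722 0.3159  6.6888 100

graft_equilibrium(params, drug_steady_state(protocol, params))
#> Equilibrium (graft subsystem) at F = 100 ng/ml: asymptotically_stable
#>         S         L       C_l
#> 3.4883964 0.9722148 6.6887688
#> max Re(eigenvalue): -0.8782263
```

Reading the numbers: before transplantation (t = 39) the graft antigens are
zero and T-cells sit at their basal levels (total ≈ 2×10³ cells/μl). The
transplant at t = 40 floods the system with alloantigen; one year later
graft-specific T-cells *C_l* have surged to ≈19×10³ cells/μl while the
drug holds at exactly 100 ng/ml. By t = 50–60 the system has settled onto
the positive graft equilibrium — ≈3.49 μg/l of surviving graft antigen out
of a carrying capacity of 7, i.e. partial tolerance at roughly half the
graft mass — matching the algebraic equilibrium to four decimals, with the
environmental T-cells *C_e* suppressed from 1.14 to 0.32 (the infection
risk of the therapy). `bifurcation_sweep(params)` traces how that
equilibrium moves across drug levels 0–350 ng/ml; `tornado()` ranks
parameter influence on *C_e*, *S* or *L*; and

```r
mlr_calibration(c(23.9, 23.1), rounding = "paper")
#> MLR calibration (paper mode):
#>   mean divided:       23.5 %
#>   undivided:          76.5 %
#>   precursor:          3 %
#>   day-0 count:        79.5 per 100 final cells
#>   replication rate:   0.08 /day
#>   max antigen conc:   10 ug/l
#>   k_cacF:             2.92 l/ug/year
```

reproduces the CFSE-dilution MLR derivation of the clonal-expansion
coefficient used as the model default.

A command-line interface wrapping these functions ships at
`inst/cli/graftsim.R` (subcommands `simulate`, `equilibria`, `bifurcation`,
`sensitivity`, `mlr`, `fixtures`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/graftsim.R", package="graftsim"))')" \
  simulate --scenario moderate --t-end 60 --out traj.csv
```

See `vignettes/transplant-model.Rmd` for the full account of the model,
its equilibrium structure and the numerical choices.

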