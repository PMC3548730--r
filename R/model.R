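# Right-hand side of the ODE system and the drug pharmacodynamics.
#
# The full system decouples, given the drug concentration F, into four
# independent antigen/T-cell subsystems:
#   environmental       (E, C_e)
#   graft regenerating  (S, L, C_l)   - indirect presentation, logistic source
#   direct presentation (U, C_u)      - non-regenerating
#   indirect, non-regen (Y, Z, C_z)
# plus the one-compartment linear drug kinetics dF/dt = k_f - k_xf * F.
# Impulsive entries at the transplantation time are state jumps handled by the
# simulator, never part of this smooth right-hand side.

#' Drug-dependent clonal-expansion coefficient
#'
#' The immunosuppressant blocks TCR signal transduction so that the maximal
#' clonal-expansion coefficient `k_cacF` is reduced exponentially with drug
#' concentration: `k_cac(F) = k_cacF * exp(-lambda * F)`.
#'
#' @param F_conc Drug concentration, ng/ml (scalar or vector, all >= 0).
#' @param params A [model_parameters()] object.
#' @return Clonal-expansion coefficient(s), l/ug/year. Strictly decreasing in
#'   `F_conc`, equal to `k_cacF` at zero drug.
#' @examples
#' drug_effect(0, default_parameters("none"))    # 2.92
#' drug_effect(100, default_parameters("moderate"))
#' @export
drug_effect <- function(F_conc, params) {
  if (!is.numeric(F_conc) || any(!is.finite(F_conc)) || any(F_conc < 0)) {
    stop_domain("drug concentration must be finite and nonnegative")
  }
  params$k_cacF * exp(-params$lambda * F_conc)
}

#' Post-transplant steady-state drug concentration
#'
#' Under continuous delivery at rate `kappa_f` with first-order elimination
#' `k_xf` and an initial loading dose, the plasma level is constant at
#' `kappa_f / k_xf` from the transplantation time onward.
#'
#' @param protocol A [therapy_protocol()] object (its `kappa_f` is used).
#' @param params A [model_parameters()] object (its `k_xf` is used).
#' @return Steady drug level, ng/ml.
#' @examples
#' p <- default_parameters("moderate")
#' drug_steady_state(therapy_protocol("continuous", kappa_f = p$kappa_f), p)  # 100
#' @export
drug_steady_state <- function(protocol, params) {
  if (params$k_xf <= 0) stop_domain("k_xf must be > 0")
  protocol$kappa_f / params$k_xf
}

#' Time derivative of the full system state
#'
#' Evaluates the smooth part of the model equations at a given state. The
#' drug delivery rate is the piecewise-constant infusion `k_f(t)` (0 before
#' transplantation, `kappa_f` during therapy on-phases); impulsive entries are
#' not part of the right-hand side.
#'
#' @param state Named numeric vector in [state_names()] order, all components
#'   finite and nonnegative.
#' @param t Time, years (unused: the smooth system is autonomous given the
#'   delivery rate, but kept for solver-facing signatures).
#' @param params A [model_parameters()] object.
#' @param delivery_rate Current drug infusion rate `k_f`, ng/ml/year.
#' @return Named numeric vector of the 11 derivatives.
#' @export
model_rhs <- function(state, t = 0, params, delivery_rate = 0) {
  if (any(!is.finite(state))) {
    stop_numeric("non-finite state component passed to model_rhs")
  }
  E <- state[["E"]]; S <- state[["S"]]; L <- state[["L"]]
  U <- state[["U"]]; Y <- state[["Y"]]; Z <- state[["Z"]]
  C_e <- state[["C_e"]]; C_l <- state[["C_l"]]
  C_u <- state[["C_u"]]; C_z <- state[["C_z"]]
  Fc <- state[["F"]]

  kcac <- params$k_cacF * exp(-params$lambda * Fc)

  dE   <- params$k_e - params$k_xec * C_e * E - params$k_xe * E
  dC_e <- params$k_c + kcac * C_e * E - params$k_xce * E * C_e - params$k_xc * C_e

  dS   <- params$k_s * S * (1 - S / params$S_star) - params$k_xsc * C_l * S
  dL   <- params$k_ls * S - params$k_xlc * C_l * L - params$k_xl * L
  dC_l <- params$k_c + kcac * C_l * L - params$k_xcs * S * C_l -
    params$k_xcl * L * C_l - params$k_xc * C_l

  dU   <- -params$k_xuc * C_u * U - params$k_xu * U
  dC_u <- params$k_c + kcac * C_u * U - params$k_xcu * U * C_u - params$k_xc * C_u

  dY   <- -params$k_xyc * C_z * Y - params$k_xy * Y
  dZ   <- params$k_zy * Y - params$k_xzc * C_z * Z - params$k_xz * Z
  dC_z <- params$k_c + kcac * C_z * Z - params$k_xcy * Y * C_z -
    params$k_xcz * Z * C_z - params$k_xc * C_z

  dF <- delivery_rate - params$k_xf * Fc

  setNames(c(dE, dS, dL, dU, dY, dZ, dC_e, dC_l, dC_u, dC_z, dF),
           .state_names)
}

# deSolve-facing wrapper; parms carries the parameter list plus the (constant
# within an integration segment) delivery rate.
.desolve_rhs <- function(t, y, parms) {
  list(model_rhs(y, t, parms$params, parms$delivery_rate))
}
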