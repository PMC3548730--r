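# Model parameters and therapy protocols.
#
# Units follow the published tables verbatim: antigen concentrations in ug/l,
# T-cell concentrations in 10^3 cell/ul, drug concentration in ng/ml, time in
# years. With this convention every tabulated value is used as printed and all
# bilinear terms are dimensionally consistent (lambda*F is dimensionless).

# Names of the dynamic state components, in canonical order (also the CSV
# column order used by write_trajectories()).
.state_names <- c("E", "S", "L", "U", "Y", "Z",
                  "C_e", "C_l", "C_u", "C_z", "F")

#' State component names
#'
#' Canonical order of the 11 dynamic state components: six antigen pools
#' (ug/l), four T-cell populations (10^3 cell/ul) and the drug concentration
#' (ng/ml).
#'
#' @return Character vector of length 11.
#' @export
state_names <- function() .state_names

# Rate/shape parameters perturbed by default in the tornado analysis
# (event times, impulse magnitudes and initial conditions excluded).
.rate_parameter_names <- c(
  "k_e", "k_xec", "k_xe",
  "k_c", "k_cacF", "lambda", "k_xc",
  "k_xce", "k_xcs", "k_xcl", "k_xcu", "k_xcy", "k_xcz",
  "k_s", "S_star", "k_xsc", "k_xlc", "k_xuc", "k_xyc", "k_xzc",
  "k_ls", "k_zy", "k_xl", "k_xu", "k_xy", "k_xz",
  "kappa_f", "k_xf"
)

.parameter_names <- c(
  .rate_parameter_names,
  "t_0", "t_tau", "S_tau", "U_tau", "Y_tau",
  "E_0", "S_0", "L_0", "U_0", "Y_0", "Z_0", "F_0",
  "C_e0", "C_l0", "C_u0", "C_z0"
)

# Published default values (drug delivery rate kappa_f depends on scenario).
.default_values <- list(
  k_e    = 1,      # environmental antigen entry, ug/l/year
  k_xec  = 1.5,    # C_e-dependent E elimination, (ul/cell x 1e-3)/year
  k_xe   = 1,      # first-order E elimination, 1/year
  k_c    = 0.3,    # basal lymphocyte production, (cell/ul x 1e3)/year
  k_cacF = 2.92,   # maximal clonal-expansion coefficient, l/ug/year
  lambda = 0.01,   # drug-effect coefficient, ml/ng
  k_xc   = 1,      # first-order T-cell elimination, 1/year
  k_xce  = 1, k_xcs = 0.02, k_xcl = 0.02,
  k_xcu  = 0.02, k_xcy = 0.02, k_xcz = 0.02,  # antigen-dependent T-cell elimination, l/ug/year
  k_s    = 2,      # logistic rate of graft antigen, 1/year
  S_star = 7,      # graft-antigen carrying capacity, ug/l
  k_xsc  = 0.15, k_xlc = 0.7, k_xuc = 0.5, k_xyc = 0.5, k_xzc = 1,
  k_ls   = 1.5,    # S -> L processing, 1/year
  k_zy   = 6,      # Y -> Z processing, 1/year
  k_xl   = 0.7, k_xu = 0.001, k_xy = 0.001, k_xz = 1,
  kappa_f = 0,     # drug delivery rate, ng/ml/year (scenario-dependent)
  k_xf   = 365,    # drug elimination, 1/year
  t_0    = 35,     # simulation start, years
  t_tau  = 40,     # transplantation time, years
  S_tau  = 1000, U_tau = 1000, Y_tau = 1000,  # impulsive antigen entries, ug/l
  E_0    = 1.38, S_0 = 0, L_0 = 0, U_0 = 0, Y_0 = 0, Z_0 = 0,
  F_0    = 0,
  C_e0   = 1.1, C_l0 = 0.3, C_u0 = 0.3, C_z0 = 0.3
)

.scenario_kappa_f <- c(none = 0, moderate = 36500, high = 127750)

#' Construct a model parameter set
#'
#' Builds a validated `model_parameters` object from the published defaults,
#' optionally overriding individual values. See [default_parameters()] for the
#' three published therapy scenarios.
#'
#' @param ... Named parameter overrides (e.g. `k_s = 0.01`). Unknown names are
#'   rejected.
#' @return An object of class `model_parameters`: a named list with all 44
#'   parameters, impulse magnitudes and initial conditions.
#' @examples
#' p <- model_parameters(kappa_f = 36500)
#' p$k_cacF
#' @export
model_parameters <- function(...) {
  overrides <- list(...)
  if (length(overrides) > 0 && (is.null(names(overrides)) || any(names(overrides) == ""))) {
    stop_config("all parameter overrides must be named")
  }
  names(overrides)[names(overrides) == "lambda_"] <- "lambda"
  unknown <- setdiff(names(overrides), .parameter_names)
  if (length(unknown) > 0) {
    stop_config(paste0("unknown parameter(s): ", paste(unknown, collapse = ", ")))
  }
  p <- modifyList(.default_values, overrides)
  p <- p[.parameter_names]
  class(p) <- "model_parameters"
  validate_parameters(p)
  p
}

#' Published parameter defaults for a therapy scenario
#'
#' Returns the published parameter set; the three scenarios differ only in the
#' drug delivery rate `kappa_f`: 0 (no treatment), 36500 (moderate) or 127750
#' (high) ng/ml/year. With first-order drug elimination `k_xf = 365`/year
#' these correspond to steady-state plasma levels of 0, 100 and 350 ng/ml.
#'
#' @param scenario One of `"none"`, `"moderate"`, `"high"`.
#' @return A `model_parameters` object.
#' @examples
#' default_parameters("moderate")$kappa_f  # 36500
#' @export
default_parameters <- function(scenario = c("none", "moderate", "high")) {
  if (length(scenario) != 1 || !scenario %in% names(.scenario_kappa_f)) {
    stop_config(paste0("unknown scenario label: ",
                       paste(scenario, collapse = ", "),
                       " (expected one of none, moderate, high)"))
  }
  model_parameters(kappa_f = unname(.scenario_kappa_f[[scenario]]))
}

validate_parameters <- function(p) {
  vals <- unlist(p[.parameter_names])
  if (any(!is.finite(vals))) {
    stop_config("all parameters must be finite numbers")
  }
  nonneg <- setdiff(.parameter_names, c("t_0", "t_tau"))
  bad <- nonneg[vals[nonneg] < 0]
  if (length(bad) > 0) {
    stop_config(paste0("parameters must be nonnegative: ", paste(bad, collapse = ", ")))
  }
  if (p$S_star <= 0) stop_config("S_star must be > 0")
  if (p$k_xf <= 0) stop_config("k_xf must be > 0")
  if (p$t_0 >= p$t_tau) stop_config("t_0 must be earlier than t_tau")
  invisible(p)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Model parameters (time in years):\n")
  v <- unlist(x)
  print(v, ...)
  invisible(x)
}

#' Initial system state implied by a parameter set
#'
#' The state vector at `t_0`: antigen and drug initial values plus the four
#' T-cell initial concentrations.
#'
#' @param params A `model_parameters` object.
#' @return Named numeric vector in [state_names()] order.
#' @export
initial_state <- function(params) {
  setNames(c(params$E_0, params$S_0, params$L_0, params$U_0, params$Y_0,
             params$Z_0, params$C_e0, params$C_l0, params$C_u0, params$C_z0,
             params$F_0),
           .state_names)
}

#' Define a drug therapy protocol
#'
#' @param mode Delivery mode: `"none"` (no drug), `"continuous"` (constant
#'   delivery at `kappa_f` from the transplantation time onward) or
#'   `"intermittent"` (square wave: on for `period` years, off for `period`
#'   years, starting in the on phase at transplantation).
#' @param kappa_f On-phase delivery rate, ng/ml/year. Ignored (forced to 0)
#'   for mode `"none"`.
#' @param period On/off half-period for intermittent delivery, years.
#' @param loading_dose Whether the impulsive loading dose `kappa_f / k_xf` is
#'   added to `F` at the transplantation time, bringing the drug instantly to
#'   its steady level.
#' @return A `therapy_protocol` object.
#' @examples
#' therapy_protocol("continuous", kappa_f = 36500)
#' therapy_protocol("intermittent", kappa_f = 36500, period = 1)
#' @export
therapy_protocol <- function(mode = c("none", "continuous", "intermittent"),
                             kappa_f = 0, period = 1, loading_dose = TRUE) {
  mode <- match.arg(mode)
  if (!is.numeric(kappa_f) || length(kappa_f) != 1 || !is.finite(kappa_f) || kappa_f < 0) {
    stop_config("kappa_f must be a single nonnegative number")
  }
  if (mode == "intermittent" && (!is.finite(period) || period <= 0)) {
    stop_config("period must be > 0 for intermittent therapy")
  }
  if (mode == "none") kappa_f <- 0
  structure(list(mode = mode, kappa_f = kappa_f, period = period,
                 loading_dose = isTRUE(loading_dose)),
            class = "therapy_protocol")
}

#' Therapy protocol matching a published scenario
#'
#' Convenience wrapper: continuous delivery (with loading dose) at the
#' scenario's `kappa_f`; the `"none"` scenario yields no delivery.
#'
#' @inheritParams default_parameters
#' @return A `therapy_protocol` object.
#' @export
scenario_protocol <- function(scenario = c("none", "moderate", "high")) {
  params <- default_parameters(scenario)
  mode <- if (params$kappa_f > 0) "continuous" else "none"
  therapy_protocol(mode, kappa_f = params$kappa_f)
}

#' @export
print.therapy_protocol <- function(x, ...) {
  cat("Therapy protocol: mode =", x$mode,
      "| kappa_f =", x$kappa_f, "ng/ml/year")
  if (x$mode == "intermittent") cat(" | period =", x$period, "years")
  cat(" | loading dose:", x$loading_dose, "\n")
  invisible(x)
}
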