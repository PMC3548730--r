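# One-at-a-time local (tornado) sensitivity analysis.
#
# Each rate parameter is increased by a small fraction (default 1%), the full
# system is re-simulated, and the percent change of a target state variable at
# fixed post-transplant evaluation times is recorded. A finite-difference
# re-simulation is used rather than forward sensitivity ODEs: at ~28
# parameters and 11 states it is simple and fast enough.

#' Parameters perturbed by default in the tornado analysis
#'
#' All dynamical rate/shape parameters (entries, eliminations, processing and
#' clonal-expansion rates, carrying capacity, drug delivery/elimination/effect
#' coefficients). Event times, impulse magnitudes and initial conditions are
#' excluded by default but may be passed explicitly to [tornado()].
#'
#' @return Character vector of parameter names.
#' @export
sensitivity_parameters <- function() .rate_parameter_names

#' Tornado sensitivity analysis
#'
#' For each parameter `p`, re-simulates with `p` scaled by
#' `(1 + perturbation)` and records the percent change of the target state
#' variable at each evaluation time, relative to the unperturbed run:
#' `100 * (target_perturbed - target_baseline) / target_baseline`.
#' Records are sorted by absolute percent change (descending) within each
#' evaluation time. Parameters whose baseline value is zero in the active
#' scenario (e.g. `kappa_f` without therapy) are skipped with a warning.
#'
#' @param params A [model_parameters()] object.
#' @param protocol A [therapy_protocol()] object. When `kappa_f` or `k_xf`
#'   is perturbed the protocol's delivery rate / loading dose follow the
#'   perturbed parameters.
#' @param target Target state variable: `"C_e"`, `"S"` or `"L"`.
#' @param eval_time Evaluation time(s), years, all after the transplantation
#'   time. A vector is served by a single set of simulations.
#' @param perturbation Fractional parameter increase (default 0.01, i.e. +1%).
#' @param parameter_set Names of parameters to perturb (default
#'   [sensitivity_parameters()]).
#' @param t_end Simulation horizon; defaults to just past `max(eval_time)`.
#' @param output_step Output grid spacing for the underlying simulations.
#' @param ... Further arguments to [simulate_transplant()] (e.g. tolerances).
#' @return Data frame of class `tornado_result` with columns `parameter`,
#'   `target`, `time`, `percent_change`, `baseline_value`, sorted in tornado
#'   order within each time.
#' @examples
#' \donttest{
#' tor <- tornado(default_parameters("moderate"), scenario_protocol("moderate"),
#'                target = "C_e", eval_time = 41,
#'                parameter_set = c("k_xc", "k_c", "k_e"))
#' head(tor)
#' }
#' @export
tornado <- function(params, protocol, target = c("C_e", "S", "L"),
                    eval_time = c(41, 50), perturbation = 0.01,
                    parameter_set = sensitivity_parameters(),
                    t_end = NULL, output_step = 0.05, ...) {
  target <- match.arg(target)
  if (any(eval_time <= params$t_tau)) {
    stop_config("eval_time must be after the transplantation time t_tau")
  }
  if (!is.finite(perturbation) || perturbation <= 0) {
    stop_config("perturbation must be > 0")
  }
  unknown <- setdiff(parameter_set, .parameter_names)
  if (length(unknown) > 0) {
    stop_config(paste0("unknown parameter(s) in parameter_set: ",
                       paste(unknown, collapse = ", ")))
  }
  if (is.null(t_end)) t_end <- max(eval_time) + 2 * output_step

  run <- function(p, proto) {
    sim <- simulate_transplant(p, proto, t_end = t_end,
                               output_step = output_step, ...)
    trajectory_at(sim, target, eval_time)
  }
  baseline <- run(params, protocol)
  if (any(baseline <= 0)) {
    stop_numeric("baseline target value is not strictly positive")
  }

  records <- list()
  for (pname in parameter_set) {
    value <- params[[pname]]
    if (value == 0) {
      warning("skipping parameter with baseline value 0: ", pname,
              call. = FALSE)
      next
    }
    p2 <- params
    p2[[pname]] <- value * (1 + perturbation)
    proto2 <- protocol
    if (pname == "kappa_f" && protocol$mode != "none") {
      proto2$kappa_f <- p2$kappa_f
    }
    perturbed <- run(p2, proto2)
    records[[pname]] <- data.frame(
      parameter = pname,
      target = target,
      time = eval_time,
      percent_change = 100 * (perturbed - baseline) / baseline,
      baseline_value = baseline)
  }
  out <- do.call(rbind, c(records, list(make.row.names = FALSE)))
  out <- out[order(out$time, -abs(out$percent_change)), ]
  rownames(out) <- NULL
  class(out) <- c("tornado_result", "data.frame")
  out
}

#' @export
print.tornado_result <- function(x, digits = 4, ...) {
  cat("Tornado sensitivity (", x$target[1], "), +",
      "1-at-a-time perturbation; ", length(unique(x$parameter)),
      " parameters x ", length(unique(x$time)), " time(s)\n", sep = "")
  print.data.frame(x, digits = digits, ...)
  invisible(x)
}
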