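# Configuration files, trajectory serialization and scenario fixtures.

.protocol_keys <- c("name", "scenario", "mode", "period", "loading_dose",
                    "t_end", "output_step", "rtol", "atol",
                    "infection_time", "infection_delta_E")

#' Load a scenario configuration file
#'
#' Reads a flat key-value configuration (JSON or YAML, decided by the file
#' extension, with a fallback that tries both). Keys are the parameter names
#' of [model_parameters()] plus the protocol/solver keys `scenario`, `mode`,
#' `period`, `loading_dose`, `t_end`, `output_step`, `rtol`, `atol`, `name`,
#' `infection_time`, `infection_delta_E`. Unknown keys are rejected with the
#' offending name; missing keys fall back to the published defaults (a notice
#' lists how many were defaulted).
#'
#' @param path Path to the configuration file.
#' @param quiet Suppress the defaulting notice.
#' @return A `scenario_config` object: list with `name`, `parameters`
#'   (a `model_parameters` object), `protocol`, `t_end`, `output_step`,
#'   `solver` (list with `rtol`, `atol`) and optional `infection`.
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop_config(paste0("config file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  if (file.size(path) == 0 ||
      all(grepl("^\\s*$", readLines(path, warn = FALSE)))) {
    raw <- list()  # empty file -> all defaults
    ext <- "handled"
  }
  raw <- if (ext == "handled") raw else if (ext %in% c("yaml", "yml")) {
    tryCatch(yaml::read_yaml(path),
             error = function(e) stop_config(paste0("YAML parse failure in ",
                                                    path, ": ", conditionMessage(e))))
  } else if (ext == "json") {
    tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
             error = function(e) stop_config(paste0("JSON parse failure in ",
                                                    path, ": ", conditionMessage(e))))
  } else {
    tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
             error = function(e) tryCatch(yaml::read_yaml(path),
               error = function(e2) stop_config(paste0("cannot parse ", path,
                                                       " as JSON or YAML"))))
  }
  if (is.null(raw)) raw <- list()  # empty file -> all defaults
  if (!is.list(raw)) stop_config(paste0("config must be a key-value mapping: ", path))
  names(raw)[names(raw) == "lambda_"] <- "lambda"
  allowed <- c(.parameter_names, .protocol_keys)
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    stop_config(paste0("unknown config key(s) in ", path, ": ",
                       paste(unknown, collapse = ", ")))
  }

  scenario <- if (!is.null(raw$scenario)) raw$scenario else "none"
  base <- default_parameters(scenario)
  overrides <- raw[intersect(names(raw), .parameter_names)]
  params <- do.call(model_parameters,
                    modifyList(unclass(base)[.parameter_names], overrides))
  n_default <- length(.parameter_names) - length(overrides) -
    if (scenario != "none" && !"kappa_f" %in% names(overrides)) 1 else 0
  if (!quiet && n_default > 0) {
    message(n_default, " parameter(s) not set in ", basename(path),
            "; using published defaults")
  }

  mode <- if (!is.null(raw$mode)) raw$mode else if (params$kappa_f > 0) "continuous" else "none"
  protocol <- therapy_protocol(mode,
                               kappa_f = params$kappa_f,
                               period = if (!is.null(raw$period)) raw$period else 1,
                               loading_dose = if (!is.null(raw$loading_dose)) raw$loading_dose else TRUE)

  infection <- NULL
  if (!is.null(raw$infection_time)) {
    infection <- list(time = raw$infection_time,
                      delta_E = if (!is.null(raw$infection_delta_E)) raw$infection_delta_E else 10)
  }

  structure(list(name = if (!is.null(raw$name)) raw$name else scenario,
                 parameters = params,
                 protocol = protocol,
                 t_end = if (!is.null(raw$t_end)) raw$t_end else 60,
                 output_step = if (!is.null(raw$output_step)) raw$output_step else 0.01,
                 solver = list(rtol = if (!is.null(raw$rtol)) raw$rtol else 1e-8,
                               atol = if (!is.null(raw$atol)) raw$atol else 1e-10),
                 infection = infection),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario config '", x$name, "': kappa_f = ", x$parameters$kappa_f,
      ", mode = ", x$protocol$mode, ", horizon = ", x$t_end, " years\n", sep = "")
  invisible(x)
}

#' Run the simulation described by a scenario configuration
#'
#' @param config A `scenario_config` from [load_config()].
#' @return A `transplant_sim` object.
#' @export
run_config <- function(config) {
  extra <- list()
  if (!is.null(config$infection) && config$infection$delta_E > 0) {
    extra <- list(event_spec(config$infection$time,
                             c(E = config$infection$delta_E),
                             label = "infection"))
  }
  simulate_transplant(config$parameters, config$protocol,
                      extra_events = extra,
                      t_end = config$t_end, output_step = config$output_step,
                      rtol = config$solver$rtol, atol = config$solver$atol)
}

#' Write simulated trajectories to CSV (with a JSON event sidecar)
#'
#' Tidy CSV with header `time,E,S,L,U,Y,Z,C_e,C_l,C_u,C_z,F` in model units;
#' values are written with 17 significant digits so that a read-back
#' reproduces the doubles bitwise. Applied events go to `<path>.events.json`.
#'
#' @param result A `transplant_sim` object.
#' @param path Output CSV path.
#' @return Invisibly, the paths written (csv and sidecar).
#' @export
write_trajectories <- function(result, path) {
  df <- as.data.frame(result)
  header <- c("time", .state_names)
  lines <- c(paste(header, collapse = ","),
             if (nrow(df) > 0)
               apply(df[, header, drop = FALSE], 1,
                     function(r) paste(sprintf("%.17g", r), collapse = ",")))
  ok <- tryCatch({writeLines(lines, path); TRUE},
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_config(paste0("cannot write trajectories to ", path))
  sidecar <- paste0(path, ".events.json")
  events <- lapply(result$events, function(ev)
    list(time = ev$time, label = ev$label, increments = as.list(ev$increments)))
  jsonlite::write_json(events, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(path, sidecar))
}

#' Read trajectories written by [write_trajectories()]
#'
#' @param path CSV path.
#' @return Data frame with `time` plus the 11 state columns.
#' @export
read_trajectories <- function(path) {
  read.csv(path, check.names = FALSE, colClasses = "numeric")
}

#' Write the standard scenario fixture configurations
#'
#' Emits five JSON configuration files covering the published experiments:
#' the three therapy scenarios (none / moderate / high, continuous delivery),
#' an intermittent one-year-cycle protocol, and an infection challenge two
#' years after transplantation.
#'
#' @param out_dir Writable directory.
#' @return Character vector of the paths written.
#' @export
make_fixtures <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fixtures <- list(
    scenario_none = list(name = "none", scenario = "none"),
    scenario_moderate = list(name = "moderate", scenario = "moderate"),
    scenario_high = list(name = "high", scenario = "high"),
    intermittent_one_year = list(name = "intermittent_one_year",
                                 scenario = "moderate", mode = "intermittent",
                                 period = 1),
    infection_challenge = list(name = "infection_challenge",
                               scenario = "none", infection_time = 42,
                               infection_delta_E = 10))
  paths <- character(0)
  for (nm in names(fixtures)) {
    p <- file.path(out_dir, paste0(nm, ".json"))
    jsonlite::write_json(fixtures[[nm]], p, auto_unbox = TRUE, pretty = TRUE)
    paths <- c(paths, p)
  }
  paths
}
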