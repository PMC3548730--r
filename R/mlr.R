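# Calibration of the clonal-expansion coefficient from CFSE-dilution mixed
# lymphocyte reaction (MLR) data.
#
# The chain: gated percentages of divided CD3+ cells -> precursor frequency
# (halving the divided fraction once per completed cycle) -> day-0 relative
# cell count -> exponential replication rate over the culture -> division by
# the maximal antigen concentration (MHC surface density x cell density x
# molecular weight) -> annualized coefficient k_cacF in l/ug/year.
#
# All percentages are relative to the FINAL cell count harvested at the end
# of the culture (CFSE precursor-frequency conventions differ; this one makes
# "undivided + precursor" the day-0 count per 100 final cells).
#
# Two rounding modes are provided: "exact" carries full precision, "paper"
# reproduces a printed worked-example chain (precursor rounded to the nearest
# whole percent, day-0 count truncated to an integer, replication rate
# rounded to two decimals, Avogadro taken as 6e23).

#' Division statistics from CFSE dilution percentages
#'
#' @param divided_percent Per-sample percentages of CD3+ cells that divided
#'   (each in 0..100).
#' @param n_cycles Number of completed division cycles during the culture
#'   (>= 1). Each cycle doubles the dividing cells, so the precursor fraction
#'   is the mean divided fraction divided by `2^n_cycles`.
#' @param rounding `"exact"` (default) or `"paper"` (precursor rounded to the
#'   nearest whole percent).
#' @return List with `mean_divided`, `undivided`, `precursor` and
#'   `day0_relative` (all per 100 final cells).
#' @examples
#' division_statistics(c(23.9, 23.1), n_cycles = 3)
#' @export
division_statistics <- function(divided_percent, n_cycles,
                                rounding = c("exact", "paper")) {
  rounding <- match.arg(rounding)
  if (length(divided_percent) == 0) {
    stop_domain("divided_percent must contain at least one sample")
  }
  if (any(!is.finite(divided_percent)) || any(divided_percent < 0) ||
      any(divided_percent > 100)) {
    stop_domain("divided_percent values must lie in [0, 100]")
  }
  if (!is.finite(n_cycles) || n_cycles < 1 || n_cycles != round(n_cycles)) {
    stop_domain("n_cycles must be a positive integer")
  }
  mean_divided <- mean(divided_percent)
  undivided <- 100 - mean_divided
  precursor <- mean_divided / 2^n_cycles
  if (rounding == "paper") precursor <- round(precursor)
  list(mean_divided = mean_divided,
       undivided = undivided,
       precursor = precursor,
       day0_relative = undivided + precursor)
}

#' Exponential replication rate from relative cell counts
#'
#' Net growth rate assuming exponential expansion between the day-0 and final
#' relative counts: `k_max = ln(final / day0) / duration`. Positive for
#' growth; swapping the two counts flips the sign.
#'
#' @param day0_relative Day-0 cell count per 100 final cells (> 0).
#' @param final_relative Final cell count on the same scale (> 0, typically
#'   100).
#' @param duration_days Culture duration, days (> 0).
#' @return Replication rate, 1/day.
#' @examples
#' replication_rate(79, 100, 3)  # ~0.0786, rounds to 0.08
#' @export
replication_rate <- function(day0_relative, final_relative, duration_days) {
  if (!is.finite(day0_relative) || day0_relative <= 0 ||
      !is.finite(final_relative) || final_relative <= 0 ||
      !is.finite(duration_days) || duration_days <= 0) {
    stop_domain("day0_relative, final_relative and duration_days must be > 0")
  }
  log(final_relative / day0_relative) / duration_days
}

#' Maximal antigen concentration of the MLR culture
#'
#' Converts MHC surface density and cell density into a mass concentration:
#' `molecules/l = mhc_per_cell * cells_per_ml * 1000`, then grams per litre
#' via the molar mass `mhc_mw_kda * 1000` g/mol, returned in ug/l.
#'
#' @param mhc_per_cell MHC molecules per cell (~1e5).
#' @param cells_per_ml Cell density of the culture (~1e6/ml).
#' @param mhc_mw_kda Mean MHC molecular weight, kDa (~60 across class I/II).
#' @param avogadro Molecules per mole (6e23 reproduces the rounded worked
#'   example; pass 6.02214076e23 for the exact constant).
#' @return Concentration, ug/l.
#' @examples
#' max_antigen_concentration(1e5, 1e6, 60)  # 10 ug/l with rounded Avogadro
#' @export
max_antigen_concentration <- function(mhc_per_cell, cells_per_ml, mhc_mw_kda,
                                      avogadro = 6e23) {
  vals <- c(mhc_per_cell, cells_per_ml, mhc_mw_kda, avogadro)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_domain("all inputs to max_antigen_concentration must be > 0")
  }
  molecules_per_l <- mhc_per_cell * cells_per_ml * 1000
  grams_per_l <- molecules_per_l / avogadro * (mhc_mw_kda * 1000)
  grams_per_l * 1e6
}

#' Annualized clonal-expansion coefficient
#'
#' Converts a per-day replication rate at maximal antigen stimulation into
#' the model coefficient: `(k_max / antigen_conc) * 365`, in l/ug/year.
#'
#' @param k_max Replication rate, 1/day.
#' @param antigen_conc Maximal antigen concentration, ug/l (> 0).
#' @return Coefficient, l/ug/year.
#' @examples
#' clonal_expansion_coefficient(0.08, 10)  # 2.92
#' @export
clonal_expansion_coefficient <- function(k_max, antigen_conc) {
  if (!is.finite(antigen_conc) || antigen_conc <= 0) {
    stop_domain("antigen_conc must be > 0")
  }
  k_max / antigen_conc * 365
}

#' Full MLR calibration chain
#'
#' Runs the complete derivation from gated CFSE percentages to the model's
#' clonal-expansion coefficient `k_cacF`.
#'
#' @inheritParams division_statistics
#' @param duration_days Culture duration, days.
#' @param mhc_per_cell,cells_per_ml,mhc_mw_kda See
#'   [max_antigen_concentration()].
#' @param rounding `"exact"` carries full precision; `"paper"` reproduces the
#'   printed worked-example chain (precursor rounded to a whole percent,
#'   day-0 count truncated to an integer before the rate computation,
#'   replication rate rounded to two decimals, Avogadro 6e23).
#' @return A `calibration_result` object: list with `mean_divided_percent`,
#'   `undivided_percent`, `precursor_percent`, `day0_relative_count`,
#'   `k_max` (1/day), `max_antigen_conc` (ug/l) and `k_cacF` (l/ug/year).
#' @examples
#' mlr_calibration(c(23.9, 23.1), n_cycles = 3, duration_days = 3,
#'                 rounding = "paper")
#' @export
mlr_calibration <- function(divided_percent, n_cycles = 3, duration_days = 3,
                            mhc_per_cell = 1e5, cells_per_ml = 1e6,
                            mhc_mw_kda = 60,
                            rounding = c("exact", "paper")) {
  rounding <- match.arg(rounding)
  if (!is.finite(duration_days) || duration_days <= 0) {
    stop_domain("duration_days must be > 0")
  }
  stats <- division_statistics(divided_percent, n_cycles, rounding)
  day0 <- if (rounding == "paper") floor(stats$day0_relative) else stats$day0_relative
  k_max <- replication_rate(day0, 100, duration_days)
  if (rounding == "paper") k_max <- round(k_max, 2)
  avogadro <- if (rounding == "paper") 6e23 else 6.02214076e23
  conc <- max_antigen_concentration(mhc_per_cell, cells_per_ml, mhc_mw_kda,
                                    avogadro)
  structure(list(mean_divided_percent = stats$mean_divided,
                 undivided_percent = stats$undivided,
                 precursor_percent = stats$precursor,
                 day0_relative_count = stats$day0_relative,
                 k_max = k_max,
                 max_antigen_conc = conc,
                 k_cacF = clonal_expansion_coefficient(k_max, conc),
                 rounding = rounding),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("MLR calibration (", x$rounding, " mode):\n", sep = "")
  cat(sprintf("  mean divided:       %.4g %%\n", x$mean_divided_percent))
  cat(sprintf("  undivided:          %.4g %%\n", x$undivided_percent))
  cat(sprintf("  precursor:          %.4g %%\n", x$precursor_percent))
  cat(sprintf("  day-0 count:        %.4g per 100 final cells\n",
              x$day0_relative_count))
  cat(sprintf("  replication rate:   %.4g /day\n", x$k_max))
  cat(sprintf("  max antigen conc:   %.4g ug/l\n", x$max_antigen_conc))
  cat(sprintf("  k_cacF:             %.4g l/ug/year\n", x$k_cacF))
  invisible(x)
}
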