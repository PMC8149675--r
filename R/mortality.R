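new_life_table <- function(age, qx, population = "unspecified") {
  structure(
    tibble(age = as.integer(age), qx = as.numeric(qx)),
    population = population,
    class = c("scd_life_table", "tbl_df", "tbl", "data.frame")
  )
}

#' Read an annual life table from CSV
#'
#' Expects a header `age,qx` with ages contiguous from 0 and annual death
#' probabilities in \[0, 1\]. The terminal row's `qx` is forced to 1 (with a
#' message) so the cohort is extinct by the end of the table.
#'
#' @param file Path to the CSV file.
#' @param population Label for the population the table describes.
#' @return An `scd_life_table` tibble with columns `age` and `qx`.
#' @export
read_life_table <- function(file, population = basename(file)) {
  df <- utils::read.csv(file)
  if (!all(c("age", "qx") %in% names(df))) {
    abort("life-table CSV must have columns 'age' and 'qx'")
  }
  expected <- seq(0L, nrow(df) - 1L)
  if (!identical(as.integer(df$age), expected)) {
    bad <- which(as.integer(df$age) != expected)[1]
    abort(paste0("life-table ages must be contiguous from 0; problem at row ",
                 bad, " (expected age ", expected[bad], ", got ", df$age[bad], ")"))
  }
  bad_q <- which(df$qx < 0 | df$qx > 1)
  if (length(bad_q) > 0) {
    abort(paste0("qx outside [0, 1] at row ", bad_q[1], " (age ", df$age[bad_q[1]],
                 ", qx = ", df$qx[bad_q[1]], ")"))
  }
  if (df$qx[nrow(df)] != 1) {
    message("terminal qx forced to 1 (was ", df$qx[nrow(df)], ")")
    df$qx[nrow(df)] <- 1
  }
  new_life_table(df$age, df$qx, population)
}

#' Synthesize a Gompertz-Makeham life table
#'
#' Annual death probabilities qx(age) = 1 - exp(-(a e^(b age) + c)): an
#' exponentially age-increasing (Gompertz) hazard of scale `a` and slope `b`
#' plus an age-independent (Makeham) hazard `c`. The terminal age gets qx = 1.
#'
#' @param a Baseline hazard scale (> 0, or 0 for no age-dependent mortality).
#' @param b Age slope of the log-hazard (>= 0).
#' @param c Age-independent hazard (>= 0).
#' @param max_age Last tabulated age (default 100).
#' @param population Label for the resulting table.
#' @return An `scd_life_table` tibble.
#' @examples
#' lt <- synthesize_life_table(a = 0, b = 0, c = -log(0.98))
#' lt$qx[1]  # constant annual death probability 0.02
#' @export
synthesize_life_table <- function(a, b, c, max_age = 100, population = "synthetic") {
  if (a < 0 || b < 0 || c < 0) abort("a, b and c must be non-negative")
  age <- 0:max_age
  hazard <- a * exp(b * age) + c
  qx <- 1 - exp(-hazard)
  if (any(qx < 0 | qx > 1)) abort("parameters produce qx outside [0, 1]")
  qx[length(qx)] <- 1
  new_life_table(age, qx, population)
}

#' Expected years lived under a life table
#'
#' Survivor-years accounting identical to the Markov engine's life-year
#' accumulation: sum over cycles t = 0..horizon-1 of S(t), with S(0) = 1 and
#' S(t+1) = S(t) (1 - qx(t)). Each cycle lived contributes one year.
#'
#' @param table An `scd_life_table`.
#' @param horizon Number of annual cycles (default: table length).
#' @return Life expectancy in years.
#' @export
life_expectancy <- function(table, horizon = nrow(table)) {
  if (horizon > nrow(table)) abort("horizon exceeds life-table length")
  surv <- cumprod(c(1, 1 - table$qx[seq_len(horizon - 1)]))
  sum(surv)
}

#' Calibrate a Gompertz-Makeham table to a target life expectancy
#'
#' Holds the slope `b` and Makeham constant `c` fixed and solves for the
#' hazard scale `a` by bracketed root-finding so that [life_expectancy()] of
#' the synthesized table matches `target_le` within `tol` years. Used for the
#' default mortality stand-ins, anchored to the published undiscounted
#' lifetime totals (75.8 years unaffected, 54.9 years under SCD standard of
#' care) because the underlying simulated life tables are not public.
#'
#' @param target_le Target life expectancy in years (must lie strictly
#'   between 1 and `horizon`).
#' @param b Fixed age slope (default 0.085, a conventional adult-mortality
#'   log-hazard slope).
#' @param c Fixed age-independent hazard (default 0.001).
#' @param horizon Cycles used in the life-expectancy accounting (default 100).
#' @param max_age Last tabulated age (default 100).
#' @param tol Calibration tolerance in years (default 0.025).
#' @param population Label for the resulting table.
#' @return An `scd_life_table` with attribute `gm_params` = c(a, b, c).
#' @export
calibrate_life_table <- function(target_le, b = 0.085, c = 0.001,
                                 horizon = 100, max_age = 100, tol = 0.025,
                                 population = "calibrated") {
  if (target_le <= 1 || target_le >= horizon) {
    abort("target_le must lie strictly between 1 and the horizon")
  }
  le_at <- function(a) {
    life_expectancy(synthesize_life_table(a, b, c, max_age), horizon)
  }
  a_lo <- 1e-12
  a_hi <- 1
  le_max <- le_at(a_lo)
  le_min <- le_at(a_hi)
  if (target_le > le_max || target_le < le_min) {
    abort(paste0("target life expectancy ", target_le,
                 " is outside the achievable range [", round(le_min, 2), ", ",
                 round(le_max, 2), "] for b = ", b, ", c = ", c))
  }
  root <- stats::uniroot(function(a) le_at(a) - target_le,
                         lower = a_lo, upper = a_hi, tol = 1e-12)
  out <- synthesize_life_table(root$root, b, c, max_age, population)
  achieved <- life_expectancy(out, horizon)
  if (abs(achieved - target_le) > tol) {
    abort(paste0("calibration failed to converge: achieved ", achieved,
                 " vs target ", target_le))
  }
  attr(out, "gm_params") <- c(a = root$root, b = b, c = c)
  out
}

#' Default mortality pair for the two model populations
#'
#' Calibrated Gompertz-Makeham stand-ins for the unpublished simulated life
#' tables: the unaffected (healthy/remission) population targets 75.8
#' undiscounted expected years and the SCD population under standard of care
#' targets 54.9, the model's published lifetime totals. Both tables are shared
#' across genders. Supply real tables via [read_life_table()] instead when
#' available.
#'
#' @param target_healthy Target life expectancy for the unaffected table.
#' @param target_scd Target life expectancy for the SCD-adjusted table.
#' @param horizon Cycles for the accounting (default 100).
#' @return List with elements `healthy` and `scd`, each an `scd_life_table`.
#' @examples
#' tables <- default_life_tables()
#' life_expectancy(tables$scd, 100)
#' @export
default_life_tables <- function(target_healthy = 75.8, target_scd = 54.9,
                                horizon = 100) {
  list(
    healthy = calibrate_life_table(target_healthy, horizon = horizon,
                                   population = "unaffected (synthetic)"),
    scd = calibrate_life_table(target_scd, horizon = horizon,
                               population = "SCD-adjusted (synthetic)")
  )
}

#' Write a life table to CSV
#'
#' @param table An `scd_life_table`.
#' @param file Output path.
#' @return The input, invisibly.
#' @export
write_life_table <- function(table, file) {
  utils::write.csv(as.data.frame(table)[, c("age", "qx")], file, row.names = FALSE)
  invisible(table)
}
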