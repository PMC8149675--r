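#' Gender-specific gamma log-link cost regression coefficients
#'
#' @param params An `scd_parameters` object.
#' @param gender `"female"` or `"male"`.
#' @return Named numeric vector with elements `intercept`, `mild`, `moderate`,
#'   `severe`, `age`, `mild_age`, `moderate_age`, `severe_age`.
#' @export
cost_coefficients <- function(params, gender) {
  gender <- match.arg(gender, c("female", "male"))
  g <- if (gender == "female") "f" else "m"
  nm <- c("intercept", "mild", "moderate", "severe", "age",
          "mild_age", "moderate_age", "severe_age")
  stats::setNames(unname(parameter_value(params, paste0("cost_", g, "_", nm))), nm)
}

# log-mean of the gamma GLM at (state, age); healthy = matched-control
# prediction with all severity indicators zero
cost_log_mean <- function(coefs, state, age) {
  i_mi <- as.numeric(state == "mild")
  i_mo <- as.numeric(state == "moderate")
  i_se <- as.numeric(state == "severe")
  coefs[["intercept"]] +
    coefs[["mild"]] * i_mi + coefs[["moderate"]] * i_mo + coefs[["severe"]] * i_se +
    (coefs[["age"]] + coefs[["mild_age"]] * i_mi + coefs[["moderate_age"]] * i_mo +
       coefs[["severe_age"]] * i_se) * age
}

#' Predicted annual direct medical cost
#'
#' Evaluates the gamma log-link regression mean
#' exp(b0 + b1 I(mild) + b2 I(moderate) + b3 I(severe) + b4 age +
#' interactions) in
#' 2018 USD. The healthy/remission state uses the matched-control prediction
#' (all severity indicators zero); deceased patients incur zero cost.
#'
#' @param coefs Coefficient vector from [cost_coefficients()].
#' @param state One of `"healthy"`, `"mild"`, `"moderate"`, `"severe"`,
#'   `"dead"` (recycled against `age`).
#' @param age Age in years (vectorised, non-negative).
#' @return Numeric vector of annual costs (USD 2018).
#' @examples
#' params <- scd_parameters()
#' annual_cost(cost_coefficients(params, "male"), "healthy", 20)
#' @export
annual_cost <- function(coefs, state, age) {
  if (any(!state %in% model_states())) {
    abort(paste0("unknown state: ", setdiff(state, model_states())[1]))
  }
  if (any(age < 0)) abort("age must be non-negative")
  n <- max(length(state), length(age))
  state <- rep_len(state, n)
  age <- rep_len(age, n)
  out <- exp(cost_log_mean(coefs, state, age))
  out[state == "dead"] <- 0
  out
}

# control-utility age bands: 1-44, 45-54, 55-64, 65-74, 75+ (age 0 folds into
# the first band: the cohort starts at birth); SCD bands: 1-18 / 19+
control_band_suffix <- function(age) {
  c("1_44", "45_54", "55_64", "65_74", "75p")[findInterval(age, c(45, 55, 65, 75)) + 1]
}

#' Health-utility (QALY) weight by state, age and gender
#'
#' Healthy/remission patients get the gender- and age-band-specific
#' normative-population weight; patients in any affected state get the SCD
#' weight for their age band (child/adolescent 1-18 vs adult 19+,
#' severity-invariant); deceased patients get zero.
#'
#' @param params An `scd_parameters` object.
#' @param gender `"female"` or `"male"`.
#' @param state Model state (recycled against `age`).
#' @param age Age in years (vectorised, non-negative).
#' @return Numeric vector of utility weights in \[0, 1\].
#' @examples
#' utility_weight(scd_parameters(), "female", "healthy", 50)
#' @export
utility_weight <- function(params, gender, state, age) {
  gender <- match.arg(gender, c("female", "male"))
  if (any(!state %in% model_states())) {
    abort(paste0("unknown state: ", setdiff(state, model_states())[1]))
  }
  if (any(age < 0)) abort("age must be non-negative")
  n <- max(length(state), length(age))
  state <- rep_len(state, n)
  age <- rep_len(age, n)
  g <- if (gender == "female") "f" else "m"
  control <- unname(parameter_value(
    params, paste0("util_control_", g, "_", control_band_suffix(age))))
  scd <- ifelse(age <= 18,
                parameter_value(params, "util_scd_child"),
                parameter_value(params, "util_scd_adult"))
  out <- ifelse(state == "healthy", control, unname(scd))
  out[state == "dead"] <- 0
  out
}

#' Single-administration durable-therapy price
#'
#' The upfront price of the durable treatment, charged once at cycle 0 of the
#' DT arm and not discounted (it is incurred at time zero).
#'
#' @param params An `scd_parameters` object.
#' @return Price in 2018 USD.
#' @export
dt_upfront_cost <- function(params) {
  price <- unname(parameter_value(params, "dt_price"))
  if (price < 0) abort("dt_price must be non-negative")
  price
}

#' Cost and utility schedule over an age range
#'
#' @param params An `scd_parameters` object.
#' @param gender `"female"` or `"male"`.
#' @param ages Integer ages (default 0:100).
#' @return A tibble (gender, state, age, cost, utility) over all live states.
#' @export
reward_schedule <- function(params, gender, ages = 0:100) {
  coefs <- cost_coefficients(params, gender)
  purrr::map_dfr(setdiff(model_states(), "dead"), function(s) {
    # computed before tibble() so the gender column cannot mask the argument
    cost <- annual_cost(coefs, rep(s, length(ages)), ages)
    utility <- utility_weight(params, gender, rep(s, length(ages)), ages)
    tibble(gender = gender, state = s, age = ages, cost = cost, utility = utility)
  })
}

# per-age reward matrices for the engine: [n_ages x 5 states]
reward_matrices <- function(params, gender, ages) {
  coefs <- cost_coefficients(params, gender)
  st <- model_states()
  cost <- sapply(st, function(s) annual_cost(coefs, rep(s, length(ages)), ages))
  util <- sapply(st, function(s) utility_weight(params, gender, rep(s, length(ages)), ages))
  if (length(ages) == 1) {
    cost <- matrix(cost, 1, dimnames = list(NULL, st))
    util <- matrix(util, 1, dimnames = list(NULL, st))
  }
  list(cost = cost, utility = util)
}
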