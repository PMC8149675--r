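# Model states, in matrix order. "healthy" is post-cure remission; the three
# SCD states are defined by annualised vaso-occlusive crisis counts
# (mild = 0/yr, moderate in (0, 2)/yr, severe >= 2/yr); "dead" is absorbing.
model_states <- function() c("healthy", "mild", "moderate", "severe", "dead")
severity_levels <- function() c("mild", "moderate", "severe")

#' Gender-specific ordered-logit transition coefficients
#'
#' Extracts the cumulative-logit regression of next-year severity on
#' current-year severity and age (with severity-by-age interactions) from the
#' parameter registry, as a named vector.
#'
#' @param params An `scd_parameters` object.
#' @param gender `"female"` or `"male"`.
#' @return Named numeric vector with elements `moderate`, `severe`, `age`,
#'   `moderate_age`, `severe_age`, `cut1`, `cut2`.
#' @export
transition_coefficients <- function(params, gender) {
  gender <- match.arg(gender, c("female", "male"))
  g <- if (gender == "female") "f" else "m"
  nm <- c("moderate", "severe", "age", "moderate_age", "severe_age", "cut1", "cut2")
  stats::setNames(unname(parameter_value(params, paste0("ol_", g, "_", nm))), nm)
}

#' Ordered-logit linear predictor for a severity transition
#'
#' Computes xb = a1 I(moderate) + a2 I(severe) + a3 age + a4 I(moderate) age +
#' a5 I(severe) age, with mild severity as the reference category. Defined only
#' on affected states: the regression was estimated on patients living with
#' SCD, so `healthy` and `dead` are rejected.
#'
#' @param coefs Coefficient vector from [transition_coefficients()].
#' @param severity Current severity: `"mild"`, `"moderate"` or `"severe"`
#'   (recycled against `age`).
#' @param age Age in years at cycle start (vectorised).
#' @return Numeric vector of linear predictor values.
#' @export
linear_predictor <- function(coefs, severity, age) {
  if (any(!severity %in% severity_levels())) {
    abort("severity must be one of 'mild', 'moderate', 'severe' (the transition regression is defined only on affected states)")
  }
  if (any(age < 0)) abort("age must be non-negative")
  is_mod <- as.numeric(severity == "moderate")
  is_sev <- as.numeric(severity == "severe")
  coefs[["moderate"]] * is_mod + coefs[["severe"]] * is_sev +
    coefs[["age"]] * age +
    coefs[["moderate_age"]] * is_mod * age +
    coefs[["severe_age"]] * is_sev * age
}

#' Annual severity-transition probabilities for a surviving patient
#'
#' Cumulative-logit form with no separate intercept (the cut points absorb
#' it): P(mild) = logis(cut1 - xb), P(mild or moderate) = logis(cut2 - xb),
#' P(severe) = 1 - logis(cut2 - xb). Rows sum to 1 by construction.
#'
#' @inheritParams linear_predictor
#' @return A tibble with columns `severity`, `age`, `p_mild`, `p_moderate`,
#'   `p_severe`, one row per (severity, age) input pair.
#' @examples
#' params <- scd_parameters()
#' severity_transition(transition_coefficients(params, "female"), "moderate", 10)
#' @export
severity_transition <- function(coefs, severity, age) {
  xb <- linear_predictor(coefs, severity, age)
  p_le_mild <- stats::plogis(coefs[["cut1"]] - xb)
  p_le_mod <- stats::plogis(coefs[["cut2"]] - xb)
  tibble(
    severity = rep_len(severity, length(xb)),
    age = rep_len(age, length(xb)),
    p_mild = p_le_mild,
    p_moderate = p_le_mod - p_le_mild,
    p_severe = 1 - p_le_mod
  )
}

# 3x3 matrix of severity-transition rows at one age (origins x destinations);
# vectorised internals feed the cycle engine through severity_row_array().
severity_row_matrix <- function(coefs, age) {
  rows <- severity_transition(coefs, severity_levels(), rep(age, 3))
  m <- as.matrix(rows[, c("p_mild", "p_moderate", "p_severe")])
  dimnames(m) <- list(severity_levels(), severity_levels())
  m
}

# array [n_ages, 3 origins, 3 destinations] for ages; the engine's hot path
severity_row_array <- function(coefs, ages) {
  n <- length(ages)
  out <- array(NA_real_, c(n, 3, 3),
               dimnames = list(NULL, severity_levels(), severity_levels()))
  for (s in severity_levels()) {
    xb <- linear_predictor(coefs, rep(s, n), ages)
    p1 <- stats::plogis(coefs[["cut1"]] - xb)
    p2 <- stats::plogis(coefs[["cut2"]] - xb)
    out[, s, "mild"] <- p1
    out[, s, "moderate"] <- p2 - p1
    out[, s, "severe"] <- 1 - p2
  }
  out
}

#' Full five-state transition matrix for one annual cycle
#'
#' Assembles the row-stochastic matrix over (healthy, mild, moderate, severe,
#' dead) at a given age. Death is resolved first: each live row sends its
#' mortality mass to `dead` and distributes the survivor mass by the
#' conditional-on-survival rule — healthy survivors relapse to mild SCD with
#' probability `relapse_prob` (and otherwise stay healthy; an affected patient
#' can never return to remission), affected survivors move between severities
#' by the ordered-logit row.
#'
#' @inheritParams linear_predictor
#' @param age Age in years at cycle start.
#' @param q_healthy Annual death probability in the healthy/remission state.
#' @param q_scd Annual death probability in any affected state.
#' @param relapse_prob Annual probability that a cured patient relapses to
#'   mild SCD, conditional on survival.
#' @return A 5x5 named matrix with rows summing to 1.
#' @export
build_cycle_matrix <- function(coefs, age, q_healthy, q_scd, relapse_prob) {
  probs <- c(q_healthy = q_healthy, q_scd = q_scd, relapse_prob = relapse_prob)
  if (any(probs < 0 | probs > 1)) {
    bad <- names(probs)[probs < 0 | probs > 1][1]
    abort(paste0(bad, " must lie in [0, 1], got ", probs[[bad]]))
  }
  st <- model_states()
  m <- matrix(0, 5, 5, dimnames = list(st, st))
  m["healthy", "healthy"] <- (1 - q_healthy) * (1 - relapse_prob)
  m["healthy", "mild"] <- (1 - q_healthy) * relapse_prob
  m["healthy", "dead"] <- q_healthy
  sev <- severity_row_matrix(coefs, age)
  m[severity_levels(), severity_levels()] <- (1 - q_scd) * sev
  m[severity_levels(), "dead"] <- q_scd
  m["dead", "dead"] <- 1
  m
}

#' Severity-transition schedule over an age range
#'
#' Convenience export of the 3x3 conditional-on-survival severity rows for a
#' gender across ages, e.g. for plotting or external checks.
#'
#' @param params An `scd_parameters` object.
#' @param gender `"female"` or `"male"`.
#' @param ages Integer ages (default 0:100).
#' @return A tibble (gender, severity, age, p_mild, p_moderate, p_severe).
#' @export
transition_schedule <- function(params, gender, ages = 0:100) {
  coefs <- transition_coefficients(params, gender)
  purrr::map_dfr(severity_levels(), function(s) {
    severity_transition(coefs, rep(s, length(ages)), ages)
  }) |>
    dplyr::mutate(gender = gender, .before = 1)
}
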