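#' Classify disease severity from an annualized crisis count
#'
#' Severity classes follow the vaso-occlusive crisis (VOC) definition: mild =
#' zero crises per year, moderate = more than 0 but fewer than 2, severe = 2
#' or more.
#'
#' @param crisis_rate Annualized VOC count (non-negative, vectorised).
#' @return Character vector of `"mild"`, `"moderate"`, `"severe"`.
#' @examples
#' classify_severity(c(0, 1.5, 2))
#' @export
classify_severity <- function(crisis_rate) {
  if (any(crisis_rate < 0, na.rm = TRUE)) abort("crisis_rate must be non-negative")
  dplyr::case_when(
    crisis_rate == 0 ~ "mild",
    crisis_rate < 2 ~ "moderate",
    TRUE ~ "severe"
  )
}

# draw a crisis rate consistent with an assigned severity class
draw_crisis_rate <- function(severity) {
  n <- length(severity)
  out <- numeric(n)
  mod <- severity == "moderate"
  sev <- severity == "severe"
  out[mod] <- stats::runif(sum(mod), 0, 2)
  out[sev] <- 2 + stats::rexp(sum(sev), rate = 1)
  out
}

#' Generate a synthetic patient-year claims panel
#'
#' Emulates the statistical structure the model's estimation stage assumes:
#' each SCD patient contributes two panel years, with year-1 severity drawn
#' from the gender's initial severity mix, year-2 severity drawn from the
#' true ordered-logit transition row at the patient's age, and each year's
#' cost drawn from a gamma distribution whose mean is the gamma-GLM log-link
#' prediction for that (gender, state, age). Crisis rates are drawn
#' consistently with the assigned class (0 for mild, uniform on (0, 2) for
#' moderate, 2 + exponential for severe). Unaffected control patients
#' (severity `"control"`, crisis rate `NA`) are included so the cost
#' regression's reference level is estimable; they are generated directly —
#' matching is not simulated.
#'
#' @param params An `scd_parameters` object supplying the true coefficients
#'   and severity mixes.
#' @param n_patients Number of SCD patients (default 10,000).
#' @param n_controls Number of unaffected controls (default `n_patients`).
#' @param seed RNG seed.
#' @param gamma_shape Gamma dispersion (shape) of the cost noise (default
#'   1.5); `Inf` gives noiseless costs equal to the GLM mean.
#' @param age_range Inclusive integer range for year-1 ages (default 0-64, a
#'   commercially insured population).
#' @return A tibble (patient_id, gender, age, year, crisis_rate, severity,
#'   annual_cost), two rows per patient.
#' @examples
#' panel <- generate_panel(scd_parameters(), n_patients = 100, seed = 1)
#' table(panel$severity)
#' @export
generate_panel <- function(params, n_patients = 10000, n_controls = n_patients,
                           seed = 1, gamma_shape = 1.5, age_range = c(0, 64)) {
  if (n_patients < 1) abort("n_patients must be at least 1")
  if (gamma_shape <= 0) abort("gamma_shape must be positive")
  set.seed(seed)
  pf <- unname(parameter_value(params, "percent_female"))
  levels3 <- severity_levels()

  draw_cost <- function(gender, state, age) {
    log_mean <- numeric(length(state))
    for (g in c("female", "male")) {
      i <- gender == g
      if (any(i)) {
        log_mean[i] <- cost_log_mean(cost_coefficients(params, g), state[i], age[i])
      }
    }
    mean_cost <- exp(log_mean)
    if (is.infinite(gamma_shape)) return(mean_cost)
    stats::rgamma(length(mean_cost), shape = gamma_shape,
                  rate = gamma_shape / mean_cost)
  }

  gender <- ifelse(stats::runif(n_patients) < pf, "female", "male")
  age1 <- sample(seq(age_range[1], age_range[2]), n_patients, replace = TRUE)
  # year-1 severity from the gender's initial mix, by inverse-CDF
  u1 <- stats::runif(n_patients)
  sev1 <- character(n_patients)
  for (g in c("female", "male")) {
    i <- gender == g
    cdf <- cumsum(params$severity[[g]]$proportions)
    sev1[i] <- levels3[1 + findInterval(u1[i], cdf[1:2])]
  }
  # year-2 severity from the true ordered-logit row at (severity-1, age)
  u2 <- stats::runif(n_patients)
  sev2 <- character(n_patients)
  for (g in c("female", "male")) {
    i <- gender == g
    if (!any(i)) next
    coefs <- transition_coefficients(params, g)
    xb <- linear_predictor(coefs, sev1[i], age1[i])
    p1 <- stats::plogis(coefs[["cut1"]] - xb)
    p2 <- stats::plogis(coefs[["cut2"]] - xb)
    sev2[i] <- levels3[1 + (u2[i] >= p1) + (u2[i] >= p2)]
  }

  scd <- tibble(
    patient_id = rep(seq_len(n_patients), 2),
    gender = rep(gender, 2),
    age = c(age1, age1 + 1L),
    year = rep(1:2, each = n_patients),
    severity = c(sev1, sev2)
  )
  scd$crisis_rate <- draw_crisis_rate(scd$severity)
  scd$annual_cost <- draw_cost(scd$gender, scd$severity, scd$age)

  ctl_gender <- ifelse(stats::runif(n_controls) < pf, "female", "male")
  ctl_age1 <- sample(seq(age_range[1], age_range[2]), n_controls, replace = TRUE)
  controls <- tibble(
    patient_id = rep(n_patients + seq_len(n_controls), 2),
    gender = rep(ctl_gender, 2),
    age = c(ctl_age1, ctl_age1 + 1L),
    year = rep(1:2, each = n_controls),
    severity = "control",
    crisis_rate = NA_real_
  )
  controls$annual_cost <- draw_cost(controls$gender, rep("healthy", nrow(controls)),
                                    controls$age)

  dplyr::arrange(dplyr::bind_rows(scd, controls), .data$patient_id, .data$year)
}

# wide year-1/year-2 severity pairs for the transition regression
panel_transition_pairs <- function(panel) {
  scd <- dplyr::filter(panel, .data$severity != "control")
  wide <- tidyr::pivot_wider(
    dplyr::select(scd, "patient_id", "gender", "age", "year", "severity"),
    names_from = "year", values_from = c("severity", "age")
  )
  tibble(
    gender = wide$gender,
    age = wide$age_1,
    moderate1 = as.numeric(wide$severity_1 == "moderate"),
    severe1 = as.numeric(wide$severity_1 == "severe"),
    severity2 = factor(wide$severity_2, levels = severity_levels(), ordered = TRUE)
  )
}

#' Refit the ordered-logit severity-transition regressions
#'
#' Maximum-likelihood cumulative-logit fit (via [MASS::polr()], which uses
#' the same P(Y <= k) = logis(cut_k - xb) convention as the forward model) of
#' year-2 severity on year-1 severity indicators, age, and their
#' interactions, run separately by gender.
#'
#' @param panel A patient-year panel from [generate_panel()] (or with the
#'   same columns).
#' @return A tibble (gender, term, estimate, std_error) with terms named as
#'   in the parameter registry (`moderate`, `severe`, `age`, `moderate_age`,
#'   `severe_age`, `cut1`, `cut2`); the fitted `polr` objects are attached as
#'   attribute `fits`.
#' @export
fit_transition_model <- function(panel) {
  pairs <- panel_transition_pairs(panel)
  if (length(unique(pairs$gender)) < 2) {
    abort("panel must contain both genders")
  }
  fits <- list()
  out <- purrr::map_dfr(c("female", "male"), function(g) {
    df <- dplyr::filter(pairs, .data$gender == g)
    if (length(unique(df$age)) < 2) {
      abort("age has no variation: age coefficients are inestimable")
    }
    if (length(unique(as.character(df$severity2))) < 2) {
      abort("year-2 severity has fewer than 2 levels: cut points are inestimable")
    }
    fit <- tryCatch(
      MASS::polr(severity2 ~ moderate1 + severe1 + age +
                   moderate1:age + severe1:age,
                 data = df, method = "logistic", Hess = TRUE),
      error = function(e) abort(paste0("ordered-logit fit failed for ", g, ": ",
                                       conditionMessage(e)))
    )
    fits[[g]] <<- fit
    est <- c(stats::coef(fit), fit$zeta)
    se <- sqrt(diag(stats::vcov(fit)))
    key <- c(moderate1 = "moderate", severe1 = "severe", age = "age",
             `moderate1:age` = "moderate_age", `severe1:age` = "severe_age",
             `mild|moderate` = "cut1", `moderate|severe` = "cut2")
    tibble(gender = g, term = unname(key[names(est)]),
           estimate = unname(est), std_error = unname(se[names(est)]))
  })
  attr(out, "fits") <- fits
  out
}

#' Refit the gamma log-link cost regressions
#'
#' Gamma-family log-link GLM of annual cost on severity indicators (control
#' patients as reference), age, and severity-by-age interactions, run
#' separately by gender.
#'
#' @inheritParams fit_transition_model
#' @return A tibble (gender, term, estimate, std_error) with registry-style
#'   terms (`intercept`, `mild`, ..., `severe_age`); fitted `glm` objects
#'   attached as attribute `fits`.
#' @export
fit_cost_model <- function(panel) {
  if (any(panel$annual_cost <= 0)) abort("annual costs must be positive")
  if (length(unique(panel$gender)) < 2) abort("panel must contain both genders")
  fits <- list()
  out <- purrr::map_dfr(c("female", "male"), function(g) {
    df <- dplyr::filter(panel, .data$gender == g)
    df <- dplyr::mutate(
      df,
      mild = as.numeric(.data$severity == "mild"),
      moderate = as.numeric(.data$severity == "moderate"),
      severe = as.numeric(.data$severity == "severe")
    )
    fit <- tryCatch(
      stats::glm(annual_cost ~ mild + moderate + severe + age +
                   mild:age + moderate:age + severe:age,
                 family = stats::Gamma(link = "log"), data = df),
      error = function(e) abort(paste0("gamma GLM failed for ", g, ": ",
                                       conditionMessage(e)))
    )
    fits[[g]] <<- fit
    # near-zero dispersion (noiseless panels) makes the SEs degenerate; the
    # point estimates remain exact
    sm <- suppressWarnings(summary(fit)$coefficients)
    key <- c(`(Intercept)` = "intercept", mild = "mild", moderate = "moderate",
             severe = "severe", age = "age", `mild:age` = "mild_age",
             `moderate:age` = "moderate_age", `severe:age` = "severe_age")
    tibble(gender = g, term = unname(key[rownames(sm)]),
           estimate = unname(sm[, "Estimate"]),
           std_error = unname(sm[, "Std. Error"]))
  })
  attr(out, "fits") <- fits
  out
}

#' Map refitted coefficients back onto parameter-registry names
#'
#' Turns the outputs of [fit_transition_model()] and [fit_cost_model()] into
#' a named vector suitable for [update_parameters()], so the Markov pipeline
#' can be rebuilt from recovered (rather than true) coefficients.
#'
#' @param transition_fit Tibble from [fit_transition_model()].
#' @param cost_fit Tibble from [fit_cost_model()].
#' @return Named numeric vector of registry values.
#' @export
recovered_parameter_values <- function(transition_fit, cost_fit) {
  tv <- stats::setNames(
    transition_fit$estimate,
    paste0("ol_", ifelse(transition_fit$gender == "female", "f", "m"),
           "_", transition_fit$term)
  )
  cv <- stats::setNames(
    cost_fit$estimate,
    paste0("cost_", ifelse(cost_fit$gender == "female", "f", "m"),
           "_", cost_fit$term)
  )
  c(tv, cv)
}
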