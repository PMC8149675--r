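#' Convert a cumulative relapse probability to an annual probability
#'
#' Assumes a constant exponential relapse rate, so a cumulative probability
#' `p_T` of relapse within `T` years converts to
#' P_annual = 1 - (1 - p_T)^(1/T). With the default median-durability reading
#' (p_T = 0.5), T = 10 gives 0.06697 and T = 20 gives 0.03406.
#'
#' @param p_T Cumulative relapse probability by year `T`, in \[0, 1).
#' @param T Duration in years (>= 1).
#' @return Annual relapse probability (conditional on survival).
#' @examples
#' annual_relapse_probability(0.5, 10)
#' @export
annual_relapse_probability <- function(p_T, T) {
  if (any(p_T < 0) || any(p_T >= 1)) {
    abort("p_T must lie in [0, 1): certain relapse has no finite-rate representation")
  }
  if (any(T < 1)) abort("T must be at least 1 year")
  1 - (1 - p_T)^(1 / T)
}

#' Specify cure durability (waning)
#'
#' In `"lifetime"` mode the cure never wanes (annual relapse probability 0);
#' in `"median_years"` mode a median time-to-relapse of `median_years` (i.e.
#' cumulative relapse probability `p_T`, default 0.5, by that year) is
#' converted to a constant annual relapse probability via
#' [annual_relapse_probability()].
#'
#' @param mode `"lifetime"` or `"median_years"`. The shorthands `10` and `20`
#'   (numeric) are accepted and mean median durability of that many years.
#' @param median_years Years to median relapse (required in median mode).
#' @param p_T Cumulative relapse probability at `median_years` (default 0.5).
#' @return A list of class `scd_waning` with the derived `p_annual`.
#' @examples
#' waning_spec("lifetime")$p_annual
#' waning_spec(10)$p_annual
#' @export
waning_spec <- function(mode = "lifetime", median_years = NULL, p_T = 0.5) {
  if (is.numeric(mode)) {
    median_years <- mode
    mode <- "median_years"
  }
  mode <- match.arg(mode, c("lifetime", "median_years"))
  if (mode == "lifetime") {
    out <- list(mode = "lifetime", median_years = NA_real_, p_T = NA_real_, p_annual = 0)
  } else {
    if (is.null(median_years)) abort("median_years is required for median-durability waning")
    out <- list(mode = "median_years", median_years = median_years, p_T = p_T,
                p_annual = annual_relapse_probability(p_T, median_years))
  }
  structure(out, class = "scd_waning")
}

#' Initial state-occupancy vector for one arm
#'
#' All durable-therapy (DT) patients start cured at birth in the
#' healthy/remission state; standard-of-care (SOC) patients start distributed
#' over mild/moderate/severe SCD by the gender's observed early-childhood
#' severity mix.
#'
#' @param params An `scd_parameters` object.
#' @param arm `"dt"` or `"soc"`.
#' @param gender `"female"` or `"male"`.
#' @return Named 5-vector of proportions over the model states.
#' @export
initial_state_vector <- function(params, arm, gender) {
  arm <- match.arg(arm, c("dt", "soc"))
  gender <- match.arg(gender, c("female", "male"))
  v <- stats::setNames(numeric(5), model_states())
  if (arm == "dt") {
    v["healthy"] <- 1
  } else {
    v[severity_levels()] <- params$severity[[gender]]$proportions
  }
  v
}

# engine precomputations for one (params, gender): transition rows, rewards,
# death probabilities over ages 0..H-1
build_model_inputs <- function(params, gender, life_tables, horizon) {
  if (horizon > nrow(life_tables$healthy) || horizon > nrow(life_tables$scd)) {
    abort("horizon exceeds life-table length")
  }
  ages <- 0:(horizon - 1)
  rw <- reward_matrices(params, gender, ages)
  list(
    ages = ages,
    sev = severity_row_array(transition_coefficients(params, gender), ages),
    cost = rw$cost,
    utility = rw$utility,
    q_healthy = life_tables$healthy$qx[seq_len(horizon)],
    q_scd = life_tables$scd$qx[seq_len(horizon)]
  )
}

#' Run the lifetime cohort simulation for one arm
#'
#' Follows a closed cohort (expected state proportions, not sampled
#' individuals) over `horizon` annual cycles from birth. Within each cycle,
#' death is resolved first from the state-appropriate life table; severity
#' transitions (and relapse, in the DT arm) apply only to survivors. Cycle-t
#' rewards accrue to the state occupied at cycle start and are discounted by
#' (1 + r)^(-t); the DT arm's upfront price is charged once at time zero,
#' undiscounted. Optional half-cycle correction averages start- and
#' end-of-cycle occupancy for rewards.
#'
#' @param params An `scd_parameters` object.
#' @param arm `"dt"` or `"soc"`.
#' @param gender `"female"` or `"male"`.
#' @param life_tables List with `healthy` and `scd` life tables (default:
#'   [default_life_tables()]).
#' @param waning An `scd_waning` object (default lifetime durability). Only
#'   relevant for the DT arm.
#' @param discount_rate Override of the registry's annual discount rate.
#' @param half_cycle Apply half-cycle correction to rewards (default FALSE).
#' @param keep_trace Store the cohort trace tibble (default TRUE; the PSA
#'   loop disables it for speed).
#' @param .inputs Precomputed [build_model_inputs()] output shared between
#'   arms of the same gender (internal fast path).
#' @return An object of class `scd_arm_result`: per-patient discounted and
#'   undiscounted cost (USD 2018), QALYs and life years, plus the cohort
#'   trace (tibble `cycle` x state occupancy).
#' @examples
#' params <- scd_parameters()
#' tables <- default_life_tables()
#' soc <- run_cohort(params, "soc", "female", tables)
#' glance(soc)
#' @export
run_cohort <- function(params, arm, gender,
                       life_tables = default_life_tables(),
                       waning = waning_spec("lifetime"),
                       discount_rate = NULL, half_cycle = FALSE,
                       keep_trace = TRUE, .inputs = NULL) {
  arm <- match.arg(arm, c("dt", "soc"))
  gender <- match.arg(gender, c("female", "male"))
  if (!inherits(waning, "scd_waning")) waning <- waning_spec(waning)
  r <- discount_rate %||% unname(parameter_value(params, "discount_rate"))
  horizon <- params$cohort$horizon
  inputs <- .inputs %||% build_model_inputs(params, gender, life_tables, horizon)
  relapse <- if (arm == "dt") waning$p_annual else 0
  v <- initial_state_vector(params, arm, gender)

  occupancy <- matrix(NA_real_, horizon + 1, 5,
                      dimnames = list(NULL, model_states()))
  occupancy[1, ] <- v
  disc <- (1 + r)^(-(0:(horizon - 1)))
  cost_t <- qaly_t <- ly_t <- numeric(horizon)

  # hot loop: scalar state variables, flat vectors, no per-cycle allocation
  sev <- inputs$sev
  p11 <- sev[, 1, 1]; p12 <- sev[, 1, 2]; p13 <- sev[, 1, 3]
  p21 <- sev[, 2, 1]; p22 <- sev[, 2, 2]; p23 <- sev[, 2, 3]
  p31 <- sev[, 3, 1]; p32 <- sev[, 3, 2]; p33 <- sev[, 3, 3]
  ch <- inputs$cost[, 1]; c1 <- inputs$cost[, 2]
  c2 <- inputs$cost[, 3]; c3 <- inputs$cost[, 4]
  uh <- inputs$utility[, 1]; u1 <- inputs$utility[, 2]
  u2 <- inputs$utility[, 3]; u3 <- inputs$utility[, 4]
  q_h <- inputs$q_healthy
  q_s <- inputs$q_scd
  h <- v[[1]]; m1 <- v[[2]]; m2 <- v[[3]]; m3 <- v[[4]]; d <- v[[5]]
  hv <- m1v <- m2v <- m3v <- dv <- numeric(horizon)
  for (t in seq_len(horizon)) {
    sh <- h * (1 - q_h[t])
    surv <- 1 - q_s[t]
    s1 <- m1 * surv; s2 <- m2 * surv; s3 <- m3 * surv
    d_n <- d + h * q_h[t] + (m1 + m2 + m3) * q_s[t]
    h_n <- sh * (1 - relapse)
    m1_n <- sh * relapse + s1 * p11[t] + s2 * p21[t] + s3 * p31[t]
    m2_n <- s1 * p12[t] + s2 * p22[t] + s3 * p32[t]
    m3_n <- s1 * p13[t] + s2 * p23[t] + s3 * p33[t]
    if (half_cycle) {
      wh <- (h + h_n) / 2; w1 <- (m1 + m1_n) / 2; w2 <- (m2 + m2_n) / 2
      w3 <- (m3 + m3_n) / 2; wd <- (d + d_n) / 2
    } else {
      wh <- h; w1 <- m1; w2 <- m2; w3 <- m3; wd <- d
    }
    cost_t[t] <- wh * ch[t] + w1 * c1[t] + w2 * c2[t] + w3 * c3[t]
    qaly_t[t] <- wh * uh[t] + w1 * u1[t] + w2 * u2[t] + w3 * u3[t]
    ly_t[t] <- 1 - wd
    h <- h_n; m1 <- m1_n; m2 <- m2_n; m3 <- m3_n; d <- d_n
    hv[t] <- h; m1v[t] <- m1; m2v[t] <- m2; m3v[t] <- m3; dv[t] <- d
  }
  occupancy[-1, 1] <- hv; occupancy[-1, 2] <- m1v; occupancy[-1, 3] <- m2v
  occupancy[-1, 4] <- m3v; occupancy[-1, 5] <- dv

  upfront <- if (arm == "dt") dt_upfront_cost(params) else 0
  totals <- list(
    cost_disc = sum(cost_t * disc) + upfront,
    cost_undisc = sum(cost_t) + upfront,
    qaly_disc = sum(qaly_t * disc),
    qaly_undisc = sum(qaly_t),
    ly_disc = sum(ly_t * disc),
    ly_undisc = sum(ly_t)
  )
  trace <- if (keep_trace) {
    dplyr::mutate(as_tibble(occupancy), cycle = 0:horizon, .before = 1)
  } else NULL
  structure(
    c(list(arm = arm, gender = gender, discount_rate = r,
           waning = waning, half_cycle = half_cycle, trace = trace),
      totals),
    class = "scd_arm_result"
  )
}

#' Pool female and male arm results into a cohort result
#'
#' Convex combination of all per-patient totals with weights
#' (`percent_female`, 1 - `percent_female`); the traces pool the same way.
#'
#' @param result_f,result_m `scd_arm_result` objects for the two genders,
#'   sharing arm and configuration.
#' @param percent_female Proportion of females in the cohort, in \[0, 1\].
#' @return A pooled `scd_arm_result` (gender `"pooled"`).
#' @export
pooled_result <- function(result_f, result_m, percent_female) {
  if (percent_female < 0 || percent_female > 1) {
    abort("percent_female must lie in [0, 1]")
  }
  if (!identical(result_f$arm, result_m$arm)) {
    abort("cannot pool results from different arms")
  }
  w <- percent_female
  out <- result_f
  out$gender <- "pooled"
  for (f in c("cost_disc", "cost_undisc", "qaly_disc", "qaly_undisc",
              "ly_disc", "ly_undisc")) {
    out[[f]] <- w * result_f[[f]] + (1 - w) * result_m[[f]]
  }
  st <- model_states()
  out$trace[st] <- w * result_f$trace[st] + (1 - w) * result_m$trace[st]
  out
}

#' @export
print.scd_arm_result <- function(x, ...) {
  cat(sprintf("<scd_arm_result> arm %s, %s (r = %.3f)\n", toupper(x$arm),
              x$gender, x$discount_rate))
  cat(sprintf("  discounted:   cost $%s, %.1f QALYs, %.1f LYs\n",
              format(round(x$cost_disc), big.mark = ","), x$qaly_disc, x$ly_disc))
  cat(sprintf("  undiscounted: cost $%s, %.1f QALYs, %.1f LYs\n",
              format(round(x$cost_undisc), big.mark = ","), x$qaly_undisc, x$ly_undisc))
  invisible(x)
}

#' Tidy an arm result into a long tibble
#'
#' @param x An `scd_arm_result`.
#' @param ... Unused.
#' @return A tibble (arm, gender, quantity, discounted, value), one row per
#'   accumulated total.
#' @export
tidy.scd_arm_result <- function(x, ...) {
  tibble(
    arm = x$arm, gender = x$gender,
    quantity = rep(c("cost", "qaly", "ly"), each = 2),
    discounted = rep(c(TRUE, FALSE), 3),
    value = c(x$cost_disc, x$cost_undisc, x$qaly_disc, x$qaly_undisc,
              x$ly_disc, x$ly_undisc)
  )
}

#' One-row summary of an arm result
#'
#' @param x An `scd_arm_result`.
#' @param ... Unused.
#' @return A one-row tibble with all six totals.
#' @export
glance.scd_arm_result <- function(x, ...) {
  tibble(
    arm = x$arm, gender = x$gender,
    cost_disc = x$cost_disc, qaly_disc = x$qaly_disc, ly_disc = x$ly_disc,
    cost_undisc = x$cost_undisc, qaly_undisc = x$qaly_undisc,
    ly_undisc = x$ly_undisc
  )
}

#' Plot the cohort trace of an arm result
#'
#' Stacked-area Markov trace: state occupancy proportions by cycle.
#'
#' @param object An `scd_arm_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scd_arm_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trace, -"cycle",
                              names_to = "state", values_to = "proportion")
  long$state <- factor(long$state, levels = rev(model_states()))
  ggplot2::ggplot(long, ggplot2::aes(.data$cycle, .data$proportion, fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(
      title = sprintf("Markov trace, %s arm (%s)", toupper(object$arm), object$gender),
      x = "Cycle (age, years)", y = "Proportion of cohort", fill = "State"
    )
}
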