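#' Run both arms and genders and pool into one comparison
#'
#' Convenience driver used by the base case and all sensitivity analyses:
#' runs the DT and SOC cohorts for each gender, pools by the registry's
#' `percent_female`, and computes the incremental comparison.
#'
#' @param params An `scd_parameters` object.
#' @param life_tables List with `healthy` and `scd` life tables.
#' @param waning An `scd_waning` (or value accepted by [waning_spec()]).
#' @param wtp Willingness-to-pay threshold (default: registry value).
#' @param half_cycle Apply half-cycle correction (default FALSE).
#' @return A list with per-gender and pooled `scd_arm_result`s (`dt`, `soc`
#'   each a list `female`/`male`/`pooled`) and `cea` (pooled `scd_cea`).
#' @export
evaluate_model <- function(params, life_tables = default_life_tables(),
                           waning = waning_spec("lifetime"),
                           wtp = NULL, half_cycle = FALSE) {
  if (!inherits(waning, "scd_waning")) waning <- waning_spec(waning)
  wtp <- wtp %||% params$cohort$wtp
  pf <- unname(parameter_value(params, "percent_female"))
  arms <- list()
  for (arm in c("dt", "soc")) {
    res <- purrr::map(c(female = "female", male = "male"), function(g) {
      run_cohort(params, arm, g, life_tables, waning, half_cycle = half_cycle)
    })
    res$pooled <- pooled_result(res$female, res$male, pf)
    arms[[arm]] <- res
  }
  list(
    dt = arms$dt, soc = arms$soc,
    cea = icer(arms$dt$pooled, arms$soc$pooled, wtp = wtp)
  )
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-evaluates the full pipeline with each DSA-eligible parameter set to its
#' low and high bound (95% CI, or +/-20% of base when no CI is available),
#' all other parameters held at base, and records the resulting pooled ICERs.
#' A model failure at a bound is recorded as `NA` with a warning rather than
#' aborting the sweep.
#'
#' @inheritParams evaluate_model
#' @param names Optional subset of parameter names to vary (default: all
#'   DSA-eligible entries).
#' @return A tibble of class `scd_tornado` with columns `parameter`, `low`,
#'   `high`, `icer_low`, `icer_high`, `swing`, sorted by descending swing.
#' @export
one_way_dsa <- function(params, life_tables = default_life_tables(),
                        waning = waning_spec("lifetime"), wtp = NULL,
                        names = NULL) {
  bounds <- dsa_bounds(params, names)
  if (nrow(bounds) == 0) abort("no DSA-eligible parameters")
  eval_at <- function(name, value) {
    tryCatch(
      evaluate_model(update_parameters(params, stats::setNames(value, name)),
                     life_tables, waning, wtp)$cea$icer,
      error = function(e) {
        warning("DSA evaluation failed for '", name, "' at ", value, ": ",
                conditionMessage(e), call. = FALSE)
        NA_real_
      }
    )
  }
  out <- purrr::pmap_dfr(bounds, function(name, base, low, high) {
    tibble(
      parameter = name, low = low, high = high,
      icer_low = eval_at(name, low),
      icer_high = eval_at(name, high)
    )
  })
  out <- dplyr::mutate(out, swing = abs(.data$icer_high - .data$icer_low))
  out <- dplyr::arrange(out, dplyr::desc(.data$swing), .data$parameter)
  structure(out, class = c("scd_tornado", class(out)))
}

#' Two-way deterministic sensitivity analysis
#'
#' Evaluates the pooled ICER on a dense grid over two parameters' DSA ranges
#' and labels each cell with the lowest willingness-to-pay level at which DT
#' is cost-effective there.
#'
#' @inheritParams evaluate_model
#' @param name_a,name_b DSA-eligible parameter names.
#' @param grid_size Points per axis (default 11; base values are included
#'   when they fall on the grid, and the center cell equals the base case at
#'   odd sizes).
#' @param wtp_levels Willingness-to-pay levels to classify against (USD/QALY).
#' @return A tibble (value_a, value_b, icer, ce_at) where `ce_at` is the
#'   lowest level in `wtp_levels` at which DT is cost-effective (`NA` if
#'   none).
#' @export
two_way_dsa <- function(params, name_a, name_b, grid_size = 11,
                        wtp_levels = seq(50000, 300000, by = 50000),
                        life_tables = default_life_tables(),
                        waning = waning_spec("lifetime")) {
  ba <- dsa_bounds(params, name_a)
  bb <- dsa_bounds(params, name_b)
  grid <- tidyr::expand_grid(
    value_a = seq(ba$low, ba$high, length.out = grid_size),
    value_b = seq(bb$low, bb$high, length.out = grid_size)
  )
  grid$icer <- purrr::map2_dbl(grid$value_a, grid$value_b, function(a, b) {
    p <- update_parameters(params, stats::setNames(c(a, b), c(name_a, name_b)))
    evaluate_model(p, life_tables, waning)$cea$icer
  })
  grid$ce_at <- purrr::map_dbl(grid$icer, function(ic) {
    ok <- wtp_levels[!is.na(ic) & ic <= wtp_levels]
    if (length(ok) == 0) NA_real_ else min(ok)
  })
  dplyr::mutate(grid, parameter_a = name_a, parameter_b = name_b, .before = 1)
}

#' Probabilistic sensitivity analysis (Monte Carlo)
#'
#' Draws `n_iter` independent parameter vectors via [sample_psa_draw()],
#' rebuilds the transition, cost, utility and initial-severity inputs from
#' each draw, runs both arms for both genders, and pools by the drawn female
#' share. Draws with inverted ordered-logit cut points are rejected and
#' redrawn (preserving the stated marginal distributions); the rejection
#' count is recorded. A master seed spawns one sub-seed per iteration so any
#' iteration is reproducible in isolation.
#'
#' @param params An `scd_parameters` object.
#' @param n_iter Number of Monte Carlo iterations (default 10,000).
#' @param seed Master seed.
#' @param life_tables List with `healthy` and `scd` life tables (fixed across
#'   iterations: mortality is not part of the sampled registry).
#' @param waning An `scd_waning` (or value accepted by [waning_spec()]).
#' @return An object of class `scd_psa`: list with `results` (tibble
#'   `iter`, `cost_dt`, `qaly_dt`, `ly_dt`, `cost_soc`, `qaly_soc`, `ly_soc`,
#'   pooled per-patient discounted totals), `draws` (tibble of the sampled
#'   parameter vectors), `n_rejected`, and `seed`.
#' @examples
#' psa <- run_psa(scd_parameters(), n_iter = 20, seed = 1)
#' evpi(psa, 150000)
#' @export
run_psa <- function(params, n_iter = 10000, seed = 1,
                    life_tables = default_life_tables(),
                    waning = waning_spec("lifetime")) {
  if (n_iter < 1) abort("n_iter must be at least 1")
  if (!inherits(waning, "scd_waning")) waning <- waning_spec(waning)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_iter)
  horizon <- params$cohort$horizon
  n_rejected <- 0L
  draws <- vector("list", n_iter)
  rows <- vector("list", n_iter)

  for (k in seq_len(n_iter)) {
    set.seed(sub_seeds[k])
    repeat {
      draw <- sample_psa_draw(params)
      if (draw_is_valid(draw)) break
      n_rejected <- n_rejected + 1L
    }
    p_k <- update_parameters(params, draw)
    pf <- draw[["percent_female"]]
    acc <- c(cost_dt = 0, qaly_dt = 0, ly_dt = 0,
             cost_soc = 0, qaly_soc = 0, ly_soc = 0)
    for (g in c("female", "male")) {
      w <- if (g == "female") pf else 1 - pf
      inputs_g <- build_model_inputs(p_k, g, life_tables, horizon)
      for (arm in c("dt", "soc")) {
        res <- run_cohort(p_k, arm, g, life_tables, waning,
                          keep_trace = FALSE, .inputs = inputs_g)
        acc[paste0(c("cost_", "qaly_", "ly_"), arm)] <-
          acc[paste0(c("cost_", "qaly_", "ly_"), arm)] +
          w * c(res$cost_disc, res$qaly_disc, res$ly_disc)
      }
    }
    draws[[k]] <- draw
    rows[[k]] <- acc
  }

  results <- as_tibble(do.call(rbind, rows))
  results <- dplyr::mutate(results, iter = dplyr::row_number(), .before = 1)
  draws_tbl <- as_tibble(do.call(rbind, draws))
  draws_tbl <- dplyr::mutate(draws_tbl, iter = dplyr::row_number(), .before = 1)
  if (n_rejected > 0) {
    message(n_rejected, " invalid draw(s) rejected and redrawn")
  }
  structure(
    list(results = results, draws = draws_tbl, n_rejected = n_rejected,
         seed = seed, n_iter = n_iter),
    class = "scd_psa"
  )
}

#' @export
print.scd_psa <- function(x, ...) {
  cat("<scd_psa>", x$n_iter, "iterations (seed", x$seed, ");",
      x$n_rejected, "rejected draws\n")
  invisible(x)
}

#' Tidy a PSA sample set
#'
#' @param x An `scd_psa` object.
#' @param ... Unused.
#' @return The per-iteration results tibble with incremental columns
#'   `delta_cost` and `delta_qaly` appended.
#' @export
tidy.scd_psa <- function(x, ...) {
  dplyr::mutate(
    x$results,
    delta_cost = .data$cost_dt - .data$cost_soc,
    delta_qaly = .data$qaly_dt - .data$qaly_soc
  )
}

#' Fraction of PSA iterations in which DT is cost-effective
#'
#' @param psa An `scd_psa` sample set.
#' @param lambda Willingness-to-pay value(s) in USD/QALY.
#' @param rule Decision rule, as in [ceac_ceaf()].
#' @return Proportion(s) in \[0, 1\], one per `lambda`.
#' @export
prob_cost_effective <- function(psa, lambda, rule = c("nmb", "icer_threshold")) {
  rule <- match.arg(rule)
  curves <- ceac_ceaf(psa, lambda_grid = lambda, rule = rule)
  curves$p_dt
}

#' Plot a tornado diagram
#'
#' @param object An `scd_tornado` tibble from [one_way_dsa()].
#' @param top Number of parameters to show (default 10).
#' @param base_icer Optional base-case ICER drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scd_tornado <- function(object, top = 10, base_icer = NULL, ...) {
  df <- utils::head(object, top)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  p <- ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low, xend = .data$icer_high,
                                       y = .data$parameter, yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::labs(title = "One-way deterministic sensitivity analysis",
                  x = "ICER (USD/QALY)", y = NULL)
  if (!is.null(base_icer)) {
    p <- p + ggplot2::geom_vline(xintercept = base_icer, linetype = "dashed")
  }
  p
}

#' Plot the PSA cost-effectiveness plane
#'
#' @param object An `scd_psa` object.
#' @param wtp Threshold line slope in USD/QALY (default 150,000).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scd_psa <- function(object, wtp = 150000, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$delta_qaly, .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed") +
    ggplot2::labs(title = "Cost-effectiveness plane (DT vs SOC)",
                  x = "Incremental QALYs", y = "Incremental cost (USD)")
}
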