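#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Incremental cost-effectiveness of durable therapy versus standard of care
#'
#' Computes discounted incremental cost, QALYs and life years, the ICER
#' (incremental cost per QALY gained), net monetary benefit per arm at the
#' willingness-to-pay threshold, and a dominance flag. When the sign of the
#' QALY difference and cost difference disagree the ICER is not a meaningful
#' number and is reported as `NA` with the dominance flag set
#' (`"dt_dominant"`: cheaper and more effective; `"dt_dominated"`: costlier
#' and less effective; `"indeterminate"`: no QALY difference).
#'
#' @param dt,soc `scd_arm_result` objects for the durable-therapy and
#'   standard-of-care arms (same configuration).
#' @param wtp Willingness-to-pay threshold in USD/QALY (default 150,000).
#' @return An object of class `scd_cea` with fields `delta_cost`,
#'   `delta_qaly`, `delta_ly`, `icer`, `dominance`, `wtp`, `nmb_dt`,
#'   `nmb_soc`.
#' @examples
#' params <- scd_parameters()
#' tables <- default_life_tables()
#' res <- icer(run_cohort(params, "dt", "female", tables),
#'             run_cohort(params, "soc", "female", tables))
#' res$icer
#' @export
icer <- function(dt, soc, wtp = 150000) {
  delta_cost <- dt$cost_disc - soc$cost_disc
  delta_qaly <- dt$qaly_disc - soc$qaly_disc
  delta_ly <- dt$ly_disc - soc$ly_disc
  dominance <- "none"
  ratio <- NA_real_
  if (delta_qaly == 0) {
    dominance <- "indeterminate"
  } else if (delta_qaly > 0 && delta_cost <= 0) {
    dominance <- "dt_dominant"
  } else if (delta_qaly < 0 && delta_cost >= 0) {
    dominance <- "dt_dominated"
  } else {
    ratio <- delta_cost / delta_qaly
  }
  structure(
    list(
      delta_cost = delta_cost, delta_qaly = delta_qaly, delta_ly = delta_ly,
      icer = ratio, dominance = dominance, wtp = wtp,
      nmb_dt = nmb(dt, wtp), nmb_soc = nmb(soc, wtp)
    ),
    class = "scd_cea"
  )
}

#' Net monetary benefit
#'
#' NMB = lambda * discounted QALYs - discounted cost. The arm with the higher
#' NMB at a threshold lambda is the optimal choice at that threshold.
#'
#' @param result An `scd_arm_result`, or a numeric discounted cost (then
#'   `qaly` must be given).
#' @param lambda Willingness to pay in USD/QALY (>= 0).
#' @param qaly Discounted QALYs when `result` is a numeric cost.
#' @return NMB in USD.
#' @export
nmb <- function(result, lambda, qaly = NULL) {
  if (any(lambda < 0)) abort("lambda must be non-negative")
  if (inherits(result, "scd_arm_result")) {
    lambda * result$qaly_disc - result$cost_disc
  } else {
    if (is.null(qaly)) abort("qaly is required when result is a numeric cost")
    lambda * qaly - result
  }
}

#' Threshold price of the durable therapy at a willingness-to-pay level
#'
#' The upfront price enters incremental cost one-for-one and undiscounted, so
#' ICER(p) = (delta_cost + (p - p0)) / delta_qaly is linear in the price p.
#' The price at which the ICER equals `lambda` is therefore
#' p* = p0 + (lambda * delta_qaly - delta_cost).
#'
#' @param base An `scd_cea` result evaluated at price `p0`, or a numeric
#'   incremental cost (then `delta_qaly` must be given).
#' @param p0 Upfront price at which `base` was computed (USD).
#' @param lambda Willingness-to-pay threshold in USD/QALY.
#' @param delta_qaly Incremental QALYs when `base` is numeric.
#' @return The threshold price p* in USD.
#' @examples
#' # price at which an incremental cost of $1.2M per 8.5 QALYs meets $150K/QALY
#' threshold_price(1.2e6, p0 = 2.1e6, lambda = 1.5e5, delta_qaly = 8.5)
#' @export
threshold_price <- function(base, p0, lambda, delta_qaly = NULL) {
  if (inherits(base, "scd_cea")) {
    delta_cost <- base$delta_cost
    delta_qaly <- base$delta_qaly
  } else {
    delta_cost <- base
    if (is.null(delta_qaly)) abort("delta_qaly is required when base is numeric")
  }
  if (delta_qaly <= 0) {
    abort("threshold price is defined only when the therapy gains QALYs (delta_qaly > 0)")
  }
  p0 + (lambda * delta_qaly - delta_cost)
}

# per-iteration NMB matrix from a PSA sample set: columns dt, soc
psa_nmb <- function(psa, lambda) {
  res <- psa$results
  cbind(dt = lambda * res$qaly_dt - res$cost_dt,
        soc = lambda * res$qaly_soc - res$cost_soc)
}

#' Cost-effectiveness acceptability curves and frontier
#'
#' From a PSA sample set, computes at each willingness-to-pay value the
#' probability that each arm is optimal (CEAC), the frontier arm (CEAF: the
#' arm with the highest expected NMB), and the per-patient expected value of
#' perfect information (EVPI). The default decision rule awards each
#' iteration to the arm with the higher net monetary benefit (ties to the
#' standard-of-care incumbent); `rule = "icer_threshold"` instead counts
#' iterations with a positive-QALY-gain ICER below lambda as DT wins, the
#' literal published counting rule (the two coincide whenever DT gains QALYs
#' at extra cost).
#'
#' @param psa An `scd_psa` sample set from [run_psa()].
#' @param lambda_grid Willingness-to-pay grid in USD/QALY (default 0 to
#'   300,000 by 5,000).
#' @param rule `"nmb"` (default) or `"icer_threshold"`.
#' @return A tibble of class `scd_voi` with columns `lambda`, `p_dt`,
#'   `p_soc`, `frontier`, `evpi`.
#' @export
ceac_ceaf <- function(psa, lambda_grid = seq(0, 300000, by = 5000),
                      rule = c("nmb", "icer_threshold")) {
  rule <- match.arg(rule)
  if (nrow(psa$results) == 0) abort("empty PSA sample set")
  rows <- purrr::map_dfr(lambda_grid, function(l) {
    nm <- psa_nmb(psa, l)
    if (rule == "nmb") {
      dt_wins <- nm[, "dt"] > nm[, "soc"]
    } else {
      dq <- psa$results$qaly_dt - psa$results$qaly_soc
      dc <- psa$results$cost_dt - psa$results$cost_soc
      dt_wins <- (dq > 0 & dc / dq < l) | (dq > 0 & dc <= 0)
    }
    p_dt <- mean(dt_wins)
    means <- colMeans(nm)
    tibble(
      lambda = l, p_dt = p_dt, p_soc = 1 - p_dt,
      frontier = if (means["dt"] > means["soc"]) "dt" else "soc",
      evpi = mean(pmax(nm[, "dt"], nm[, "soc"])) - max(means)
    )
  })
  structure(rows, class = c("scd_voi", class(rows)))
}

#' Expected value of perfect information
#'
#' EVPI(lambda) = E\[max over arms of NMB\] - max over arms of E\[NMB\]: the
#' expected per-patient gain from resolving all parameter uncertainty before
#' choosing an arm. Non-negative by construction.
#'
#' @param psa An `scd_psa` sample set from [run_psa()].
#' @param lambda Willingness to pay in USD/QALY (vectorised).
#' @return EVPI in USD per patient, one value per `lambda`.
#' @export
evpi <- function(psa, lambda) {
  if (nrow(psa$results) == 0) abort("empty PSA sample set")
  vapply(lambda, function(l) {
    nm <- psa_nmb(psa, l)
    mean(pmax(nm[, "dt"], nm[, "soc"])) - max(colMeans(nm))
  }, numeric(1))
}

#' @export
print.scd_cea <- function(x, ...) {
  cat("<scd_cea>\n")
  cat(sprintf("  delta cost  $%s\n", format(round(x$delta_cost), big.mark = ",")))
  cat(sprintf("  delta QALY  %.3f   delta LY %.3f\n", x$delta_qaly, x$delta_ly))
  if (is.na(x$icer)) {
    cat("  ICER: not defined (", x$dominance, ")\n", sep = "")
  } else {
    cat(sprintf("  ICER  $%s/QALY (WTP $%s)\n",
                format(round(x$icer), big.mark = ","),
                format(x$wtp, big.mark = ",")))
  }
  invisible(x)
}

#' Tidy a cost-effectiveness result
#'
#' @param x An `scd_cea` object.
#' @param ... Unused.
#' @return A one-row tibble with incremental quantities, ICER, dominance flag
#'   and per-arm NMB at the stored threshold.
#' @export
tidy.scd_cea <- function(x, ...) {
  tibble(
    delta_cost = x$delta_cost, delta_qaly = x$delta_qaly, delta_ly = x$delta_ly,
    icer = x$icer, dominance = x$dominance, wtp = x$wtp,
    nmb_dt = x$nmb_dt, nmb_soc = x$nmb_soc
  )
}

#' @rdname tidy.scd_cea
#' @export
glance.scd_cea <- tidy.scd_cea

#' Plot CEAC/CEAF or EVPI curves
#'
#' @param object An `scd_voi` tibble from [ceac_ceaf()].
#' @param what `"ceac"` (acceptability curves with the frontier highlighted)
#'   or `"evpi"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scd_voi <- function(object, what = c("ceac", "evpi"), ...) {
  what <- match.arg(what)
  if (what == "ceac") {
    long <- tidyr::pivot_longer(object, c("p_dt", "p_soc"),
                                names_to = "arm", values_to = "probability")
    long$arm <- ifelse(long$arm == "p_dt", "DT", "SOC")
    ggplot2::ggplot(long, ggplot2::aes(.data$lambda, .data$probability,
                                       colour = .data$arm)) +
      ggplot2::geom_line() +
      ggplot2::labs(title = "Cost-effectiveness acceptability curves",
                    x = "Willingness to pay (USD/QALY)",
                    y = "Probability cost-effective", colour = "Arm")
  } else {
    ggplot2::ggplot(object, ggplot2::aes(.data$lambda, .data$evpi)) +
      ggplot2::geom_line() +
      ggplot2::labs(title = "Expected value of perfect information",
                    x = "Willingness to pay (USD/QALY)",
                    y = "EVPI (USD per patient)")
  }
}
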