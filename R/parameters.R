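#' @importFrom rlang .data abort %||%
#' @importFrom tibble tibble as_tibble
NULL

# Names every valid configuration must define. The registry mirrors the model's
# published input table: cohort settings, initial severity mix, utility weights,
# ordered-logit transition coefficients and gamma log-link cost coefficients,
# all gender-stratified where the source regressions were run by gender.
required_parameter_names <- function() {
  c(
    "discount_rate", "n_patients", "percent_female", "dt_price",
    paste0("util_control_f_", c("1_44", "45_54", "55_64", "65_74", "75p")),
    paste0("util_control_m_", c("1_44", "45_54", "55_64", "65_74", "75p")),
    "util_scd_child", "util_scd_adult",
    paste0("ol_f_", c("moderate", "severe", "age", "moderate_age", "severe_age", "cut1", "cut2")),
    paste0("ol_m_", c("moderate", "severe", "age", "moderate_age", "severe_age", "cut1", "cut2")),
    paste0("cost_f_", c("intercept", "mild", "moderate", "severe", "age",
                        "mild_age", "moderate_age", "severe_age")),
    paste0("cost_m_", c("intercept", "mild", "moderate", "severe", "age",
                        "mild_age", "moderate_age", "severe_age"))
  )
}

dist_kinds <- c("beta", "dirichlet", "normal", "truncated_normal_01", "uniform", "fixed")
dsa_rules <- c("ci95", "plus_minus_20pct", "excluded")

#' Load a model parameter set
#'
#' Reads a structured configuration (JSON, or YAML if the file extension is
#' `.yml`/`.yaml`) holding every model input: the cohort settings, the
#' gender-specific Dirichlet initial severity mixes, and one entry per scalar
#' parameter with its base value, optional 95% CI, sampling distribution for
#' probabilistic sensitivity analysis (PSA), and deterministic sensitivity
#' analysis (DSA) rule. The packaged default configuration reproduces the
#' published input table for the durable-therapy cost-effectiveness model.
#'
#' @param path Path to a configuration file. `NULL` (default) loads the
#'   packaged default registry.
#' @return An object of class `scd_parameters`: a list with
#'   \describe{
#'     \item{entries}{tibble with columns `name`, `base`, `ci_low`, `ci_high`,
#'       `dist_kind`, `dist_params` (list column), `dsa_rule`, `psa_included`,
#'       `gender`}
#'     \item{severity}{per-gender Dirichlet counts and base proportions for the
#'       initial mild/moderate/severe mix of the standard-of-care arm}
#'     \item{cohort}{list with `horizon` (cycles) and `wtp` (USD/QALY)}
#'   }
#' @examples
#' params <- scd_parameters()
#' parameter_value(params, "dt_price")
#' @export
load_parameters <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1_defaults.json", package = "sicklecea")
  }
  if (!file.exists(path)) {
    abort(paste0("configuration file not found: ", path))
  }
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading YAML configuration requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  parse_parameter_config(raw)
}

#' @rdname load_parameters
#' @export
scd_parameters <- function(path = NULL) load_parameters(path)

parse_parameter_config <- function(raw) {
  for (block in c("cohort", "severity", "parameters")) {
    if (is.null(raw[[block]])) abort(paste0("configuration is missing the '", block, "' block"))
  }
  entries <- purrr::map_dfr(raw$parameters, function(p) {
    if (is.null(p$name) || is.null(p$base)) {
      abort("every parameter entry needs 'name' and 'base'")
    }
    ci <- if (is.null(p$ci) || length(p$ci) == 0) c(NA_real_, NA_real_) else as.numeric(p$ci)
    tibble(
      name = as.character(p$name),
      base = as.numeric(p$base),
      ci_low = ci[1], ci_high = ci[2],
      dist_kind = as.character(p$dist$kind %||% "fixed"),
      dist_params = list(as.numeric(p$dist$params %||% numeric(0))),
      dsa_rule = as.character(p$dsa %||% "excluded"),
      psa_included = isTRUE(p$psa),
      gender = as.character(p$gender %||% "both")
    )
  })
  sev <- purrr::map(raw$severity[c("female", "male")], function(s) {
    alphas <- as.numeric(s$alphas)
    list(alphas = alphas, proportions = alphas / sum(alphas))
  })
  # severity mixes are PSA-sampled (jointly, per gender) unless disabled
  sev$psa_included <- !isFALSE(raw$severity$psa)
  params <- structure(
    list(
      entries = entries,
      severity = sev,
      cohort = list(
        horizon = as.integer(raw$cohort$horizon %||% 100L),
        wtp = as.numeric(raw$cohort$wtp %||% 150000)
      )
    ),
    class = "scd_parameters"
  )
  validate_parameters(params)
  params
}

validate_parameters <- function(params) {
  entries <- params$entries
  missing <- setdiff(required_parameter_names(), entries$name)
  if (length(missing) > 0) {
    abort(paste0("parameter registry incomplete; missing: ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(entries$name)) {
    abort(paste0("duplicate parameter names: ",
                 paste(unique(entries$name[duplicated(entries$name)]), collapse = ", ")))
  }
  bad_kind <- setdiff(unique(entries$dist_kind), dist_kinds)
  if (length(bad_kind) > 0) abort(paste0("unknown distribution kind: ", bad_kind[1]))
  bad_rule <- setdiff(unique(entries$dsa_rule), dsa_rules)
  if (length(bad_rule) > 0) abort(paste0("unknown DSA rule: ", bad_rule[1]))

  for (i in seq_len(nrow(entries))) {
    e <- entries[i, ]
    dp <- e$dist_params[[1]]
    ok <- switch(e$dist_kind,
      beta = length(dp) == 2 && all(dp > 0),
      dirichlet = length(dp) >= 2 && all(dp > 0),
      normal = length(dp) == 2 && dp[2] > 0,
      truncated_normal_01 = length(dp) == 2 && dp[2] > 0,
      uniform = length(dp) == 2 && dp[1] < dp[2],
      fixed = TRUE
    )
    if (!ok) {
      abort(paste0("invalid distribution parameters for '", e$name, "' (",
                   e$dist_kind, ": ", paste(dp, collapse = ", "), ")"))
    }
    has_ci <- !is.na(e$ci_low) && !is.na(e$ci_high)
    # inclusive: printed CIs are rounded and can coincide with the base value
    if (has_ci && !(e$ci_low <= e$base && e$base <= e$ci_high)) {
      abort(paste0("parameter '", e$name, "': base value ", e$base,
                   " must lie inside its 95% CI (", e$ci_low, ", ", e$ci_high, ")"))
    }
    if (e$dsa_rule == "ci95" && !has_ci) {
      abort(paste0("parameter '", e$name, "': DSA rule 'ci95' requires a 95% CI"))
    }
  }

  ev <- stats::setNames(entries$base, entries$name)
  if (ev[["discount_rate"]] < 0) abort("discount_rate must be non-negative")
  if (ev[["percent_female"]] < 0 || ev[["percent_female"]] > 1) {
    abort("percent_female must lie in [0, 1]")
  }
  if (ev[["dt_price"]] < 0) abort("dt_price must be non-negative")
  if (ev[["n_patients"]] < 1) abort("n_patients must be at least 1")
  if (params$cohort$horizon < 1) abort("horizon must be at least 1")

  for (g in c("female", "male")) {
    s <- params$severity[[g]]
    if (is.null(s) || length(s$alphas) != 3 || any(s$alphas <= 0)) {
      abort(paste0("severity block for '", g, "' must hold 3 positive Dirichlet counts"))
    }
    if (abs(sum(s$proportions) - 1) > 1e-12) {
      abort("severity proportions must sum to 1")
    }
  }
  invisible(params)
}

#' Look up a parameter's current base value
#'
#' @param params An `scd_parameters` object.
#' @param name Parameter name (see `params$entries$name`).
#' @return The scalar base value.
#' @export
parameter_value <- function(params, name) {
  idx <- match(name, params$entries$name)
  if (anyNA(idx)) abort(paste0("unknown parameter: ", paste(name[is.na(idx)], collapse = ", ")))
  stats::setNames(params$entries$base[idx], name)
}

#' Replace base values in a parameter set
#'
#' Returns a modified copy with the named entries' base values replaced.
#' Severity proportions can be replaced through pseudo-names
#' `severity_f_mild`, `severity_f_moderate`, `severity_f_severe` (and `_m_`
#' for males); a replaced gender triple is renormalised to sum to 1.
#' CI-range validation is not re-applied (sensitivity analyses legitimately
#' push values to their CI bounds).
#'
#' @param params An `scd_parameters` object.
#' @param values Named numeric vector of replacement values.
#' @return A modified `scd_parameters` object.
#' @export
update_parameters <- function(params, values) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  sev_names <- c(outer(c("severity_f_", "severity_m_"), c("mild", "moderate", "severe"), paste0))
  sev_vals <- values[names(values) %in% sev_names]
  values <- values[!names(values) %in% sev_names]
  if (length(values) > 0) {
    idx <- match(names(values), params$entries$name)
    if (anyNA(idx)) {
      abort(paste0("unknown parameter: ", paste(names(values)[is.na(idx)], collapse = ", ")))
    }
    params$entries$base[idx] <- unname(values)
  }
  for (g in c("f", "m")) {
    key <- paste0("severity_", g, "_", c("mild", "moderate", "severe"))
    if (any(key %in% names(sev_vals))) {
      gname <- if (g == "f") "female" else "male"
      p <- params$severity[[gname]]$proportions
      hit <- key %in% names(sev_vals)
      p[hit] <- sev_vals[key[hit]]
      if (any(p < 0)) abort("severity proportions must be non-negative")
      params$severity[[gname]]$proportions <- p / sum(p)
    }
  }
  params
}

#' Deterministic sensitivity analysis bounds
#'
#' Returns the low/high evaluation points for each DSA-eligible parameter:
#' the stored 95% CI under rule `ci95`, or `(0.8, 1.2) * base` under rule
#' `plus_minus_20pct`. Requesting a parameter whose rule is `excluded` is an
#' error.
#'
#' @param params An `scd_parameters` object.
#' @param names Optional character vector restricting the output; default all
#'   DSA-eligible entries.
#' @return A tibble with columns `name`, `base`, `low`, `high`.
#' @examples
#' dsa_bounds(scd_parameters(), "dt_price")
#' @export
dsa_bounds <- function(params, names = NULL) {
  entries <- params$entries
  if (is.null(names)) {
    entries <- dplyr::filter(entries, .data$dsa_rule != "excluded")
  } else {
    idx <- match(names, entries$name)
    if (anyNA(idx)) abort(paste0("unknown parameter: ", paste(names[is.na(idx)], collapse = ", ")))
    entries <- entries[idx, ]
    if (any(entries$dsa_rule == "excluded")) {
      abort(paste0("parameter(s) excluded from DSA: ",
                   paste(entries$name[entries$dsa_rule == "excluded"], collapse = ", ")))
    }
  }
  dplyr::transmute(
    entries,
    name = .data$name,
    base = .data$base,
    low = ifelse(.data$dsa_rule == "ci95", .data$ci_low, 0.8 * .data$base),
    high = ifelse(.data$dsa_rule == "ci95", .data$ci_high, 1.2 * .data$base)
  )
}

# -- PSA sampling ------------------------------------------------------------

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# normal truncated to [0,1] via inverse-CDF (exact, no rejection loop)
rtruncnorm01 <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  hi <- stats::pnorm(1, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

sample_entry <- function(kind, dp, base) {
  switch(kind,
    beta = stats::rbeta(1, dp[1], dp[2]),
    normal = stats::rnorm(1, dp[1], dp[2]),
    truncated_normal_01 = rtruncnorm01(1, dp[1], dp[2]),
    uniform = stats::runif(1, dp[1], dp[2]),
    fixed = base,
    abort(paste0("cannot sample distribution kind: ", kind))
  )
}

#' Draw one probabilistic sensitivity analysis parameter vector
#'
#' Draws one independent value from every PSA-included entry's distribution
#' (beta, normal, truncated normal on the unit interval, or uniform), keeps
#' excluded entries
#' (discount rate, cohort size) at their base values, and draws each gender's
#' initial severity mix jointly from its Dirichlet. Uses R's global RNG stream;
#' call `set.seed()` first for reproducibility.
#'
#' @param params An `scd_parameters` object.
#' @return Named numeric vector with one element per registry entry plus the
#'   six `severity_{f,m}_{mild,moderate,severe}` proportions. Pass it to
#'   [update_parameters()] to materialise the draw.
#' @examples
#' set.seed(1)
#' draw <- sample_psa_draw(scd_parameters())
#' draw[["discount_rate"]]  # fixed at base, not varied in PSA
#' @export
sample_psa_draw <- function(params) {
  entries <- params$entries
  vals <- vapply(seq_len(nrow(entries)), function(i) {
    if (!entries$psa_included[i]) return(entries$base[i])
    sample_entry(entries$dist_kind[i], entries$dist_params[[i]], entries$base[i])
  }, numeric(1))
  names(vals) <- entries$name
  sev_draw <- function(g) {
    if (isFALSE(params$severity$psa_included)) {
      params$severity[[g]]$proportions
    } else {
      rdirichlet1(params$severity[[g]]$alphas)
    }
  }
  sev <- c(
    stats::setNames(sev_draw("female"), paste0("severity_f_", c("mild", "moderate", "severe"))),
    stats::setNames(sev_draw("male"), paste0("severity_m_", c("mild", "moderate", "severe")))
  )
  c(vals, sev)
}

# a drawn vector is model-valid iff the ordered-logit cut points stay ordered
draw_is_valid <- function(draw) {
  draw[["ol_f_cut1"]] < draw[["ol_f_cut2"]] && draw[["ol_m_cut1"]] < draw[["ol_m_cut2"]]
}

#' Dump the active parameter registry as a flat table
#'
#' @param params An `scd_parameters` object.
#' @param file Optional path; when given, the table is also written as CSV.
#' @return A tibble (name, base, ci_low, ci_high, dist_kind, dist_params,
#'   dsa_rule, psa_included, gender) with `dist_params` collapsed to a
#'   semicolon-separated string.
#' @export
dump_parameters <- function(params, file = NULL) {
  out <- dplyr::mutate(
    params$entries,
    dist_params = purrr::map_chr(.data$dist_params, paste, collapse = ";")
  )
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

#' @export
print.scd_parameters <- function(x, ...) {
  cat("<scd_parameters>", nrow(x$entries), "entries;",
      "horizon", x$cohort$horizon, "cycles; WTP", format(x$cohort$wtp, big.mark = ","),
      "USD/QALY\n")
  cat("  initial severity (F):",
      paste(sprintf("%.3f", x$severity$female$proportions), collapse = "/"),
      " (M):", paste(sprintf("%.3f", x$severity$male$proportions), collapse = "/"), "\n")
  invisible(x)
}

# cohort-level convenience accessors (values live in the entry registry)
cohort_config <- function(params) {
  list(
    n_patients = unname(parameter_value(params, "n_patients")),
    percent_female = unname(parameter_value(params, "percent_female")),
    discount_rate = unname(parameter_value(params, "discount_rate")),
    horizon = params$cohort$horizon,
    dt_price = unname(parameter_value(params, "dt_price")),
    wtp = params$cohort$wtp
  )
}
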