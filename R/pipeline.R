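#' Run the base-case analysis
#'
#' Runs both arms for both genders plus the pooled cohort under the given
#' waning assumption and collects the per-patient discounted and undiscounted
#' totals, the incremental comparisons, and the cohort traces — the model's
#' headline results bundle.
#'
#' @inheritParams evaluate_model
#' @return A list of class `scd_base_case` with
#'   \describe{
#'     \item{results}{tibble of 6 rows (arm x female/male/pooled) with all
#'       discounted and undiscounted totals}
#'     \item{cea}{tibble of pooled/female/male incremental comparisons}
#'     \item{traces}{tibble of stacked cohort traces (arm, gender, cycle,
#'       state occupancies)}
#'     \item{model}{the underlying [evaluate_model()] output}
#'   }
#' @examples
#' base <- run_base_case(scd_parameters())
#' base$cea
#' @export
run_base_case <- function(params, life_tables = default_life_tables(),
                          waning = waning_spec("lifetime"), wtp = NULL,
                          half_cycle = FALSE) {
  if (!inherits(waning, "scd_waning")) waning <- waning_spec(waning)
  model <- evaluate_model(params, life_tables, waning, wtp, half_cycle)
  results <- purrr::map_dfr(c("dt", "soc"), function(arm) {
    purrr::map_dfr(c("female", "male", "pooled"), function(g) {
      glance(model[[arm]][[g]])
    })
  })
  wtp_used <- wtp %||% params$cohort$wtp
  cea_rows <- purrr::map_dfr(c("pooled", "female", "male"), function(g) {
    dplyr::mutate(tidy(icer(model$dt[[g]], model$soc[[g]], wtp = wtp_used)),
                  gender = g, .before = 1)
  })
  traces <- purrr::map_dfr(c("dt", "soc"), function(arm) {
    purrr::map_dfr(c("female", "male", "pooled"), function(g) {
      dplyr::mutate(model[[arm]][[g]]$trace, arm = arm, gender = g, .before = 1)
    })
  })
  structure(
    list(results = results, cea = cea_rows, traces = traces,
         waning = waning, model = model),
    class = "scd_base_case"
  )
}

#' @export
print.scd_base_case <- function(x, ...) {
  cat("<scd_base_case> waning:", x$waning$mode,
      if (x$waning$mode == "median_years") paste0("(", x$waning$median_years, "y)"), "\n")
  print(x$results)
  invisible(x)
}

#' Run the full analysis pipeline and write all artifacts
#'
#' Sequentially executes the base case, the cure-durability scenarios
#' (lifetime, median 20 years, median 10 years), the one-way deterministic
#' sensitivity analysis, the Monte Carlo PSA, and the value-of-information
#' analysis, writing every output as CSV/JSON under `out_dir` together with a
#' run manifest (config hash, seed, file registry, timings). All randomness
#' flows from `seed`. Numeric CSVs are written unformatted, so reruns with
#' the same seed are byte-identical.
#'
#' @param params An `scd_parameters` object.
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed for the PSA.
#' @param n_psa PSA iterations (default 10,000).
#' @param life_tables List with `healthy` and `scd` life tables.
#' @param lambda_grid Willingness-to-pay grid for the VOI curves.
#' @return Invisibly, a list with all result objects and the manifest.
#' @export
run_full_report <- function(params, out_dir, seed = 1, n_psa = 10000,
                            life_tables = default_life_tables(),
                            lambda_grid = seq(0, 300000, by = 5000)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(as.data.frame(df), path, row.names = FALSE)
    files <<- c(files, name)
    path
  }

  scenarios <- list(lifetime = waning_spec("lifetime"),
                    years20 = waning_spec(20), years10 = waning_spec(10))
  base <- run_base_case(params, life_tables, scenarios$lifetime)
  emit(base$results, "base_case.csv")
  emit(base$cea, "base_case_cea.csv")
  emit(base$traces, "traces.csv")

  scenario_rows <- purrr::map_dfr(names(scenarios), function(nm) {
    w <- scenarios[[nm]]
    model <- evaluate_model(params, life_tables, w)
    dplyr::mutate(tidy(model$cea), scenario = nm,
                  relapse_annual = w$p_annual, .before = 1)
  })
  emit(scenario_rows, "scenarios.csv")

  tornado <- one_way_dsa(params, life_tables)
  emit(tornado, "tornado.csv")

  psa <- run_psa(params, n_iter = n_psa, seed = seed, life_tables = life_tables)
  emit(psa$results, "psa_results.csv")
  emit(psa$draws, "psa_draws.csv")

  voi <- ceac_ceaf(psa, lambda_grid)
  emit(dplyr::select(voi, "lambda", "p_dt", "p_soc", "frontier"), "ceac.csv")
  emit(dplyr::select(voi, "lambda", "evpi"), "evpi.csv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("sicklecea")),
    seed = seed,
    n_psa = n_psa,
    relapse_probabilities = purrr::map_dbl(scenarios, "p_annual"),
    config_hash = rlang::hash(params),
    results_hash = rlang::hash(list(base$results, scenario_rows, tornado,
                                    psa$results, voi)),
    files = files,
    elapsed_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(base = base, scenarios = scenario_rows, tornado = tornado,
                 psa = psa, voi = voi, manifest = manifest))
}
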