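# shared fixtures, computed once per test run
.fixture_env <- new.env(parent = emptyenv())

fixture_params <- function() {
  if (is.null(.fixture_env$params)) .fixture_env$params <- scd_parameters()
  .fixture_env$params
}

fixture_tables <- function() {
  if (is.null(.fixture_env$tables)) .fixture_env$tables <- default_life_tables()
  .fixture_env$tables
}

# a deathless life-table pair: qx = 0 everywhere except the terminal age
immortal_tables <- function(max_age = 100) {
  lt <- synthesize_life_table(a = 0, b = 0, c = 0, max_age = max_age)
  list(healthy = lt, scd = lt)
}

# minimal hand-built arm result, for arithmetic on published per-arm totals
fake_arm_result <- function(arm, cost_disc, qaly_disc, ly_disc = 0,
                            gender = "pooled", cost_undisc = cost_disc,
                            qaly_undisc = qaly_disc, ly_undisc = ly_disc) {
  structure(
    list(arm = arm, gender = gender, discount_rate = 0.03,
         waning = waning_spec("lifetime"), half_cycle = FALSE,
         trace = tibble::tibble(cycle = 0, healthy = 1, mild = 0, moderate = 0,
                                severe = 0, dead = 0),
         cost_disc = cost_disc, cost_undisc = cost_undisc,
         qaly_disc = qaly_disc, qaly_undisc = qaly_undisc,
         ly_disc = ly_disc, ly_undisc = ly_undisc),
    class = "scd_arm_result"
  )
}

# PSA-shaped object from explicit per-iteration arm outcomes
fake_psa <- function(cost_dt, qaly_dt, cost_soc, qaly_soc) {
  structure(
    list(
      results = tibble::tibble(
        iter = seq_along(cost_dt),
        cost_dt = cost_dt, qaly_dt = qaly_dt, ly_dt = 0,
        cost_soc = cost_soc, qaly_soc = qaly_soc, ly_soc = 0
      ),
      draws = tibble::tibble(iter = seq_along(cost_dt)),
      n_rejected = 0L, seed = NA_integer_, n_iter = length(cost_dt)
    ),
    class = "scd_psa"
  )
}

# rewrite the packaged default config with a modification and reload it
reload_modified_config <- function(modify) {
  raw <- jsonlite::read_json(
    system.file("extdata", "table1_defaults.json", package = "sicklecea"),
    simplifyVector = TRUE, simplifyDataFrame = FALSE
  )
  raw <- modify(raw)
  path <- withr::local_tempfile(fileext = ".json", .local_envir = parent.frame())
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA, null = "null")
  load_parameters(path)
}
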