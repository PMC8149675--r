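test_that("packaged default registry reproduces the published input table", {
  params <- fixture_params()

  # every required row present, no duplicates
  expect_setequal(
    intersect(sicklecea:::required_parameter_names(), params$entries$name),
    sicklecea:::required_parameter_names()
  )
  expect_false(anyDuplicated(params$entries$name) > 0)

  # severity mixes normalise to the printed percentages (1 decimal)
  expect_equal(round(100 * params$severity$female$proportions, 1),
               c(50.8, 22.1, 27.1))
  expect_equal(round(100 * params$severity$male$proportions, 1),
               c(48.3, 23.1, 28.7))
  expect_equal(sum(params$severity$female$proportions), 1, tolerance = 1e-12)

  expect_equal(unname(parameter_value(params, "dt_price")), 2.1e6)
  expect_equal(unname(parameter_value(params, "discount_rate")), 0.03)
  expect_equal(unname(parameter_value(params, "percent_female")), 0.47)
  expect_equal(unname(parameter_value(params, "util_scd_child")), 0.69)
  expect_equal(params$cohort$horizon, 100)
  expect_equal(params$cohort$wtp, 150000)
})

test_that("configuration validation rejects malformed input", {
  # negative discount rate
  expect_error(
    reload_modified_config(function(raw) {
      i <- which(vapply(raw$parameters, `[[`, "", "name") == "discount_rate")
      raw$parameters[[i]]$base <- -0.01
      raw
    }),
    "discount_rate"
  )
  # a missing mandatory parameter is named in the error
  expect_error(
    reload_modified_config(function(raw) {
      keep <- vapply(raw$parameters, `[[`, "", "name") != "util_scd_adult"
      raw$parameters <- raw$parameters[keep]
      raw
    }),
    "util_scd_adult"
  )
  # invalid distribution parameters
  expect_error(
    reload_modified_config(function(raw) {
      i <- which(vapply(raw$parameters, `[[`, "", "name") == "percent_female")
      raw$parameters[[i]]$dist$params <- c(-1, 47)
      raw
    }),
    "invalid distribution"
  )
  # base value outside its CI
  expect_error(
    reload_modified_config(function(raw) {
      i <- which(vapply(raw$parameters, `[[`, "", "name") == "util_scd_child")
      raw$parameters[[i]]$base <- 0.95
      raw
    }),
    "CI"
  )
})

test_that("DSA bounds follow the CI-else-20-percent rule", {
  params <- fixture_params()
  b <- dsa_bounds(params, "dt_price")
  expect_equal(c(b$low, b$high), c(1.68e6, 2.52e6))
  b <- dsa_bounds(params, "discount_rate")
  expect_equal(c(b$low, b$high), c(0.024, 0.036))

  # degenerate zero base under the +/-20% rule
  p0 <- update_parameters(params, c(dt_price = 0))
  b <- dsa_bounds(p0, "dt_price")
  expect_equal(c(b$low, b$high), c(0, 0))

  # excluded entries are refused by name and absent from the default sweep
  expect_error(dsa_bounds(params, "n_patients"), "excluded")
  expect_false("n_patients" %in% dsa_bounds(params)$name)
})

test_that("PSA draws honour distributions, exclusions and the seed", {
  params <- fixture_params()

  set.seed(7); d1 <- sample_psa_draw(params)
  set.seed(7); d2 <- sample_psa_draw(params)
  expect_identical(d1, d2)

  # one value per entry plus the six severity proportions
  expect_length(d1, nrow(params$entries) + 6)

  set.seed(11)
  draws <- t(replicate(4000, sample_psa_draw(params)))

  # not varied in PSA: always the base value
  expect_true(all(draws[, "discount_rate"] == 0.03))
  expect_true(all(draws[, "n_patients"] == 10000))

  # truncation contract on the utility weights
  expect_true(all(draws[, "util_scd_child"] >= 0 & draws[, "util_scd_child"] <= 1))
  expect_true(all(draws[, "util_scd_adult"] >= 0 & draws[, "util_scd_adult"] <= 1))

  # beta mean: percent_female ~ Beta(49, 47), mean 49/96
  x <- draws[, "percent_female"]
  expect_lt(abs(mean(x) - 49 / 96), 3 * sd(x) / sqrt(length(x)))

  # uniform price stays in its support and centres on 2.1M
  expect_true(all(draws[, "dt_price"] >= 1.68e6 & draws[, "dt_price"] <= 2.52e6))
  expect_lt(abs(mean(draws[, "dt_price"]) - 2.1e6),
            3 * sd(draws[, "dt_price"]) / sqrt(nrow(draws)))

  # dirichlet draws sum to 1 and centre on the base proportions
  sf <- draws[, paste0("severity_f_", c("mild", "moderate", "severe"))]
  expect_equal(unname(rowSums(sf)), rep(1, nrow(sf)), tolerance = 1e-12)
  expect_equal(unname(colMeans(sf)), params$severity$female$proportions,
               tolerance = 0.01)
})

test_that("update_parameters replaces values and renormalises severity", {
  params <- fixture_params()
  p2 <- update_parameters(params, c(dt_price = 1e6, ol_f_cut1 = 0.9))
  expect_equal(unname(parameter_value(p2, "dt_price")), 1e6)
  expect_equal(unname(parameter_value(p2, "ol_f_cut1")), 0.9)
  # untouched entries keep their base
  expect_equal(unname(parameter_value(p2, "ol_m_cut1")), 0.787)
  expect_error(update_parameters(params, c(nonexistent = 1)), "unknown parameter")

  p3 <- update_parameters(params, c(
    severity_f_mild = 0.5, severity_f_moderate = 0.3, severity_f_severe = 0.2
  ))
  expect_equal(p3$severity$female$proportions, c(0.5, 0.3, 0.2))
  expect_equal(sum(p3$severity$female$proportions), 1)
})

test_that("YAML configurations load equivalently to JSON", {
  skip_if_not_installed("yaml")
  raw <- jsonlite::read_json(
    system.file("extdata", "table1_defaults.json", package = "sicklecea"),
    simplifyVector = TRUE, simplifyDataFrame = FALSE
  )
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(raw, path)
  p_yaml <- load_parameters(path)
  p_json <- fixture_params()
  expect_equal(p_yaml$entries, p_json$entries)
  expect_equal(p_yaml$severity, p_json$severity)
})

test_that("parameter dump is a complete flat table", {
  params <- fixture_params()
  path <- withr::local_tempfile(fileext = ".csv")
  out <- dump_parameters(params, path)
  expect_equal(nrow(out), nrow(params$entries))
  reread <- read.csv(path)
  expect_equal(reread$name, out$name)
  expect_equal(reread$base, out$base)
})
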