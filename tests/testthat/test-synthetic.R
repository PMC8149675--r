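test_that("severity classification follows the crisis-count cutoffs", {
  expect_equal(classify_severity(0), "mild")
  expect_equal(classify_severity(1.5), "moderate")
  expect_equal(classify_severity(2), "severe")
  expect_equal(classify_severity(c(0, 0.01, 1.99, 2, 7)),
               c("mild", "moderate", "moderate", "severe", "severe"))
  expect_error(classify_severity(-0.1), "non-negative")
})

test_that("generated panels satisfy their construction invariants", {
  params <- fixture_params()
  panel <- generate_panel(params, n_patients = 2000, seed = 11)

  # two rows per patient, SCD and controls
  expect_equal(nrow(panel), 2 * 2 * 2000)
  expect_equal(sum(panel$year == 1), 4000)
  expect_equal(sum(panel$year == 2), 4000)

  scd <- panel[panel$severity != "control", ]
  ctl <- panel[panel$severity == "control", ]
  # the assigned class always matches its own crisis count
  expect_equal(classify_severity(scd$crisis_rate), scd$severity)
  expect_true(all(is.na(ctl$crisis_rate)))
  expect_true(all(panel$annual_cost > 0))

  # determinism under the seed
  expect_identical(panel, generate_panel(params, n_patients = 2000, seed = 11))
  expect_false(identical(panel, generate_panel(params, n_patients = 2000, seed = 12)))

  # degenerate (infinite-shape) costs equal the GLM mean exactly
  noiseless <- generate_panel(params, n_patients = 300, seed = 5, gamma_shape = Inf)
  for (g in c("female", "male")) {
    sub <- noiseless[noiseless$gender == g & noiseless$severity != "control", ]
    co <- cost_coefficients(params, g)
    expect_equal(sub$annual_cost, annual_cost(co, sub$severity, sub$age),
                 tolerance = 1e-12)
  }
})

test_that("year-2 severities follow the true transition rows", {
  params <- fixture_params()
  panel <- generate_panel(params, n_patients = 20000, seed = 17)
  pairs <- sicklecea:::panel_transition_pairs(panel)
  for (g in c("female", "male")) {
    co <- transition_coefficients(params, g)
    for (s1 in c("mild", "moderate", "severe")) {
      sub <- pairs[pairs$gender == g &
                     pairs$moderate1 == (s1 == "moderate") &
                     pairs$severe1 == (s1 == "severe"), ]
      # oracle probability, averaged over the realised ages in the cell
      oracle <- severity_transition(co, rep(s1, nrow(sub)), sub$age)
      for (s2 in c("mild", "moderate", "severe")) {
        p_hat <- mean(sub$severity2 == s2)
        p_true <- mean(oracle[[paste0("p_", s2)]])
        se <- sqrt(p_true * (1 - p_true) / nrow(sub))
        expect_lt(abs(p_hat - p_true), 3.5 * se + 1e-12)
      }
    }
  }
})

test_that("refitting recovers the generating coefficients", {
  params <- fixture_params()
  panel <- generate_panel(params, n_patients = 20000, seed = 23)

  tf <- fit_transition_model(panel)
  for (g in c("female", "male")) {
    truth <- transition_coefficients(params, g)
    est <- tf[tf$gender == g, ]
    key <- c("moderate", "severe", "age", "moderate_age", "severe_age",
             "cut1", "cut2")
    for (k in key) {
      row <- est[est$term == k, ]
      expect_lt(abs(row$estimate - truth[[k]]), 4 * row$std_error)
    }
    # ordered-logit constraint: cut points stay ordered
    expect_lt(est$estimate[est$term == "cut1"], est$estimate[est$term == "cut2"])
  }

  cf <- fit_cost_model(panel)
  for (g in c("female", "male")) {
    truth <- cost_coefficients(params, g)
    est <- cf[cf$gender == g, ]
    for (k in c("intercept", "mild", "moderate", "severe", "age",
                "mild_age", "moderate_age", "severe_age")) {
      row <- est[est$term == k, ]
      expect_lt(abs(row$estimate - truth[[k]]), 4 * row$std_error)
    }
  }

  # a noiseless panel pins the cost coefficients to high precision
  clean <- generate_panel(params, n_patients = 4000, seed = 29, gamma_shape = Inf)
  # an exact fit makes the gamma AIC degenerate (harmless NaN warning)
  cf0 <- suppressWarnings(fit_cost_model(clean))
  for (g in c("female", "male")) {
    truth <- cost_coefficients(params, g)
    est <- cf0[cf0$gender == g, ]
    key <- c(intercept = "intercept", mild = "mild", moderate = "moderate",
             severe = "severe", age = "age", mild_age = "mild_age",
             moderate_age = "moderate_age", severe_age = "severe_age")
    got <- setNames(est$estimate, est$term)[key]
    expect_equal(unname(got), unname(truth[key]), tolerance = 1e-6)
  }
  # link-function identity: prediction at (control, age 0) is exp(intercept)
  fit_f <- attr(cf0, "fits")$female
  b0 <- cf0$estimate[cf0$gender == "female" & cf0$term == "intercept"]
  expect_equal(unname(predict(fit_f, newdata = data.frame(
    mild = 0, moderate = 0, severe = 0, age = 0
  ), type = "response")), exp(b0), tolerance = 1e-9)
})

test_that("degenerate panels are rejected with informative errors", {
  params <- fixture_params()
  panel <- generate_panel(params, n_patients = 400, seed = 31)

  # constant age makes the age coefficients inestimable
  flat <- panel
  flat$age <- 30
  expect_error(fit_transition_model(flat), "age")

  # non-positive costs are a data error
  bad <- panel
  bad$annual_cost[1] <- 0
  expect_error(fit_cost_model(bad), "positive")

  # one-gender panels cannot feed gender-stratified regressions
  expect_error(fit_transition_model(panel[panel$gender == "female", ]), "gender")
  expect_error(fit_cost_model(panel[panel$gender == "male", ]), "gender")
})

test_that("recovered coefficients can rebuild the model registry", {
  params <- fixture_params()
  panel <- generate_panel(params, n_patients = 5000, seed = 37)
  vals <- recovered_parameter_values(fit_transition_model(panel),
                                     fit_cost_model(panel))
  expect_length(vals, 14 + 16)
  p_rec <- update_parameters(params, vals)
  expect_equal(unname(parameter_value(p_rec, "ol_f_cut1")),
               unname(vals[["ol_f_cut1"]]))
  # the rebuilt registry drives the engine without error
  res <- run_cohort(p_rec, "soc", "female", fixture_tables())
  expect_true(res$qaly_disc > 0)
})
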