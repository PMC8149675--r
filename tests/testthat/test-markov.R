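test_that("waning conversion reproduces the constant-rate closed form", {
  expect_equal(round(annual_relapse_probability(0.5, 10), 5), 0.06697)
  expect_equal(round(annual_relapse_probability(0.5, 20), 5), 0.03406)
  # one-year duration returns the cumulative probability itself
  expect_equal(annual_relapse_probability(0.5, 1), 0.5)
  expect_equal(annual_relapse_probability(0, 10), 0)
  expect_error(annual_relapse_probability(1, 10), "finite-rate")
  expect_error(annual_relapse_probability(0.5, 0.5), "at least 1")

  expect_equal(waning_spec("lifetime")$p_annual, 0)
  expect_equal(waning_spec(10)$p_annual, annual_relapse_probability(0.5, 10))
  expect_equal(waning_spec("median_years", 20)$p_annual,
               annual_relapse_probability(0.5, 20))
})

test_that("initial state vectors reflect arm and observed severity mix", {
  params <- fixture_params()
  expect_equal(unname(initial_state_vector(params, "dt", "female")),
               c(1, 0, 0, 0, 0))
  v <- initial_state_vector(params, "soc", "female")
  expect_equal(round(unname(v), 3), c(0, 0.508, 0.221, 0.271, 0))
  v <- initial_state_vector(params, "soc", "male")
  expect_equal(round(unname(v), 3), c(0, 0.483, 0.231, 0.287, 0))
})

test_that("degenerate cohorts recover hand-computable totals", {
  params <- fixture_params()
  p0 <- update_parameters(params, c(discount_rate = 0))
  tabs <- immortal_tables()

  # deathless lifetime-cure cohort: 100 life years; QALYs = summed control
  # weights (female bands: 45*0.89 + 10*0.87 + 10*0.84 + 10*0.84 + 25*0.82)
  dt <- run_cohort(p0, "dt", "female", tabs)
  expect_equal(dt$ly_undisc, 100)
  expect_equal(dt$qaly_undisc, 45 * 0.89 + 10 * 0.87 + 10 * 0.84 + 10 * 0.84 + 25 * 0.82,
               tolerance = 1e-10)
  # zero-rate identity: discounted equals undiscounted
  expect_equal(dt$cost_disc, dt$cost_undisc)
  expect_equal(dt$qaly_disc, dt$qaly_undisc)

  soc <- run_cohort(p0, "soc", "male", tabs)
  expect_equal(soc$ly_disc, soc$ly_undisc)
  expect_equal(soc$qaly_disc, soc$qaly_undisc)

  # with a positive rate, discounted totals are strictly smaller
  soc_r <- run_cohort(params, "soc", "male", tabs)
  expect_lt(soc_r$cost_disc, soc_r$cost_undisc)
  expect_lt(soc_r$qaly_disc, soc_r$qaly_undisc)
})

test_that("calibrated default mortality reproduces the lifetime totals in-engine", {
  params <- fixture_params()
  tabs <- fixture_tables()
  soc <- run_cohort(params, "soc", "female", tabs)
  expect_equal(soc$ly_undisc, 54.9, tolerance = 0.5)
  dt <- run_cohort(params, "dt", "female", tabs)
  expect_equal(dt$ly_undisc, 75.8, tolerance = 0.5)
})

test_that("traces conserve mass, absorb into death, and respond monotonically", {
  params <- fixture_params()
  tabs <- fixture_tables()

  set.seed(3)
  for (i in 1:6) {
    arm <- sample(c("dt", "soc"), 1)
    g <- sample(c("female", "male"), 1)
    w <- if (runif(1) < 0.5) waning_spec("lifetime") else waning_spec(sample(5:30, 1))
    res <- run_cohort(params, arm, g, tabs, w)
    occ <- as.matrix(res$trace[, -1])
    expect_equal(unname(rowSums(occ)), rep(1, nrow(occ)), tolerance = 1e-10)
    expect_true(all(diff(occ[, "dead"]) >= -1e-14))
    expect_true(all(occ >= -1e-14))
  }

  # a table ending at age horizon-1 (terminal qx = 1) fully absorbs the cohort
  short <- synthesize_life_table(0.001, 0.07, 0.001, max_age = 99)
  res <- run_cohort(params, "soc", "female", list(healthy = short, scd = short))
  expect_equal(res$trace$dead[101], 1, tolerance = 1e-12)

  # QALYs fall as relapse risk grows (DT arm) and as the discount rate grows
  qalys <- vapply(c(0, 5, 10, 20), function(T) {
    w <- if (T == 0) waning_spec("lifetime") else waning_spec(T)
    run_cohort(params, "dt", "female", tabs, w)$qaly_disc
  }, numeric(1))
  expect_true(all(diff(qalys[c(1, 4, 3, 2)]) < 0))  # lifetime > T=20 > T=10 > T=5

  q_rate <- vapply(c(0, 0.015, 0.03, 0.06), function(r) {
    run_cohort(params, "dt", "female", tabs, discount_rate = r)$qaly_disc
  }, numeric(1))
  expect_true(all(diff(q_rate) < 0))
})

test_that("pooling is the convex combination of gender results", {
  params <- fixture_params()
  tabs <- fixture_tables()
  f <- run_cohort(params, "soc", "female", tabs)
  m <- run_cohort(params, "soc", "male", tabs)

  expect_equal(glance(pooled_result(f, m, 1))[, -(1:2)], glance(f)[, -(1:2)])
  half <- pooled_result(f, m, 0.5)
  expect_equal(half$cost_disc, (f$cost_disc + m$cost_disc) / 2)
  expect_equal(half$qaly_disc, (f$qaly_disc + m$qaly_disc) / 2)
  expect_error(pooled_result(f, m, 1.2), "\\[0, 1\\]")

  # published per-gender absolutes pool to within 1% of the published
  # overall incremental cost at 47% females
  dt_f <- fake_arm_result("dt", 2377583, 26.8, gender = "female")
  dt_m <- fake_arm_result("dt", 2367928, 26.1, gender = "male")
  soc_f <- fake_arm_result("soc", 1098098, 18.0, gender = "female")
  soc_m <- fake_arm_result("soc", 1244733, 17.9, gender = "male")
  delta <- pooled_result(dt_f, dt_m, 0.47)$cost_disc -
    pooled_result(soc_f, soc_m, 0.47)$cost_disc
  expect_equal(delta, 1196916, tolerance = 0.01)
})

test_that("removing the disease penalty leaves only the upfront price", {
  params <- fixture_params()
  # SCD utilities := control utilities (flat 0.8 for both populations),
  # SCD costs := control costs (zero severity main effects and interactions),
  # shared mortality: the arms must then differ by the upfront price alone
  flat <- c(
    setNames(rep(0.8, 5), paste0("util_control_f_", c("1_44", "45_54", "55_64", "65_74", "75p"))),
    setNames(rep(0.8, 5), paste0("util_control_m_", c("1_44", "45_54", "55_64", "65_74", "75p"))),
    util_scd_child = 0.8, util_scd_adult = 0.8,
    setNames(rep(0, 6), c(paste0("cost_f_", c("mild", "moderate", "severe")),
                          paste0("cost_f_", c("mild_age", "moderate_age", "severe_age")))),
    setNames(rep(0, 6), c(paste0("cost_m_", c("mild", "moderate", "severe")),
                          paste0("cost_m_", c("mild_age", "moderate_age", "severe_age"))))
  )
  p_eq <- update_parameters(params, flat)
  lt <- calibrate_life_table(65)
  tabs <- list(healthy = lt, scd = lt)
  dt <- run_cohort(p_eq, "dt", "female", tabs)
  soc <- run_cohort(p_eq, "soc", "female", tabs)
  expect_equal(dt$qaly_disc, soc$qaly_disc, tolerance = 1e-12)
  expect_equal(dt$ly_disc, soc$ly_disc, tolerance = 1e-12)
  expect_equal(dt$cost_disc - soc$cost_disc, 2.1e6, tolerance = 1e-9)
  expect_equal(dt$cost_undisc - soc$cost_undisc, 2.1e6, tolerance = 1e-9)
})

test_that("tidy and glance expose all six accumulated totals", {
  res <- run_cohort(fixture_params(), "soc", "female", fixture_tables())
  td <- tidy(res)
  expect_equal(nrow(td), 6)
  expect_setequal(td$quantity, c("cost", "qaly", "ly"))
  gl <- glance(res)
  expect_equal(gl$cost_disc, res$cost_disc)
  expect_s3_class(autoplot(res), "ggplot")
})
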