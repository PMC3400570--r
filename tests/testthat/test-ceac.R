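test_that("p-value halving rule maps inference to acceptability", {
  expect_equal(prob_cost_effective(-100, 0.10), 0.05)
  expect_equal(prob_cost_effective(100, 0.10), 0.95)
  expect_equal(prob_cost_effective(0, 1.0), 0.5)
  expect_error(prob_cost_effective(10, 1.2), class = "nbcea_config_error")
  # antisymmetry: flipping the sign of the INB reflects the probability
  withr::local_seed(17)
  for (i in 1:20) {
    inb <- rnorm(1, 0, 500)
    p <- runif(1)
    expect_equal(prob_cost_effective(-inb, p),
                 1 - prob_cost_effective(inb, p), tolerance = 1e-12)
  }
})

test_that("regression CEAC crosses 0.5 where the ICER sits", {
  rows <- table1_rows()
  res <- icer_from_rows(rows)
  curve <- ceac_curve(rows, c(15000, 25000, 35000, 45000))
  expect_s3_class(curve, "ceac_curve")
  expect_equal(curve$label, rep("overall", 4))
  expect_lt(curve$prob_ce[curve$ro == 15000], 0.5)
  expect_gt(curve$prob_ce[curve$ro == 35000], 0.5)
  # prob >= 0.5 exactly when the INB is non-negative
  expect_equal(curve$prob_ce >= 0.5, curve$inb >= 0)
  # the 0.5 crossing brackets the sample ICER
  below <- max(curve$ro[curve$prob_ce < 0.5])
  above <- min(curve$ro[curve$prob_ce > 0.5])
  expect_true(below < res$icer_cfa && res$icer_cfa < above)
})

test_that("identical arms give a flat curve at one half", {
  one_arm <- tibble::tibble(effect = c(1, 0, 1, 0), societal_cost = c(5, 2, 9, 4))
  rows <- dplyr::bind_rows(
    dplyr::mutate(one_arm, district = "intervention", sci = 1L),
    dplyr::mutate(one_arm, district = "comparison", sci = 0L)
  )
  curve <- ceac_curve(rows, c(0, 10000, 30000))
  expect_equal(curve$prob_ce, rep(0.5, 3), tolerance = 1e-12)
})

test_that("curves are labelled by model", {
  withr::local_seed(23)
  rows <- build_analysis_rows(random_cohort(40), cost_config(800))
  adj <- ceac_curve(rows, c(0, 20000), covariates = "dist_far")
  expect_equal(unique(adj$label), "adjusted")
})

test_that("analytic CEAC reproduces closed-form probabilities", {
  cv <- analytic_ceac(0.124, 0.003, 3534, ro_grid = c(25050, 28500, 30060))
  z <- (0.124 * 30060 - 3534) / (30060 * 0.003)
  expect_equal(cv$prob_ce[3], pnorm(z), tolerance = 1e-12)
  # at the ICER the INB is zero and the curve sits at one half
  expect_equal(cv$prob_ce[2], 0.5, tolerance = 1e-9)
  # strict monotonicity whenever both increments are positive: assert on
  # the z scale, where the tails do not saturate at double precision
  grid <- default_ro_grid()
  full <- analytic_ceac(0.124, 0.003, 3534, se_c = 40, ro_grid = grid)
  expect_true(all(diff(full$inb / full$se) > 0))
  expect_true(all(diff(full$prob_ce) >= 0))
})

test_that("zero-variance increments give a step curve and degenerate CI", {
  icer_val <- 3534 / 0.124
  step <- analytic_ceac(0.124, 0, 3534, se_c = 0,
                        ro_grid = seq(20000, 40000, 1000))
  expect_true(all(step$prob_ce[step$ro < icer_val] == 0))
  expect_true(all(step$prob_ce[step$ro > icer_val] == 1))
  ci <- ci_from_ceac(step)
  # both bounds collapse into the grid interval holding the ICER
  expect_true(ci$ro_low >= 28000 && ci$ro_high <= 29000)
})

test_that("CEAC-derived CI matches the analytic inversion and brackets the ICER", {
  # fine grid so interpolation error is negligible
  curve <- analytic_ceac(0.124, 0.003, 3534, ro_grid = seq(20000, 40000, 10))
  ci <- ci_from_ceac(curve)
  expect_equal(ci$ro_low, 3534 / (0.124 + qnorm(0.975) * 0.003), tolerance = 1e-4)
  expect_equal(ci$ro_high, 3534 / (0.124 - qnorm(0.975) * 0.003), tolerance = 1e-4)
  icer_val <- 3534 / 0.124
  expect_true(ci$ro_low < icer_val && icer_val < ci$ro_high)
  expect_true(ci$ro_low > 25050 && ci$ro_high < 30060)
})

test_that("a grid that never reaches a bound reports it unbounded", {
  curve <- analytic_ceac(0.124, 0.003, 3534, ro_grid = seq(25000, 28000, 500))
  expect_warning(ci <- ci_from_ceac(curve), regexp = "upper")
  expect_equal(ci$ro_high, Inf)
  expect_true(is.finite(ci$ro_low))
})

test_that("stratum curves separate when the effect depends on distance", {
  cfg <- scenario_library("distance_effect", seed = 19L)
  rows <- build_analysis_rows(generate_cohort(cfg),
                              cost_config(cfg$system_incremental_cost))
  curves <- ceac_by_stratum(rows, seq(0, 60000, 2000), "distance")
  expect_setequal(unique(curves$label),
                  c("overall", "dist: <=5 km", "dist: >5 km"))
  # overall curve is the simple-model curve
  overall <- curves[curves$label == "overall", ]
  simple <- ceac_curve(rows, seq(0, 60000, 2000))
  expect_equal(overall$prob_ce, simple$prob_ce, tolerance = 1e-12)
  # the far stratum has the larger effect gain, hence the smaller ICER and
  # a left-shifted curve: at intermediate Ro its acceptability is higher
  far <- curves[curves$label == "dist: >5 km", ]
  near <- curves[curves$label == "dist: <=5 km", ]
  mid <- stratified_icer(rows, "distance", delta_c = "stratum")
  icer_far <- mid$icer_cfa[mid$stratum == "dist: >5 km"]
  icer_near <- mid$icer_cfa[mid$stratum == "dist: <=5 km"]
  expect_lt(icer_far, icer_near)
  between <- far$ro > icer_far & far$ro < icer_near
  expect_true(all(far$prob_ce[between] > near$prob_ce[between]))
})

test_that("a one-level stratum yields the overall curve plus a warning", {
  rows <- table1_rows() |>
    dplyr::mutate(dist_far = 0L)
  expect_warning(curves <- ceac_by_stratum(rows, c(0, 30000), "distance"),
                 regexp = "omitted")
  expect_setequal(unique(curves$label), c("overall", "dist: <=5 km"))
})

test_that("regression and covariance-aware analytic curves agree closely", {
  # large stochastic cohort; the analytic curve needs the within-household
  # effect-cost covariance because the societal cost contains the delivery
  # cost itself
  cfg <- scenario_library("study_stochastic", seed = 7L)
  cfg$n_intervention <- 20000L
  cfg$n_comparison <- 20000L
  rows <- build_analysis_rows(generate_cohort(cfg),
                              cost_config(cfg$system_incremental_cost))
  grid <- seq(20000, 40000, 1000)
  reg <- ceac_curve(rows, grid)
  moments <- function(arm) {
    s <- rows[rows$district == arm, ]
    list(n = nrow(s), ve = var(s$effect), vc = var(s$societal_cost),
         cec = cov(s$effect, s$societal_cost))
  }
  i <- moments("intervention")
  c0 <- moments("comparison")
  gs <- group_summaries(rows)
  an <- analytic_ceac(
    delta_e = gs$effect_proportion[1] - gs$effect_proportion[2],
    se_e = sqrt(i$ve / i$n + c0$ve / c0$n),
    delta_c = gs$mean_cost[1] - gs$mean_cost[2],
    se_c = sqrt(i$vc / i$n + c0$vc / c0$n),
    cov_ec = i$cec / i$n + c0$cec / c0$n,
    ro_grid = grid
  )
  expect_lt(max(abs(reg$prob_ce - an$prob_ce)), 0.02)
})
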