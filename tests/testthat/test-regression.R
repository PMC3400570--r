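test_that("net benefit monetises the effect and subtracts cost", {
  expect_equal(net_benefit(1, 4000, 15000), 11000)
  expect_equal(net_benefit(0, 1042, 25000), -1042)
  expect_equal(net_benefit(c(1, 0), c(500, 700), 0), c(-500, -700))
  expect_error(net_benefit(1, 100, -5), class = "nbcea_config_error")
})

test_that("ols_fit handles the textbook cases", {
  withr::local_seed(5)
  y <- rnorm(20, 3)
  # intercept-only: coefficient is the mean
  f <- ols_fit(cbind(`(Intercept)` = rep(1, 20)), y)
  expect_equal(f$coefficients$estimate, mean(y))
  # intercept + dummy: dummy coefficient is the group-mean difference
  g <- rep(c(0, 1), each = 10)
  f2 <- ols_fit(cbind(`(Intercept)` = 1, g = g), y)
  expect_equal(f2$coefficients$estimate[2], mean(y[g == 1]) - mean(y[g == 0]))
  # duplicated column: rank error naming the column
  expect_error(ols_fit(cbind(`(Intercept)` = 1, g = g, g2 = g), y),
               class = "nbcea_design_error", regexp = "g2")
})

test_that("robust (HC1) standard errors differ under heteroskedasticity", {
  withr::local_seed(6)
  g <- rep(c(0, 1), each = 50)
  y <- rnorm(100, sd = ifelse(g == 1, 5, 1))
  x <- cbind(`(Intercept)` = 1, g = g)
  cl <- ols_fit(x, y, "classical")
  rb <- ols_fit(x, y, "robust")
  expect_equal(cl$coefficients$estimate, rb$coefficients$estimate)
  expect_false(isTRUE(all.equal(cl$coefficients$std.error,
                                rb$coefficients$std.error)))
})

test_that("simple model equals the group-mean decomposition exactly", {
  withr::local_seed(9)
  data <- random_cohort(40)
  rows <- build_analysis_rows(data, cost_config(1500))
  for (ro in c(0, 10000, 30000)) {
    fit <- simple_nb_regression(rows, ro)
    nb <- rows$effect * ro - rows$societal_cost
    alpha <- fit$coefficients$estimate[fit$coefficients$term == "(Intercept)"]
    delta <- fit$coefficients$estimate[fit$coefficients$term == "sci"]
    expect_equal(alpha, mean(nb[rows$sci == 0]), tolerance = 1e-9)
    expect_equal(delta, mean(nb[rows$sci == 1]) - mean(nb[rows$sci == 0]),
                 tolerance = 1e-9)
    # simple-model F equals the squared t ratio on the treatment dummy
    tval <- fit$coefficients$statistic[fit$coefficients$term == "sci"]
    expect_equal(fit$f_stat, tval^2, tolerance = 1e-9)
  }
})

test_that("identical net benefit in both arms gives a zero treatment effect", {
  one_arm <- tibble::tibble(effect = c(1, 0, 1), societal_cost = c(5, 2, 9))
  rows <- dplyr::bind_rows(
    dplyr::mutate(one_arm, district = "intervention", sci = 1L),
    dplyr::mutate(one_arm, district = "comparison", sci = 0L)
  )
  fit <- simple_nb_regression(rows, 20000)
  expect_equal(fit$coefficients$estimate[fit$coefficients$term == "sci"], 0,
               tolerance = 1e-9)
})

test_that("grid fits are ordered and linear in the ceiling ratio", {
  withr::local_seed(13)
  rows <- build_analysis_rows(random_cohort(60), cost_config(2000))
  summ <- group_summaries(rows)
  de <- summ$effect_proportion[summ$arm == "intervention"] -
    summ$effect_proportion[summ$arm == "comparison"]
  dc <- summ$mean_cost[summ$arm == "intervention"] -
    summ$mean_cost[summ$arm == "comparison"]
  grid <- nb_regression_grid(rows, c(0, 15000, 25000))
  deltas <- grid$estimate[grid$term == "sci"]
  expect_equal(deltas, de * c(0, 15000, 25000) - dc, tolerance = 1e-9)
  expect_equal(deltas[1], -dc, tolerance = 1e-9)
  if (de > 0) expect_true(all(diff(deltas) > 0))
  # empty grid is an empty result
  empty <- nb_regression_grid(rows, numeric(0))
  expect_equal(nrow(empty), 0)
  # grid must increase strictly
  expect_error(nb_regression_grid(rows, c(0, 0, 1000)),
               class = "nbcea_config_error")
})

test_that("nb_grid_table reshapes to coefficients by ceiling ratio", {
  withr::local_seed(13)
  rows <- build_analysis_rows(random_cohort(30), cost_config(2000))
  grid <- nb_regression_grid(rows, c(0, 15000))
  tab <- nb_grid_table(grid)
  expect_equal(tab$quantity, c("(Intercept)", "sci", "F", "adj_R2"))
  expect_named(tab, c("quantity", "ro_0", "ro_15000"))
  gl <- attr(grid, "glance")
  expect_equal(tab$ro_0[tab$quantity == "F"], gl$f_stat[gl$ro == 0])
})

test_that("adjusted model validates its specification", {
  withr::local_seed(21)
  rows <- build_analysis_rows(random_cohort(30), cost_config(2000))
  expect_error(adjusted_nb_regression(rows, 1000, character(0),
                                      interactions = TRUE),
               class = "nbcea_config_error")
  expect_error(adjusted_nb_regression(rows, 1000, "height"),
               class = "nbcea_config_error", regexp = "height")
  fit <- adjusted_nb_regression(rows, 20000, c("edu_some", "dist_far"),
                                interactions = TRUE)
  expect_setequal(fit$coefficients$term,
                  c("(Intercept)", "edu_some", "dist_far", "sci",
                    "sci:edu_some", "sci:dist_far"))
  expect_equal(fit$model, "interaction")
})

test_that("covariates absent from the generating process stay near zero", {
  # education and assets do not enter the delivery or cost model here, so
  # their coefficients should be statistically indistinguishable from zero
  # in most replicates (95% level)
  reps <- 40
  null_hits <- 0
  terms_checked <- 0
  for (r in seq_len(reps)) {
    cfg <- scenario_library("null", seed = 700 + r)
    rows <- build_analysis_rows(generate_cohort(cfg), cost_config(0))
    fit <- adjusted_nb_regression(rows, 25000, c("edu_some", "asset"))
    co <- fit$coefficients[fit$coefficients$term %in%
                             c("edu_some", paste0("asset", 2:5)), ]
    null_hits <- null_hits + sum(co$p.value > 0.05)
    terms_checked <- terms_checked + nrow(co)
  }
  # expected non-rejection rate 0.95; allow 3 binomial SDs
  p_hat <- null_hits / terms_checked
  expect_gt(p_hat, 0.95 - 3 * sqrt(0.95 * 0.05 / terms_checked))
})

test_that("a built-in treatment-by-distance interaction is recovered", {
  cfg <- scenario_library("distance_effect", seed = 55L)
  truth <- implied_interaction_inb(cfg, 30000)
  # independent recomputation from the cell probabilities: the comparison
  # arm has no distance effect, so the interaction is the intervention-arm
  # far-vs-near delivery gap monetised at ro minus the out-of-pocket cost
  gap <- plogis(qlogis(0.40) + 0.302) - 0.40
  expect_equal(truth, gap * (30000 - 3000), tolerance = 1e-12)
  expect_equal(truth, 2000, tolerance = 0.01) # ~ +2,000 CFA by design
  rows <- build_analysis_rows(generate_cohort(cfg),
                              cost_config(cfg$system_incremental_cost))
  fit <- adjusted_nb_regression(rows, 30000, "dist_far", interactions = TRUE)
  co <- fit$coefficients[fit$coefficients$term == "sci:dist_far", ]
  expect_lt(abs(co$estimate - truth), qnorm(0.975) * co$std.error * 1.5)
})

test_that("collinearity diagnostics flag what they should", {
  withr::local_seed(31)
  # independent covariates: small |r|, VIFs near 1
  cfg <- generator_config(5000, 5000, seed = 8L)
  rows <- build_analysis_rows(generate_cohort(cfg), cost_config(1000))
  diag_ind <- collinearity_diagnostics(rows, c("edu_some", "dist_far"))
  r_ed <- diag_ind$correlation["edu_some", "dist_far"]
  expect_lt(abs(r_ed), 0.1)
  expect_equal(nrow(diag_ind$flagged_pairs), 0)
  vifs <- diag_ind$vif$vif[!diag_ind$vif$constant]
  expect_true(all(vifs < 1.5))

  # distance-dependent assets induce a flagged distance-asset correlation
  cfg2 <- generator_config(5000, 5000,
                           covariates = list(asset_distance_slope = 3),
                           seed = 8L)
  rows2 <- build_analysis_rows(generate_cohort(cfg2), cost_config(1000))
  diag_dep <- collinearity_diagnostics(rows2, c("dist_far", "asset"),
                                       threshold = 0.3)
  pairs <- diag_dep$flagged_pairs
  expect_true(any(pairs$var1 == "dist_far" & grepl("^asset", pairs$var2) |
                    pairs$var2 == "dist_far" & grepl("^asset", pairs$var1)))

  # constant column: undefined VIF, flagged as constant
  rows3 <- dplyr::mutate(rows, edu_some = 0L)
  diag_const <- collinearity_diagnostics(rows3, c("edu_some", "dist_far"))
  row_const <- diag_const$vif[diag_const$vif$column == "edu_some", ]
  expect_true(row_const$constant)
  expect_true(is.na(row_const$vif))
})

test_that("tidy and glance expose the fit in broom style", {
  withr::local_seed(3)
  rows <- build_analysis_rows(random_cohort(30), cost_config(500))
  fit <- simple_nb_regression(rows, 10000)
  td <- tidy(fit)
  expect_named(td, c("ro", "term", "estimate", "std.error", "statistic",
                     "p.value"))
  gl <- glance(fit)
  expect_equal(gl$n, nrow(rows))
  expect_equal(gl$model, "simple")
})
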