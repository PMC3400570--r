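# small in-code fixtures shared across test files

# a minimal well-formed household tibble covering the 4 (arm x delivery)
# cells
four_cell_cohort <- function() {
  tibble::tibble(
    id = c("a", "b", "c", "d"),
    district = c("intervention", "intervention", "comparison", "comparison"),
    institutional_delivery = c(1L, 0L, 1L, 0L),
    household_cost = c(600, NA, 450, NA),
    distance_km = c(2, 8, 3.5, 12),
    education_head = c("some", "none", "none", "some"),
    asset_quintile = c(3L, 1L, 5L, 2L)
  )
}

cohort_csv <- function(data) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  readr::write_csv(data, path, na = "")
  path
}

# a random small two-arm cohort for property tests; deliveries guaranteed
# in both arms so costs are always identifiable
random_cohort <- function(n_per_arm = 30) {
  make_arm <- function(arm, n) {
    delivery <- c(1L, 1L, stats::rbinom(n - 2, 1, 0.5))
    tibble::tibble(
      id = paste0(arm, seq_len(n)),
      district = arm,
      institutional_delivery = delivery,
      household_cost = ifelse(delivery == 1, stats::rgamma(n, 4, scale = 800),
                              NA_real_),
      distance_km = stats::rgamma(n, 2, scale = 3),
      education_head = sample(c("none", "some"), n, replace = TRUE),
      asset_quintile = sample.int(5, n, replace = TRUE)
    )
  }
  dplyr::bind_rows(make_arm("intervention", n_per_arm),
                   make_arm("comparison", n_per_arm))
}

# analysis rows for the deterministic calibration cohort
table1_rows <- function(seed = 1L) {
  cfg <- scenario_library("table1_exact", seed = seed)
  build_analysis_rows(generate_cohort(cfg),
                      cost_config(cfg$system_incremental_cost))
}
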