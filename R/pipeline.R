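#' Run the full net-benefit cost-effectiveness pipeline
#'
#' End-to-end orchestration: read (or generate) the cohort, validate it,
#' attribute societal costs, compute arm summaries and the overall and
#' stratified ICERs, fit the net-benefit regression grid (simple, and
#' adjusted/interaction when covariates are given, with collinearity
#' diagnostics), build the CEAC (overall, per stratum, and adjusted) and
#' extract the CEAC-based confidence interval for the ICER. All result
#' tables are written as CSV under `output_dir` together with a
#' machine-readable JSON manifest and a short human-readable summary; the
#' run is a pure function of (input, configuration, seed).
#'
#' @param input Path to a household CSV in the canonical dialect. Exactly
#'   one of `input`/`scenario` must be supplied.
#' @param scenario Name of a built-in generator scenario
#'   (see [scenario_library()]).
#' @param output_dir Directory for the artifact bundle (created if absent).
#' @param system_cost Health-system incremental cost per intervention
#'   household, CFA. Required with `input`; for a scenario it defaults to
#'   the scenario's own value.
#' @param ppp_rate CFA per international dollar (reporting only).
#' @param ro_grid Ceiling-ratio grid; defaults to [default_ro_grid()].
#' @param covariates Optional covariates for the adjusted model (subset of
#'   `c("edu_some", "dist_far", "asset")`).
#' @param interactions Add treatment-by-covariate interactions to the
#'   adjusted model?
#' @param se_type `"classical"` or `"robust"`.
#' @param strata Stratification variables for Table-2-style ICERs and
#'   per-stratum CEACs; default `"distance"`. `NULL` to skip.
#' @param strict Strict cost validation when reading `input`.
#' @param distance_threshold_km Near/far distance cut, km.
#' @param seed Seed for scenario generation.
#' @param verbose Log progress to stderr via [message()]?
#' @return (Invisibly) a named list with every intermediate object
#'   (`data`, `rows`, `summaries`, `icer`, `stratified`, `grid`,
#'   `adjusted_grid`, `collinearity`, `ceac`, `ceac_strata`, `ci`,
#'   `files`).
#' @export
run_pipeline <- function(input = NULL, scenario = NULL, output_dir,
                         system_cost = NULL, ppp_rate = 167,
                         ro_grid = default_ro_grid(),
                         covariates = NULL, interactions = FALSE,
                         se_type = c("classical", "robust"),
                         strata = "distance", strict = TRUE,
                         distance_threshold_km = 5, seed = 1L,
                         verbose = TRUE) {
  se_type <- match.arg(se_type)
  if (is.null(input) == is.null(scenario)) {
    abort("supply exactly one of `input` (CSV path) or `scenario` (name)",
          class = "nbcea_config_error")
  }
  say <- function(...) if (verbose) message("[nbcea] ", ...)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir) || file.access(output_dir, 2) != 0) {
    abort(paste0("output_dir '", output_dir, "' is not writable"),
          class = "nbcea_config_error")
  }
  files <- character(0)
  emit <- function(obj, name) {
    path <- file.path(output_dir, name)
    readr::write_csv(as_tibble(obj), path, na = "", progress = FALSE)
    files <<- c(files, name)
    path
  }

  # --- input stage -------------------------------------------------------
  if (!is.null(scenario)) {
    config <- scenario_library(scenario, seed = as.integer(seed))
    say("generating scenario '", scenario, "' (seed ", seed, ")")
    data <- generate_cohort(config)
    if (is.null(system_cost)) system_cost <- config$system_incremental_cost
    emit(data, "cohort.csv")
  } else {
    if (is.null(system_cost)) {
      abort("system_cost (CFA) is required when analysing a cohort CSV",
            class = "nbcea_config_error")
    }
    say("reading cohort from ", input)
    data <- read_household_table(input, strict = strict)
  }
  cfg <- cost_config(system_incremental_cost = system_cost,
                     ppp_rate = ppp_rate)

  # --- validation + cost attribution ------------------------------------
  validation <- validate_cohort(data)
  say("cohort: ", paste(sprintf("%s n=%d (%.1f%% facility deliveries)",
                                validation$arms$district, validation$arms$n,
                                100 * validation$arms$delivery_prop),
                        collapse = "; "))
  emit(validation$arms, "validation_arms.csv")
  rows <- build_analysis_rows(data, cfg, distance_threshold_km)

  # --- summaries + ICER --------------------------------------------------
  summaries <- group_summaries(rows)
  emit(summaries, "group_summaries.csv")
  overall <- icer_from_rows(rows, ppp_rate)
  say(sprintf("ICER %.0f CFA (I$%.0f), quadrant %s",
              overall$icer_cfa, overall$icer_intl, overall$quadrant))
  emit(overall, "icer.csv")
  stratified <- list()
  for (sv in strata %||% character(0)) {
    stratified[[sv]] <- stratified_icer(rows, sv, ppp_rate = ppp_rate)
    emit(stratified[[sv]], paste0("icer_by_", sv, ".csv"))
  }

  # --- regression grid ---------------------------------------------------
  say("fitting simple net-benefit regressions over ", length(ro_grid),
      " ceiling ratios")
  grid <- nb_regression_grid(rows, ro_grid, se_type = se_type)
  emit(grid, "nb_grid.csv")
  emit(nb_grid_table(grid), "nb_grid_table.csv")
  emit(attr(grid, "glance"), "nb_grid_fitstats.csv")
  adjusted_grid <- NULL
  collin <- NULL
  if (!is.null(covariates)) {
    say("fitting adjusted model (covariates: ",
        paste(covariates, collapse = ", "),
        if (interactions) "; with interactions" else "", ")")
    adjusted_grid <- nb_regression_grid(rows, ro_grid, covariates,
                                        interactions, se_type)
    emit(adjusted_grid, "nb_grid_adjusted.csv")
    collin <- collinearity_diagnostics(rows, covariates, interactions)
    emit(collin$vif, "collinearity_vif.csv")
    if (nrow(collin$flagged_pairs) > 0) {
      emit(collin$flagged_pairs, "collinearity_flagged.csv")
    }
  }

  # --- CEAC --------------------------------------------------------------
  ceac <- ceac_curve(rows, ro_grid, se_type = se_type)
  emit(ceac, "ceac.csv")
  ceac_strata <- list()
  for (sv in strata %||% character(0)) {
    ceac_strata[[sv]] <- ceac_by_stratum(rows, ro_grid, sv, se_type)
    emit(ceac_strata[[sv]], paste0("ceac_by_", sv, ".csv"))
  }
  if (!is.null(covariates)) {
    adj_curve <- ceac_curve(rows, ro_grid, covariates, interactions = FALSE,
                            se_type = se_type, label = "adjusted")
    emit(adj_curve, "ceac_adjusted.csv")
  }
  ci <- ci_from_ceac(ceac)
  say(sprintf("CEAC 95%% interval for the ICER: (%.0f, %.0f) CFA",
              ci$ro_low, ci$ro_high))
  emit(ci, "ceac_ci.csv")

  # --- manifest + summary ------------------------------------------------
  manifest <- list(
    package = "nbcea",
    version = as.character(utils::packageVersion("nbcea")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    input = input %||% NA, scenario = scenario %||% NA,
    seed = seed, system_cost = system_cost, ppp_rate = ppp_rate,
    ro_grid = list(min = min(ro_grid), max = max(ro_grid),
                   n = length(ro_grid)),
    covariates = covariates %||% list(), interactions = interactions,
    se_type = se_type, strata = strata %||% list(), strict = strict,
    distance_threshold_km = distance_threshold_km,
    n_households = nrow(data),
    key_estimates = list(delta_c = overall$delta_c,
                         delta_e = overall$delta_e,
                         icer_cfa = overall$icer_cfa,
                         icer_intl = overall$icer_intl,
                         ceac_ci_low = ci$ro_low,
                         ceac_ci_high = ci$ro_high),
    files = files
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  summary_lines <- c(
    "nbcea pipeline summary",
    sprintf("households: %d (%s)", nrow(data),
            paste(sprintf("%s %d", validation$arms$district,
                          validation$arms$n), collapse = ", ")),
    sprintf("delivery proportions: %s",
            paste(sprintf("%s %.1f%%", validation$arms$district,
                          100 * validation$arms$delivery_prop),
                  collapse = ", ")),
    sprintf("cost increment: %.0f CFA; effect increment: %.1f pp",
            overall$delta_c, 100 * overall$delta_e),
    sprintf("ICER: %.0f CFA per additional facility delivery (I$%.0f)",
            overall$icer_cfa, overall$icer_intl),
    sprintf("CEAC-based 95%% interval for the ICER: (%.0f, %.0f) CFA",
            ci$ro_low, ci$ro_high)
  )
  writeLines(summary_lines, file.path(output_dir, "summary.txt"))

  invisible(list(data = data, validation = validation, rows = rows,
                 summaries = summaries, icer = overall,
                 stratified = stratified, grid = grid,
                 adjusted_grid = adjusted_grid, collinearity = collin,
                 ceac = ceac, ceac_strata = ceac_strata, ci = ci,
                 manifest = manifest,
                 files = c(files, "manifest.json", "summary.txt")))
}

#' Read a pipeline run configuration from YAML
#'
#' Flat YAML mapping of [run_pipeline()] arguments, with the nested blocks
#' `cost: {system_incremental_cost, ppp_rate}`,
#' `regression: {covariates, interactions, se_type}` and
#' `ro_grid: {start, stop, step}` accepted as structured alternatives to
#' the flat keys.
#'
#' @param path YAML file path.
#' @return Named list suitable for `do.call(run_pipeline, ...)`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- raw
  if (!is.null(raw$cost)) {
    out$system_cost <- raw$cost$system_incremental_cost
    out$ppp_rate <- raw$cost$ppp_rate %||% 167
    out$cost <- NULL
  }
  if (!is.null(raw$regression)) {
    out$covariates <- unlist(raw$regression$covariates) %||% NULL
    out$interactions <- raw$regression$interactions %||% FALSE
    out$se_type <- raw$regression$se_type %||% "classical"
    out$regression <- NULL
  }
  if (is.list(raw$ro_grid)) {
    out$ro_grid <- seq(raw$ro_grid$start, raw$ro_grid$stop,
                       by = raw$ro_grid$step)
  }
  if (!is.null(out$strata)) out$strata <- unlist(out$strata)
  allowed <- names(formals(run_pipeline))
  bad <- setdiff(names(out), allowed)
  if (length(bad) > 0) {
    abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")),
          class = "nbcea_config_error")
  }
  out
}
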