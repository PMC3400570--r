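#' Configuration for the two-district cohort generator
#'
#' Describes a synthetic two-district household cohort: arm sizes, a
#' logistic model for the probability of institutional delivery, marginal
#' covariate distributions, gamma out-of-pocket cost distributions, and the
#' health-system incremental cost. Two modes are supported:
#'
#' \describe{
#'   \item{`"stochastic"`}{covariates, deliveries and costs are drawn from
#'     the configured distributions — use for calibration/coverage studies;}
#'   \item{`"exact"`}{each arm receives exactly `round(n * p)` deliveries
#'     (assigned to the first households of the arm) and every delivering
#'     household carries the arm's fixed mean out-of-pocket cost, so arm
#'     delivery proportions and mean costs hit their targets exactly —
#'     use to reproduce printed district-level figures deterministically.}
#' }
#'
#' @param n_intervention,n_comparison Arm sizes, `>= 1`.
#' @param delivery Named list of log-odds terms: `intercept`, `sci`
#'   (intervention main effect), `dist_far`, `edu_some`, `asset` (linear in
#'   quintile, centred at 3), and interactions `sci_dist_far`,
#'   `sci_edu_some`, `sci_asset`. Missing entries default to 0.
#' @param covariates Named list: `p_edu_some` (default 0.35),
#'   `distance_shape`/`distance_scale` (gamma, km; defaults 2 and 3, mean
#'   6 km so both 5-km strata are populated), `asset_distance_slope`
#'   (default 0; positive values tilt asset quintiles downward with
#'   distance, inducing distance-asset collinearity).
#' @param cost Named list: `hh_mean_intervention`, `hh_mean_comparison`
#'   (mean out-of-pocket cost of a facility delivery, CFA), `cv`
#'   (coefficient of variation of the gamma cost draw, default 0.5).
#' @param system_incremental_cost Health-system incremental cost per
#'   intervention household, CFA.
#' @param mode `"stochastic"` or `"exact"`.
#' @param exact_p Named list `intervention`/`comparison`: target delivery
#'   proportions for exact mode (also used to set the default logits).
#' @param seed Integer master seed; per-arm substreams are derived from it
#'   so one arm's draws do not depend on the other arm's size.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_intervention, n_comparison,
                             delivery = list(),
                             covariates = list(),
                             cost = list(),
                             system_incremental_cost = 0,
                             mode = c("stochastic", "exact"),
                             exact_p = list(intervention = 0.44,
                                            comparison = 0.315),
                             seed = 1L) {
  mode <- match.arg(mode)
  if (n_intervention < 1 || n_comparison < 1) {
    abort("arm sizes must be >= 1", class = "nbcea_config_error")
  }
  delivery <- modifyList(list(intercept = qlogis(0.315), sci = 0,
                              dist_far = 0, edu_some = 0, asset = 0,
                              sci_dist_far = 0, sci_edu_some = 0,
                              sci_asset = 0), delivery)
  covariates <- modifyList(list(p_edu_some = 0.35, distance_shape = 2,
                                distance_scale = 3,
                                asset_distance_slope = 0), covariates)
  cost <- modifyList(list(hh_mean_intervention = 3000,
                          hh_mean_comparison = 3308, cv = 0.5), cost)
  if (covariates$p_edu_some < 0 || covariates$p_edu_some > 1) {
    abort("p_edu_some must lie in [0, 1]", class = "nbcea_config_error")
  }
  if (covariates$distance_shape <= 0 || covariates$distance_scale <= 0 ||
      cost$cv <= 0 || cost$hh_mean_intervention <= 0 ||
      cost$hh_mean_comparison <= 0) {
    abort("gamma parameters (distance shape/scale, cost means, cv) must be > 0",
          class = "nbcea_config_error")
  }
  if (system_incremental_cost < 0) {
    abort("system_incremental_cost must be >= 0", class = "nbcea_config_error")
  }
  if (any(unlist(exact_p) <= 0) || any(unlist(exact_p) >= 1)) {
    abort("exact-mode target proportions must lie in (0, 1)",
          class = "nbcea_config_error")
  }
  structure(list(
    n_intervention = as.integer(n_intervention),
    n_comparison = as.integer(n_comparison),
    delivery = delivery, covariates = covariates, cost = cost,
    system_incremental_cost = system_incremental_cost,
    mode = mode, exact_p = exact_p, seed = as.integer(seed)
  ), class = "generator_config")
}

# run code with a private, seeded RNG stream, restoring global state after
with_private_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

generate_arm <- function(config, arm, n, arm_seed) {
  cv <- config$covariates
  dl <- config$delivery
  sci <- as.integer(arm == "intervention")
  with_private_seed(arm_seed, {
    distance <- rgamma(n, shape = cv$distance_shape, scale = cv$distance_scale)
    edu <- rbinom(n, 1, cv$p_edu_some)
    if (cv$asset_distance_slope != 0) {
      score <- stats::rnorm(n) - cv$asset_distance_slope *
        (distance - mean(distance)) / sd(distance)
      asset <- as.integer(dplyr::ntile(score, 5))
    } else {
      asset <- sample.int(5, n, replace = TRUE)
    }
    dist_far <- as.integer(distance > 5)
    hh_mean <- if (arm == "intervention") config$cost$hh_mean_intervention
               else config$cost$hh_mean_comparison
    if (config$mode == "exact") {
      p_target <- if (arm == "intervention") config$exact_p$intervention
                  else config$exact_p$comparison
      k <- round(n * p_target)
      delivery <- c(rep(1L, k), rep(0L, n - k))
      cost <- ifelse(delivery == 1, hh_mean, NA_real_)
    } else {
      eta <- dl$intercept + dl$sci * sci +
        (dl$dist_far + dl$sci_dist_far * sci) * dist_far +
        (dl$edu_some + dl$sci_edu_some * sci) * edu +
        (dl$asset + dl$sci_asset * sci) * (asset - 3)
      delivery <- rbinom(n, 1, plogis(eta))
      shape <- 1 / config$cost$cv^2
      cost <- ifelse(delivery == 1,
                     rgamma(n, shape = shape, scale = hh_mean / shape),
                     NA_real_)
    }
    tibble(
      id = paste0(substr(arm, 1, 3), "_", seq_len(n)),
      district = arm,
      institutional_delivery = as.integer(delivery),
      household_cost = cost,
      distance_km = distance,
      education_head = ifelse(edu == 1, "some", "none"),
      asset_quintile = as.integer(asset)
    )
  })
}

#' Generate a synthetic two-district household cohort
#'
#' Draws a cohort per the configuration; fully deterministic given
#' (`seed`, config). The global RNG state is left untouched.
#'
#' @param config A [generator_config()].
#' @return Household tibble in the canonical dialect (see
#'   [read_household_table()]).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  seeds <- with_private_seed(config$seed,
                             sample.int(.Machine$integer.max - 1L, 2))
  bind_rows(
    generate_arm(config, "intervention", config$n_intervention, seeds[1]),
    generate_arm(config, "comparison", config$n_comparison, seeds[2])
  )
}

#' Calibrate a generator to district-level summary targets
#'
#' Solves the cost-attribution identities for the health-system incremental
#' cost and sets the delivery logits so the generator reproduces published
#' district-level figures. With societal mean cost `m_int` and delivery
#' proportion `p_int` in the intervention district, and a mean out-of-pocket
#' delivery cost `h_int`, the attribution rule forces
#' `system_incremental_cost = m_int - p_int * h_int`; in the comparison
#' district consistency requires `m_comp = p_comp * h_comp`.
#'
#' @param target_intervention,target_comparison Lists or one-row data frames
#'   with `effect_proportion` and `mean_cost` (societal, CFA).
#' @param hh_cost_means Named numeric, `c(intervention = , comparison = )`:
#'   mean out-of-pocket cost of a facility delivery per arm, CFA.
#' @param n_intervention,n_comparison Arm sizes for the returned config.
#' @param mode Generator mode, default `"exact"`.
#' @param tol Relative tolerance for the comparison-arm consistency check.
#' @param seed Master seed.
#' @return A [generator_config()] hitting the targets.
#' @export
calibrate_to_summaries <- function(target_intervention, target_comparison,
                                   hh_cost_means,
                                   n_intervention = 10000,
                                   n_comparison = 10000,
                                   mode = "exact", tol = 0.01, seed = 1L) {
  p_int <- target_intervention$effect_proportion
  p_comp <- target_comparison$effect_proportion
  if (p_int <= 0 || p_int >= 1 || p_comp <= 0 || p_comp >= 1) {
    abort("target proportions must lie in (0, 1)", class = "nbcea_config_error")
  }
  sys <- target_intervention$mean_cost - p_int * hh_cost_means[["intervention"]]
  if (sys < 0) {
    abort(paste0("infeasible targets: implied system_incremental_cost = ",
                 format(sys), " CFA (< 0)"),
          class = "nbcea_config_error")
  }
  implied_comp <- p_comp * hh_cost_means[["comparison"]]
  if (abs(implied_comp - target_comparison$mean_cost) >
      tol * max(1, abs(target_comparison$mean_cost))) {
    abort(paste0("comparison-arm targets inconsistent: p * hh_cost = ",
                 format(implied_comp), " but mean_cost target = ",
                 format(target_comparison$mean_cost)),
          class = "nbcea_config_error")
  }
  generator_config(
    n_intervention = n_intervention, n_comparison = n_comparison,
    delivery = list(intercept = qlogis(p_comp),
                    sci = qlogis(p_int) - qlogis(p_comp)),
    cost = list(hh_mean_intervention = hh_cost_means[["intervention"]],
                hh_mean_comparison = hh_cost_means[["comparison"]]),
    system_incremental_cost = sys,
    mode = mode,
    exact_p = list(intervention = p_int, comparison = p_comp),
    seed = seed
  )
}

#' Built-in generator scenarios
#'
#' Named configurations covering the situations the package is validated
#' on:
#' \describe{
#'   \item{`table1_exact`}{deterministic calibration cohort, 10,000
#'     households per arm; intervention: delivery proportion 0.44,
#'     out-of-pocket cost 3,000 CFA per delivery, system cost 3,256
#'     CFA/household (societal mean 4,576 CFA); comparison: proportion
#'     0.315, out-of-pocket 3,308 CFA (societal mean ~1,042 CFA).}
#'   \item{`study_stochastic`}{the same district-level moments drawn
#'     stochastically at the study's arm sizes (40,469 intervention /
#'     48,272 comparison households).}
#'   \item{`distance_effect`}{stochastic cohort with a built-in positive
#'     treatment-by-distance log-odds interaction (0.302), sized so the
#'     implied interaction on the net-benefit scale is about +2,000 CFA at
#'     Ro = 30,000 (see [implied_interaction_inb()]).}
#'   \item{`null`}{no arm effect anywhere (identical delivery model and
#'     costs, zero system cost) — for type-I-error checks.}
#' }
#'
#' @param name Optional scenario name; omit for the full named list.
#' @param ... Overrides passed to the selected config (e.g.
#'   `n_intervention`, `seed`); only with `name`.
#' @return A named list of `generator_config`s, or a single config.
#' @export
scenario_library <- function(name = NULL, ...) {
  lib <- list(
    table1_exact = calibrate_to_summaries(
      list(effect_proportion = 0.44, mean_cost = 4576),
      list(effect_proportion = 0.315, mean_cost = 1042),
      hh_cost_means = c(intervention = 3000, comparison = 3308),
      n_intervention = 10000, n_comparison = 10000, mode = "exact"
    ),
    study_stochastic = calibrate_to_summaries(
      list(effect_proportion = 0.44, mean_cost = 4576),
      list(effect_proportion = 0.315, mean_cost = 1042),
      hh_cost_means = c(intervention = 3000, comparison = 3308),
      n_intervention = 40469, n_comparison = 48272, mode = "stochastic"
    ),
    distance_effect = generator_config(
      n_intervention = 10000, n_comparison = 10000,
      delivery = list(intercept = qlogis(0.315),
                      sci = qlogis(0.40) - qlogis(0.315),
                      sci_dist_far = 0.302),
      cost = list(hh_mean_intervention = 3000, hh_mean_comparison = 3308),
      system_incremental_cost = 3256,
      mode = "stochastic"
    ),
    null = generator_config(
      n_intervention = 2000, n_comparison = 2000,
      delivery = list(intercept = qlogis(0.315), sci = 0),
      cost = list(hh_mean_intervention = 3000, hh_mean_comparison = 3000),
      system_incremental_cost = 0,
      mode = "stochastic"
    )
  )
  if (is.null(name)) return(lib)
  if (!name %in% names(lib)) {
    abort(paste0("unknown scenario '", name, "'; available: ",
                 paste(names(lib), collapse = ", ")),
          class = "nbcea_config_error")
  }
  cfg <- lib[[name]]
  overrides <- list(...)
  if (length(overrides) > 0) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad) > 0) {
      abort(paste0("unknown config field(s): ", paste(bad, collapse = ", ")),
            class = "nbcea_config_error")
    }
    cfg[names(overrides)] <- overrides
    cfg$n_intervention <- as.integer(cfg$n_intervention)
    cfg$n_comparison <- as.integer(cfg$n_comparison)
    cfg$seed <- as.integer(cfg$seed)
  }
  cfg
}

#' Implied treatment-by-distance interaction on the net-benefit scale
#'
#' For a generator whose delivery probability depends only on arm and the
#' far-distance indicator (education and asset coefficients zero), the
#' population interaction coefficient of the saturated net-benefit model
#' `NB ~ sci * dist_far` at ceiling ratio `ro` is available in closed form.
#' Writing `p(a, d)` for the delivery probability in arm `a` at distance
#' stratum `d`, `h_a` for the arm's mean out-of-pocket delivery cost:
#' `gamma(ro) = (p(1,1) - p(1,0)) (ro - h_int) - (p(0,1) - p(0,0)) (ro - h_comp)`
#' (the per-household system cost is additive within the intervention arm
#' and cancels from the interaction).
#'
#' Used as the ground truth in interaction-recovery (CI coverage) studies.
#'
#' @param config A [generator_config()] with zero education/asset delivery
#'   coefficients.
#' @param ro Ceiling ratio, CFA.
#' @return The implied interaction coefficient, CFA.
#' @export
implied_interaction_inb <- function(config, ro) {
  dl <- config$delivery
  if (dl$edu_some != 0 || dl$asset != 0 || dl$sci_edu_some != 0 ||
      dl$sci_asset != 0) {
    abort("closed form requires zero education/asset delivery coefficients",
          class = "nbcea_config_error")
  }
  p <- function(sci, far) {
    plogis(dl$intercept + dl$sci * sci +
             (dl$dist_far + dl$sci_dist_far * sci) * far)
  }
  (p(1, 1) - p(1, 0)) * (ro - config$cost$hh_mean_intervention) -
    (p(0, 1) - p(0, 0)) * (ro - config$cost$hh_mean_comparison)
}
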