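#' Cost-attribution configuration
#'
#' Bundles the two economy-wide cost parameters: the incremental cost to the
#' health system of supporting one intervention-district household (CFA), and
#' the purchasing-power-parity exchange rate used only at the reporting
#' boundary (CFA per international dollar; 167 in the study setting).
#'
#' `attribute_to` controls which intervention-district households carry the
#' health-system cost. The default, `"all_households"`, charges it to every
#' intervention household whether or not it delivered in a facility — the
#' societal-perspective attribution rule this package is built around. The
#' alternative `"deliveries_only"` charges it only to delivering households.
#'
#' @param system_incremental_cost Health-system incremental cost per
#'   intervention-district household, CFA, `>= 0`.
#' @param ppp_rate CFA per international dollar, `> 0`; default 167.
#' @param attribute_to `"all_households"` (default) or `"deliveries_only"`.
#' @return A `cost_config` list.
#' @export
cost_config <- function(system_incremental_cost, ppp_rate = 167,
                        attribute_to = c("all_households", "deliveries_only")) {
  attribute_to <- match.arg(attribute_to)
  if (!is.numeric(system_incremental_cost) || length(system_incremental_cost) != 1 ||
      is.na(system_incremental_cost) || system_incremental_cost < 0) {
    abort("system_incremental_cost must be a single number >= 0",
          class = "nbcea_config_error")
  }
  if (!is.numeric(ppp_rate) || length(ppp_rate) != 1 || is.na(ppp_rate) ||
      ppp_rate <= 0) {
    abort("ppp_rate must be a single number > 0", class = "nbcea_config_error")
  }
  structure(list(system_incremental_cost = system_incremental_cost,
                 ppp_rate = ppp_rate, attribute_to = attribute_to),
            class = "cost_config")
}

#' Societal-perspective per-household cost
#'
#' Applies the district-specific attribution rules that construct the cost
#' side of the per-household net benefit:
#' \itemize{
#'   \item intervention district, facility delivery: household out-of-pocket
#'     cost plus the health-system incremental cost;
#'   \item intervention district, no facility delivery: the health-system
#'     incremental cost alone;
#'   \item comparison district, facility delivery: the household
#'     out-of-pocket cost alone (the standard health-system cost cancels
#'     between districts);
#'   \item comparison district, no facility delivery: zero.
#' }
#'
#' @param district Character vector, `"intervention"`/`"comparison"`.
#' @param institutional_delivery 0/1 vector.
#' @param household_cost Out-of-pocket cost (CFA); may be `NA` for
#'   non-delivering households.
#' @param config A [cost_config()].
#' @return Numeric vector of societal costs, CFA.
#' @export
#' @examples
#' cfg <- cost_config(system_incremental_cost = 3000)
#' societal_cost("intervention", 1, 600, cfg)   # 3600
#' societal_cost("intervention", 0, NA, cfg)    # 3000
#' societal_cost("comparison", 0, NA, cfg)      # 0
societal_cost <- function(district, institutional_delivery, household_cost,
                          config) {
  stopifnot(inherits(config, "cost_config"))
  need_cost <- institutional_delivery == 1 & is.na(household_cost)
  if (any(need_cost)) {
    abort(paste0("household_cost missing for ", sum(need_cost),
                 " delivering household(s); run read_household_table() with ",
                 "strict = FALSE to impute"),
          class = "nbcea_row_error")
  }
  hh <- ifelse(institutional_delivery == 1, household_cost, 0)
  sys <- config$system_incremental_cost
  carries_sys <- if (config$attribute_to == "all_households") {
    district == "intervention"
  } else {
    district == "intervention" & institutional_delivery == 1
  }
  hh + ifelse(carries_sys, sys, 0)
}

#' Build the net-benefit analysis table
#'
#' Turns a validated two-arm household table into one analysis row per
#' household: derived covariates, the binary effect (institutional delivery)
#' and the societal-perspective cost.
#'
#' @param data Household tibble (both arms present).
#' @param config A [cost_config()].
#' @param distance_threshold_km Passed to [derive_covariates()].
#' @return Tibble with columns `id`, `district`, covariates (`sci`,
#'   `edu_some`, `dist_far`, `asset2`..`asset5`, plus the raw covariates),
#'   `effect` and `societal_cost`.
#' @export
build_analysis_rows <- function(data, config, distance_threshold_km = 5) {
  validate_cohort(data)
  data |>
    derive_covariates(distance_threshold_km) |>
    mutate(
      effect = .data$institutional_delivery,
      societal_cost = societal_cost(.data$district, .data$institutional_delivery,
                                    .data$household_cost, config)
    )
}

#' Convert CFA to international dollars
#'
#' Division by the PPP rate. All computation in this package stays in CFA;
#' conversion is a reporting-boundary operation, and reported I$ figures are
#' conventionally rounded to the nearest whole dollar (half away from zero),
#' which `rounded = TRUE` applies.
#'
#' @param amount_cfa Numeric, CFA.
#' @param config A [cost_config()] (only `ppp_rate` is used).
#' @param rounded Round to the nearest integer I$? Default `FALSE`.
#' @return Numeric, international dollars.
#' @export
#' @examples
#' to_international_dollars(28430, cost_config(0), rounded = TRUE)  # 170
to_international_dollars <- function(amount_cfa, config, rounded = FALSE) {
  stopifnot(inherits(config, "cost_config"))
  out <- amount_cfa / config$ppp_rate
  if (rounded) out <- round_half_away(out)
  out
}

# round half away from zero (base round() is half-to-even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
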