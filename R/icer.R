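#' Per-arm summary of effect and cost
#'
#' Means of the binary effect (institutional delivery) and the societal
#' cost for one district. The effect SD uses the sample (n - 1) denominator
#' and the SE is SD / sqrt(n).
#'
#' @param rows Analysis tibble from [build_analysis_rows()].
#' @param arm `"intervention"` or `"comparison"`.
#' @return One-row tibble: `arm`, `n`, `effect_proportion`, `effect_sd`,
#'   `effect_se`, `mean_cost`.
#' @export
group_summary <- function(rows, arm = c("intervention", "comparison")) {
  arm <- match.arg(arm)
  sub <- rows[rows$district == arm, ]
  if (nrow(sub) == 0) {
    abort(paste0("no households in arm '", arm, "'"),
          class = "nbcea_cohort_error")
  }
  tibble(
    arm = arm,
    n = nrow(sub),
    effect_proportion = mean(sub$effect),
    effect_sd = sd(sub$effect),
    effect_se = sd(sub$effect) / sqrt(nrow(sub)),
    mean_cost = mean(sub$societal_cost)
  )
}

#' Both arm summaries at once
#'
#' @inheritParams group_summary
#' @return Two-row tibble (intervention first), see [group_summary()].
#' @export
group_summaries <- function(rows) {
  bind_rows(group_summary(rows, "intervention"),
            group_summary(rows, "comparison"))
}

#' Classify a point on the cost-effectiveness plane
#'
#' Quadrants are named from the intervention's standpoint with incremental
#' effect on the x axis and incremental cost on the y axis: more effective
#' and more costly is the north-east trade-off quadrant, more effective and
#' cheaper is south-east dominance, less effective and more costly is
#' north-west domination, less effective and cheaper the south-west
#' trade-off. A zero effect increment falls on the vertical axis and is
#' assigned to the adjacent eastern quadrant with an explanatory status
#' carried by [icer()]; a zero cost increment goes to the dominant/dominated
#' side by the sign of the effect.
#'
#' @param delta_c Incremental cost (CFA), vectorised.
#' @param delta_e Incremental effect, vectorised.
#' @return Character vector in
#'   `{"NE-tradeoff","SE-dominant","NW-dominated","SW-tradeoff"}`.
#' @export
classify_quadrant <- function(delta_c, delta_e) {
  n <- max(length(delta_c), length(delta_e))
  delta_c <- rep_len(delta_c, n)
  delta_e <- rep_len(delta_e, n)
  dplyr::case_when(
    delta_e > 0 & delta_c > 0 ~ "NE-tradeoff",
    delta_e > 0 & delta_c <= 0 ~ "SE-dominant",
    delta_e < 0 & delta_c >= 0 ~ "NW-dominated",
    delta_e < 0 & delta_c < 0 ~ "SW-tradeoff",
    delta_e == 0 & delta_c > 0 ~ "NE-tradeoff",
    delta_e == 0 & delta_c < 0 ~ "SE-dominant",
    .default = "NE-tradeoff"
  )
}

#' Incremental cost-effectiveness ratio
#'
#' The ratio of the incremental mean societal cost to the incremental effect
#' proportion between the two districts. When the effect increment is zero
#' the ratio is undefined: the result keeps the increments and quadrant but
#' flags `icer_defined = FALSE` (use the net-benefit regression instead).
#'
#' @param intervention,comparison One-row tibbles from [group_summary()].
#' @param ppp_rate CFA per international dollar for the I$ column.
#' @param stratum Optional stratum label carried into the result.
#' @return One-row tibble of class `icer_result`: `stratum`, `delta_c`,
#'   `delta_e`, `delta_e_se`, `icer_cfa`, `icer_intl` (rounded to whole I$),
#'   `quadrant`, `icer_defined`, `status`.
#' @export
icer <- function(intervention, comparison, ppp_rate = 167, stratum = NA_character_) {
  delta_c <- intervention$mean_cost - comparison$mean_cost
  delta_e <- intervention$effect_proportion - comparison$effect_proportion
  delta_e_se <- sqrt(intervention$effect_se^2 + comparison$effect_se^2)
  defined <- delta_e != 0
  icer_cfa <- if (defined) delta_c / delta_e else NA_real_
  status <- if (defined) "ok" else "undefined ICER: no effect gain (delta_e = 0)"
  structure(
    tibble(
      stratum = stratum,
      delta_c = delta_c,
      delta_e = delta_e,
      delta_e_se = delta_e_se,
      icer_cfa = icer_cfa,
      icer_intl = if (defined) round_half_away(icer_cfa / ppp_rate) else NA_real_,
      quadrant = classify_quadrant(delta_c, delta_e),
      icer_defined = defined,
      status = status
    ),
    class = c("icer_result", "tbl_df", "tbl", "data.frame")
  )
}

#' ICER from an analysis table
#'
#' Convenience wrapper: arm summaries then [icer()].
#'
#' @inheritParams group_summary
#' @inheritParams icer
#' @return See [icer()].
#' @export
icer_from_rows <- function(rows, ppp_rate = 167, stratum = NA_character_) {
  icer(group_summary(rows, "intervention"), group_summary(rows, "comparison"),
       ppp_rate = ppp_rate, stratum = stratum)
}

#' Stratified ICERs
#'
#' ICERs within the strata of one derived covariate. By default the cost
#' increment is held fixed at the overall (whole-cohort) value in every
#' stratum, so strata differ only through their effect increments — the
#' presentation used when a single district-level cost increment is the
#' only cost quantity available. Set `delta_c = "stratum"` for fully
#' stratum-specific increments, or pass a number to fix it explicitly.
#'
#' A stratum missing one of the arms is flagged (`status`), not computed.
#'
#' @param rows Analysis tibble from [build_analysis_rows()].
#' @param stratum_var One of `"education"`, `"distance"`, `"asset"`.
#' @param delta_c `"overall"` (default), `"stratum"`, or a fixed CFA value.
#' @param ppp_rate CFA per international dollar.
#' @return Tibble of class `icer_result`, one row per stratum.
#' @export
stratified_icer <- function(rows,
                            stratum_var = c("education", "distance", "asset"),
                            delta_c = "overall", ppp_rate = 167) {
  stratum_var <- match.arg(stratum_var)
  labels <- switch(stratum_var,
    education = ifelse(rows$edu_some == 1, "edu: some", "edu: none"),
    distance = ifelse(rows$dist_far == 1, "dist: >5 km", "dist: <=5 km"),
    asset = paste0("asset: Q", rows$asset_quintile)
  )
  fixed <- if (is.numeric(delta_c)) {
    delta_c
  } else if (identical(delta_c, "overall")) {
    icer_from_rows(rows, ppp_rate)$delta_c
  } else if (identical(delta_c, "stratum")) {
    NULL
  } else {
    abort("delta_c must be \"overall\", \"stratum\", or a number",
          class = "nbcea_config_error")
  }

  out <- lapply(sort(unique(labels)), function(lab) {
    sub <- rows[labels == lab, ]
    if (length(unique(sub$district)) < 2) {
      return(tibble(stratum = lab, delta_c = NA_real_, delta_e = NA_real_,
                    delta_e_se = NA_real_, icer_cfa = NA_real_,
                    icer_intl = NA_real_, quadrant = NA_character_,
                    icer_defined = FALSE,
                    status = "stratum missing one arm; not computed"))
    }
    res <- icer_from_rows(sub, ppp_rate, stratum = lab)
    if (!is.null(fixed)) {
      res$delta_c <- fixed
      res$icer_cfa <- if (res$icer_defined) fixed / res$delta_e else NA_real_
      res$icer_intl <- if (res$icer_defined) {
        round_half_away(res$icer_cfa / ppp_rate)
      } else NA_real_
      res$quadrant <- classify_quadrant(res$delta_c, res$delta_e)
    }
    res
  })
  structure(bind_rows(out), class = c("icer_result", "tbl_df", "tbl", "data.frame"))
}
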