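#' Probability the intervention is cost-effective at one ceiling ratio
#'
#' The p-value halving rule: the regression p-value on the treatment dummy
#' is two-sided, but only a one-sided statement — is the incremental net
#' benefit positive? — is needed. For a negative incremental net benefit the
#' probability the intervention is preferred is the one-sided p-value
#' (`p/2`); for a non-negative one it is `1 - p/2`. A zero incremental net
#' benefit (p = 1) gives 0.5.
#'
#' @param inb Incremental net benefit, CFA, vectorised.
#' @param p_two_sided Two-sided p-value(s) in `[0, 1]`.
#' @return Probability in `[0, 1]`, vectorised.
#' @export
prob_cost_effective <- function(inb, p_two_sided) {
  if (any(is.na(p_two_sided)) || any(p_two_sided < 0 | p_two_sided > 1)) {
    abort("p_two_sided must lie in [0, 1]", class = "nbcea_config_error")
  }
  ifelse(inb < 0, p_two_sided / 2, 1 - p_two_sided / 2)
}

new_ceac_curve <- function(points, label) {
  points$label <- label
  structure(points, class = c("ceac_curve", "tbl_df", "tbl", "data.frame"))
}

#' Regression-based cost-effectiveness acceptability curve
#'
#' Fits the net-benefit regression at every ceiling ratio of the grid and
#' converts the treatment coefficient's inference into the probability that
#' the intervention is cost-effective via [prob_cost_effective()].
#'
#' @inheritParams nb_regression_grid
#' @param label Curve label; defaults to `"overall"` for the simple model
#'   and `"adjusted"` when covariates are supplied.
#' @return Tibble of class `ceac_curve`: `ro`, `inb` (treatment
#'   coefficient), `se`, `p_two_sided`, `prob_ce`, `label`.
#' @export
ceac_curve <- function(rows, ro_grid = default_ro_grid(), covariates = NULL,
                       interactions = FALSE,
                       se_type = c("classical", "robust"), label = NULL) {
  se_type <- match.arg(se_type)
  label <- label %||% if (is.null(covariates)) "overall" else "adjusted"
  grid <- nb_regression_grid(rows, ro_grid, covariates, interactions, se_type)
  sci <- grid[grid$term == "sci", ]
  points <- tibble(
    ro = sci$ro, inb = sci$estimate, se = sci$std.error,
    p_two_sided = sci$p.value,
    prob_ce = prob_cost_effective(sci$estimate, sci$p.value)
  )
  new_ceac_curve(points, label)
}

#' CEACs by stratum of one covariate
#'
#' The overall (whole-cohort) curve plus one simple-model curve per stratum
#' of the chosen covariate. Strata missing one of the arms are omitted with
#' a warning.
#'
#' @inheritParams ceac_curve
#' @param stratum_var One of `"education"`, `"distance"`, `"asset"`.
#' @return A single `ceac_curve` tibble with one `label` per curve
#'   (`"overall"` first).
#' @export
ceac_by_stratum <- function(rows, ro_grid = default_ro_grid(),
                            stratum_var = c("education", "distance", "asset"),
                            se_type = c("classical", "robust")) {
  stratum_var <- match.arg(stratum_var)
  se_type <- match.arg(se_type)
  labels <- switch(stratum_var,
    education = ifelse(rows$edu_some == 1, "edu: some", "edu: none"),
    distance = ifelse(rows$dist_far == 1, "dist: >5 km", "dist: <=5 km"),
    asset = paste0("asset: Q", rows$asset_quintile)
  )
  if (length(unique(labels)) < 2) {
    warn(paste0("stratum variable '", stratum_var,
                "' has a single level; stratum curves omitted beyond it"))
  }
  curves <- list(ceac_curve(rows, ro_grid, se_type = se_type, label = "overall"))
  for (lab in sort(unique(labels))) {
    sub <- rows[labels == lab, ]
    if (length(unique(sub$district)) < 2) {
      warn(paste0("stratum '", lab, "' is missing one arm; curve omitted"))
      next
    }
    curves <- c(curves, list(ceac_curve(sub, ro_grid, se_type = se_type,
                                        label = lab)))
  }
  out <- bind_rows(curves)
  structure(out, class = c("ceac_curve", "tbl_df", "tbl", "data.frame"))
}

#' Analytic (normal-approximation) CEAC from arm-level increments
#'
#' Closed-form shortcut consistent with the regression construction: at each
#' ceiling ratio the incremental net benefit is `delta_e * ro - delta_c`
#' with standard error `sqrt(ro^2 * se_e^2 + se_c^2 - 2 * ro * cov_ec)`,
#' and the probability of cost-effectiveness is the normal upper-tail
#' `pnorm(inb / se)`. By default the increments are treated as independent
#' (`cov_ec = 0`); when effect and cost are measured on the same
#' households they are correlated (here the societal cost contains the
#' delivery cost itself), and supplying the increment covariance makes the
#' analytic curve match the regression-based one closely. When no cost
#' dispersion is available (`se_c = 0`, the default) the uncertainty is
#' carried entirely by the effect increment. With both SEs zero the curve
#' degenerates to a step at the ICER: 0 below, 1 above, 0.5 at.
#'
#' @param delta_e Incremental effect proportion.
#' @param se_e Its standard error, `>= 0`.
#' @param delta_c Incremental cost, CFA.
#' @param se_c Standard error of the incremental cost, `>= 0`; default 0.
#' @param cov_ec Covariance of the effect and cost increments; default 0
#'   (independence).
#' @param ro_grid Ceiling-ratio grid; defaults to [default_ro_grid()].
#' @param label Curve label, default `"analytic"`.
#' @return Tibble of class `ceac_curve` (see [ceac_curve()]).
#' @export
#' @examples
#' # effect increment 12.4% (SE 0.3%), cost increment 3,534 CFA
#' cv <- analytic_ceac(0.124, 0.003, 3534, ro_grid = c(25050, 28500, 30060))
#' round(cv$prob_ce, 2)  # 0.00, 0.50 (at ~the ICER), 0.98
analytic_ceac <- function(delta_e, se_e, delta_c, se_c = 0, cov_ec = 0,
                          ro_grid = default_ro_grid(), label = "analytic") {
  stopifnot(se_e >= 0, se_c >= 0)
  inb <- delta_e * ro_grid - delta_c
  var_inb <- ro_grid^2 * se_e^2 + se_c^2 - 2 * ro_grid * cov_ec
  if (any(var_inb < 0)) {
    abort("cov_ec implies a negative net-benefit variance on the grid",
          class = "nbcea_config_error")
  }
  se <- sqrt(var_inb)
  z <- ifelse(se > 0, inb / se, sign(inb) * Inf)
  prob <- pnorm(z)
  prob[se == 0 & inb == 0] <- 0.5
  points <- tibble(
    ro = ro_grid, inb = inb, se = se,
    p_two_sided = ifelse(is.finite(z), 2 * pnorm(-abs(z)),
                         as.numeric(inb == 0)),
    prob_ce = prob
  )
  new_ceac_curve(points, label)
}

#' Confidence interval for the ICER from a CEAC
#'
#' Reads the interval off the acceptability curve: the Ro values where the
#' probability of cost-effectiveness crosses `(1 - level)/2` and
#' `1 - (1 - level)/2`, linearly interpolated between grid points. For a
#' curve rising through 0.5 at the ICER this brackets the sample ICER. A
#' bound the curve never crosses is reported as `-Inf`/`Inf` with a
#' warning; refine or extend the grid for tighter brackets.
#'
#' @param curve A single-label `ceac_curve`.
#' @param level Confidence level, default 0.95.
#' @return One-row tibble: `level`, `ro_low`, `ro_high`.
#' @export
ci_from_ceac <- function(curve, level = 0.95) {
  stopifnot(level > 0, level < 1)
  if (length(unique(curve$label)) > 1) {
    abort("ci_from_ceac expects a single curve; filter on `label` first",
          class = "nbcea_config_error")
  }
  curve <- curve[order(curve$ro), ]
  cross <- function(q) {
    p <- curve$prob_ce
    ro <- curve$ro
    if (any(p == q)) return(ro[which(p == q)[1]])
    idx <- which(diff(sign(p - q)) != 0)
    if (length(idx) == 0) return(NA_real_)
    i <- idx[1]
    ro[i] + (q - p[i]) * (ro[i + 1] - ro[i]) / (p[i + 1] - p[i])
  }
  lo <- cross((1 - level) / 2)
  hi <- cross(1 - (1 - level) / 2)
  if (is.na(lo)) {
    warn("CEAC never crosses the lower probability bound; lower CI limit unbounded")
    lo <- -Inf
  }
  if (is.na(hi)) {
    warn("CEAC never crosses the upper probability bound; upper CI limit unbounded")
    hi <- Inf
  }
  tibble(level = level, ro_low = lo, ro_high = hi)
}
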