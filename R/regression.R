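#' Per-household net benefit
#'
#' Monetises the binary effect at a willingness-to-pay ceiling ratio and
#' subtracts the societal cost: `NB = effect * ro - cost`. At `ro = 0` the
#' net benefit is simply minus the cost.
#'
#' @param effect 0/1 effect indicator, vectorised.
#' @param cost Societal cost, CFA, vectorised.
#' @param ro Ceiling ratio, CFA per unit effect, a single value `>= 0`.
#' @return Numeric vector, CFA.
#' @export
net_benefit <- function(effect, cost, ro) {
  if (!is.numeric(ro) || length(ro) != 1 || is.na(ro) || ro < 0) {
    abort("ro must be a single non-negative ceiling ratio (CFA)",
          class = "nbcea_config_error")
  }
  effect * ro - cost
}

#' Default ceiling-ratio grid
#'
#' 0 to 60,000 CFA in steps of 1,000 — wide enough to span the region where
#' a maternal-health ICER of a few tens of thousands of CFA transitions from
#' clearly unacceptable to clearly acceptable.
#'
#' @return Numeric vector of 61 ceiling ratios.
#' @export
default_ro_grid <- function() seq(0, 60000, by = 1000)

#' Ordinary least squares with full inference output
#'
#' Thin wrapper around [stats::lm()] for a caller-supplied design matrix
#' (including its intercept column): coefficients, classical
#' (homoskedastic) or HC1-robust standard errors, two-sided p-values from
#' the t distribution with n - k df, the overall F statistic against the
#' intercept-only model, and adjusted R-squared. A rank-deficient design is
#' an error naming the collinear columns.
#'
#' @param x Numeric design matrix with named columns, n x k, n >= k.
#' @param y Numeric outcome vector, length n.
#' @param se_type `"classical"` (default) or `"robust"` (HC1). The F
#'   statistic is always the classical one.
#' @return List of class `ols_fit`: `coefficients` tibble (`term`,
#'   `estimate`, `std.error`, `statistic`, `p.value`), `vcov`, `sigma2`,
#'   `f_stat`, `df1`, `df2`, `adj_r2`, `n`, `se_type`.
#' @export
ols_fit <- function(x, y, se_type = c("classical", "robust")) {
  se_type <- match.arg(se_type)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (nrow(x) != length(y)) abort("nrow(x) must equal length(y)")
  if (nrow(x) < ncol(x)) {
    abort("design has more columns than rows", class = "nbcea_design_error")
  }
  dec <- qr(x)
  if (dec$rank < ncol(x)) {
    bad <- colnames(x)[dec$pivot[(dec$rank + 1):ncol(x)]]
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(bad, collapse = ", ")),
          class = "nbcea_design_error")
  }

  fit <- lm(y ~ 0 + x)
  est <- coef(fit)
  names(est) <- colnames(x)
  n <- nrow(x)
  k <- ncol(x)
  res <- fit$residuals
  rss <- sum(res^2)
  sigma2 <- rss / (n - k)

  vc <- if (se_type == "robust") {
    unname(sandwich::vcovHC(fit, type = "HC1"))
  } else {
    sigma2 * solve(crossprod(x))
  }
  dimnames(vc) <- list(colnames(x), colnames(x))
  se <- sqrt(diag(vc))
  tval <- est / se
  pval <- 2 * pt(-abs(tval), df = n - k)

  # F and adjusted R^2 against the intercept-only model when the design
  # carries an intercept, against zero otherwise
  has_intercept <- any(apply(x, 2, function(col) all(col == col[1] & col[1] != 0)))
  tss <- if (has_intercept) sum((y - mean(y))^2) else sum(y^2)
  df1 <- if (has_intercept) k - 1 else k
  f_stat <- if (df1 > 0 && rss > 0) {
    ((tss - rss) / df1) / (rss / (n - k))
  } else if (df1 > 0) {
    Inf
  } else {
    NA_real_
  }
  adj_r2 <- if (tss > 0) {
    1 - (rss / (n - k)) / (tss / (n - if (has_intercept) 1 else 0))
  } else NA_real_

  structure(list(
    coefficients = tibble(term = colnames(x), estimate = unname(est),
                          std.error = unname(se), statistic = unname(tval),
                          p.value = unname(pval)),
    vcov = vc, sigma2 = sigma2, f_stat = f_stat, df1 = df1, df2 = n - k,
    adj_r2 = adj_r2, n = n, se_type = se_type
  ), class = "ols_fit")
}

# design matrix for the net-benefit regressions; covariates is a character
# subset of c("edu_some", "dist_far", "asset")
nb_design <- function(rows, covariates = NULL, interactions = FALSE) {
  if (interactions && length(covariates) == 0) {
    abort("interactions = TRUE requires at least one covariate",
          class = "nbcea_config_error")
  }
  allowed <- c("edu_some", "dist_far", "asset")
  bad <- setdiff(covariates, allowed)
  if (length(bad) > 0) {
    abort(paste0("unknown covariate(s): ", paste(bad, collapse = ", "),
                 "; choose from ", paste(allowed, collapse = ", ")),
          class = "nbcea_config_error")
  }
  cov_cols <- character(0)
  for (cv in covariates) {
    cov_cols <- c(cov_cols,
                  if (cv == "asset") paste0("asset", 2:5) else cv)
  }
  cols <- c(list(`(Intercept)` = rep(1, nrow(rows))),
            lapply(setNames(cov_cols, cov_cols), function(cc) rows[[cc]]),
            list(sci = rows$sci))
  if (interactions) {
    inter <- lapply(setNames(cov_cols, paste0("sci:", cov_cols)),
                    function(cc) rows$sci * rows[[cc]])
    cols <- c(cols, inter)
  }
  do.call(cbind, cols)
}

new_nb_regression <- function(fit, ro, model, se_type) {
  structure(list(ro = ro, model = model,
                 coefficients = fit$coefficients,
                 f_stat = fit$f_stat, df1 = fit$df1, df2 = fit$df2,
                 adj_r2 = fit$adj_r2, n = fit$n, se_type = se_type),
            class = "nb_regression")
}

#' Simple net-benefit regression
#'
#' Regresses the per-household net benefit at one ceiling ratio on the
#' treatment dummy alone: `NB_i = alpha + delta * SCI_i + e_i`, with SCI = 1
#' for intervention-district households. The constant is then the mean net
#' benefit in the comparison district and `delta` — the coefficient on SCI —
#' is the incremental net benefit; a positive `delta` at a ceiling ratio Ro
#' means the ICER lies below Ro and the intervention is deemed
#' cost-effective at that willingness to pay.
#'
#' @param rows Analysis tibble from [build_analysis_rows()]; both arms.
#' @param ro Ceiling ratio, CFA, `>= 0`.
#' @param se_type `"classical"` or `"robust"` (HC1).
#' @return Object of class `nb_regression`; see [tidy.nb_regression()] and
#'   [glance.nb_regression()].
#' @export
simple_nb_regression <- function(rows, ro, se_type = c("classical", "robust")) {
  se_type <- match.arg(se_type)
  if (length(unique(rows$district)) < 2) {
    abort("both districts required for a net-benefit regression",
          class = "nbcea_cohort_error")
  }
  nb <- net_benefit(rows$effect, rows$societal_cost, ro)
  x <- cbind(`(Intercept)` = rep(1, nrow(rows)), sci = rows$sci)
  new_nb_regression(ols_fit(x, nb, se_type), ro, "simple", se_type)
}

#' Covariate-adjusted net-benefit regression
#'
#' Adds household covariates, and optionally treatment-by-covariate
#' interaction terms, to the simple model:
#' `NB_i = alpha + sum_j beta_j x_ij + delta * SCI_i (+ sum_j gamma_j SCI_i x_ij) + e_i`.
#' The interaction coefficients measure how the incremental net benefit —
#' hence cost-effectiveness — varies at the margin across subgroups.
#'
#' @inheritParams simple_nb_regression
#' @param covariates Character subset of `c("edu_some", "dist_far",
#'   "asset")`; `"asset"` expands to quintile dummies `asset2`..`asset5`
#'   (quintile 1 reference).
#' @param interactions Add `sci x covariate` terms? Requires a non-empty
#'   `covariates`.
#' @return Object of class `nb_regression` (`model` is `"adjusted"` or
#'   `"interaction"`).
#' @export
adjusted_nb_regression <- function(rows, ro, covariates,
                                   interactions = FALSE,
                                   se_type = c("classical", "robust")) {
  se_type <- match.arg(se_type)
  if (length(covariates) == 0) {
    abort("adjusted_nb_regression needs at least one covariate; use simple_nb_regression otherwise",
          class = "nbcea_config_error")
  }
  if (length(unique(rows$district)) < 2) {
    abort("both districts required for a net-benefit regression",
          class = "nbcea_cohort_error")
  }
  nb <- net_benefit(rows$effect, rows$societal_cost, ro)
  x <- nb_design(rows, covariates, interactions)
  new_nb_regression(ols_fit(x, nb, se_type), ro,
                    if (interactions) "interaction" else "adjusted", se_type)
}

#' Net-benefit regression over a ceiling-ratio grid
#'
#' Refits the (simple or adjusted) net-benefit regression at every ceiling
#' ratio of a strictly increasing grid, producing the familiar
#' coefficients-by-ceiling-ratio table.
#'
#' @inheritParams adjusted_nb_regression
#' @param ro_grid Strictly increasing vector of ceiling ratios, CFA;
#'   defaults to [default_ro_grid()]. An empty grid yields an empty result.
#' @param covariates Optional; `NULL` fits the simple model.
#' @return Tibble of class `nb_grid`, long over (`ro`, `term`) with columns
#'   `estimate`, `std.error`, `statistic`, `p.value`, and an attached
#'   `glance` attribute (per-`ro` `f_stat`, `df1`, `df2`, `adj_r2`, `n`).
#'   Reshape with [nb_grid_table()].
#' @export
nb_regression_grid <- function(rows, ro_grid = default_ro_grid(),
                               covariates = NULL, interactions = FALSE,
                               se_type = c("classical", "robust")) {
  se_type <- match.arg(se_type)
  if (length(ro_grid) == 0) {
    out <- tibble(ro = numeric(0), term = character(0), estimate = numeric(0),
                  std.error = numeric(0), statistic = numeric(0),
                  p.value = numeric(0))
    attr(out, "glance") <- tibble(ro = numeric(0), f_stat = numeric(0),
                                  df1 = numeric(0), df2 = numeric(0),
                                  adj_r2 = numeric(0), n = integer(0))
    class(out) <- c("nb_grid", class(out))
    return(out)
  }
  if (any(!is.finite(ro_grid)) || any(ro_grid < 0) ||
      (length(ro_grid) > 1 && any(diff(ro_grid) <= 0))) {
    abort("ro_grid must be non-negative and strictly increasing",
          class = "nbcea_config_error")
  }
  fits <- lapply(ro_grid, function(ro) {
    if (is.null(covariates)) {
      simple_nb_regression(rows, ro, se_type)
    } else {
      adjusted_nb_regression(rows, ro, covariates, interactions, se_type)
    }
  })
  out <- bind_rows(lapply(fits, tidy))
  attr(out, "glance") <- bind_rows(lapply(fits, glance))
  attr(out, "model") <- fits[[1]]$model
  class(out) <- c("nb_grid", class(out))
  out
}

#' Reshape a regression grid into a coefficients-by-ceiling-ratio table
#'
#' One row per coefficient (plus the overall F and adjusted R-squared),
#' one column per ceiling ratio.
#'
#' @param grid An `nb_grid` from [nb_regression_grid()].
#' @param cell Which per-coefficient quantity fills the cells:
#'   `"estimate"` (default), `"std.error"`, `"statistic"`, or `"p.value"`.
#' @return Wide tibble; first column `quantity`, then one `ro_<value>`
#'   column per grid point.
#' @export
nb_grid_table <- function(grid, cell = c("estimate", "std.error",
                                         "statistic", "p.value")) {
  cell <- match.arg(cell)
  wide <- grid |>
    as_tibble() |>
    select("ro", "term", quantity = all_of(cell)) |>
    tidyr::pivot_wider(names_from = "ro", values_from = "quantity",
                       names_prefix = "ro_") |>
    rename(quantity = "term")
  gl <- attr(grid, "glance")
  extras <- tibble(quantity = c("F", "adj_R2"))
  for (ro in gl$ro) {
    extras[[paste0("ro_", ro)]] <- c(gl$f_stat[gl$ro == ro],
                                     gl$adj_r2[gl$ro == ro])
  }
  bind_rows(wide, extras)
}

#' Collinearity diagnostics for a net-benefit design
#'
#' Pairwise correlations and variance inflation factors over the
#' non-intercept design columns (treatment dummy, covariates, and
#' interaction terms when requested). Pairs with |r| above the threshold
#' are flagged; a constant column has an undefined VIF and is flagged.
#'
#' @inheritParams adjusted_nb_regression
#' @param threshold |r| above which a pair is flagged; default 0.7.
#' @return List of class `collinearity_diagnostics`: `correlation` matrix,
#'   `vif` tibble, `flagged_pairs` tibble.
#' @export
collinearity_diagnostics <- function(rows, covariates,
                                     interactions = FALSE, threshold = 0.7) {
  x <- nb_design(rows, covariates, interactions)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  constant <- apply(x, 2, function(col) sd(col) == 0)
  xs <- x[, !constant, drop = FALSE]
  r <- if (ncol(xs) >= 2) stats::cor(xs) else
    matrix(1, ncol(xs), ncol(xs), dimnames = list(colnames(xs), colnames(xs)))
  vif_vals <- rep(NA_real_, ncol(x))
  names(vif_vals) <- colnames(x)
  if (ncol(xs) >= 2) {
    inv <- tryCatch(solve(r), error = function(e) NULL)
    if (!is.null(inv)) vif_vals[colnames(xs)] <- diag(inv)
  } else if (ncol(xs) == 1) {
    vif_vals[colnames(xs)] <- 1
  }
  pairs <- which(abs(r) > threshold & upper.tri(r), arr.ind = TRUE)
  flagged <- tibble(
    var1 = rownames(r)[pairs[, 1]],
    var2 = colnames(r)[pairs[, 2]],
    r = r[pairs]
  )
  structure(list(
    correlation = r,
    vif = tibble(column = colnames(x), vif = unname(vif_vals),
                 constant = unname(constant)),
    flagged_pairs = flagged,
    threshold = threshold
  ), class = "collinearity_diagnostics")
}

#' @export
print.collinearity_diagnostics <- function(x, ...) {
  cat("Collinearity diagnostics (|r| threshold", x$threshold, ")\n")
  print(round(x$correlation, 3))
  print(x$vif)
  if (nrow(x$flagged_pairs) > 0) {
    cat("Flagged pairs:\n")
    print(x$flagged_pairs)
  }
  invisible(x)
}

#' Tidy a net-benefit regression
#'
#' @param x An `nb_regression` object.
#' @param ... Unused.
#' @return Tibble: `ro`, `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
tidy.nb_regression <- function(x, ...) {
  mutate(x$coefficients, ro = x$ro, .before = 1)
}

#' One-row summary of a net-benefit regression
#'
#' @param x An `nb_regression` object.
#' @param ... Unused.
#' @return Tibble: `ro`, `model`, `n`, `f_stat`, `df1`, `df2`, `adj_r2`,
#'   `se_type`.
#' @export
glance.nb_regression <- function(x, ...) {
  tibble(ro = x$ro, model = x$model, n = x$n, f_stat = x$f_stat,
         df1 = x$df1, df2 = x$df2, adj_r2 = x$adj_r2, se_type = x$se_type)
}

#' @export
print.nb_regression <- function(x, ...) {
  cat("Net-benefit regression (", x$model, "), Ro = ", format(x$ro),
      " CFA, n = ", x$n, "\n", sep = "")
  print(x$coefficients)
  cat("F(", x$df1, ", ", x$df2, ") = ", format(x$f_stat, digits = 4),
      ", adjusted R^2 = ", format(x$adj_r2, digits = 3), "\n", sep = "")
  invisible(x)
}
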