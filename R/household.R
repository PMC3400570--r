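#' Read a household survey table
#'
#' Reads a comma-delimited household table in the canonical dialect: one row
#' per surveyed household with columns `id`, `district`
#' (`"intervention"`/`"comparison"`), `institutional_delivery` (0/1),
#' `household_cost` (CFA, required when a delivery took place, ignored
#' otherwise), `distance_km`, `education_head` (`"none"`/`"some"`) and
#' `asset_quintile` (1-5). Optional columns `revenue`, `family_size` and
#' `perinatal_death` are kept when present; unknown columns are dropped.
#'
#' Validation is row-level: a delivering household with a missing cost is an
#' error in strict mode and is mean-imputed (arm-specific mean among observed
#' delivering households) with a warning otherwise. Non-numeric costs or
#' distances and out-of-range categorical codes are always errors.
#'
#' @param file Path, connection, or literal CSV text (wrap in [I()]).
#' @param strict Logical; if `TRUE` (default) a delivering household with a
#'   missing `household_cost` aborts, naming the offending rows.
#' @return A tibble of validated household records, in input order, with a
#'   `parse_report` attribute (rows read, rows imputed).
#' @seealso [write_household_table()], [validate_cohort()],
#'   [derive_covariates()]
#' @export
#' @examples
#' csv <- I("id,district,institutional_delivery,household_cost,distance_km,education_head,asset_quintile
#' h1,intervention,1,3500,2.1,some,3
#' h2,comparison,0,,7.4,none,1")
#' read_household_table(csv)
read_household_table <- function(file, strict = TRUE) {
  raw <- readr::read_csv(file, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  mandatory <- c("id", "district", "institutional_delivery", "household_cost",
                 "distance_km", "education_head", "asset_quintile")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("household table is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "nbcea_schema_error")
  }
  optional <- intersect(c("revenue", "family_size", "perinatal_death"), names(raw))
  raw <- raw[, c(mandatory, optional)]

  num_field <- function(x, name, integerish = FALSE) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & x != "" & is.na(out))
    if (length(bad) > 0) {
      abort(paste0("non-numeric `", name, "` in row(s): ",
                   paste(head(bad, 5), collapse = ", ")),
            class = "nbcea_row_error")
    }
    out[!is.na(x) & x == ""] <- NA_real_
    if (integerish) out <- as.integer(round(out))
    out
  }

  data <- tibble(
    id = raw$id,
    district = raw$district,
    institutional_delivery = num_field(raw$institutional_delivery, "institutional_delivery", TRUE),
    household_cost = num_field(raw$household_cost, "household_cost"),
    distance_km = num_field(raw$distance_km, "distance_km"),
    education_head = raw$education_head,
    asset_quintile = num_field(raw$asset_quintile, "asset_quintile", TRUE)
  )
  for (col in optional) data[[col]] <- num_field(raw[[col]], col)

  check_household_fields(data)

  # missing cost for a delivering household: error (strict) or impute
  miss <- which(data$institutional_delivery == 1 &
                  (is.na(data$household_cost)))
  n_imputed <- 0L
  if (length(miss) > 0) {
    if (strict) {
      abort(paste0("institutional_delivery = 1 with missing household_cost in row(s): ",
                   paste(head(miss, 10), collapse = ", "),
                   " (strict mode)"),
            class = "nbcea_row_error")
    }
    for (arm in unique(data$district[miss])) {
      sel <- miss[data$district[miss] == arm]
      donor <- data$household_cost[data$district == arm &
                                     data$institutional_delivery == 1 &
                                     !is.na(data$household_cost)]
      if (length(donor) == 0) {
        abort(paste0("cannot impute household_cost in arm '", arm,
                     "': no delivering household with an observed cost"),
              class = "nbcea_row_error")
      }
      data$household_cost[sel] <- mean(donor)
    }
    n_imputed <- length(miss)
    warn(paste0("imputed household_cost for ", n_imputed,
                " delivering household(s) with the arm-specific mean"))
  }

  attr(data, "parse_report") <- tibble(
    rows_read = nrow(data), rows_imputed = n_imputed
  )
  data
}

# field-level invariants shared by the reader and validate_cohort()
check_household_fields <- function(data) {
  bad_district <- which(!data$district %in% c("intervention", "comparison"))
  if (length(bad_district) > 0) {
    abort(paste0("district must be 'intervention' or 'comparison'; bad row(s): ",
                 paste(head(bad_district, 5), collapse = ", ")),
          class = "nbcea_row_error")
  }
  bad_del <- which(!data$institutional_delivery %in% c(0L, 1L))
  if (length(bad_del) > 0) {
    abort(paste0("institutional_delivery must be 0 or 1; bad row(s): ",
                 paste(head(bad_del, 5), collapse = ", ")),
          class = "nbcea_row_error")
  }
  bad_asset <- which(is.na(data$asset_quintile) | !data$asset_quintile %in% 1:5)
  if (length(bad_asset) > 0) {
    abort(paste0("asset_quintile must be an integer in 1..5; bad row(s): ",
                 paste(head(bad_asset, 5), collapse = ", ")),
          class = "nbcea_row_error")
  }
  bad_dist <- which(is.na(data$distance_km) | data$distance_km < 0)
  if (length(bad_dist) > 0) {
    abort(paste0("distance_km must be a non-negative number; bad row(s): ",
                 paste(head(bad_dist, 5), collapse = ", ")),
          class = "nbcea_row_error")
  }
  bad_edu <- which(!data$education_head %in% c("none", "some"))
  if (length(bad_edu) > 0) {
    abort(paste0("education_head must be 'none' or 'some'; bad row(s): ",
                 paste(head(bad_edu, 5), collapse = ", ")),
          class = "nbcea_row_error")
  }
  bad_cost <- which(!is.na(data$household_cost) & data$household_cost < 0)
  if (length(bad_cost) > 0) {
    abort(paste0("household_cost must be >= 0; bad row(s): ",
                 paste(head(bad_cost, 5), collapse = ", ")),
          class = "nbcea_row_error")
  }
  invisible(data)
}

#' Write a household table in the canonical CSV dialect
#'
#' @param data Household tibble as produced by [read_household_table()] or
#'   [generate_cohort()].
#' @param file Path to write to.
#' @return `data`, invisibly.
#' @export
write_household_table <- function(data, file) {
  readr::write_csv(data, file, na = "", progress = FALSE)
  invisible(data)
}

#' Derive analysis covariates from household records
#'
#' Adds the binary covariates used throughout the analysis: `sci` (1 for the
#' intervention district), `edu_some` (1 if the household head has at least
#' some education), `dist_far` (1 if the household lies strictly more than
#' `distance_threshold_km` from the nearest facility; a household at exactly
#' the threshold is "near"), and asset-quintile dummies `asset2`..`asset5`
#' with quintile 1 as reference.
#'
#' @param data Validated household tibble.
#' @param distance_threshold_km Distance cut in km; default 5.
#' @return `data` with covariate columns appended (recomputed if present, so
#'   the operation is idempotent).
#' @export
derive_covariates <- function(data, distance_threshold_km = 5) {
  stopifnot(is.numeric(distance_threshold_km), distance_threshold_km >= 0)
  data |>
    mutate(
      sci = as.integer(.data$district == "intervention"),
      edu_some = as.integer(.data$education_head == "some"),
      dist_far = as.integer(.data$distance_km > distance_threshold_km),
      asset2 = as.integer(.data$asset_quintile == 2L),
      asset3 = as.integer(.data$asset_quintile == 3L),
      asset4 = as.integer(.data$asset_quintile == 4L),
      asset5 = as.integer(.data$asset_quintile == 5L)
    )
}

#' Validate a two-arm cohort
#'
#' Arm-level checks on a household table: both districts must be represented
#' (increments are undefined otherwise). Returns per-arm counts, delivery
#' proportions and a missingness table.
#'
#' @param data Household tibble.
#' @return An object of class `cohort_validation`: a list with `arms` (one
#'   row per district: n, deliveries, delivery proportion) and `missingness`
#'   (per column count of missing values).
#' @export
validate_cohort <- function(data) {
  check_household_fields(data)
  arms_present <- sort(unique(data$district))
  if (!setequal(arms_present, c("comparison", "intervention"))) {
    abort(paste0("cohort must contain both districts; found only: ",
                 paste(arms_present, collapse = ", ")),
          class = "nbcea_cohort_error")
  }
  arms <- data |>
    group_by(.data$district) |>
    summarise(
      n = dplyr::n(),
      deliveries = sum(.data$institutional_delivery),
      delivery_prop = mean(.data$institutional_delivery),
      .groups = "drop"
    )
  missingness <- tibble(
    column = names(data),
    n_missing = vapply(data, function(x) sum(is.na(x)), integer(1))
  )
  structure(list(arms = arms, missingness = missingness),
            class = "cohort_validation")
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat("Two-arm cohort validation\n")
  print(x$arms)
  miss <- x$missingness[x$missingness$n_missing > 0, ]
  if (nrow(miss) > 0) {
    cat("Columns with missing values:\n")
    print(miss)
  } else {
    cat("No missing values.\n")
  }
  invisible(x)
}
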