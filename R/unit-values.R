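#' Quality-adjusted unit values
#'
#' For each household x category with recorded purchases, the unit value is
#' the expenditure-share-weighted mean of per-record unit prices
#' (expenditure/quantity per record); with a single record this reduces to
#' total expenditure over total quantity. Cells without purchases are left
#' missing, flagged for geographic imputation.
#'
#' @param purchases A `purchase_table`.
#' @return A `price_table` data frame with one row per household x category
#'   cell: `household_id`, `category`, `unit_value` (NA when unobserved),
#'   `imputed`, `imputation_level` (one of observed/state/region/national),
#'   `state`, `region`.
#' @export
compute_unit_values <- function(purchases) {
  config <- attr(purchases, "config")
  df <- as.data.frame(purchases)
  bad <- which(df$expenditure > 0 & df$quantity <= 0)
  if (length(bad))
    stop("zero quantity with positive expenditure in row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  dt <- data.table::as.data.table(df)
  data.table::setnames(dt, c(config$state_column, config$region_column),
                       c(".state", ".region"), skip_absent = TRUE)
  hh <- unique(dt[, list(household_id, .state, .region)])
  dt <- dt[expenditure > 0]
  # expenditure-weighted mean of per-record unit prices:
  #   sum(e_r * (e_r/q_r)) / sum(e_r)
  uv <- dt[, list(
    unit_value = sum(expenditure * (expenditure / quantity)) /
      sum(expenditure)),
    by = c("household_id", "category")]
  grid <- data.table::CJ(household_id = hh$household_id,
                         category = config$categories, unique = TRUE)
  grid <- merge(grid, hh, by = "household_id")
  out <- merge(grid, uv, by = c("household_id", "category"), all.x = TRUE)
  out[, `:=`(imputed = is.na(unit_value),
             imputation_level = data.table::fifelse(is.na(unit_value),
                                                    NA_character_,
                                                    "observed"))]
  data.table::setnames(out, c(".state", ".region"), c("state", "region"))
  out <- as.data.frame(out)
  structure(out, config = config, class = c("price_table", "data.frame"))
}

#' Impute missing unit values from geographic averages
#'
#' Missing cells are filled with the mean observed unit value of the same
#' category in the household's state; where a state has no observation the
#' region mean is used, then the national mean, and the level used is
#' recorded. Observed unit values are never modified.
#'
#' @param prices A `price_table` from [compute_unit_values()].
#' @return The completed `price_table`: every cell positive, `imputed` and
#'   `imputation_level` filled.
#' @export
impute_prices <- function(prices) {
  config <- attr(prices, "config")
  dt <- data.table::as.data.table(as.data.frame(prices))
  obs <- dt[!is.na(unit_value)]
  none <- setdiff(config$categories, unique(obs$category))
  if (length(none))
    stop("no observed unit value anywhere for category(ies): ",
         paste(none, collapse = ", "), "; estimation impossible",
         call. = FALSE)
  st <- obs[, list(state_mean = mean(unit_value)), by = c("category", "state")]
  rg <- obs[, list(region_mean = mean(unit_value)), by = c("category", "region")]
  nat <- obs[, list(national_mean = mean(unit_value)), by = "category"]
  dt <- merge(dt, st, by = c("category", "state"), all.x = TRUE)
  dt <- merge(dt, rg, by = c("category", "region"), all.x = TRUE)
  dt <- merge(dt, nat, by = "category", all.x = TRUE)
  miss <- is.na(dt$unit_value)
  lvl <- data.table::fifelse(!miss, dt$imputation_level,
           data.table::fifelse(!is.na(dt$state_mean), "state",
             data.table::fifelse(!is.na(dt$region_mean), "region",
                                 "national")))
  fill <- data.table::fcoalesce(dt$unit_value, dt$state_mean,
                                dt$region_mean, dt$national_mean)
  dt[, `:=`(unit_value = fill, imputation_level = lvl)]
  dt[, c("state_mean", "region_mean", "national_mean") := NULL]
  stopifnot(all(dt$unit_value > 0))
  data.table::setorder(dt, household_id, category)
  out <- as.data.frame(dt)
  structure(out, config = config, class = c("price_table", "data.frame"))
}

#' Replace all unit values with state-average prices
#'
#' Alternative price construction in which every household in a state faces
#' the state's average observed unit value for each category (households'
#' own unit values are not kept). Falls back to region and national means
#' for states without observations.
#'
#' @param prices A `price_table` from [compute_unit_values()].
#' @return A completed `price_table` with state-level prices.
#' @export
state_average_prices <- function(prices) {
  config <- attr(prices, "config")
  dt <- data.table::as.data.table(as.data.frame(prices))
  obs <- dt[!is.na(unit_value)]
  st <- obs[, list(fill = mean(unit_value)), by = c("category", "state")]
  rg <- obs[, list(rfill = mean(unit_value)), by = c("category", "region")]
  nat <- obs[, list(nfill = mean(unit_value)), by = "category"]
  dt <- merge(dt, st, by = c("category", "state"), all.x = TRUE)
  dt <- merge(dt, rg, by = c("category", "region"), all.x = TRUE)
  dt <- merge(dt, nat, by = "category", all.x = TRUE)
  dt[, `:=`(unit_value = data.table::fcoalesce(fill, rfill, nfill),
            imputed = TRUE, imputation_level = "state")]
  dt[, c("fill", "rfill", "nfill") := NULL]
  data.table::setorder(dt, household_id, category)
  out <- as.data.frame(dt)
  structure(out, config = config, class = c("price_table", "data.frame"))
}
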