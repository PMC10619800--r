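#' Assemble demand-system design data
#'
#' Builds the household-level matrices the estimator consumes: expenditure
#' shares `w` (zero for non-purchases), log prices `lnp` from the completed
#' price table, log total food expenditure `lnm`, the Tornqvist price index
#' `ln_a`, the approximate deviation-weighted aggregator `b`, sample mean
#' shares and base (geometric-mean) log prices, plus the covariate matrix,
#' income and geography carried through for the first stage.
#'
#' Households with non-positive total food expenditure are dropped and
#' counted.
#'
#' @param purchases A `purchase_table`.
#' @param prices A completed `price_table` (see [impute_prices()]).
#' @param config A [category_config()]; defaults to the one attached to
#'   `purchases`.
#' @return An object of class `demand_system_data`: list with elements
#'   `w`, `lnp` (H x n matrices), `lnm`, `ln_a`, `b` (H-vectors),
#'   `mean_shares`, `base_log_prices` (n-vectors), `covariates`
#'   (H x k matrix), `income`, `state`, `region`, `household_id`,
#'   `categories`, `reference`, `n_dropped`.
#' @export
assemble_system <- function(purchases, prices,
                            config = attr(purchases, "config")) {
  stopifnot(inherits(config, "category_config"))
  cats <- config$categories
  n <- length(cats)

  pdf_ <- as.data.frame(prices)
  hh <- sort(unique(pdf_$household_id))
  H <- length(hh)
  hidx <- match(pdf_$household_id, hh)
  cidx <- match(pdf_$category, cats)
  lnp <- matrix(NA_real_, H, n, dimnames = list(NULL, cats))
  lnp[cbind(hidx, cidx)] <- log(pdf_$unit_value)
  if (anyNA(lnp))
    stop("price table incomplete: run impute_prices() first", call. = FALSE)

  df <- as.data.frame(purchases)
  df <- df[df$household_id %in% hh, , drop = FALSE]
  emat <- matrix(0, H, n, dimnames = list(NULL, cats))
  agg <- data.table::as.data.table(df)[
    , list(expenditure = sum(expenditure)),
    by = c("household_id", "category")]
  emat[cbind(match(agg$household_id, hh),
             match(agg$category, cats))] <- agg$expenditure
  m <- rowSums(emat)
  keep <- m > 0
  n_dropped <- sum(!keep)
  if (!any(keep)) stop("no household with positive total expenditure",
                       call. = FALSE)
  if (n_dropped)
    message(n_dropped, " household(s) dropped for zero total expenditure")
  emat <- emat[keep, , drop = FALSE]
  lnp <- lnp[keep, , drop = FALSE]
  m <- m[keep]
  hh <- hh[keep]
  H <- length(hh)
  w <- emat / m

  # household-level covariates, income and geography (first row per household)
  first <- df[!duplicated(df$household_id), , drop = FALSE]
  first <- first[match(hh, first$household_id), , drop = FALSE]
  covariates <- as.matrix(first[, config$covariate_columns, drop = FALSE])
  storage.mode(covariates) <- "double"

  mean_shares <- colMeans(w)
  base_log_prices <- colMeans(lnp)
  data <- structure(
    list(w = w, lnp = lnp, lnm = log(m),
         ln_a = rep(0, H), b = rep(1, H),
         mean_shares = mean_shares, base_log_prices = base_log_prices,
         covariates = covariates,
         income = first[[config$income_column]],
         state = first[[config$state_column]],
         region = first[[config$region_column]],
         household_id = hh,
         categories = cats,
         reference = config$reference_category,
         n_dropped = n_dropped,
         b_mode = "approx"),
    class = "demand_system_data")
  data$ln_a <- tornqvist_index(data)
  data$b <- matsuda_b_index(data)
  data
}

#' @export
print.demand_system_data <- function(x, ...) {
  cat("Demand-system data: ", nrow(x$w), " households x ",
      ncol(x$w), " categories\n", sep = "")
  cat("  mean shares: ",
      paste(sprintf("%s=%.3f", x$categories, x$mean_shares),
            collapse = ", "), "\n", sep = "")
  cat("  dropped households: ", x$n_dropped, "\n", sep = "")
  invisible(x)
}

#' Tornqvist price index
#'
#' Per-household log index
#' `ln a(p_h) = sum_i (w_ih + wbar_i)/2 * (ln p_ih - ln pbar_i)` with base
#' prices `pbar` the cross-household geometric mean of post-imputation unit
#' values, so the index is exactly zero when a household faces base prices.
#'
#' @param data A `demand_system_data`.
#' @param w Optional share matrix overriding `data$w` (e.g. fitted shares).
#' @return H-vector `ln a`.
#' @export
tornqvist_index <- function(data, w = data$w) {
  dev <- sweep(data$lnp, 2L, data$base_log_prices)
  avg <- 0.5 * sweep(w, 2L, data$mean_shares, `+`)
  out <- rowSums(avg * dev)
  stopifnot(all(is.finite(out)))
  out
}

#' Demand-system expenditure aggregator b(p)
#'
#' Two modes. `approx` (parameter-free): deviation-weighted log index
#' `ln b(p_h) = sum_i (w_ih - wbar_i)/2 * (ln p_ih - ln pbar_i)`, the
#' linear-approximation companion of the Tornqvist index. `exact`: the
#' Cobb-Douglas QUAIDS aggregator `ln b(p_h) = sum_i beta_i ln p_ih`,
#' recomputed from the current beta inside estimation iterations.
#'
#' @param data A `demand_system_data`.
#' @param beta n-vector of expenditure coefficients; required for
#'   `mode = "exact"`.
#' @param mode `"approx"` or `"exact"`.
#' @return H-vector `b(p) > 0`.
#' @export
matsuda_b_index <- function(data, beta = NULL,
                            mode = c("approx", "exact")) {
  mode <- match.arg(mode)
  if (mode == "exact") {
    if (is.null(beta))
      stop("exact mode requires beta", call. = FALSE)
    lb <- drop(data$lnp %*% beta)
  } else {
    dev <- sweep(data$lnp, 2L, data$base_log_prices)
    half <- 0.5 * sweep(data$w, 2L, data$mean_shares)
    lb <- rowSums(half * dev)
  }
  out <- exp(lb)
  stopifnot(all(is.finite(out)))
  out
}
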