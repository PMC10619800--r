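# Small in-code fixtures shared across the test files.

toy_config <- function(categories = c("ssb", "milk", "other_foods"),
                       covariates = c("urban", "log_income")) {
  category_config(categories,
                  reference_category = categories[length(categories)],
                  covariate_columns = covariates)
}

# One long-format purchase row.
prow <- function(hh, cat, exp, qty, state = "S01", region = "R1",
                 income = 2000, urban = 1, log_income = log(2000)) {
  data.frame(household_id = hh, category = cat, expenditure = exp,
             quantity = qty, state = state, region = region,
             income = income, urban = urban, log_income = log_income,
             stringsAsFactors = FALSE)
}

toy_purchases <- function(config = toy_config()) {
  df <- rbind(
    prow("h1", "ssb", 6, 3), prow("h1", "milk", 4, 2),
    prow("h1", "other_foods", 10, 5),
    prow("h2", "milk", 2, 1, state = "S02"),
    prow("h2", "other_foods", 8, 4, state = "S02"),
    prow("h3", "ssb", 3, 1, state = "S02", region = "R1"),
    prow("h3", "other_foods", 7, 7, state = "S02"))
  as_purchase_table(df, config)
}

# Random structured parameter set for oracle checks (no restrictions).
random_pm <- function(n, sd_gamma = 0.03) {
  g <- matrix(stats::rnorm(n * n, 0, sd_gamma), n, n)
  list(alpha = stats::runif(n, 0.05, 0.3),
       gamma = g,
       beta = stats::rnorm(n, 0, 0.02),
       lambda = stats::rnorm(n, 0, 0.003),
       theta = stats::rnorm(n, 0, 0.01),
       rho = stats::rnorm(n, 0, 0.01))
}

# Random evaluation point with strictly positive shares.
random_point <- function(n, censored = TRUE) {
  w <- stats::runif(n, 0.05, 1); w <- w / sum(w)
  mw <- stats::runif(n, 0.05, 1); mw <- mw / sum(mw)
  pt <- list(shares = stats::setNames(w, paste0("g", seq_len(n))),
             lnp = stats::rnorm(n, 0, 0.2),
             lnm = stats::runif(1, 2, 5),
             mean_shares = mw,
             base_log_prices = stats::rnorm(n, 0, 0.1),
             cdf = if (censored) stats::runif(n, 0.2, 1) else rep(1, n),
             subgroup_label = "draw", n_households = 1L)
  pt$ln_a <- sum(0.5 * (pt$shares + pt$mean_shares) *
                   (pt$lnp - pt$base_log_prices))
  class(pt) <- "evaluation_point"
  pt
}

# Independent numeric oracle: the cdf-scaled latent share system at a
# point, as a function of log prices and log expenditure, written from the
# model definition (not from the package internals).
oracle_system <- function(pm, pt, b_mode) {
  function(lnp, lnm) {
    la <- sum(0.5 * (pt$shares + pt$mean_shares) *
                (lnp - pt$base_log_prices))
    lb <- if (b_mode == "exact") sum(pm$beta * lnp) else
      sum(0.5 * (pt$shares - pt$mean_shares) * (lnp - pt$base_log_prices))
    x <- lnm - la
    b <- exp(lb)
    pt$cdf * (pm$alpha + drop(pm$gamma %*% lnp) +
                pm$beta * x + pm$lambda / b * x^2)
  }
}

# Central-difference elasticities from the oracle system.
oracle_elasticities <- function(pm, pt, b_mode, h = 1e-4) {
  n <- length(pt$shares)
  F <- oracle_system(pm, pt, b_mode)
  price <- matrix(NA_real_, n, n)
  for (j in seq_len(n)) {
    up <- pt$lnp; up[j] <- up[j] + h
    dn <- pt$lnp; dn[j] <- dn[j] - h
    price[, j] <- (F(up, pt$lnm) - F(dn, pt$lnm)) / (2 * h) /
      pt$shares - (seq_len(n) == j)
  }
  expenditure <- (F(pt$lnp, pt$lnm + h) - F(pt$lnp, pt$lnm - h)) /
    (2 * h) / pt$shares + 1
  list(price = price, expenditure = expenditure)
}

# Simulated dataset pushed through preprocessing only.
assembled_from_truth <- function(truth, H, seed = truth$seed,
                                 censor = TRUE) {
  p <- simulate_purchases(truth, H, seed = seed, censor = censor)
  prices <- impute_prices(compute_unit_values(p))
  assemble_system(p, prices)
}
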