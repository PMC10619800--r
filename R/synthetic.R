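## Synthetic household budget microdata with known ground truth.
##
## The generator emulates the statistical structure the estimator assumes:
## a latent QUAIDS share system with state-level price variation, total
## food expenditure driven by covariates plus an endogenous shock that also
## loads on the share errors, and per-category purchase-incidence censoring
## from probit latents whose shocks are correlated with the share errors.
## For every non-reference category the implied conditional mean of the
## observed share is exactly the estimated (cdf-scaled, pdf- and
## residual-augmented) share equation, so recovery experiments test the
## implementation under the estimator's own assumptions. The reference
## category absorbs the budget not spent on censored goods, keeping total
## observed food expenditure equal to the drawn total for every household
## that purchases the reference good.

#' Default synthetic ground truth
#'
#' Builds a deterministic-in-seed parameter set for `n_goods` categories:
#' a dominant residual category (the "other foods" role, latent share 0.65
#' and ~99% purchase prevalence), the remaining latent budget split across
#' the other goods, purchase prevalences spanning roughly 15%-99%,
#' symmetric/homogeneous/adding-up-consistent generating parameters, and
#' 27 synthetic states in 5 regions with state-level log-price variation.
#'
#' @param n_goods Number of categories (>= 2); the last is the reference.
#' @param seed Integer seed; fixes the state price draws and all
#'   subsequent simulation defaults.
#' @param n_households Default sample size for [simulate_purchases()].
#' @param noise_scale Share-equation innovation SD; default scales with
#'   the smallest latent share so censored categories stay away from the
#'   zero boundary for any `n_goods`.
#' @param price_state_sd SD of per-state log-price means.
#' @param price_household_sd SD of household log-price noise around the
#'   state mean (default 0: prices vary at state level only, as when
#'   prices are state-average unit values).
#' @return An object of class `synthetic_truth`.
#' @export
make_default_truth <- function(n_goods = 4, seed = 1,
                               n_households = 10000L,
                               noise_scale = NULL,
                               price_state_sd = 0.12,
                               price_household_sd = 0) {
  stopifnot(n_goods >= 2)
  n <- n_goods
  cats <- c(if (n > 1) sprintf("good_%d", seq_len(n - 1)), "other_foods")
  if (n == 4) cats <- c("ready_ssb", "prepared_ssb", "milk", "other_foods")

  s <- numeric(n)
  s[n] <- 0.65
  if (n > 1) {
    wts <- seq_len(n - 1) + 1
    s[seq_len(n - 1)] <- 0.35 * wts / sum(wts)
  }
  if (is.null(noise_scale)) noise_scale <- min(0.012, 0.15 * min(s))
  prevalence <- c(if (n > 2) seq(0.15, 0.75, length.out = n - 1)
                  else if (n == 2) 0.45, 0.995)

  kappa <- 0.5
  gamma <- kappa * outer(s, s)
  diag(gamma) <- -kappa * s * (1 - s)
  beta <- 0.1 * (as.numeric(seq_len(n) == n) - s)
  dev <- s - 1 / n
  lambda <- 0.004 * dev / max(abs(dev))
  # anchor the latent shares at `s` at the population mean of
  # x = ln(m/a): alpha_i = s_i - beta_i xbar - lambda_i xbar^2 keeps
  # adding-up (sum beta = sum lambda = 0) and shares positive across the
  # realistic x range
  expenditure_model <- c(intercept = 1.0, urban = 0.3,
                         log_income = 0.35, hh_size = 0.05)
  covariate_means <- c(urban = 0.8, log_income = 7.6, hh_size = 3)
  x_center <- expenditure_model["intercept"] +
    sum(expenditure_model[names(covariate_means)] * covariate_means)
  alpha <- s - beta * x_center - lambda * x_center^2
  # loadings proportional to the latent share keep small categories away
  # from the zero boundary whatever n is
  theta <- 0.1 * s * (-1)^seq_len(n)
  theta[n] <- -sum(theta[-n])
  rho <- 0.075 * s * (-1)^(seq_len(n) + 1)
  rho[n] <- 0

  covariate_names <- c("urban", "log_income", "hh_size")
  probit_slopes <- cbind(
    urban = rep(0.10, n),
    log_income = rep(c(0.20, 0.30), length.out = n),
    hh_size = rep(0.05, n))
  # the staple (reference) category is bought by essentially everyone;
  # its rare non-purchase is a diary-week accident, not income-driven
  probit_slopes[n, ] <- 0
  # intercepts chosen so the covariate-averaged cdf is near the target
  idx_var <- drop(probit_slopes^2 %*% c(0.8 * 0.2, 0.6^2, 2))
  probit_intercepts <- stats::qnorm(prevalence) * sqrt(1 + idx_var)

  set.seed(seed %% .Machine$integer.max)
  state_means <- matrix(stats::rnorm(n * 27, 0, price_state_sd), n, 27,
                        dimnames = list(cats, sprintf("S%02d", 1:27)))

  structure(
    list(categories = cats, reference = cats[n], n_goods = n,
         latent_shares_at_center = stats::setNames(s, cats),
         x_center = unname(x_center),
         alpha = stats::setNames(alpha, cats),
         gamma = `dimnames<-`(gamma, list(cats, cats)),
         beta = stats::setNames(beta, cats),
         lambda = stats::setNames(lambda, cats),
         theta = stats::setNames(theta, cats),
         rho = stats::setNames(rho, cats),
         prevalence_targets = stats::setNames(prevalence, cats),
         probit_intercepts = probit_intercepts,
         probit_slopes = probit_slopes,
         covariate_names = covariate_names,
         covariate_means = covariate_means,
         expenditure_model = expenditure_model,
         expenditure_shock_sd = 0.45,
         price_state_means = state_means,
         price_state_sd = price_state_sd,
         price_household_sd = price_household_sd,
         noise_scale = noise_scale,
         n_households = as.integer(n_households),
         seed = as.integer(seed)),
    class = "synthetic_truth")
}

#' Category configuration matching a synthetic truth
#'
#' @param truth A `synthetic_truth`.
#' @return A [category_config()].
#' @export
truth_config <- function(truth) {
  category_config(truth$categories,
                  reference_category = truth$reference,
                  covariate_columns = truth$covariate_names)
}

#' Simulate household purchase microdata from a synthetic truth
#'
#' Draws states, covariates, an endogenous expenditure shock, state-level
#' prices, latent QUAIDS shares and probit purchase censoring, and emits a
#' long-format purchase table. The household price index entering the
#' latent shares is the same Tornqvist index the estimation pipeline will
#' compute from the emitted data (resolved by fixed-point iteration), and
#' quantities are expenditure/price so unit values reproduce the generated
#' prices exactly.
#'
#' @param truth A `synthetic_truth`.
#' @param n_households Sample size (default `truth$n_households`).
#' @param seed Seed (default `truth$seed`); same seed, same table.
#' @param censor Set FALSE to disable purchase censoring (all goods
#'   purchased by all households).
#' @return A `purchase_table` with attributes `truth` and
#'   `sim` (household-level simulation internals for oracle checks:
#'   expenditure shock, censoring indicators, implied prevalence targets).
#' @export
simulate_purchases <- function(truth, n_households = truth$n_households,
                               seed = truth$seed, censor = TRUE) {
  stopifnot(inherits(truth, "synthetic_truth"))
  H <- as.integer(n_households)
  n <- truth$n_goods
  ref <- n
  set.seed(seed %% .Machine$integer.max)

  state_id <- sample.int(27, H, replace = TRUE)
  region_of_state <- rep(sprintf("R%d", 1:5), times = c(6, 6, 5, 5, 5))
  urban <- stats::rbinom(H, 1, 0.8)
  log_income <- stats::rnorm(H, 7.6, 0.6)
  hh_size <- 1 + stats::rpois(H, 2)
  Z <- cbind(urban = urban, log_income = log_income, hh_size = hh_size)
  Zc <- sweep(Z, 2L, truth$covariate_means)

  v <- stats::rnorm(H, 0, truth$expenditure_shock_sd)
  em <- truth$expenditure_model
  lnm <- em["intercept"] + drop(Z %*% em[colnames(Z)]) + v
  # the share-equation loading uses the component of the expenditure shock
  # orthogonal to the covariates: exactly what a residual-inclusion first
  # stage on this sample recovers
  vload <- stats::lm.fit(cbind(1, Z), v)$residuals

  lnp <- t(truth$price_state_means[, state_id, drop = FALSE])
  if (truth$price_household_sd > 0)
    lnp <- lnp + matrix(stats::rnorm(H * n, 0, truth$price_household_sd),
                        H, n)
  colnames(lnp) <- truth$categories

  probit_index <- matrix(truth$probit_intercepts, H, n, byrow = TRUE) +
    Zc %*% t(truth$probit_slopes)
  u_c <- matrix(stats::rnorm(H * n), H, n)
  d <- if (censor) (probit_index + u_c) > 0 else
    matrix(TRUE, H, n)
  Phi_true <- stats::pnorm(probit_index)

  eps <- matrix(stats::rnorm(H * (n - 1), 0, truth$noise_scale), H, n - 1)

  # fixed point: latent shares <-> the pipeline's Tornqvist index computed
  # from the observed (censored) shares
  m <- exp(lnm)
  ln_a <- rep(0, H)
  lnm_used <- lnm
  b <- exp(drop(lnp %*% truth$beta))
  emat <- NULL
  for (iter in 1:12) {
    x <- lnm_used - ln_a
    wlat <- matrix(truth$alpha, H, n, byrow = TRUE) +
      lnp %*% t(truth$gamma) +
      outer(x, truth$beta) + outer(x^2, truth$lambda) / b
    ystar <- wlat
    if (n > 1) {
      for (i in seq_len(n - 1)) {
        load <- if (censor) truth$theta[i] * vload / Phi_true[, i] +
          truth$rho[i] * u_c[, i] else truth$theta[i] * vload
        ystar[, i] <- wlat[, i] + load + eps[, i]
      }
      ystar[, ref] <- 1 - rowSums(ystar[, -ref, drop = FALSE])
    }
    emat_new <- matrix(0, H, n)
    for (i in seq_len(n - 1))
      emat_new[, i] <- d[, i] * pmax(ystar[, i], 0) * m
    # households buying the staple: it absorbs the unspent budget; rare
    # staple non-purchasers spread the full budget over purchased goods
    emat_new[, ref] <- d[, ref] *
      pmax(m - rowSums(emat_new[, -ref, drop = FALSE]), 0)
    noref <- !d[, ref]
    if (any(noref)) {
      tot <- rowSums(emat_new[noref, -ref, drop = FALSE])
      scale <- ifelse(tot > 0, m[noref] / tot, 0)
      emat_new[noref, -ref] <- emat_new[noref, -ref, drop = FALSE] * scale
    }
    m_obs <- rowSums(emat_new)
    live <- m_obs > 0
    w_obs <- emat_new / ifelse(m_obs > 0, m_obs, 1)
    wbar <- colMeans(w_obs[live, , drop = FALSE])
    lnpbar <- colMeans(lnp[live, , drop = FALSE])
    dev <- sweep(lnp, 2L, lnpbar)
    ln_a_new <- rowSums(0.5 * sweep(w_obs, 2L, wbar, `+`) * dev)
    lnm_new <- ifelse(live, log(m_obs), lnm)
    delta <- max(abs(ln_a_new - ln_a), abs(lnm_new - lnm_used))
    ln_a <- ln_a_new
    lnm_used <- lnm_new
    emat <- emat_new
    if (delta < 1e-12) break
  }

  price <- exp(lnp)
  rows <- which(emat > 0, arr.ind = TRUE)
  ord <- order(rows[, 1L], rows[, 2L])
  rows <- rows[ord, , drop = FALSE]
  hidx <- rows[, 1L]; cidx <- rows[, 2L]
  df <- data.frame(
    household_id = sprintf("H%06d", hidx),
    category = truth$categories[cidx],
    expenditure = emat[rows],
    quantity = emat[rows] / price[rows],
    state = sprintf("S%02d", state_id[hidx]),
    region = region_of_state[state_id[hidx]],
    income = exp(log_income[hidx]),
    urban = urban[hidx],
    log_income = log_income[hidx],
    hh_size = hh_size[hidx],
    stringsAsFactors = FALSE)

  out <- as_purchase_table(df, truth_config(truth))
  attr(out, "truth") <- truth
  attr(out, "sim") <- list(
    expenditure_shock = v,
    censored = !d,
    implied_prevalence = colMeans(Phi_true),
    latent_ln_a = ln_a,
    household_index = seq_len(H))
  out
}

#' Full estimation pipeline on a purchase table
#'
#' Runs unit values, geographic price imputation, system assembly, the
#' first-stage probits, the expenditure-endogeneity residual, NLSUR
#' estimation, and the elasticity matrix; optionally income-quintile
#' elasticities.
#'
#' @param purchases A `purchase_table`.
#' @param config A [category_config()]; defaults to the attached one.
#' @param state_prices Replace all unit values with state averages instead
#'   of imputing only missing cells (default FALSE).
#' @param censored Apply the two-step zero-purchase correction (default
#'   TRUE).
#' @param endogeneity Apply the expenditure-residual correction (default
#'   TRUE).
#' @param quintiles Compute first/fifth income-quintile elasticities.
#' @param ... Passed to [nlsur_fit()] (restriction flags, `b_mode`,
#'   `drop_reference`, tolerances).
#' @return List with `data`, `probits`, `resid`, `params`, `diagnostics`,
#'   `elasticities`, and optionally `quintile_elasticities`.
#' @export
quaids_pipeline <- function(purchases,
                            config = attr(purchases, "config"),
                            state_prices = FALSE,
                            censored = TRUE, endogeneity = TRUE,
                            quintiles = FALSE, ...) {
  uv <- compute_unit_values(purchases)
  prices <- if (state_prices) state_average_prices(uv) else
    impute_prices(uv)
  data <- assemble_system(purchases, prices, config)
  probits <- if (censored) fit_all_probits(data) else NULL
  resid <- if (endogeneity)
    blundell_robin_residual(data$lnm, data$covariates) else NULL
  fit <- nlsur_fit(data, probits, resid, ...)
  el <- elasticity_matrix(fit$params, data, probits)
  out <- list(data = data, probits = probits, resid = resid,
              params = fit$params, diagnostics = fit$diagnostics,
              elasticities = el)
  if (quintiles)
    out$quintile_elasticities <-
      quintile_elasticities(fit$params, data, probits)
  out
}

# Truth coefficient vector arranged in the layout of a fitted model.
truth_coef_vector <- function(truth, layout) {
  out <- numeric(layout$P)
  for (e in seq_along(layout$eqs)) {
    i <- layout$eqs[e]
    out[param_pos(layout, e, "alpha")] <- truth$alpha[i]
    for (j in seq_len(layout$n))
      out[param_pos(layout, e, "gamma", j)] <- truth$gamma[i, j]
    out[param_pos(layout, e, "beta")] <- truth$beta[i]
    out[param_pos(layout, e, "lambda")] <- truth$lambda[i]
    if (layout$has_theta)
      out[param_pos(layout, e, "theta")] <- truth$theta[i]
    if (layout$has_rho)
      out[param_pos(layout, e, "rho")] <- truth$rho[i]
  }
  stats::setNames(out, layout$names)
}

#' Parameter- and elasticity-recovery experiment
#'
#' Simulates `n_replicates` datasets from a known truth, runs the full
#' pipeline on each (probit first stage, expenditure residual, NLSUR with
#' homogeneity and symmetry, reference equation dropped so every estimated
#' equation is exactly the generating conditional mean), and compares
#' estimates with the generating values.
#'
#' @param truth A `synthetic_truth`.
#' @param n_households Households per replicate.
#' @param n_replicates Number of replicates.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return An object of class `recovery_report`: per-parameter bias, RMSE,
#'   median absolute z-score and 95% CI coverage; per-good own-price
#'   elasticity truth, mean estimate, bias and RMSE; plus the raw
#'   replicate draws.
#' @export
recovery_experiment <- function(truth, n_households = truth$n_households,
                                n_replicates = 20L, seed = truth$seed) {
  est <- se <- NULL
  own <- own_true <- NULL
  layout <- NULL
  tru <- NULL
  for (r in seq_len(n_replicates)) {
    purchases <- simulate_purchases(truth, n_households, seed = seed + r)
    pipe <- quaids_pipeline(purchases,
                            drop_reference = TRUE,
                            impose_homogeneity = TRUE,
                            impose_symmetry = TRUE,
                            impose_adding_up = FALSE,
                            b_mode = "exact")
    params <- pipe$params
    if (is.null(layout)) {
      layout <- params$layout
      tru <- truth_coef_vector(truth, layout)
      est <- matrix(NA_real_, n_replicates, layout$P,
                    dimnames = list(NULL, layout$names))
      se <- est
      nel <- layout$n
      own <- matrix(NA_real_, n_replicates, nel,
                    dimnames = list(NULL, truth$categories))
      own_true <- own
    }
    est[r, ] <- params$coef
    se[r, ] <- sqrt(pmax(diag(params$vcov), 0))
    own[r, ] <- diag(pipe$elasticities$price_elasticities)
    pm_true <- truth[c("alpha", "gamma", "beta", "lambda", "theta", "rho")]
    el_true <- elasticities_at(pm_true, pipe$elasticities$evaluation,
                               b_mode = "exact")
    own_true[r, ] <- diag(el_true$price)
  }
  z <- abs(sweep(est, 2L, tru)) / se
  covered <- abs(sweep(est, 2L, tru)) <= 1.96 * se
  par_tab <- data.frame(
    parameter = layout$names,
    truth = tru,
    mean_estimate = colMeans(est),
    bias = colMeans(est) - tru,
    rmse = sqrt(colMeans(sweep(est, 2L, tru)^2)),
    median_abs_z = apply(z, 2L, stats::median),
    coverage_95 = colMeans(covered),
    row.names = NULL)
  el_bias <- colMeans(own - own_true)
  el_tab <- data.frame(
    category = truth$categories,
    true_own_price = colMeans(own_true),
    mean_estimate = colMeans(own),
    bias = el_bias,
    rmse = sqrt(colMeans((own - own_true)^2)),
    row.names = NULL)
  structure(
    list(parameters = par_tab,
         own_price = el_tab,
         median_abs_own_price_bias = stats::median(abs(el_bias)),
         overall_coverage = mean(covered),
         n_replicates = n_replicates,
         n_households = n_households,
         estimates = est, standard_errors = se),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery experiment: ", x$n_replicates, " replicates x ",
      x$n_households, " households\n", sep = "")
  cat("  median |own-price elasticity bias|: ",
      sprintf("%.4f", x$median_abs_own_price_bias), "\n", sep = "")
  cat("  95% CI coverage (all parameters): ",
      sprintf("%.3f", x$overall_coverage), "\n", sep = "")
  cat("  worst parameter median |z|: ",
      sprintf("%.2f", max(x$parameters$median_abs_z)), "\n", sep = "")
  invisible(x)
}
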