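## Marshallian price and expenditure elasticities of the censored QUAIDS
## system, evaluated at a representative point (sample or subgroup means),
## with delta-method standard errors from the NLSUR parameter covariance.

#' Representative evaluation point for elasticities
#'
#' Builds the point at which elasticities are evaluated: (sub)sample means
#' of observed shares, log prices, log total expenditure and the probit
#' cdf, with the price indices `ln a(p)` and `b(p)` recomputed at the mean
#' shares/prices so that the point is internally consistent with the index
#' definitions (rather than averaging the household-level indices).
#'
#' @param data A `demand_system_data`.
#' @param corrections A `probit_set` or `NULL` (cdf taken as 1).
#' @param mask Optional logical/integer subgroup selector over households.
#' @param subgroup_label Label stored with the point.
#' @return An object of class `evaluation_point`: `shares`, `lnp`, `lnm`,
#'   `ln_a`, `b`, `cdf`, `mean_shares`, `base_log_prices`,
#'   `subgroup_label`, `n_households`.
#' @export
evaluation_point <- function(data, corrections = NULL, mask = NULL,
                             subgroup_label = "full sample") {
  H <- nrow(data$w)
  if (is.null(mask)) mask <- rep(TRUE, H)
  if (is.numeric(mask)) mask <- seq_len(H) %in% mask
  if (!any(mask)) stop("empty subgroup", call. = FALSE)
  n <- length(data$categories)
  shares <- colMeans(data$w[mask, , drop = FALSE])
  if (any(shares <= 0))
    stop("non-positive mean share at evaluation point; use a larger ",
         "subgroup", call. = FALSE)
  lnp <- colMeans(data$lnp[mask, , drop = FALSE])
  cdf <- if (is.null(corrections)) rep(1, n) else
    vapply(seq_len(n), function(i) mean(corrections[[i]]$cdf[mask]),
           numeric(1))
  pt <- list(shares = shares, lnp = lnp,
             lnm = mean(data$lnm[mask]),
             mean_shares = data$mean_shares,
             base_log_prices = data$base_log_prices,
             cdf = cdf,
             subgroup_label = subgroup_label,
             n_households = sum(mask))
  pt$ln_a <- point_ln_a(pt, lnp)
  class(pt) <- "evaluation_point"
  pt
}

# Tornqvist index at the point, as a function of a price vector (shares at
# the point held fixed): sum_i (w_i + wbar_i)/2 (lnp_i - lnpbar_i).
point_ln_a <- function(point, lnp)
  sum(0.5 * (point$shares + point$mean_shares) *
        (lnp - point$base_log_prices))

# log b at the point for a given mode/beta, as a function of prices.
point_ln_b <- function(point, lnp, b_mode, beta) {
  if (b_mode == "exact") sum(beta * lnp)
  else sum(0.5 * (point$shares - point$mean_shares) *
             (lnp - point$base_log_prices))
}

# All price and expenditure elasticities at a point for a given structured
# parameter set. Returns list(price = n x n, expenditure = n-vector).
# mu_variant "scaled": mu_i = beta_i + 2 lambda_i x / b (the analytic
# derivative of the share system); "printed": mu_i = beta_i + 2 lambda_i x.
elasticities_at <- function(pm, point, b_mode,
                            derivation = c("analytic", "verbatim"),
                            mu_variant = c("scaled", "printed")) {
  derivation <- match.arg(derivation)
  mu_variant <- match.arg(mu_variant)
  n <- length(point$shares)
  lnp <- point$lnp
  ln_a <- point_ln_a(point, lnp)
  b <- exp(point_ln_b(point, lnp, b_mode, pm$beta))
  x <- point$lnm - ln_a
  w <- point$shares
  Phi <- point$cdf
  mu <- if (mu_variant == "scaled") pm$beta + 2 * pm$lambda * x / b
        else pm$beta + 2 * pm$lambda * x
  # index derivatives: d ln a / d ln p_j and d ln b / d ln p_j
  a_j <- 0.5 * (w + point$mean_shares)
  b_j <- if (b_mode == "exact") pm$beta
         else 0.5 * (w - point$mean_shares)
  price <- matrix(NA_real_, n, n,
                  dimnames = list(names(w), names(w)))
  if (derivation == "analytic") {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      dwidlpj <- pm$gamma[i, j] - mu[i] * a_j[j] -
        (pm$lambda[i] * x^2 / b) * b_j[j]
      price[i, j] <- Phi[i] * dwidlpj / w[i] - (i == j)
    }
  } else {
    # the share-derivative expression as printed, for comparison
    for (i in seq_len(n)) for (j in seq_len(n)) {
      term <- pm$gamma[i, j] +
        mu[i] * (pm$alpha[i] + sum(pm$gamma[, j] * lnp)) -
        pm$lambda[i] * pm$beta[i] / b * x^2
      price[i, j] <- Phi[i] * term / w[i] - (i == j)
    }
  }
  expenditure <- Phi * (pm$beta + 2 * pm$lambda * x / b) / w + 1
  list(price = price, expenditure = expenditure)
}

#' Marshallian price elasticity of one good with respect to one price
#'
#' The uncompensated elasticity `e_ij`: the censoring-cdf-scaled analytic
#' derivative of the latent share with respect to `ln p_j`, divided by the
#' share of good i at the evaluation point, minus the Kronecker delta.
#'
#' @param params A `quaids_params`.
#' @param point An [evaluation_point()].
#' @param i,j Category indices (or labels).
#' @param derivation `"analytic"` (derivative of the estimated share
#'   system; default) or `"verbatim"` (the published closed-form display,
#'   kept for comparison).
#' @return Scalar elasticity.
#' @export
price_elasticity <- function(params, point, i, j,
                             derivation = c("analytic", "verbatim")) {
  derivation <- match.arg(derivation)
  if (is.character(i)) i <- match(i, params$categories)
  if (is.character(j)) j <- match(j, params$categories)
  pm <- params_matrices(params)
  elasticities_at(pm, point, params$b_mode, derivation)$price[i, j]
}

#' Total-expenditure elasticity of one good
#'
#' `e_i = Phi_i (beta_i + 2 lambda_i ln(m/a)/b) / w_i + 1` at the
#' evaluation point.
#'
#' @inheritParams price_elasticity
#' @return Scalar elasticity.
#' @export
expenditure_elasticity <- function(params, point, i) {
  if (is.character(i)) i <- match(i, params$categories)
  pm <- params_matrices(params)
  elasticities_at(pm, point, params$b_mode)$expenditure[i]
}

#' Full elasticity matrix with delta-method standard errors
#'
#' Computes the n x n Marshallian price-elasticity matrix and the
#' expenditure-elasticity vector at the (sub)sample-mean evaluation point,
#' with standard errors `sqrt(g' V g)` where `g` is the central-difference
#' gradient of each elasticity with respect to the estimated coefficients
#' and `V` their NLSUR covariance (first-stage estimation uncertainty is
#' not propagated).
#'
#' @param params A `quaids_params` (with covariance).
#' @param data A `demand_system_data`.
#' @param corrections A `probit_set` or `NULL`.
#' @param mask Optional subgroup selector (see [evaluation_point()]).
#' @param subgroup_label Label for the result.
#' @param derivation Elasticity derivation mode, see [price_elasticity()].
#' @param compute_se Set FALSE to skip the delta method.
#' @return An object of class `elasticity_result`: `price_elasticities`,
#'   `expenditure_elasticities`, `se_price`, `se_expenditure`,
#'   `evaluation`, `derivation_mode`.
#' @export
elasticity_matrix <- function(params, data, corrections = NULL,
                              mask = NULL, subgroup_label = "full sample",
                              derivation = c("analytic", "verbatim"),
                              compute_se = TRUE) {
  derivation <- match.arg(derivation)
  point <- evaluation_point(data, corrections, mask, subgroup_label)
  n <- length(params$categories)
  val_fun <- function(coef) {
    pm <- params_matrices(params, coef)
    el <- elasticities_at(pm, point, params$b_mode, derivation)
    c(as.vector(el$price), el$expenditure)
  }
  v0 <- val_fun(params$coef)
  price <- matrix(v0[seq_len(n * n)], n, n,
                  dimnames = list(params$categories, params$categories))
  expend <- stats::setNames(v0[n * n + seq_len(n)], params$categories)
  se_price <- se_expend <- NULL
  if (compute_se && !is.null(params$vcov)) {
    P <- length(params$coef)
    G <- matrix(0, length(v0), P)
    hstep <- pmax(abs(params$coef), 1) * 1e-6
    for (p in seq_len(P)) {
      up <- params$coef; up[p] <- up[p] + hstep[p]
      dn <- params$coef; dn[p] <- dn[p] - hstep[p]
      G[, p] <- (val_fun(up) - val_fun(dn)) / (2 * hstep[p])
    }
    vars <- rowSums((G %*% params$vcov) * G)
    se <- sqrt(pmax(vars, 0))
    se_price <- matrix(se[seq_len(n * n)], n, n,
                       dimnames = dimnames(price))
    se_expend <- stats::setNames(se[n * n + seq_len(n)],
                                 params$categories)
  }
  structure(
    list(price_elasticities = price,
         expenditure_elasticities = expend,
         se_price = se_price,
         se_expenditure = se_expend,
         evaluation = point,
         derivation_mode = derivation,
         categories = params$categories),
    class = "elasticity_result")
}

#' @export
print.elasticity_result <- function(x, digits = 2, ...) {
  cat("Elasticities at ", x$evaluation$subgroup_label, " means (",
      x$evaluation$n_households, " households, ", x$derivation_mode,
      " derivation)\n", sep = "")
  cat("Own-price: ",
      paste(sprintf("%s=%.*f", x$categories, digits,
                    diag(x$price_elasticities)), collapse = ", "),
      "\n", sep = "")
  cat("Expenditure: ",
      paste(sprintf("%s=%.*f", x$categories, digits,
                    x$expenditure_elasticities), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Income-quintile elasticities
#'
#' Ranks households by income, splits them into quintiles (ties to the
#' lower quintile), and evaluates the full-sample parameters at each
#' requested quintile's subgroup means (no re-estimation).
#'
#' @param params A `quaids_params`.
#' @param data A `demand_system_data`.
#' @param corrections A `probit_set` or `NULL`.
#' @param income H-vector of household income; defaults to `data$income`.
#' @param quintiles Which quintiles to evaluate (default first and fifth).
#' @param ... Passed to [elasticity_matrix()].
#' @return Named list of `elasticity_result`, one per quintile.
#' @export
quintile_elasticities <- function(params, data, corrections = NULL,
                                  income = data$income,
                                  quintiles = c(1L, 5L), ...) {
  stopifnot(all(is.finite(income)))
  H <- length(income)
  q <- income_quintile(income)
  out <- list()
  for (k in quintiles) {
    mask <- q == k
    if (sum(mask) < 30L)
      warning("quintile ", k, " has fewer than 30 households",
              call. = FALSE)
    out[[paste0("quintile_", k)]] <-
      elasticity_matrix(params, data, corrections, mask = mask,
                        subgroup_label = paste("income quintile", k), ...)
  }
  out
}

#' Quintile membership by income rank
#'
#' @param income Numeric vector.
#' @return Integer vector in 1..5; ties resolved to the lower quintile.
#' @export
income_quintile <- function(income) {
  H <- length(income)
  r <- rank(income, ties.method = "min")
  pmin(1L + ((r - 1L) * 5L) %/% H, 5L)
}

#' First-order tax counterfactual
#'
#' Percent quantity changes implied by percent price changes through the
#' Marshallian elasticity matrix: `dq_i = sum_j e_ij dp_j` (first order,
#' expenditure held fixed).
#'
#' @param result An `elasticity_result` (or a bare elasticity matrix).
#' @param price_change n-vector of percent price changes.
#' @return n-vector of percent quantity changes.
#' @export
tax_counterfactual <- function(result, price_change) {
  E <- if (inherits(result, "elasticity_result"))
    result$price_elasticities else as.matrix(result)
  stopifnot(ncol(E) == length(price_change))
  drop(E %*% price_change)
}
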