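#' Probit model of the purchase decision
#'
#' Maximum-likelihood probit of a binary purchase indicator on a regressor
#' matrix (intercept included unless `z` already has one). Returns the
#' fitted cumulative probabilities and the standard-normal density at the
#' linear index, the quantities the zero-purchase correction plugs into the
#' share system. Fitted probabilities are clipped to
#' `[1e-9, 1 - 1e-9]` before use and the number of clipped values recorded.
#'
#' If the optimizer diverges (perfect or quasi-separation), a tiny L2
#' penalty is added to the log-likelihood and the fit retried; the result
#' is flagged via `regularized = TRUE`.
#'
#' @param consumed Binary H-vector (0/1 or logical).
#' @param z H x k numeric regressor matrix (no intercept column needed).
#' @param category Optional label attached to the result.
#' @return An object of class `probit_result`: `coefficients`, `cdf`,
#'   `pdf`, `index` (linear predictor), `converged`, `regularized`,
#'   `loglik`, `n_clipped`, `category`.
#' @export
fit_probit <- function(consumed, z, category = NA_character_) {
  consumed <- as.numeric(consumed)
  if (length(unique(consumed)) < 2L)
    stop("purchase indicator has a single outcome",
         if (!is.na(category)) paste0(" for category '", category, "'"),
         call. = FALSE)
  z <- as.matrix(z)
  X <- cbind(`(Intercept)` = 1, z)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("probit regressor matrix is rank deficient", call. = FALSE)

  fit <- suppressWarnings(
    stats::glm.fit(X, consumed, family = stats::binomial(link = "probit"),
                   control = list(maxit = 100)))
  coefs <- fit$coefficients
  regularized <- FALSE
  diverged <- !fit$converged || any(!is.finite(coefs)) ||
    max(abs(coefs)) > 25
  if (diverged) {
    warning("probit divergence (possible separation); refitting with a ",
            "tiny L2 penalty", call. = FALSE)
    coefs <- ridge_probit(consumed, X, penalty = 1e-4)
    regularized <- TRUE
  }
  eta <- drop(X %*% coefs)
  cdf <- stats::pnorm(eta)
  n_clipped <- sum(cdf < 1e-9 | cdf > 1 - 1e-9)
  cdf <- pmin(pmax(cdf, 1e-9), 1 - 1e-9)
  pdf <- stats::dnorm(eta)
  ll <- sum(consumed * stats::pnorm(eta, log.p = TRUE) +
              (1 - consumed) * stats::pnorm(-eta, log.p = TRUE))
  structure(
    list(coefficients = stats::setNames(coefs, colnames(X)),
         cdf = cdf, pdf = pdf, index = eta,
         converged = if (regularized) TRUE else fit$converged,
         regularized = regularized,
         loglik = ll, n_clipped = n_clipped,
         prevalence = mean(consumed), category = category),
    class = "probit_result")
}

# Newton iterations on the L2-penalized probit log-likelihood.
ridge_probit <- function(y, X, penalty = 1e-4, maxit = 200L) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- pmin(pmax(stats::pnorm(eta), 1e-12), 1 - 1e-12)
    d <- stats::dnorm(eta)
    score <- drop(crossprod(X, d * (y - p) / (p * (1 - p)))) -
      2 * penalty * beta
    wgt <- d^2 / (p * (1 - p))
    info <- crossprod(X * sqrt(wgt)) + diag(2 * penalty, ncol(X))
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  beta
}

#' @export
print.probit_result <- function(x, ...) {
  cat("Probit purchase model",
      if (!is.na(x$category)) paste0(" [", x$category, "]"),
      ": prevalence ", sprintf("%.1f%%", 100 * x$prevalence),
      ", logLik ", sprintf("%.1f", x$loglik),
      if (x$regularized) ", L2-regularized", "\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' First-stage probits for every category
#'
#' Fits one purchase-decision probit per category, with the household
#' Tornqvist index and the sociodemographic covariates as regressors.
#' Purchase indicators are derived as `w > 0`. High-prevalence categories
#' (even above 99.5%) are still fitted; their convergence status is carried
#' in the result.
#'
#' @param data A `demand_system_data`.
#' @param covariates Regressor matrix; defaults to `data$covariates`.
#' @param include_price_index Include `ln a(p)` among the regressors
#'   (default TRUE, the price control of the purchase model). Set to a
#'   character vector of category labels to use category-specific log
#'   prices instead.
#' @return A list of `probit_result`, one per category, class
#'   `probit_set`.
#' @export
fit_all_probits <- function(data, covariates = data$covariates,
                            include_price_index = TRUE) {
  results <- vector("list", length(data$categories))
  names(results) <- data$categories
  for (i in seq_along(data$categories)) {
    cat_i <- data$categories[i]
    z <- covariates
    if (isTRUE(include_price_index)) {
      z <- cbind(z, ln_a = data$ln_a)
    } else if (is.character(include_price_index)) {
      z <- cbind(z, data$lnp[, include_price_index, drop = FALSE])
    }
    consumed <- data$w[, i] > 0
    results[[i]] <- tryCatch(
      fit_probit(consumed, z, category = cat_i),
      error = function(e)
        stop("first-stage probit failed for category '", cat_i, "': ",
             conditionMessage(e), call. = FALSE))
  }
  structure(results, class = "probit_set")
}

#' Coefficient table of a probit set
#'
#' @param probits A `probit_set`.
#' @return Data frame, category x regressor layout.
#' @export
probit_coefficient_table <- function(probits) {
  tab <- do.call(rbind, lapply(probits, function(p) p$coefficients))
  data.frame(category = names(probits), tab, check.names = FALSE,
             row.names = NULL)
}

#' Expenditure-endogeneity residual (residual-inclusion control)
#'
#' Ordinary least squares of log total food expenditure on household
#' characteristics; the residuals enter the share system as an additional
#' regressor to control for the endogeneity of total expenditure.
#'
#' @param lnm H-vector of log total food expenditure.
#' @param household_chars H x k regressor matrix (an intercept is added).
#' @return An object of class `expenditure_residual`: `vhat`,
#'   `first_stage_coefficients`, `r_squared`, `fitted`.
#' @export
blundell_robin_residual <- function(lnm, household_chars) {
  X <- cbind(`(Intercept)` = 1, as.matrix(household_chars))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("collinear expenditure-regression column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  coefs <- qr.coef(qrX, lnm)
  fitted <- drop(X %*% coefs)
  vhat <- lnm - fitted
  tss <- sum((lnm - mean(lnm))^2)
  structure(
    list(vhat = vhat,
         first_stage_coefficients = stats::setNames(coefs, colnames(X)),
         r_squared = if (tss > 0) 1 - sum(vhat^2) / tss else NA_real_,
         fitted = fitted),
    class = "expenditure_residual")
}
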