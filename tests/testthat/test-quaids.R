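test_that("predicted shares collapse to alpha when everything else is off", {
  n <- 3
  alpha <- c(0.2, 0.3, 0.5)
  params <- quaids_params(alpha, matrix(0, n, n), rep(0, n), rep(0, n),
                          theta = rep(0, n), rho = rep(0, n),
                          categories = c("a", "b", "c"))
  H <- 4
  data <- list(w = matrix(1 / n, H, n), lnp = matrix(rnorm(H * n), H, n),
               lnm = rnorm(H), ln_a = rnorm(H), b = rep(1, H),
               mean_shares = rep(1 / n, n), base_log_prices = rep(0, n))
  pred <- predict_shares(params, data)
  expect_equal(unname(pred), matrix(alpha, H, n, byrow = TRUE))
})

test_that("cdf scaling and pdf terms enter the prediction term by term", {
  n <- 2
  alpha <- c(0.4, 0.6)
  params <- quaids_params(alpha, matrix(0, n, n), rep(0, n), rep(0, n),
                          rho = c(1, 1), categories = c("a", "b"))
  H <- 3
  data <- list(w = matrix(0.5, H, n), lnp = matrix(0, H, n),
               lnm = rep(0, H), ln_a = rep(0, H), b = rep(1, H),
               mean_shares = rep(0.5, n), base_log_prices = rep(0, n))
  corrections <- lapply(1:2, function(i)
    structure(list(cdf = rep(0.5, H), pdf = rep(0.39894, H)),
              class = "probit_result"))
  pred <- predict_shares(params, data, corrections)
  expect_equal(unname(pred[, 1]), rep(0.5 * 0.4 + 0.39894, H))
  expect_equal(unname(pred[, 2]), rep(0.5 * 0.6 + 0.39894, H))
})

test_that("predicted shares match an independent evaluation of the
          augmented share equation", {
  set.seed(501)
  n <- 4; H <- 5
  pm <- random_pm(n)
  params <- quaids_params(pm$alpha, pm$gamma, pm$beta, pm$lambda,
                          theta = pm$theta, rho = pm$rho,
                          b_mode = "exact")
  data <- list(w = matrix(1 / n, H, n), lnp = matrix(rnorm(H * n, 0, 0.3), H, n),
               lnm = runif(H, 2, 4), ln_a = rnorm(H, 0, 0.1),
               b = rep(1, H), mean_shares = rep(1 / n, n),
               base_log_prices = rep(0, n))
  corrections <- lapply(seq_len(n), function(i) {
    idx <- rnorm(H)
    structure(list(cdf = pnorm(idx), pdf = dnorm(idx)),
              class = "probit_result")
  })
  resid <- structure(list(vhat = rnorm(H)), class = "expenditure_residual")
  pred <- predict_shares(params, data, corrections, resid)
  # independent hand evaluation
  x <- data$lnm - data$ln_a
  b <- exp(drop(data$lnp %*% pm$beta))
  for (i in seq_len(n)) {
    manual <- corrections[[i]]$cdf *
      (pm$alpha[i] + drop(data$lnp %*% pm$gamma[i, ]) + pm$beta[i] * x +
         pm$lambda[i] / b * x^2) +
      pm$theta[i] * resid$vhat + pm$rho[i] * corrections[[i]]$pdf
    expect_equal(unname(pred[, i]), manual, tolerance = 1e-12)
  }
})

test_that("noise-free data is a fixed point of the estimator", {
  truth <- make_default_truth(4, seed = 502, noise_scale = 0)
  p <- simulate_purchases(truth, 2500, censor = FALSE)
  d <- assemble_system(p, impute_prices(compute_unit_values(p)))
  r <- blundell_robin_residual(d$lnm, d$covariates)
  fit <- nlsur_fit(d, NULL, r, impose_adding_up = TRUE, b_mode = "exact")
  tru <- censquaids:::truth_coef_vector(truth, fit$params$layout)
  expect_lt(max(abs(fit$params$coef - tru)), 1e-6)
  expect_true(fit$diagnostics$converged)
  expect_equal(fit$diagnostics$rmse, rep(0, 4), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("imposed restrictions hold exactly on the fitted parameters", {
  truth <- make_default_truth(3, seed = 503)
  d <- assembled_from_truth(truth, 2500)
  probits <- fit_all_probits(d)
  r <- blundell_robin_residual(d$lnm, d$covariates)
  fit <- nlsur_fit(d, probits, r, impose_homogeneity = TRUE,
                   impose_symmetry = TRUE, impose_adding_up = TRUE)
  pm <- params_matrices(fit$params)
  expect_equal(unname(rowSums(pm$gamma)), rep(0, 3), tolerance = 1e-8)
  expect_equal(unname(colSums(pm$gamma)), rep(0, 3), tolerance = 1e-8)
  expect_equal(pm$gamma, t(pm$gamma), tolerance = 1e-8)
  expect_equal(sum(pm$alpha), 1, tolerance = 1e-8)
  expect_equal(sum(pm$beta), 0, tolerance = 1e-8)
  expect_equal(sum(pm$lambda), 0, tolerance = 1e-8)
  # covariance is symmetric positive semi-definite
  V <- fit$params$vcov
  expect_equal(V, t(V), tolerance = 1e-10)
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10 * max(ev))
})

test_that("an unrestricted first GLS pass equals equation-by-equation
          least squares", {
  truth <- make_default_truth(3, seed = 504)
  d <- assembled_from_truth(truth, 1200)
  probits <- fit_all_probits(d)
  r <- blundell_robin_residual(d$lnm, d$covariates)
  fit <- suppressWarnings(
    nlsur_fit(d, probits, r, impose_homogeneity = FALSE,
              impose_symmetry = FALSE, impose_adding_up = FALSE,
              b_mode = "approx", max_iter = 1))
  x <- d$lnm - d$ln_a
  x2b <- x^2 / d$b
  k <- 3 + 5
  for (e in 1:3) {
    X <- cbind(1, d$lnp, x, x2b) * probits[[e]]$cdf
    X <- cbind(X, r$vhat, probits[[e]]$pdf)
    ols <- qr.coef(qr(X), d$w[, e])
    idx <- (e - 1) * k + seq_len(k)
    expect_equal(unname(fit$params$coef[idx]), unname(ols),
                 tolerance = 1e-8)
  }
})

test_that("the AIDS special case matches an independent restricted GLS", {
  # lambda and the quadratic column excluded, uncensored: the model is the
  # linear approximate demand system; compare against a from-scratch
  # kronecker-form restricted GLS on the same design
  truth <- make_default_truth(3, seed = 505)
  truth$lambda[] <- 0
  truth$alpha <- truth$latent_shares_at_center -
    truth$beta * truth$x_center
  d <- assembled_from_truth(truth, 1500, censor = FALSE)
  fit <- suppressWarnings(
    nlsur_fit(d, NULL, NULL, impose_homogeneity = TRUE,
              impose_symmetry = FALSE, impose_adding_up = FALSE,
              b_mode = "approx", max_iter = 1))
  x <- d$lnm - d$ln_a
  Z <- cbind(1, d$lnp, x, x^2 / d$b)
  k <- ncol(Z)
  XX <- kronecker(diag(3), crossprod(Z))
  Xy <- as.vector(vapply(1:3, function(e) crossprod(Z, d$w[, e]),
                         numeric(k)))
  # homogeneity via constraint elimination, written independently
  C <- matrix(0, 3, 3 * k)
  for (e in 1:3) C[e, (e - 1) * k + 2:4] <- 1
  Nb <- qr.Q(qr(t(C)), complete = TRUE)[, 4:(3 * k)]
  delta <- solve(crossprod(Nb, XX %*% Nb), crossprod(Nb, Xy))
  theta_oracle <- drop(Nb %*% delta)
  expect_equal(unname(fit$params$coef), theta_oracle, tolerance = 1e-6)
})

test_that("estimates are invariant under category reordering", {
  truth <- make_default_truth(3, seed = 506)
  p <- simulate_purchases(truth, 1500)
  perm <- c(2, 1, 3)  # keep the reference category last
  cfg <- attr(p, "config")
  cfg_perm <- category_config(cfg$categories[perm],
                              reference_category = cfg$reference_category,
                              covariate_columns = cfg$covariate_columns)
  run <- function(config) {
    p2 <- as_purchase_table(as.data.frame(p), config)
    d <- assemble_system(p2, impute_prices(compute_unit_values(p2)))
    probits <- fit_all_probits(d)
    r <- blundell_robin_residual(d$lnm, d$covariates)
    nlsur_fit(d, probits, r)$params
  }
  a <- params_matrices(run(cfg))
  b <- params_matrices(run(cfg_perm))
  expect_equal(a$alpha[cfg_perm$categories], b$alpha, tolerance = 1e-4)
  expect_equal(a$gamma[cfg_perm$categories, cfg_perm$categories],
               b$gamma, tolerance = 1e-4)
  expect_equal(a$beta[cfg_perm$categories], b$beta, tolerance = 1e-4)
})

test_that("common price rescaling leaves fitted shares unchanged under
          homogeneity", {
  truth <- make_default_truth(3, seed = 507)
  p <- simulate_purchases(truth, 1200)
  d1 <- assemble_system(p, impute_prices(compute_unit_values(p)))
  p2 <- as.data.frame(p)
  p2$quantity <- p2$quantity / 3  # unit values scale by 3
  p2 <- as_purchase_table(p2, attr(p, "config"))
  d2 <- assemble_system(p2, impute_prices(compute_unit_values(p2)))
  run <- function(d) {
    probits <- fit_all_probits(d)
    r <- blundell_robin_residual(d$lnm, d$covariates)
    fit <- nlsur_fit(d, probits, r, impose_homogeneity = TRUE,
                     impose_symmetry = TRUE, b_mode = "approx")
    predict_shares(fit$params, d, probits, r)
  }
  expect_equal(run(d1), run(d2), tolerance = 1e-6)
})

test_that("each exact GLS pass can only improve the objective", {
  truth <- make_default_truth(3, seed = 508)
  d <- assembled_from_truth(truth, 1500)
  probits <- fit_all_probits(d)
  r <- blundell_robin_residual(d$lnm, d$covariates)
  fit <- nlsur_fit(d, probits, r, b_mode = "approx")
  # the solution cannot do worse, under the final weighting, than the
  # naive start (mean shares, all slopes zero)
  Sigma_inv <- solve(fit$params$sigma)
  naive <- quaids_params(d$mean_shares, matrix(0, 3, 3), rep(0, 3),
                         rep(0, 3), theta = rep(0, 3), rho = rep(0, 3),
                         categories = d$categories, b_mode = "approx")
  E_fit <- d$w - predict_shares(fit$params, d, probits, r)
  E_naive <- d$w - predict_shares(naive, d, probits, r)
  obj <- function(E) sum((E %*% Sigma_inv) * E)
  expect_lt(obj(E_fit), obj(E_naive))
  expect_true(all(is.finite(fit$diagnostics$objective_trace)))
})

test_that("restriction options are validated", {
  truth <- make_default_truth(3, seed = 509)
  d <- assembled_from_truth(truth, 800)
  expect_error(nlsur_fit(d, NULL, NULL, drop_reference = TRUE,
                         impose_adding_up = TRUE),
               "adding-up")
})
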