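## Core estimator for the censored QUAIDS share system.
##
## The estimated share equation for household h and category i is
##   w_ih = Phi_i(z_h) [ alpha_i + sum_j gamma_ij ln p_jh
##                       + beta_i x_h + (lambda_i / b_h) x_h^2 ]
##          + theta_i vhat_h + rho_i phi_i(z_h) + error,
## with x_h = ln(m_h / a(p_h)), Phi_i/phi_i the first-stage probit cdf/pdf
## (identically 1/0 when no censoring correction is supplied), vhat the
## expenditure-endogeneity residual, and b_h either the precomputed
## deviation-weighted index ("approx") or exp(sum_i beta_i ln p_ih)
## ("exact", refreshed from the current beta between GLS solves).
## Given the indices the system is linear in the parameters, so each inner
## step is an exact restricted linear GLS solve; the outer loop updates the
## cross-equation residual covariance (feasible GLS) and, in exact mode, b.

# Per-equation coefficient block: alpha, gamma_1..n, beta, lambda,
# then optionally theta and rho.
param_layout <- function(n, eqs, has_theta, has_rho, categories) {
  nms <- c("alpha", paste0("gamma_", categories), "beta", "lambda",
           if (has_theta) "theta", if (has_rho) "rho")
  k <- length(nms)
  full <- as.vector(t(outer(categories[eqs], nms,
                            function(a, b) paste(b, a, sep = "."))))
  list(n = n, eqs = eqs, k = k, P = k * length(eqs),
       block_names = nms, names = full,
       has_theta = has_theta, has_rho = has_rho,
       categories = categories)
}

# Column index of coefficient `what` (e.g. "beta" or c("gamma", j)) in the
# stacked parameter vector for estimated equation position e (1-based along
# `eqs`).
param_pos <- function(layout, e, what, j = NULL) {
  off <- (e - 1L) * layout$k
  base <- switch(what,
                 alpha = 1L,
                 gamma = 1L + j,
                 beta = layout$n + 2L,
                 lambda = layout$n + 3L,
                 theta = layout$n + 4L,
                 rho = layout$n + 3L + (layout$has_theta) + 1L)
  off + base
}

# Linear restriction system C theta = d for the stacked parameter vector.
restriction_system <- function(layout, impose_homogeneity,
                               impose_symmetry, impose_adding_up) {
  P <- layout$P
  eqs <- layout$eqs
  rows <- list(); rhs <- numeric(0)
  add_row <- function(r, v) {
    rows[[length(rows) + 1L]] <<- r
    rhs[length(rhs) + 1L] <<- v
  }
  if (impose_homogeneity) {
    for (e in seq_along(eqs)) {
      r <- numeric(P)
      for (j in seq_len(layout$n)) r[param_pos(layout, e, "gamma", j)] <- 1
      add_row(r, 0)
    }
  }
  if (impose_symmetry) {
    for (a in seq_along(eqs)) for (b in seq_along(eqs)) {
      if (a >= b) next
      r <- numeric(P)
      r[param_pos(layout, a, "gamma", eqs[b])] <- 1
      r[param_pos(layout, b, "gamma", eqs[a])] <- -1
      add_row(r, 0)
    }
  }
  if (impose_adding_up) {
    if (length(eqs) < layout$n)
      stop("adding-up can only be imposed when all equations are estimated",
           call. = FALSE)
    for (what in c("alpha", "beta", "lambda")) {
      r <- numeric(P)
      for (e in seq_along(eqs)) r[param_pos(layout, e, what)] <- 1
      add_row(r, if (what == "alpha") 1 else 0)
    }
    for (j in seq_len(layout$n)) {
      r <- numeric(P)
      for (e in seq_along(eqs)) r[param_pos(layout, e, "gamma", j)] <- 1
      add_row(r, 0)
    }
  }
  if (!length(rows))
    return(list(N = diag(P), theta0 = numeric(P), r = 0L))
  C <- do.call(rbind, rows)
  # drop linearly dependent (mutually consistent) restriction rows
  qt <- qr(t(C))
  keep <- qt$pivot[seq_len(qt$rank)]
  C <- C[keep, , drop = FALSE]
  d <- rhs[keep]
  theta0 <- drop(crossprod(C, solve(tcrossprod(C), d)))
  Qfull <- qr.Q(qr(t(C)), complete = TRUE)
  N <- Qfull[, (nrow(C) + 1L):P, drop = FALSE]
  list(N = N, theta0 = theta0, r = nrow(C))
}

# Design matrices, one per estimated equation, given the current b vector.
build_designs <- function(data, Phi, phi, vhat, b, layout) {
  x <- data$lnm - data$ln_a
  x2b <- x * x / b
  lapply(seq_along(layout$eqs), function(e) {
    i <- layout$eqs[e]
    X <- cbind(1, data$lnp, x, x2b) * Phi[, i]
    if (layout$has_theta) X <- cbind(X, vhat)
    if (layout$has_rho) X <- cbind(X, phi[, i])
    colnames(X) <- layout$block_names
    X
  })
}

# One restricted GLS solve of the stacked linear system.
gls_solve <- function(Xlist, Y, Sigma_inv, restr) {
  g <- length(Xlist); k <- ncol(Xlist[[1L]]); P <- g * k
  M <- matrix(0, P, P); v <- numeric(P)
  for (a in seq_len(g)) {
    ia <- ((a - 1L) * k + 1L):(a * k)
    for (b in seq_len(g)) {
      s <- Sigma_inv[a, b]
      if (s == 0) next
      ib <- ((b - 1L) * k + 1L):(b * k)
      M[ia, ib] <- M[ia, ib] + s * crossprod(Xlist[[a]], Xlist[[b]])
      v[ia] <- v[ia] + s * crossprod(Xlist[[a]], Y[, b])
    }
  }
  N <- restr$N; theta0 <- restr$theta0
  A <- crossprod(N, M %*% N)
  bvec <- crossprod(N, v - M %*% theta0)
  Ainv <- tryCatch(solve(A), error = function(e) {
    # free directions carrying no GLS information (e.g. the adding-up
    # combination of an uncensored unrestricted system): pseudo-inverse
    ea <- eigen((A + t(A)) / 2, symmetric = TRUE)
    keep <- ea$values > 1e-12 * max(ea$values)
    ea$vectors %*% (ifelse(keep, 1 / ea$values, 0) * t(ea$vectors))
  })
  delta <- drop(Ainv %*% bvec)
  theta <- theta0 + drop(N %*% delta)
  V <- N %*% Ainv %*% t(N)
  list(theta = theta, vcov = (V + t(V)) / 2)
}

#' Fit the censored QUAIDS system by iterated feasible GLS (NLSUR)
#'
#' Joint estimation of all share equations (optionally with the reference
#' equation dropped) by iterated feasible generalized least squares:
#' given the cross-equation residual covariance, the restricted GLS
#' criterion is minimized exactly (the system is linear in the parameters
#' given the price indices); the covariance is then updated from the
#' residuals and, in exact-b mode, the expenditure aggregator `b(p)` is
#' refreshed from the current beta. Iteration stops when the largest
#' parameter change falls below `tol`.
#'
#' @param data A `demand_system_data`.
#' @param corrections A `probit_set` from [fit_all_probits()], or `NULL`
#'   for an uncensored system (cdf fixed at 1, no pdf regressor).
#' @param resid An `expenditure_residual` from
#'   [blundell_robin_residual()], or `NULL` to omit the endogeneity
#'   control.
#' @param impose_homogeneity,impose_symmetry Impose `sum_j gamma_ij = 0`
#'   and `gamma_ij = gamma_ji` (defaults TRUE).
#' @param impose_adding_up Impose the latent-system adding-up restrictions
#'   (`sum_i alpha_i = 1`, `sum_i beta_i = sum_i lambda_i = 0`, zero
#'   column sums of gamma); only available when all equations are
#'   estimated.
#' @param drop_reference Drop the reference-category equation and recover
#'   its latent parameters from adding-up (and, for its gamma row,
#'   homogeneity plus symmetry). Default FALSE: the full system is
#'   estimated, the coherent default under the censoring correction, which
#'   breaks adding-up of observed shares.
#' @param b_mode `"exact"` (Cobb-Douglas aggregator recomputed from the
#'   current beta each iteration; default) or `"approx"` (precomputed
#'   deviation-weighted index held fixed).
#' @param tol Convergence tolerance on the maximum absolute parameter
#'   change (default 1e-6).
#' @param max_iter Maximum outer iterations (default 500).
#' @param weight_updates Maximum number of residual-covariance (and, in
#'   exact mode, aggregator) refinements before the weighting is held
#'   fixed and the solve closed exactly at it (default 50). Weakly
#'   identified large systems need this cap; well-conditioned systems
#'   stabilize earlier and are unaffected.
#' @return A list with components `params` (a `quaids_params`) and
#'   `diagnostics` (a `quaids_diagnostics`: per-equation R2/RMSE/MAE,
#'   iteration count, convergence flag, objective trace).
#' @export
nlsur_fit <- function(data, corrections = NULL, resid = NULL,
                      impose_homogeneity = TRUE, impose_symmetry = TRUE,
                      impose_adding_up = is.null(corrections),
                      drop_reference = FALSE,
                      b_mode = c("exact", "approx"),
                      tol = 1e-6, max_iter = 500L,
                      weight_updates = 50L) {
  b_mode <- match.arg(b_mode)
  n <- length(data$categories)
  H <- nrow(data$w)
  ref <- match(data$reference, data$categories)
  eqs <- if (drop_reference) setdiff(seq_len(n), ref) else seq_len(n)
  has_theta <- !is.null(resid)
  has_rho <- !is.null(corrections)

  Phi <- matrix(1, H, n)
  phi <- matrix(0, H, n)
  if (!is.null(corrections)) {
    for (i in seq_len(n)) {
      Phi[, i] <- corrections[[i]]$cdf
      phi[, i] <- corrections[[i]]$pdf
    }
  }
  vhat <- if (has_theta) resid$vhat else NULL

  layout <- param_layout(n, eqs, has_theta, has_rho, data$categories)
  if (H * length(eqs) <= layout$P)
    stop("too few households for the number of free parameters",
         call. = FALSE)
  restr <- restriction_system(layout, impose_homogeneity, impose_symmetry,
                              impose_adding_up)
  Y <- data$w[, eqs, drop = FALSE]
  g <- length(eqs)

  beta_cur <- rep(0, n)
  Sigma_inv <- diag(g)
  Sigma <- NULL
  theta <- NULL
  vc <- NULL
  trace <- numeric(0)
  converged <- FALSE
  sigma_ridged <- FALSE
  frozen <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    if (!frozen || b_mode != "exact")
      b <- if (b_mode == "exact")
        exp(drop(data$lnp %*% beta_cur)) else data$b
    Xlist <- build_designs(data, Phi, phi, vhat, b, layout)
    sol <- gls_solve(Xlist, Y, Sigma_inv, restr)
    raw_step <- if (is.null(theta)) Inf else max(abs(sol$theta - theta))
    theta <- sol$theta
    vc <- sol$vcov
    E <- Y
    for (e in seq_len(g)) {
      idx <- ((e - 1L) * layout$k + 1L):(e * layout$k)
      E[, e] <- Y[, e] - drop(Xlist[[e]] %*% theta[idx])
    }
    trace[it] <- sum((E %*% Sigma_inv) * E)
    for (e in seq_len(g))
      beta_cur[eqs[e]] <- theta[param_pos(layout, e, "beta")]
    if (raw_step < tol || max(abs(E)) < 1e-10) { converged <- TRUE; break }
    if (frozen) next
    Sigma_new <- crossprod(E) / H
    stable <- !is.null(Sigma) &&
      max(abs(Sigma_new - Sigma)) < 1e-7 * max(abs(Sigma_new))
    # weight updates are capped: once the residual covariance has
    # stabilized -- or after `weight_updates` refinements in weakly
    # identified systems where the refinement loop does not contract --
    # the weighting (and, in exact mode, the aggregator b) is held fixed
    # and the restricted GLS solve closes exactly at those weights
    if (stable || it >= weight_updates) { frozen <- TRUE; next }
    Sigma <- Sigma_new
    # residuals of a full share system sum to (near) zero across
    # equations, so Sigma can be singular or nearly so; floor its
    # spectrum to bound the GLS weights
    ev <- eigen(Sigma, symmetric = TRUE)
    floor_ <- 1e-6 * max(ev$values)
    if (any(ev$values < floor_)) sigma_ridged <- TRUE
    Sigma_inv <- ev$vectors %*% ((1 / pmax(ev$values, floor_)) *
                                   t(ev$vectors))
  }
  if (!converged)
    warning("NLSUR did not converge in ", max_iter, " iterations",
            call. = FALSE)

  params <- structure(
    list(coef = stats::setNames(theta, layout$names),
         vcov = vc,
         layout = layout,
         sigma = Sigma,
         categories = data$categories,
         reference = data$reference,
         restrictions = list(homogeneity = impose_homogeneity,
                             symmetry = impose_symmetry,
                             adding_up = impose_adding_up,
                             drop_reference = drop_reference),
         b_mode = b_mode,
         sigma_ridged = sigma_ridged),
    class = "quaids_params")

  fitted <- Y - E
  r2 <- vapply(seq_len(g), function(e) {
    tss <- sum((Y[, e] - mean(Y[, e]))^2)
    1 - sum(E[, e]^2) / tss
  }, numeric(1))
  diagnostics <- structure(
    list(equation = data$categories[eqs],
         r_squared = r2,
         rmse = sqrt(colMeans(E^2)),
         mae = colMeans(abs(E)),
         iterations = it,
         converged = converged,
         objective_trace = trace,
         sigma_ridged = sigma_ridged),
    class = "quaids_diagnostics")
  list(params = params, diagnostics = diagnostics)
}

#' Construct a parameter object from explicit values
#'
#' Builds a `quaids_params` from given parameter vectors/matrices, e.g.
#' for worked examples, simulation truths or serialized fits. No
#' covariance is attached.
#'
#' @param alpha,beta,lambda n-vectors; `gamma` an n x n matrix.
#' @param theta,rho Optional n-vectors (endogeneity-residual and
#'   probit-pdf coefficients).
#' @param categories Category labels.
#' @param reference Reference-category label.
#' @param b_mode `"exact"` or `"approx"`.
#' @return A `quaids_params`.
#' @export
quaids_params <- function(alpha, gamma, beta, lambda,
                          theta = NULL, rho = NULL,
                          categories = names(alpha),
                          reference = categories[length(categories)],
                          b_mode = "exact") {
  n <- length(alpha)
  if (is.null(categories)) categories <- paste0("good_", seq_len(n))
  stopifnot(nrow(gamma) == n, ncol(gamma) == n,
            length(beta) == n, length(lambda) == n)
  layout <- param_layout(n, seq_len(n), !is.null(theta), !is.null(rho),
                         categories)
  coef <- numeric(layout$P)
  for (e in seq_len(n)) {
    coef[param_pos(layout, e, "alpha")] <- alpha[e]
    for (j in seq_len(n))
      coef[param_pos(layout, e, "gamma", j)] <- gamma[e, j]
    coef[param_pos(layout, e, "beta")] <- beta[e]
    coef[param_pos(layout, e, "lambda")] <- lambda[e]
    if (!is.null(theta)) coef[param_pos(layout, e, "theta")] <- theta[e]
    if (!is.null(rho)) coef[param_pos(layout, e, "rho")] <- rho[e]
  }
  structure(
    list(coef = stats::setNames(coef, layout$names),
         vcov = NULL, layout = layout, sigma = NULL,
         categories = categories, reference = reference,
         restrictions = list(homogeneity = FALSE, symmetry = FALSE,
                             adding_up = FALSE, drop_reference = FALSE),
         b_mode = b_mode, sigma_ridged = FALSE),
    class = "quaids_params")
}

#' Structured parameter matrices of a fitted system
#'
#' Unpacks the stacked coefficient vector into named vectors/matrices
#' (`alpha`, `gamma`, `beta`, `lambda`, `theta`, `rho`). When the
#' reference equation was dropped, its latent parameters are recovered
#' from the adding-up identities (and its gamma row from homogeneity plus
#' symmetry, when imposed); its theta/rho are `NA`.
#'
#' @param params A `quaids_params`.
#' @param coef Optional replacement coefficient vector (same layout), used
#'   e.g. for delta-method differentiation.
#' @return List with `alpha`, `beta`, `lambda`, `theta`, `rho` (n-vectors)
#'   and `gamma` (n x n), named by category.
#' @export
params_matrices <- function(params, coef = params$coef) {
  lay <- params$layout
  n <- lay$n
  cats <- lay$categories
  alpha <- beta <- lambda <- theta <- rho <- rep(NA_real_, n)
  gamma <- matrix(NA_real_, n, n, dimnames = list(cats, cats))
  for (e in seq_along(lay$eqs)) {
    i <- lay$eqs[e]
    alpha[i] <- coef[param_pos(lay, e, "alpha")]
    beta[i] <- coef[param_pos(lay, e, "beta")]
    lambda[i] <- coef[param_pos(lay, e, "lambda")]
    for (j in seq_len(n)) gamma[i, j] <- coef[param_pos(lay, e, "gamma", j)]
    if (lay$has_theta) theta[i] <- coef[param_pos(lay, e, "theta")]
    if (lay$has_rho) rho[i] <- coef[param_pos(lay, e, "rho")]
  }
  if (length(lay$eqs) < n) {
    miss <- setdiff(seq_len(n), lay$eqs)
    for (i in miss) {
      alpha[i] <- 1 - sum(alpha[-miss])
      beta[i] <- -sum(beta[-miss])
      lambda[i] <- -sum(lambda[-miss])
      if (params$restrictions$symmetry) {
        for (j in setdiff(seq_len(n), i)) gamma[i, j] <- gamma[j, i]
        if (params$restrictions$homogeneity)
          gamma[i, i] <- -sum(gamma[i, setdiff(seq_len(n), i)])
      }
    }
  }
  names(alpha) <- names(beta) <- names(lambda) <- cats
  names(theta) <- names(rho) <- cats
  list(alpha = alpha, gamma = gamma, beta = beta, lambda = lambda,
       theta = theta, rho = rho)
}

#' @export
print.quaids_params <- function(x, ...) {
  pm <- params_matrices(x)
  cat("Censored QUAIDS parameters (", length(x$layout$eqs), " of ",
      x$layout$n, " equations estimated, b-mode: ", x$b_mode, ")\n",
      sep = "")
  r <- x$restrictions
  cat("  restrictions:",
      if (r$homogeneity) "homogeneity", if (r$symmetry) "symmetry",
      if (r$adding_up) "adding-up",
      if (r$drop_reference) "(reference equation dropped)",
      if (!any(unlist(r[1:3]))) "none", "\n")
  cat("  alpha: ", paste(sprintf("%.4f", pm$alpha), collapse = " "), "\n")
  cat("  beta:  ", paste(sprintf("%.4f", pm$beta), collapse = " "), "\n")
  cat("  lambda:", paste(sprintf("%.4f", pm$lambda), collapse = " "), "\n")
  invisible(x)
}

#' @export
print.quaids_diagnostics <- function(x, ...) {
  cat("NLSUR fit: ", x$iterations, " iterations, ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  print(data.frame(equation = x$equation,
                   r_squared = round(x$r_squared, 4),
                   rmse = signif(x$rmse, 4),
                   mae = signif(x$mae, 4)))
  invisible(x)
}

#' Predicted expenditure shares under the augmented share system
#'
#' Deterministic evaluation of the estimated share equation (censoring
#' cdf-scaled latent QUAIDS share plus endogeneity-residual and pdf terms)
#' for every household and estimated category.
#'
#' @param params A `quaids_params`.
#' @param data A `demand_system_data`.
#' @param corrections,resid The first-stage objects used in the fit
#'   (or `NULL`, matching the fit).
#' @return H x n_estimated matrix of predicted shares, columns named by
#'   category.
#' @export
predict_shares <- function(params, data, corrections = NULL, resid = NULL) {
  lay <- params$layout
  pm <- params_matrices(params)
  H <- nrow(data$w)
  n <- lay$n
  Phi <- matrix(1, H, n); phi <- matrix(0, H, n)
  if (!is.null(corrections)) {
    for (i in seq_len(n)) {
      Phi[, i] <- corrections[[i]]$cdf
      phi[, i] <- corrections[[i]]$pdf
    }
  }
  x <- data$lnm - data$ln_a
  b <- if (params$b_mode == "exact")
    exp(drop(data$lnp %*% ifelse(is.na(pm$beta), 0, pm$beta)))
  else data$b
  out <- matrix(NA_real_, H, length(lay$eqs),
                dimnames = list(NULL, lay$categories[lay$eqs]))
  for (e in seq_along(lay$eqs)) {
    i <- lay$eqs[e]
    latent <- pm$alpha[i] + drop(data$lnp %*% pm$gamma[i, ]) +
      pm$beta[i] * x + (pm$lambda[i] / b) * x^2
    pred <- Phi[, i] * latent
    if (lay$has_theta && !is.null(resid))
      pred <- pred + pm$theta[i] * resid$vhat
    if (lay$has_rho) pred <- pred + pm$rho[i] * phi[, i]
    if (any(!is.finite(pred)))
      stop("non-finite predicted share for category '",
           lay$categories[i], "'", call. = FALSE)
    out[, e] <- pred
  }
  out
}

#' Serialize fitted parameters to JSON
#'
#' @param params A `quaids_params`.
#' @param path Destination file.
#' @export
write_quaids_params <- function(params, path) {
  pm <- params_matrices(params)
  obj <- list(categories = params$categories,
              reference = params$reference,
              restrictions = params$restrictions,
              b_mode = params$b_mode,
              alpha = pm$alpha, gamma = pm$gamma, beta = pm$beta,
              lambda = pm$lambda, theta = pm$theta, rho = pm$rho,
              coef = as.list(params$coef),
              vcov = params$vcov)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", matrix = "rowmajor")
  invisible(path)
}

#' Per-equation goodness-of-fit table
#'
#' @param diagnostics A `quaids_diagnostics`.
#' @return Data frame with equation, R2, RMSE, MAE.
#' @export
fit_statistics <- function(diagnostics) {
  data.frame(equation = diagnostics$equation,
             r_squared = diagnostics$r_squared,
             rmse = diagnostics$rmse,
             mae = diagnostics$mae,
             row.names = NULL)
}
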