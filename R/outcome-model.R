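#' Outcome-model parameters
#'
#' Parameters of the per-(stratum, arm) linear mixed models for the potential
#' outcomes. Three cells carry a model: always-survivors under treatment
#' (`alpha_11_1`), always-survivors under control (`alpha_11_0`) and the
#' protected stratum under treatment (`alpha_10_1`); never-survivors, and the
#' protected under control, have no outcome (truncation by death). One
#' cluster random effect `eta[i] ~ N(0, tau2)` and one residual variance
#' `sigma2` are shared by all three cells.
#'
#' @param alpha_11_1,alpha_11_0,alpha_10_1 Coefficient vectors of length `p`.
#' @param eta Numeric vector of cluster effects (length = number of clusters).
#' @param sigma2,tau2 Positive residual and cluster-effect variances.
#' @return An object of class `outcome_params`.
#' @export
outcome_params <- function(alpha_11_1, alpha_11_0, alpha_10_1, eta,
                           sigma2, tau2) {
  p <- length(alpha_11_1)
  if (length(alpha_11_0) != p || length(alpha_10_1) != p) {
    stop("the three alpha vectors must have equal length")
  }
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be positive")
  if (!is.finite(tau2) || tau2 <= 0) stop("tau2 must be positive")
  structure(list(alpha_11_1 = as.numeric(alpha_11_1),
                 alpha_11_0 = as.numeric(alpha_11_0),
                 alpha_10_1 = as.numeric(alpha_10_1),
                 eta = as.numeric(eta), sigma2 = sigma2, tau2 = tau2),
            class = "outcome_params")
}

#' Prior hyperparameters
#'
#' Conjugate priors used throughout: independent `N(0, coef_prior_var)` on
#' every regression coefficient (outcome and strata models alike) and
#' `InvGamma(ig_shape, ig_rate)` on each variance component (`sigma2`,
#' `tau2`, and `phi2` when the strata model is clustered). The defaults are
#' diffuse; the model's own hyperparameters are configurable because no
#' single weakly-informative choice suits every outcome scale.
#'
#' @param coef_prior_var Prior variance of each coefficient (default `1e4`).
#' @param ig_shape,ig_rate Inverse-gamma shape and rate (default `0.01` each).
#' @return An object of class `sace_priors`.
#' @export
sace_priors <- function(coef_prior_var = 1e4, ig_shape = 0.01,
                        ig_rate = 0.01) {
  stopifnot(coef_prior_var > 0, ig_shape > 0, ig_rate > 0)
  structure(list(coef_prior_var = coef_prior_var, ig_shape = ig_shape,
                 ig_rate = ig_rate), class = "sace_priors")
}

# Cell index per row given memberships: 1 = (G=11, D=1), 2 = (G=11, D=0),
# 3 = (G=10, D=1); NA for cells without an outcome model.
outcome_cells <- function(data, g) {
  cell <- rep(NA_integer_, data$n)
  cell[g == 3L & data$D == 1] <- 1L
  cell[g == 3L & data$D == 0] <- 2L
  cell[g == 2L & data$D == 1] <- 3L
  cell
}

# Linear predictor X alpha_cell (without eta) for rows with a modeled cell.
cell_linear_predictor <- function(data, cell, params) {
  mu <- rep(NA_real_, data$n)
  A <- cbind(params$alpha_11_1, params$alpha_11_0, params$alpha_10_1)
  for (k in 1:3) {
    idx <- which(cell == k)
    if (length(idx)) mu[idx] <- drop(data$X[idx, , drop = FALSE] %*% A[, k])
  }
  mu
}

#' Log-density of an observed outcome under its stratum/arm model
#'
#' Normal log-density with mean `x' alpha_{stratum, arm} + eta_i` and
#' variance `sigma2`. Only three cells are modeled: `(11, 1)`, `(11, 0)` and
#' `(10, 1)`; requesting any other cell is an error because the outcome is
#' undefined there.
#'
#' @param y Observed outcome value.
#' @param x Covariate row (intercept first).
#' @param arm Treatment arm, 0 or 1.
#' @param stratum Stratum label, `"11"` or `"10"`.
#' @param params An [outcome_params] object.
#' @param cluster_index Integer cluster index (selects `eta[i]`).
#' @return Scalar log-density.
#' @export
outcome_log_density <- function(y, x, arm, stratum, params, cluster_index) {
  stratum <- as.character(stratum)
  alpha <- if (stratum == "11" && arm == 1) params$alpha_11_1
    else if (stratum == "11" && arm == 0) params$alpha_11_0
    else if (stratum == "10" && arm == 1) params$alpha_10_1
    else stop("no outcome model for stratum ", stratum, " in arm ", arm)
  mu <- sum(as.numeric(x) * alpha) + params$eta[cluster_index]
  stats::dnorm(y, mu, sqrt(params$sigma2), log = TRUE)
}

# Draw from the conjugate conditional N(mean, P^{-1}) with
# P = X'X / sigma2 + I / prior_var, mean = P^{-1} X'(z) / sigma2.
# z is the outcome net of cluster effects. Returns the draw; the posterior
# mean/precision are attached for diagnostic use.
conj_coef_draw <- function(X, z, sigma2, prior_var) {
  p <- ncol(X)
  P <- crossprod(X) / sigma2 + diag(1 / prior_var, p)
  R <- chol(P)
  m <- backsolve(R, forwardsolve(t(R), crossprod(X, z) / sigma2))
  draw <- drop(m + backsolve(R, stats::rnorm(p)))
  if (!all(is.finite(draw))) stop("non-finite coefficient draw")
  attr(draw, "mean") <- drop(m)
  draw
}

#' Gibbs update of the outcome regression coefficients
#'
#' For each of the three modeled (stratum, arm) cells independently, draws
#' the coefficient vector from its exact conjugate multivariate-normal full
#' conditional, using only rows currently assigned to that cell that have an
#' observed outcome. A cell with no such rows draws from the prior, keeping
#' the chain irreducible.
#'
#' @param data A [crt_data] object.
#' @param memberships Character membership vector (`"00"/"10"/"11"`).
#' @param params Current [outcome_params].
#' @param priors A [sace_priors] object.
#' @return `params` with the three alpha vectors replaced by fresh draws.
#' @export
gibbs_update_coefficients <- function(data, memberships, params, priors) {
  g <- membership_codes(memberships)
  cell <- outcome_cells(data, g)
  obs <- data$S == 1
  z_all <- data$Y - params$eta[data$cluster]
  slots <- c("alpha_11_1", "alpha_11_0", "alpha_10_1")
  for (k in 1:3) {
    idx <- which(obs & cell == k)
    if (length(idx) == 0L) {
      params[[slots[k]]] <- stats::rnorm(data$p, 0,
                                         sqrt(priors$coef_prior_var))
    } else {
      params[[slots[k]]] <- as.numeric(conj_coef_draw(
        data$X[idx, , drop = FALSE], z_all[idx],
        params$sigma2, priors$coef_prior_var))
    }
  }
  params
}

#' Gibbs update of the cluster random effects
#'
#' Per cluster `i`, with `k_i` observed-outcome rows and residuals
#' `r = y - x' alpha_cell`, draws
#' `eta_i ~ N( (sum r / sigma2) / (k_i / sigma2 + 1 / tau2),
#'             1 / (k_i / sigma2 + 1 / tau2) )`;
#' a cluster with no observed outcomes draws from the `N(0, tau2)` prior.
#'
#' @inheritParams gibbs_update_coefficients
#' @return `params` with `eta` replaced by a fresh draw.
#' @export
gibbs_update_cluster_effects <- function(data, memberships, params) {
  g <- membership_codes(memberships)
  cell <- outcome_cells(data, g)
  obs <- which(data$S == 1 & !is.na(cell))
  mu <- cell_linear_predictor(data, cell, params)
  r <- data$Y[obs] - mu[obs]
  k_i <- tabulate(data$cluster[obs], data$I)
  sum_r <- numeric(data$I)
  if (length(obs)) {
    agg <- rowsum(r, group = data$cluster[obs])
    sum_r[as.integer(rownames(agg))] <- agg[, 1]
  }
  prec <- k_i / params$sigma2 + 1 / params$tau2
  params$eta <- stats::rnorm(data$I, (sum_r / params$sigma2) / prec,
                             sqrt(1 / prec))
  params
}

#' Gibbs update of the variance components
#'
#' Conjugate inverse-gamma draws:
#' `sigma2 ~ InvGamma(ig_shape + N_obs/2, ig_rate + SSR/2)` with
#' `SSR = sum (y - x'alpha - eta)^2` over observed-outcome rows, and
#' `tau2 ~ InvGamma(ig_shape + I/2, ig_rate + sum(eta^2)/2)`.
#'
#' @inheritParams gibbs_update_coefficients
#' @return `params` with `sigma2` and `tau2` replaced by fresh draws.
#' @export
gibbs_update_variances <- function(data, memberships, params, priors) {
  g <- membership_codes(memberships)
  cell <- outcome_cells(data, g)
  obs <- which(data$S == 1 & !is.na(cell))
  mu <- cell_linear_predictor(data, cell, params)
  resid <- data$Y[obs] - mu[obs] - params$eta[data$cluster[obs]]
  ssr <- sum(resid^2)
  params$sigma2 <- 1 / stats::rgamma(1, priors$ig_shape + length(obs) / 2,
                                     rate = priors$ig_rate + ssr / 2)
  params$tau2 <- 1 / stats::rgamma(1, priors$ig_shape + data$I / 2,
                                   rate = priors$ig_rate +
                                     sum(params$eta^2) / 2)
  params
}

# One full conjugate sweep (coefficients -> cluster effects -> variances)
# with the cell assignment computed once; order and laws identical to the
# three exported update functions.
gibbs_sweep <- function(data, g, params, priors) {
  cell <- outcome_cells(data, g)
  obs <- data$S == 1
  idx_cell <- list(which(obs & cell == 1L), which(obs & cell == 2L),
                   which(obs & cell == 3L))
  z_all <- data$Y - params$eta[data$cluster]
  slots <- c("alpha_11_1", "alpha_11_0", "alpha_10_1")
  for (k in 1:3) {
    idx <- idx_cell[[k]]
    if (length(idx) == 0L) {
      params[[slots[k]]] <- stats::rnorm(data$p, 0,
                                         sqrt(priors$coef_prior_var))
    } else {
      params[[slots[k]]] <- as.numeric(conj_coef_draw(
        data$X[idx, , drop = FALSE], z_all[idx],
        params$sigma2, priors$coef_prior_var))
    }
  }

  # residuals y - x'alpha_cell for observed rows, under the fresh alphas
  A <- cbind(params$alpha_11_1, params$alpha_11_0, params$alpha_10_1)
  r_cell <- cl_cell <- vector("list", 3)
  for (k in 1:3) {
    idx <- idx_cell[[k]]
    if (length(idx)) {
      r_cell[[k]] <- data$Y[idx] -
        drop(data$X[idx, , drop = FALSE] %*% A[, k])
      cl_cell[[k]] <- data$cluster[idx]
    }
  }
  r <- as.numeric(unlist(r_cell, use.names = FALSE))
  cl_obs <- as.integer(unlist(cl_cell, use.names = FALSE))
  n_obs <- length(r)
  k_i <- tabulate(cl_obs, data$I)
  sum_r <- numeric(data$I)
  if (n_obs) {
    agg <- rowsum(r, group = cl_obs)
    sum_r[as.integer(rownames(agg))] <- agg[, 1]
  }
  prec <- k_i / params$sigma2 + 1 / params$tau2
  params$eta <- stats::rnorm(data$I, (sum_r / params$sigma2) / prec,
                             sqrt(1 / prec))

  resid <- r - params$eta[cl_obs]
  params$sigma2 <- 1 / stats::rgamma(1, priors$ig_shape + n_obs / 2,
                                     rate = priors$ig_rate +
                                       sum(resid^2) / 2)
  params$tau2 <- 1 / stats::rgamma(1, priors$ig_shape + data$I / 2,
                                   rate = priors$ig_rate +
                                     sum(params$eta^2) / 2)
  params
}

#' Outcome intracluster correlation coefficient
#'
#' `rho = tau2 / (tau2 + sigma2)`: the share of total outcome variance
#' attributable to between-cluster variation.
#'
#' @param tau2,sigma2 Positive variance components.
#' @return The ICC, in `(0, 1)`.
#' @examples
#' outcome_icc(1, 5)  # 1/6
#' @export
outcome_icc <- function(tau2, sigma2) {
  if (!is.finite(tau2) || tau2 <= 0) stop("tau2 must be positive")
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be positive")
  tau2 / (tau2 + sigma2)
}
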