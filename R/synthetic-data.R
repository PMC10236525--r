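#' Synthetic CRT configuration
#'
#' Data-generating process for a two-arm cluster-randomized trial with three
#' latent principal strata and truncation by death. Defaults reproduce the
#' benchmark generating process used throughout the package's validation:
#' 100 clusters of 15, covariates `X1 ~ N(0, 4)` (variance 4) and
#' `X2 ~ Unif(-5, 5)`, membership coefficients `beta = (-1, 0.3, 0.5)`,
#' `gamma = (-0.8, 0.6, 0.4)` (marginal stratum shares about 21.1% / 26.5% /
#' 52.4% never / protected / always), outcome coefficients
#' `alpha_11_1 = (1.5, 0.5, 0.8)`, `alpha_11_0 = (0.2, 0.3, 0.6)`,
#' `alpha_10_1 = (-1.5, 0.9, 0.5)`, and variances `sigma2 = 5`, `tau2 = 1`
#' (outcome ICC 1/6).
#'
#' @param m Cluster size (mean cluster size when `cv > 0`).
#' @param n_clusters Number of clusters.
#' @param cv Coefficient of variation of cluster sizes, `sd(m)/mean(m)`;
#'   `0` gives equal sizes.
#' @param beta,gamma Strata-model coefficient vectors (length 3 here:
#'   intercept, X1, X2).
#' @param alpha_11_1,alpha_11_0,alpha_10_1 Outcome-model coefficients for the
#'   three modeled (stratum, arm) cells.
#' @param sigma2,tau2 Residual and cluster-effect variances of the outcome.
#' @param strata_icc Latent-scale ICC of stratum membership; `> 0` adds a
#'   shared cluster intercept `chi_i ~ N(0, latent_icc_to_phi2(strata_icc))`
#'   to both non-reference linear predictors.
#' @param allocation Fraction of clusters assigned to treatment.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(m = 15, n_clusters = 100, cv = 0,
                       beta = c(-1, 0.3, 0.5), gamma = c(-0.8, 0.6, 0.4),
                       alpha_11_1 = c(1.5, 0.5, 0.8),
                       alpha_11_0 = c(0.2, 0.3, 0.6),
                       alpha_10_1 = c(-1.5, 0.9, 0.5),
                       sigma2 = 5, tau2 = 1, strata_icc = 0,
                       allocation = 0.5) {
  stopifnot(m >= 2, n_clusters >= 2, cv >= 0, sigma2 > 0, tau2 > 0,
            strata_icc >= 0, strata_icc < 1,
            allocation > 0, allocation < 1)
  p <- length(beta)
  if (length(gamma) != p || length(alpha_11_1) != p ||
      length(alpha_11_0) != p || length(alpha_10_1) != p) {
    stop("all coefficient vectors must have the same length")
  }
  structure(list(m = m, n_clusters = n_clusters, cv = cv, beta = beta,
                 gamma = gamma, alpha_11_1 = alpha_11_1,
                 alpha_11_0 = alpha_11_0, alpha_10_1 = alpha_10_1,
                 sigma2 = sigma2, tau2 = tau2, strata_icc = strata_icc,
                 allocation = allocation), class = "sim_config")
}

# Draw covariate rows (1, X1, X2) of the benchmark DGP.
draw_covariates <- function(n) {
  cbind(1, rnorm(n, 0, 2), runif(n, -5, 5))
}

#' Generate a synthetic cluster-randomized trial
#'
#' Simulates the full counterfactual table and masks it by the realized
#' cluster-level treatment. Cluster sizes are equal (`cv = 0`) or drawn from
#' a gamma distribution with mean `m` and standard deviation `cv * m`,
#' rounded and floored at 2. Membership is drawn from the multinomial
#' logistic model; potential outcomes follow the per-(stratum, arm) linear
#' mixed models with a shared cluster effect `eta_i ~ N(0, tau2)` and
#' independent `N(0, sigma2)` residuals per defined counterfactual.
#' Never-survivors have no outcome under either arm; the protected have one
#' only under treatment. Observed `S` and `Y` are the potential values
#' selected by the cluster's arm, so truncation (missing `Y`) occurs exactly
#' where `S = 0`.
#'
#' @param config A [sim_config] object.
#' @param seed Integer seed; identical seeds give identical trials.
#' @return A list with `data` (a [crt_data]) and `truth` (a data.frame with
#'   the true stratum `G`, potential survival `S1`/`S0` and outcomes
#'   `Y1`/`Y0`, `NA` where truncated) plus attributes `prop` (realized
#'   stratum shares) and `config`.
#' @export
simulate_crt <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n_cl <- config$n_clusters
  if (config$cv == 0) {
    sizes <- rep(as.integer(round(config$m)), n_cl)
  } else {
    shape <- 1 / config$cv^2
    sizes <- pmax(2L, as.integer(round(
      rgamma(n_cl, shape = shape, scale = config$m / shape))))
  }
  n <- sum(sizes)
  cluster <- rep(seq_len(n_cl), times = sizes)

  n_treat <- max(1L, min(n_cl - 1L, round(config$allocation * n_cl)))
  D_cluster <- numeric(n_cl)
  D_cluster[sample.int(n_cl, n_treat)] <- 1
  D <- D_cluster[cluster]

  X <- draw_covariates(n)
  chi <- NULL; phi2 <- NULL
  if (config$strata_icc > 0) {
    phi2 <- latent_icc_to_phi2(config$strata_icc)
    chi <- rnorm(n_cl, 0, sqrt(phi2))
  }
  sp <- strata_params(config$beta, config$gamma, chi = chi, phi2 = phi2)
  pr <- exp(strata_log_probs(X, sp, cluster = cluster))
  u <- runif(n)
  G_code <- 1L + (u >= pr[, 1]) + (u >= pr[, 1] + pr[, 2])  # 1=00,2=10,3=11
  G <- c("00", "10", "11")[G_code]

  eta <- rnorm(n_cl, 0, sqrt(config$tau2))
  sd_e <- sqrt(config$sigma2)
  Y1 <- Y0 <- rep(NA_real_, n)
  as_idx <- G_code == 3L
  pr_idx <- G_code == 2L
  Y1[as_idx] <- drop(X[as_idx, , drop = FALSE] %*% config$alpha_11_1) +
    eta[cluster[as_idx]] + rnorm(sum(as_idx), 0, sd_e)
  Y0[as_idx] <- drop(X[as_idx, , drop = FALSE] %*% config$alpha_11_0) +
    eta[cluster[as_idx]] + rnorm(sum(as_idx), 0, sd_e)
  Y1[pr_idx] <- drop(X[pr_idx, , drop = FALSE] %*% config$alpha_10_1) +
    eta[cluster[pr_idx]] + rnorm(sum(pr_idx), 0, sd_e)

  S1 <- as.integer(G_code >= 2L)  # survive under treatment: 10 or 11
  S0 <- as.integer(G_code == 3L)  # survive under control: 11 only
  S <- ifelse(D == 1, S1, S0)
  Y <- ifelse(D == 1, Y1, Y0)
  Y[S == 0] <- NA_real_

  df <- data.frame(cluster = cluster, D = D, S = S, Y = Y,
                   X1 = X[, 2], X2 = X[, 3])
  truth <- data.frame(cluster = cluster, G = G, S1 = S1, S0 = S0,
                      Y1 = Y1, Y0 = Y0)
  attr(truth, "prop") <- strata_proportion_draw(G)
  attr(truth, "config") <- config
  list(data = crt_data(df, covariates = c("X1", "X2")), truth = truth)
}

#' Monte-Carlo oracle for the true SACE of a generating process
#'
#' Estimates `E[x'(alpha_11_1 - alpha_11_0) | G = 11]` by direct simulation:
#' covariate rows (and, if configured, cluster intercepts on the latent
#' membership scale) are drawn from the generating process and the
#' counterfactual-mean contrast is averaged with weights equal to each
#' row's always-survivor probability — the exact conditional expectation
#' given the draw, so no stratum labels need to be sampled. Cluster effects
#' and residuals cancel in the contrast and do not enter.
#'
#' @param config A [sim_config] object.
#' @param n_draws Number of Monte-Carlo draws (default `1e6`).
#' @param seed Integer seed.
#' @return A list with the oracle `value`, its Monte-Carlo `se`, and
#'   `n_draws`.
#' @export
true_sace_oracle <- function(config, n_draws = 1e6, seed = 1L) {
  stopifnot(inherits(config, "sim_config"), n_draws >= 1)
  set.seed(seed)
  X <- draw_covariates(n_draws)
  chi <- NULL; phi2 <- NULL; cluster <- NULL
  if (config$strata_icc > 0) {
    phi2 <- latent_icc_to_phi2(config$strata_icc)
    chi <- rnorm(n_draws, 0, sqrt(phi2))
    cluster <- seq_len(n_draws)
  }
  sp <- strata_params(config$beta, config$gamma, chi = chi, phi2 = phi2)
  w <- exp(strata_log_probs(X, sp, cluster = cluster)[, 3])
  if (sum(w) <= 0) stop("always-survivor probability vanished everywhere")
  v <- drop(X %*% (config$alpha_11_1 - config$alpha_11_0))
  value <- sum(w * v) / sum(w)
  infl <- w * (v - value) / mean(w)
  list(value = value, se = stats::sd(infl) / sqrt(n_draws),
       n_draws = n_draws)
}

#' Marginal stratum proportions of a generating process
#'
#' Monte-Carlo average of the three membership probabilities over the
#' covariate (and latent cluster-intercept) distribution.
#'
#' @inheritParams true_sace_oracle
#' @return Named vector `c(p00, p10, p11)` of marginal shares.
#' @export
marginal_strata_proportions <- function(config, n_draws = 1e6, seed = 1L) {
  stopifnot(inherits(config, "sim_config"), n_draws >= 1)
  set.seed(seed)
  X <- draw_covariates(n_draws)
  chi <- NULL; phi2 <- NULL; cluster <- NULL
  if (config$strata_icc > 0) {
    phi2 <- latent_icc_to_phi2(config$strata_icc)
    chi <- rnorm(n_draws, 0, sqrt(phi2))
    cluster <- seq_len(n_draws)
  }
  sp <- strata_params(config$beta, config$gamma, chi = chi, phi2 = phi2)
  p <- colMeans(exp(strata_log_probs(X, sp, cluster = cluster)))
  names(p) <- c("p00", "p10", "p11")
  p
}
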