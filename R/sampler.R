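#' Metropolis tuning parameters
#'
#' Settings for the adaptive random-walk Metropolis updates of the strata
#' coefficients. Proposals are multivariate t, centred at the current value,
#' with scale matrix `s * T` per block; `T_beta` and `T_gamma` are tuned to
#' the empirical covariance of the burn-in draws (Haario-style adaptation)
#' and the scalars `s_beta`, `s_gamma` are nudged toward the target
#' acceptance rate. Adaptation runs only during burn-in, so the retained
#' chain uses a fixed (hence Markov) kernel.
#'
#' @param t_df Degrees of freedom of the t proposal (default 4: heavy-tailed
#'   but finite-variance).
#' @param target_rate Target acceptance rate for the vector blocks (default
#'   0.234, the classical random-walk optimum).
#' @param adapt_start First iteration at which adaptation may occur.
#' @param adapt_interval Iterations between adaptation events.
#' @param s_beta,s_gamma Initial scale factors; default `2.38^2 / p`, set
#'   when the chain is initialized.
#' @param T_beta,T_gamma Initial `p x p` scale matrices (default `0.05 * I`).
#' @param s_chi Initial proposal standard deviation for the per-cluster
#'   scalar random walks on the strata intercepts, when used.
#' @return An object of class `mh_tuning`.
#' @export
mh_tuning <- function(t_df = 4, target_rate = 0.234, adapt_start = 200,
                      adapt_interval = 100, s_beta = NULL, s_gamma = NULL,
                      T_beta = NULL, T_gamma = NULL, s_chi = 0.5) {
  stopifnot(t_df > 0, target_rate > 0, target_rate < 1,
            adapt_start >= 1, adapt_interval >= 1, s_chi > 0)
  structure(list(t_df = t_df, target_rate = target_rate,
                 adapt_start = adapt_start, adapt_interval = adapt_interval,
                 s_beta = s_beta, s_gamma = s_gamma,
                 T_beta = T_beta, T_gamma = T_gamma, s_chi = s_chi),
            class = "mh_tuning")
}

# Multivariate-t increment with scale matrix s * T and t_df degrees of
# freedom (proposal is symmetric, so no Hastings correction is needed).
rmvt_step <- function(T_mat, s, df) {
  p <- nrow(T_mat)
  z <- drop(crossprod(chol(T_mat), stats::rnorm(p))) * sqrt(s)
  z / sqrt(stats::rchisq(1, df) / df)
}

# --- latent membership augmentation -----------------------------------------

# Vectorized augmentation on integer codes (1=00, 2=10, 3=11). Returns the
# membership log-probability matrix alongside so callers can reuse it.
sample_memberships_codes <- function(data, sp, op, lp = NULL) {
  if (is.null(lp)) lp <- strata_log_probs(data$X, sp, cluster = data$cluster)
  g <- integer(data$n)
  g[data$D == 1 & data$S == 0] <- 1L  # never-survivor, deterministic
  g[data$D == 0 & data$S == 1] <- 3L  # always-survivor, deterministic

  # treated survivors: always-survivor vs protected, weighting the strata
  # probabilities by the outcome density of the observed Y under each cell
  ts <- which(data$D == 1 & data$S == 1)
  if (length(ts)) {
    Xts <- data$X[ts, , drop = FALSE]
    e <- op$eta[data$cluster[ts]]
    sd_y <- sqrt(op$sigma2)
    l11 <- lp[ts, 3] + stats::dnorm(data$Y[ts],
                                    drop(Xts %*% op$alpha_11_1) + e,
                                    sd_y, log = TRUE)
    l10 <- lp[ts, 2] + stats::dnorm(data$Y[ts],
                                    drop(Xts %*% op$alpha_10_1) + e,
                                    sd_y, log = TRUE)
    p11 <- 1 / (1 + exp(l10 - l11))
    dead <- !is.finite(p11)  # both components underflow
    if (any(dead)) {
      warning(sum(dead), " treated survivor(s) had vanishing outcome ",
              "density in both cells; assigned by strata probabilities alone")
      p11[dead] <- 1 / (1 + exp(lp[ts, 2][dead] - lp[ts, 3][dead]))
    }
    g[ts] <- ifelse(stats::runif(length(ts)) < p11, 3L, 2L)
  }

  # control deaths: protected vs never-survivor; the outcome is truncated so
  # only the membership probabilities enter
  cd <- which(data$D == 0 & data$S == 0)
  if (length(cd)) {
    p10 <- 1 / (1 + exp(lp[cd, 1] - lp[cd, 2]))
    g[cd] <- ifelse(stats::runif(length(cd)) < p10, 2L, 1L)
  }
  list(g = g, lp = lp)
}

#' Draw latent principal-stratum memberships
#'
#' Data-augmentation step. Under monotonicity two observed groups are
#' deterministic — treated deaths are never-survivors, control survivors are
#' always-survivors. Treated survivors are always-survivors or protected,
#' resolved by the posterior odds `p11 * N(y | x'a111 + eta, s2)` versus
#' `p10 * N(y | x'a110 + eta, s2)`; control deaths are protected or
#' never-survivors with probability `p10 / (p10 + p00)` (no outcome term —
#' the outcome is truncated).
#'
#' @param data A [crt_data] object.
#' @param strata_params A [strata_params] object.
#' @param outcome_params An [outcome_params] object.
#' @return Character vector of labels `"00"`, `"10"`, `"11"`, consistent with
#'   each row's observed treatment and survival.
#' @export
sample_memberships <- function(data, strata_params, outcome_params) {
  c("00", "10", "11")[sample_memberships_codes(data, strata_params,
                                               outcome_params)$g]
}

# --- Metropolis updates ------------------------------------------------------

# log target for the strata coefficients: membership log-likelihood plus
# independent N(0, coef_prior_var) priors on every coefficient.
strata_log_target <- function(g, data, sp, prior_var, lp = NULL) {
  if (is.null(lp)) lp <- strata_log_probs(data$X, sp, cluster = data$cluster)
  ll <- sum(pmax(lp[cbind(seq_along(g), g)], log(1e-300)))
  ll + sum(stats::dnorm(c(sp$beta, sp$gamma), 0, sqrt(prior_var), log = TRUE))
}

mh_update_strata_codes <- function(data, g, sp, tuning, priors, lp = NULL) {
  if (is.null(lp)) lp <- strata_log_probs(data$X, sp, cluster = data$cluster)
  cur <- strata_log_target(g, data, sp, priors$coef_prior_var, lp = lp)
  acc <- c(beta = FALSE, gamma = FALSE)

  prop <- sp
  prop$beta <- sp$beta + rmvt_step(tuning$T_beta, tuning$s_beta, tuning$t_df)
  lp_prop <- strata_log_probs(data$X, prop, cluster = data$cluster)
  new <- strata_log_target(g, data, prop, priors$coef_prior_var, lp = lp_prop)
  if (is.finite(new) && log(stats::runif(1)) < new - cur) {
    sp <- prop; cur <- new; lp <- lp_prop; acc["beta"] <- TRUE
  }

  prop <- sp
  prop$gamma <- sp$gamma + rmvt_step(tuning$T_gamma, tuning$s_gamma,
                                     tuning$t_df)
  lp_prop <- strata_log_probs(data$X, prop, cluster = data$cluster)
  new <- strata_log_target(g, data, prop, priors$coef_prior_var, lp = lp_prop)
  if (is.finite(new) && log(stats::runif(1)) < new - cur) {
    sp <- prop; lp <- lp_prop; acc["gamma"] <- TRUE
  }
  list(params = sp, accept = acc, lp = lp)
}

#' Metropolis update of the strata coefficients
#'
#' Updates `beta` then `gamma` as separate blocks by random-walk Metropolis
#' with symmetric multivariate-t proposals; the target is the membership
#' log-likelihood plus the normal prior, so the acceptance probability is
#' `min(1, exp(delta log-target))`.
#'
#' @param data A [crt_data] object.
#' @param memberships Character membership labels.
#' @param strata_params Current [strata_params].
#' @param tuning An [mh_tuning] object with `s_*` and `T_*` set.
#' @param priors A [sace_priors] object (supplies `coef_prior_var`).
#' @return A list with elements `params` (updated [strata_params]) and
#'   `accept` (named logical vector for the two blocks).
#' @export
mh_update_strata_coefficients <- function(data, memberships, strata_params,
                                          tuning, priors = sace_priors()) {
  g <- membership_codes(memberships)
  mh_update_strata_codes(data, g, strata_params, tuning, priors)
}

#' Adapt a Metropolis proposal from chain history
#'
#' Haario-style adaptation: the scale matrix becomes the empirical covariance
#' of the past draws plus `1e-6 * I`, and the scalar factor is multiplied by
#' `exp(accept_rate - target_rate)`. If the history is degenerate (no
#' variation) the matrix is left unchanged and the scalar halved. Intended to
#' run only during burn-in.
#'
#' @param history Matrix of past draws for one block (rows = iterations);
#'   at least `2 p` rows.
#' @param tuning An [mh_tuning] object.
#' @param accept_rate Acceptance rate observed since the last adaptation.
#' @param block `"beta"` or `"gamma"`: which block's `T` and `s` to update.
#' @return The updated [mh_tuning] object.
#' @export
adapt_proposal <- function(history, tuning, accept_rate, block = "beta") {
  history <- as.matrix(history)
  p <- ncol(history)
  if (nrow(history) < 2 * p) stop("need at least 2p draws to adapt")
  s_slot <- paste0("s_", block); T_slot <- paste0("T_", block)
  V <- stats::cov(history)
  if (!all(is.finite(V)) || all(abs(V) < .Machine$double.eps)) {
    tuning[[s_slot]] <- tuning[[s_slot]] / 2
  } else {
    tuning[[T_slot]] <- V + diag(1e-6, p)
    tuning[[s_slot]] <- tuning[[s_slot]] *
      exp(accept_rate - tuning$target_rate)
  }
  tuning
}

mh_update_chi_codes <- function(data, g, sp, priors, s_chi, lp_cur = NULL) {
  if (is.null(lp_cur)) {
    lp_cur <- strata_log_probs(data$X, sp, cluster = data$cluster)
  }
  row_ll <- pmax(lp_cur[cbind(seq_along(g), g)], log(1e-300))
  ll_cur <- drop(rowsum(row_ll, data$cluster, reorder = TRUE))

  prop <- sp
  prop$chi <- sp$chi + stats::rnorm(data$I, 0, s_chi)
  lp_new <- strata_log_probs(data$X, prop, cluster = data$cluster)
  row_ll_new <- pmax(lp_new[cbind(seq_along(g), g)], log(1e-300))
  ll_new <- drop(rowsum(row_ll_new, data$cluster, reorder = TRUE))

  log_r <- (ll_new + stats::dnorm(prop$chi, 0, sqrt(sp$phi2), log = TRUE)) -
           (ll_cur + stats::dnorm(sp$chi, 0, sqrt(sp$phi2), log = TRUE))
  acc <- log(stats::runif(data$I)) < log_r
  sp$chi[acc] <- prop$chi[acc]
  sp$phi2 <- 1 / stats::rgamma(1, priors$ig_shape + data$I / 2,
                               rate = priors$ig_rate + sum(sp$chi^2) / 2)
  list(params = sp, accept_rate = mean(acc))
}

#' Metropolis update of the strata-model cluster intercepts
#'
#' When the membership model carries cluster random intercepts, each `chi_i`
#' is updated by an independent scalar random walk (the membership likelihood
#' factorizes over clusters given the coefficients), targeting that cluster's
#' membership log-likelihood plus the `N(0, phi2)` prior; `phi2` is then
#' refreshed from its conjugate inverse-gamma conditional.
#'
#' @inheritParams mh_update_strata_coefficients
#' @param s_chi Proposal standard deviation for the scalar walks.
#' @return A list with `params` (updated [strata_params], including `phi2`)
#'   and `accept_rate` (mean per-cluster acceptance).
#' @export
mh_update_cluster_intercepts <- function(data, memberships, strata_params,
                                         priors = sace_priors(),
                                         s_chi = 0.5) {
  if (is.null(strata_params$chi)) {
    stop("strata_params has no cluster intercepts")
  }
  g <- membership_codes(memberships)
  mh_update_chi_codes(data, g, strata_params, priors, s_chi)
}

# --- one full MCMC sweep -----------------------------------------------------

# state: list(g, sp, op). Performs membership augmentation, the Gibbs block
# for the outcome model, and the Metropolis block for the strata model. The
# membership log-probability matrix is computed once per sweep and reused
# wherever the strata parameters are unchanged.
mcmc_step <- function(data, state, priors, tuning, strata_clustering) {
  aug <- sample_memberships_codes(data, state$sp, state$op)
  g <- aug$g
  op <- gibbs_sweep(data, g, state$op, priors)
  mh <- mh_update_strata_codes(data, g, state$sp, tuning, priors,
                               lp = aug$lp)
  sp <- mh$params
  chi_rate <- NA_real_
  if (strata_clustering) {
    upd <- mh_update_chi_codes(data, g, sp, priors, tuning$s_chi,
                               lp_cur = mh$lp)
    sp <- upd$params
    chi_rate <- upd$accept_rate
  }
  list(g = g, sp = sp, op = op, accept = mh$accept, chi_rate = chi_rate)
}

# --- initialization ----------------------------------------------------------

# Covariate-anchored starting probabilities for the ambiguous rows. The
# control arm identifies P(G = 11 | x) (survival there means always-survivor)
# and treated deaths identify P(G = 00 | x); the protected share is the
# remainder. Initializing the ambiguous memberships from these anchored
# probabilities, rather than uniformly, starts the two treated-survivor
# outcome components apart in a way consistent with the membership model's
# identified mode — uniform starts leave the component assignment to chance
# and can seed a persistent label-swapped local mode.
init_membership_probs <- function(data) {
  ctrl <- data$D == 0
  trt <- !ctrl
  p11 <- rep(mean(data$S[ctrl]), data$n)
  p00 <- rep(mean(1 - data$S[trt]), data$n)
  fit11 <- tryCatch(
    stats::glm.fit(data$X[ctrl, , drop = FALSE], data$S[ctrl],
                   family = stats::binomial()),
    error = function(e) NULL)
  if (!is.null(fit11) && all(is.finite(fit11$coefficients))) {
    p11 <- drop(stats::plogis(data$X %*% fit11$coefficients))
  }
  fit00 <- tryCatch(
    stats::glm.fit(data$X[trt, , drop = FALSE], 1 - data$S[trt],
                   family = stats::binomial()),
    error = function(e) NULL)
  if (!is.null(fit00) && all(is.finite(fit00$coefficients))) {
    p00 <- drop(stats::plogis(data$X %*% fit00$coefficients))
  }
  p10 <- pmax(1 - p11 - p00, 0.02)
  list(p11 = pmax(p11, 0.02), p10 = p10, p00 = pmax(p00, 0.02))
}

init_state <- function(data, priors, strata_clustering) {
  pr <- init_membership_probs(data)
  g <- integer(data$n)
  g[data$D == 1 & data$S == 0] <- 1L
  g[data$D == 0 & data$S == 1] <- 3L
  ts <- which(data$D == 1 & data$S == 1)
  if (length(ts)) {
    q11 <- pr$p11[ts] / (pr$p11[ts] + pr$p10[ts])
    w <- q11
    if (length(ts) >= 4 * data$p) {
      # EM pass for the two-component regression mixture among treated
      # survivors, with the anchored membership probabilities as per-row
      # prior weights. Weighted least squares under q11 and 1 - q11 gives a
      # small but consistently signed separation of the two cells (the
      # covariation of membership with the outcome is exactly the signal
      # that identifies the pairing); the EM iterations then amplify it, so
      # the chain starts at the membership-consistent mode rather than
      # choosing one of the two label pairings by chance.
      Xts <- data$X[ts, , drop = FALSE]
      yts <- data$Y[ts]
      wls <- function(wt) {
        drop(solve(crossprod(Xts * wt, Xts) + diag(1e-8, data$p),
                   crossprod(Xts * wt, yts)))
      }
      a11 <- wls(q11); a10 <- wls(1 - q11)
      s2 <- max(stats::var(yts - drop(Xts %*% wls(rep(1, length(ts))))),
                1e-6)
      for (k in 1:50) {
        d1 <- q11 * stats::dnorm(yts, drop(Xts %*% a11), sqrt(s2))
        d0 <- (1 - q11) * stats::dnorm(yts, drop(Xts %*% a10), sqrt(s2))
        w <- d1 / pmax(d1 + d0, 1e-300)
        if (sum(w) < 1 || sum(1 - w) < 1) break
        a11 <- wls(w); a10 <- wls(1 - w)
        s2 <- max(sum(w * (yts - drop(Xts %*% a11))^2 +
                        (1 - w) * (yts - drop(Xts %*% a10))^2) /
                    length(ts), 1e-6)
      }
    }
    g[ts] <- ifelse(stats::runif(length(ts)) < w, 3L, 2L)
  }
  cd <- which(data$D == 0 & data$S == 0)
  if (length(cd)) {
    q10 <- pr$p10[cd] / (pr$p10[cd] + pr$p00[cd])
    g[cd] <- ifelse(stats::runif(length(cd)) < q10, 2L, 1L)
  }
  # per-cell least squares (ridge-stabilized) with a little jitter
  ls_fit <- function(idx) {
    if (length(idx) < data$p) return(stats::rnorm(data$p, 0, 0.1))
    X <- data$X[idx, , drop = FALSE]
    drop(solve(crossprod(X) + diag(1e-8, data$p),
               crossprod(X, data$Y[idx]))) + stats::rnorm(data$p, 0, 0.05)
  }
  cell <- outcome_cells(data, g)
  obs <- data$S == 1
  a1 <- ls_fit(which(obs & cell == 1L))
  a0 <- ls_fit(which(obs & cell == 2L))
  a10 <- ls_fit(which(obs & cell == 3L))

  op <- outcome_params(a1, a0, a10, eta = numeric(data$I),
                       sigma2 = max(stats::var(data$Y[obs]), 0.1),
                       tau2 = max(stats::var(data$Y[obs]) / 10, 0.05))
  mu <- cell_linear_predictor(data, cell, op)
  resid <- data$Y[obs] - mu[obs]
  op$sigma2 <- max(stats::var(resid), 0.1)
  cl_means <- tapply(resid, data$cluster[obs], mean)
  op$tau2 <- max(stats::var(as.numeric(cl_means)), 0.05)

  sp <- strata_params(stats::rnorm(data$p, 0, 0.1),
                      stats::rnorm(data$p, 0, 0.1),
                      chi = if (strata_clustering) numeric(data$I) else NULL,
                      phi2 = if (strata_clustering) 0.1 else NULL)
  list(g = g, sp = sp, op = op)
}

# --- the chain ---------------------------------------------------------------

#' MCMC run configuration
#'
#' @param iterations Total iterations per chain (default 2000).
#' @param burn_in Burn-in iterations discarded from the front (default 500).
#' @param thin Keep every `thin`-th post-burn-in draw (default 1).
#' @param chains Number of independent chains for [sace_fit()] (default 2).
#' @param priors A [sace_priors] object.
#' @param tuning An [mh_tuning] object.
#' @param strata_clustering Logical: add cluster random intercepts to the
#'   membership model (default `FALSE`).
#' @return An object of class `sace_config`.
#' @export
sace_config <- function(iterations = 2000, burn_in = 500, thin = 1,
                        chains = 2, priors = sace_priors(),
                        tuning = mh_tuning(), strata_clustering = FALSE) {
  if (burn_in >= iterations) stop("burn_in must be smaller than iterations")
  if (thin < 1 || chains < 1) stop("thin and chains must be >= 1")
  structure(list(iterations = iterations, burn_in = burn_in, thin = thin,
                 chains = chains, priors = priors, tuning = tuning,
                 strata_clustering = isTRUE(strata_clustering)),
            class = "sace_config")
}

#' Run one MCMC chain
#'
#' Each iteration performs, in order: (1) latent membership augmentation,
#' (2) conjugate Gibbs draws of the outcome coefficients, (3) cluster
#' effects, (4) variances, (5) Metropolis updates of the strata coefficients
#' (and, optionally, the strata-model cluster intercepts), then (6) records
#' the derived estimand draws (SACE, counterfactual means among
#' always-survivors, stratum proportions, outcome ICC). Proposal adaptation
#' runs only during burn-in.
#'
#' @param data A [crt_data] object.
#' @param config A [sace_config] object.
#' @param seed Integer seed; the chain is fully reproducible given the seed.
#' @return An object of class `sace_chain`: a list with `draws` (matrix, one
#'   row per retained iteration), `accept` rates, the frozen tuning, and a
#'   count of draws with an empty always-survivor set.
#' @export
run_chain <- function(data, config, seed = 1L) {
  stopifnot(inherits(data, "crt_data"), inherits(config, "sace_config"))
  set.seed(seed)
  p <- data$p
  priors <- config$priors
  tuning <- config$tuning
  if (is.null(tuning$s_beta)) tuning$s_beta <- 2.38^2 / p
  if (is.null(tuning$s_gamma)) tuning$s_gamma <- 2.38^2 / p
  if (is.null(tuning$T_beta)) tuning$T_beta <- diag(0.05, p)
  if (is.null(tuning$T_gamma)) tuning$T_gamma <- diag(0.05, p)

  if (config$strata_clustering && any(data$n_i <= 1L)) {
    warning("some clusters have a single participant; the clustered strata ",
            "model may fail to converge - consider strata_clustering = FALSE")
  }

  state <- init_state(data, priors, config$strata_clustering)

  covs <- data$covariates
  par_names <- c(paste0("beta[", c("1", covs), "]"),
                 paste0("gamma[", c("1", covs), "]"),
                 paste0("alpha_11_1[", c("1", covs), "]"),
                 paste0("alpha_11_0[", c("1", covs), "]"),
                 paste0("alpha_10_1[", c("1", covs), "]"),
                 "sigma2", "tau2",
                 if (config$strata_clustering) "phi2",
                 "delta", "ybar1", "ybar0",
                 "prop00", "prop10", "prop11", "rho",
                 paste0("as_mean[", covs, "]"))
  n_keep <- floor((config$iterations - config$burn_in) / config$thin)
  draws <- matrix(NA_real_, n_keep, length(par_names),
                  dimnames = list(NULL, par_names))

  beta_hist <- matrix(NA_real_, config$burn_in, p)
  gamma_hist <- matrix(NA_real_, config$burn_in, p)
  win_acc <- c(beta = 0L, gamma = 0L); win_n <- 0L
  chi_acc_sum <- 0; chi_acc_n <- 0L
  post_acc <- c(beta = 0L, gamma = 0L); post_n <- 0L
  n_empty_always <- 0L
  kept <- 0L

  for (it in seq_len(config$iterations)) {
    state_new <- mcmc_step(data, state, priors, tuning,
                           config$strata_clustering)
    state <- state_new[c("g", "sp", "op")]
    in_burn <- it <= config$burn_in

    if (in_burn) {
      beta_hist[it, ] <- state$sp$beta
      gamma_hist[it, ] <- state$sp$gamma
      win_acc <- win_acc + state_new$accept
      win_n <- win_n + 1L
      if (!is.na(state_new$chi_rate)) {
        chi_acc_sum <- chi_acc_sum + state_new$chi_rate
        chi_acc_n <- chi_acc_n + 1L
      }
      if (it >= tuning$adapt_start && it >= 2 * p &&
          (it - tuning$adapt_start) %% tuning$adapt_interval == 0) {
        # drop the first half of the history: the initial transient inflates
        # the empirical covariance and over-scales the proposal
        win <- seq.int(max(1L, it %/% 2L), it)
        tuning <- adapt_proposal(beta_hist[win, , drop = FALSE],
                                 tuning, win_acc[["beta"]] / win_n, "beta")
        tuning <- adapt_proposal(gamma_hist[win, , drop = FALSE],
                                 tuning, win_acc[["gamma"]] / win_n, "gamma")
        if (config$strata_clustering && chi_acc_n > 0L) {
          tuning$s_chi <- tuning$s_chi *
            exp(chi_acc_sum / chi_acc_n - 0.44)
          chi_acc_sum <- 0; chi_acc_n <- 0L
        }
        win_acc <- c(beta = 0L, gamma = 0L); win_n <- 0L
      }
    } else {
      post_acc <- post_acc + state_new$accept
      post_n <- post_n + 1L
      if ((it - config$burn_in) %% config$thin == 0) {
        kept <- kept + 1L
        as_rows <- which(state$g == 3L)
        if (length(as_rows) == 0L) {
          n_empty_always <- n_empty_always + 1L
          est <- c(NA_real_, NA_real_, NA_real_)
          prof <- rep(NA_real_, length(covs))
        } else {
          Xa <- data$X[as_rows, , drop = FALSE]
          e <- state$op$eta[data$cluster[as_rows]]
          yb1 <- mean(drop(Xa %*% state$op$alpha_11_1) + e)
          yb0 <- mean(drop(Xa %*% state$op$alpha_11_0) + e)
          est <- c(yb1 - yb0, yb1, yb0)
          prof <- colMeans(Xa[, -1, drop = FALSE])
        }
        props <- tabulate(state$g, 3L) / data$n
        draws[kept, ] <- c(
          state$sp$beta, state$sp$gamma,
          state$op$alpha_11_1, state$op$alpha_11_0, state$op$alpha_10_1,
          state$op$sigma2, state$op$tau2,
          if (config$strata_clustering) state$sp$phi2,
          est, props,
          outcome_icc(state$op$tau2, state$op$sigma2), prof)
      }
    }
  }

  structure(list(
    draws = draws[seq_len(kept), , drop = FALSE],
    accept = c(beta = post_acc[["beta"]] / post_n,
               gamma = post_acc[["gamma"]] / post_n),
    tuning = tuning, seed = seed, config = config,
    n_empty_always = n_empty_always
  ), class = "sace_chain")
}

#' Fit the joint SACE model
#'
#' Runs `config$chains` independent MCMC chains (seeds `seed`, `seed + 1`,
#' ...), pools the retained draws, and computes split-Rhat convergence
#' diagnostics per parameter.
#'
#' @inheritParams run_chain
#' @return An object of class `sace_fit` with the pooled `draws`, per-chain
#'   results, `rhat` vector, acceptance rates, and the data.
#' @seealso [sace_summary()] for the posterior table, [run_recovery_study()]
#'   for the simulation harness.
#' @export
sace_fit <- function(data, config = sace_config(), seed = 1L) {
  chains <- lapply(seq_len(config$chains) - 1L, function(k) {
    run_chain(data, config, seed = seed + k)
  })
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  rhat <- apply_split_rhat(lapply(chains, `[[`, "draws"))
  accept <- rowMeans(vapply(chains, `[[`, numeric(2), "accept"))
  structure(list(draws = draws, chains = chains, rhat = rhat,
                 accept = accept, data = data, config = config, seed = seed,
                 n_empty_always = sum(vapply(chains, `[[`, integer(1),
                                             "n_empty_always"))),
            class = "sace_fit")
}

# split-Rhat across chains: each chain is split in half and the classical
# between/within variance ratio is computed over the resulting sequences.
split_rhat <- function(seqs) {
  seqs <- lapply(seqs, function(x) x[!is.na(x)])
  seqs <- seqs[vapply(seqs, length, integer(1)) >= 4L]
  if (length(seqs) == 0L) return(NA_real_)
  halves <- unlist(lapply(seqs, function(x) {
    h <- length(x) %/% 2
    list(x[seq_len(h)], x[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves); n <- min(lengths(halves))
  halves <- lapply(halves, function(x) x[seq_len(n)])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars); B <- n * stats::var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

apply_split_rhat <- function(draw_list) {
  cols <- colnames(draw_list[[1]])
  vapply(cols, function(cn) {
    split_rhat(lapply(draw_list, function(d) d[, cn]))
  }, numeric(1))
}

#' @export
print.sace_fit <- function(x, ...) {
  cat("<sace_fit> ", length(x$chains), " chain(s) x ",
      nrow(x$chains[[1]]$draws), " retained draws\n", sep = "")
  cat("  MH acceptance: beta ", round(x$accept[["beta"]], 3),
      ", gamma ", round(x$accept[["gamma"]], 3), "\n", sep = "")
  key <- c("delta", "rho", "sigma2", "tau2")
  cat("  split-Rhat (key parameters): ",
      paste(key, round(x$rhat[key], 3), sep = " = ", collapse = ", "),
      "\n", sep = "")
  print(sace_summary(x, comparator = FALSE), row.names = FALSE)
  invisible(x)
}

#' Export chain draws as a tidy table
#'
#' One row per retained iteration x parameter, suitable for external
#' diagnostics.
#'
#' @param x A [sace_fit] object.
#' @param ... Unused.
#' @return A data.frame with columns `chain`, `iteration`, `parameter`,
#'   `value`.
#' @export
as.data.frame.sace_fit <- function(x, ...) {
  out <- do.call(rbind, lapply(seq_along(x$chains), function(k) {
    d <- x$chains[[k]]$draws
    data.frame(chain = k,
               iteration = rep(seq_len(nrow(d)), times = ncol(d)),
               parameter = rep(colnames(d), each = nrow(d)),
               value = as.vector(d))
  }))
  rownames(out) <- NULL
  out
}
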