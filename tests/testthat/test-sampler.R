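test_that("membership augmentation respects the monotonicity table", {
  data <- make_toy_data(n_clusters = 10, size = 8, seed = 3)
  sp <- strata_params(bench_beta, bench_gamma)
  op <- outcome_params(c(1.5, 0.5, 0.8), c(0.2, 0.3, 0.6), c(-1.5, 0.9, 0.5),
                       eta = rep(0, 10), sigma2 = 5, tau2 = 1)
  set.seed(4)
  for (i in 1:20) {
    g <- sample_memberships(data, sp, op)
    expect_true(memberships_admissible(data, g))
  }
})

test_that("control-death augmentation frequencies match p10/(p10+p00)", {
  # fixed-parameter chain: the augmentation probability for (D=0, S=0) rows
  # has the analytic form p10 / (p10 + p00), with no outcome term
  df <- data.frame(cluster = rep(1:2, each = 4), D = 0, S = 0, Y = NA,
                   X1 = c(-2, -0.5, 0, 0.6, 1.1, 1.8, -1.2, 0.3),
                   X2 = c(1, -3, 2.5, 0, -1, 4, -2, 3))
  data <- make_manual_data(df)
  sp <- strata_params(bench_beta, bench_gamma)
  op <- outcome_params(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0), eta = c(0, 0),
                       sigma2 = 1, tau2 = 1)
  n_rep <- 4000
  set.seed(31)
  freq <- rowMeans(replicate(n_rep, sample_memberships(data, sp, op) == "10"))
  expected <- vapply(seq_len(8), function(i) {
    p <- stratum_probabilities(data$X[i, ], sp)
    p[["p10"]] / (p[["p10"]] + p[["p00"]])
  }, numeric(1))
  se <- sqrt(expected * (1 - expected) / n_rep)
  expect_true(all(abs(freq - expected) < 3 * se))

  # symmetric special case: p10 = p00 gives exactly 1/2
  sp_sym <- strata_params(c(0.3, 0, 0), c(0.3, 0, 0))
  set.seed(32)
  freq_sym <- mean(replicate(n_rep,
                             sample_memberships(data, sp_sym, op)[1] == "10"))
  expect_equal(freq_sym, 0.5, tolerance = 3 * sqrt(0.25 / n_rep))
})

test_that("treated-survivor augmentation weighs strata by outcome density", {
  # equal strata probabilities; y at the always-survivor mean and 3 residual
  # SDs from the protected mean -> P(G=11) = phi(0) / (phi(0) + phi(3))
  df <- data.frame(cluster = 1, D = 1, S = 1, Y = 0, X1 = 0, X2 = 0)
  data <- make_manual_data(df)
  sp <- strata_params(c(0, 0, 0), c(0, 0, 0))
  op <- outcome_params(c(0, 0, 0), c(9, 0, 0), c(3, 0, 0),
                       eta = 0, sigma2 = 1, tau2 = 1)
  n_rep <- 6000
  set.seed(33)
  freq <- mean(replicate(n_rep, sample_memberships(data, sp, op) == "11"))
  expected <- 0.9890130574  # frozen: dnorm(0) / (dnorm(0) + dnorm(3))
  expect_equal(freq, expected, tolerance = 3 * sqrt(expected *
                                                      (1 - expected) / n_rep))
})

test_that("deterministic rows are assigned with probability one", {
  df <- data.frame(cluster = c(1, 2), D = c(1, 0), S = c(0, 1),
                   Y = c(NA, 0.4), X1 = c(1, -1), X2 = c(0, 2))
  data <- make_manual_data(df)
  sp <- strata_params(bench_beta, bench_gamma)
  op <- outcome_params(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0), eta = c(0, 0),
                       sigma2 = 1, tau2 = 1)
  set.seed(34)
  for (i in 1:10) {
    expect_identical(sample_memberships(data, sp, op), c("00", "11"))
  }
})

test_that("Metropolis target equals membership likelihood plus prior", {
  # single unit with G = 11, x = (1): moving the beta intercept 0 -> 1 with
  # gamma at 0 changes the membership term by log[3 / (2 + e)]
  df <- data.frame(cluster = 1, D = 0, S = 1, Y = 0.2)
  data <- crt_data(df, covariates = character(0))
  pv <- 100
  t0 <- sacecrt:::strata_log_target(3L, data, strata_params(0, 0), pv)
  t1 <- sacecrt:::strata_log_target(3L, data, strata_params(1, 0), pv)
  hand <- log(3 / (2 + exp(1))) +
    dnorm(1, 0, sqrt(pv), log = TRUE) - dnorm(0, 0, sqrt(pv), log = TRUE)
  expect_equal(t1 - t0, hand, tolerance = 1e-10)
})

test_that("a null proposal is always accepted", {
  data <- make_toy_data(n_clusters = 6, size = 5, seed = 13)
  g <- admissible_labels(data, seed = 14)
  sp <- strata_params(bench_beta, bench_gamma)
  tuning <- mh_tuning(s_beta = 1e-24, s_gamma = 1e-24,
                      T_beta = diag(1e-12, 3), T_gamma = diag(1e-12, 3))
  set.seed(15)
  acc <- replicate(25, unlist(
    mh_update_strata_coefficients(data, g, sp, tuning)$accept))
  expect_true(all(acc))
})

test_that("proposal adaptation follows the Haario recipe", {
  tuning <- mh_tuning(s_beta = 2.38^2 / 3, T_beta = diag(0.05, 3))

  # degenerate history: T unchanged, s halved
  hist0 <- matrix(1, nrow = 20, ncol = 3)
  out <- adapt_proposal(hist0, tuning, accept_rate = 0.3, block = "beta")
  expect_identical(out$T_beta, tuning$T_beta)
  expect_equal(out$s_beta, tuning$s_beta / 2)

  # i.i.d. standard-normal history: T approaches identity + eps I
  set.seed(41)
  hist1 <- matrix(rnorm(3000 * 3), ncol = 3)
  out <- adapt_proposal(hist1, tuning, accept_rate = tuning$target_rate,
                        block = "beta")
  expect_equal(out$T_beta, diag(1 + 1e-6, 3), tolerance = 0.1)
  # acceptance at target: s unchanged
  expect_equal(out$s_beta, tuning$s_beta, tolerance = 1e-12)

  expect_error(adapt_proposal(hist1[1:4, ], tuning, 0.3, "beta"),
               "2p draws")
})

test_that("cluster-intercept update targets likelihood times prior", {
  # single-cluster toy: the MH draws of chi (phi2 held fixed) match 1-D
  # quadrature of  exp(cluster log-lik) * N(0, phi2)
  df <- data.frame(cluster = 1, D = c(1, 1, 1, 1, 1), S = c(1, 1, 1, 0, 0),
                   Y = c(0.1, -0.5, 0.8, NA, NA), X1 = c(0.5, -1, 0, 1, -2),
                   X2 = c(0, 2, -1, 0.5, 1))
  data <- make_manual_data(df)
  g <- c("11", "11", "10", "00", "00")
  phi2 <- 0.8
  sp <- strata_params(bench_beta, bench_gamma, chi = 0, phi2 = phi2)

  log_post <- function(chi) {
    vapply(chi, function(ci) {
      spi <- strata_params(bench_beta, bench_gamma, chi = ci, phi2 = phi2)
      membership_log_likelihood(g, data, spi) +
        dnorm(ci, 0, sqrt(phi2), log = TRUE)
    }, numeric(1))
  }
  grid <- seq(-5, 5, length.out = 4001)
  w <- exp(log_post(grid) - max(log_post(grid)))
  quad_mean <- sum(grid * w) / sum(w)
  quad_sd <- sqrt(sum((grid - quad_mean)^2 * w) / sum(w))

  set.seed(51)
  n_it <- 20000
  draws <- numeric(n_it)
  for (i in seq_len(n_it)) {
    upd <- mh_update_cluster_intercepts(data, g, sp, s_chi = 1.0)
    sp <- upd$params
    sp$phi2 <- phi2  # hold the prior variance fixed for this check
    draws[i] <- sp$chi
  }
  draws <- draws[-(1:1000)]
  ess_floor <- length(draws) / 20  # conservative for a scalar random walk
  expect_equal(mean(draws), quad_mean,
               tolerance = 3 * quad_sd / sqrt(ess_floor))
  expect_equal(sd(draws), quad_sd, tolerance = 0.15 * quad_sd)
})

test_that("phi2 conditional reduces to InvGamma(a + I/2, b) at chi = 0", {
  data <- make_toy_data(n_clusters = 5, size = 4, seed = 61)
  g <- admissible_labels(data, seed = 62)
  priors <- sace_priors(ig_shape = 2, ig_rate = 2)
  set.seed(63)
  draws <- replicate(4000, {
    sp <- strata_params(bench_beta, bench_gamma, chi = rep(0, 5), phi2 = 1)
    out <- mh_update_cluster_intercepts(data, g, sp, priors = priors,
                                        s_chi = 1e-14)
    out$params$phi2
  })
  # with chi == 0 (null proposals): 1/phi2 ~ Gamma(2 + 5/2, rate 2)
  shape <- 2 + 5 / 2
  expect_equal(mean(1 / draws), shape / 2,
               tolerance = 3 * sqrt(shape / 4 / 4000))
})

test_that("chains are reproducible and configurations validated", {
  data <- make_toy_data(n_clusters = 8, size = 5, seed = 71)
  cfg <- sace_config(iterations = 120, burn_in = 40)
  c1 <- run_chain(data, cfg, seed = 5)
  c2 <- run_chain(data, cfg, seed = 5)
  expect_identical(c1$draws, c2$draws)
  c3 <- run_chain(data, cfg, seed = 6)
  expect_false(identical(c1$draws, c3$draws))

  expect_error(sace_config(iterations = 100, burn_in = 100), "burn_in")
  expect_error(sace_config(chains = 0), "chains")
})

test_that("every iteration keeps memberships consistent with monotonicity", {
  data <- make_toy_data(n_clusters = 8, size = 5, seed = 81)
  set.seed(82)
  state <- sacecrt:::init_state(data, sace_priors(), FALSE)
  tuning <- mh_tuning(s_beta = 2.38^2 / 3, s_gamma = 2.38^2 / 3,
                      T_beta = diag(0.05, 3), T_gamma = diag(0.05, 3))
  for (i in 1:40) {
    out <- sacecrt:::mcmc_step(data, state, sace_priors(), tuning, FALSE)
    state <- out[c("g", "sp", "op")]
    expect_true(memberships_admissible(data,
                                       c("00", "10", "11")[state$g]))
  }
})

test_that("adapted acceptance rates land in a healthy band", {
  sim <- simulate_crt(sim_config(), seed = 91)
  fit <- run_chain(sim$data, sace_config(iterations = 1500, burn_in = 500,
                                         chains = 1), seed = 92)
  expect_gte(fit$accept[["beta"]], 0.1)
  expect_lte(fit$accept[["beta"]], 0.5)
  expect_gte(fit$accept[["gamma"]], 0.1)
  expect_lte(fit$accept[["gamma"]], 0.5)
})

test_that("the clustered strata model runs and warns on size-1 clusters", {
  cfg_sim <- sim_config(m = 6, n_clusters = 10, strata_icc = 0.1)
  sim <- simulate_crt(cfg_sim, seed = 101)
  fit <- run_chain(sim$data,
                   sace_config(iterations = 150, burn_in = 50,
                               strata_clustering = TRUE), seed = 102)
  expect_true("phi2" %in% colnames(fit$draws))
  expect_true(all(fit$draws[, "phi2"] > 0))

  df <- sim$data$df
  df <- df[-(which(df$cluster == 1)[-1]), ]  # shrink cluster 1 to one row
  data1 <- crt_data(df, covariates = c("X1", "X2"))
  expect_warning(
    run_chain(data1, sace_config(iterations = 60, burn_in = 20,
                                 strata_clustering = TRUE), seed = 103),
    "single participant")
})
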