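test_that("outcome log-density is the stated normal log-density", {
  op <- outcome_params(c(1.5, 0.5, 0.8), c(0.2, 0.3, 0.6), c(-1.5, 0.9, 0.5),
                       eta = c(0.1, -0.3), sigma2 = 5, tau2 = 1)
  # zero residual: y exactly at the cell mean
  x <- c(1, 1, 0)
  mu <- sum(x * c(1.5, 0.5, 0.8)) + 0.1
  expect_equal(outcome_log_density(mu, x, arm = 1, stratum = "11", op, 1),
               -0.5 * log(2 * pi * 5), tolerance = 1e-12)
  # unit residual at unit variance
  op1 <- outcome_params(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0), eta = c(0, 0),
                        sigma2 = 1, tau2 = 1)
  expect_equal(outcome_log_density(1, c(1, 0, 0), 1, "11", op1, 1),
               -0.5 * log(2 * pi) - 0.5, tolerance = 1e-12)
  # frozen from direct evaluation: residual 2 - 2.1, variance 5
  expect_equal(outcome_log_density(2, x, 1, "11", op, 1),
               -1.724657489, tolerance = 1e-8)
  # unmodeled cells are errors, not zero densities
  expect_error(outcome_log_density(1, x, 1, "00", op, 1), "no outcome model")
  expect_error(outcome_log_density(1, x, 0, "10", op, 1), "no outcome model")
})

test_that("coefficient Gibbs draws match the closed-form ridge posterior", {
  # 5-row fixture, p = 2, all rows in the (11, treated) cell
  df <- data.frame(cluster = rep(1:2, c(3, 2)), D = 1, S = 1,
                   Y = c(1.2, -0.4, 0.8, 2.1, 0.3),
                   X1 = c(0.5, -1.0, 0.2, 1.5, -0.7))
  data <- make_manual_data(df)
  g <- rep("11", 5)
  eta <- c(0.3, -0.2)
  sigma2 <- 2
  prior_var <- 10
  op <- outcome_params(c(0, 0), c(0, 0), c(0, 0), eta = eta,
                       sigma2 = sigma2, tau2 = 1)
  priors <- sace_priors(coef_prior_var = prior_var)

  # independent dense-solve oracle for the conditional mean and covariance
  X <- cbind(1, df$X1)
  z <- df$Y - eta[data$cluster]
  P <- t(X) %*% X / sigma2 + diag(1 / prior_var, 2)
  m_oracle <- solve(P, t(X) %*% z / sigma2)
  V_oracle <- solve(P)

  set.seed(42)
  draws <- t(replicate(4000, {
    gibbs_update_coefficients(data, g, op, priors)$alpha_11_1
  }))
  mc_se <- sqrt(diag(V_oracle) / 4000)
  expect_true(all(abs(colMeans(draws) - m_oracle) < 3 * mc_se))
  expect_equal(cov(draws), V_oracle, tolerance = 0.1)

  # cells with no rows fall back to the prior
  set.seed(43)
  prior_draws <- t(replicate(4000, {
    gibbs_update_coefficients(data, g, op, priors)$alpha_10_1
  }))
  expect_true(all(abs(colMeans(prior_draws)) <
                    3 * sqrt(prior_var / 4000)))
  expect_equal(apply(prior_draws, 2, var), rep(prior_var, 2),
               tolerance = 0.15)
})

test_that("flat-prior coefficient posterior approaches least squares", {
  df <- data.frame(cluster = 1:6, D = 1, S = 1,
                   Y = c(2.0, 1.1, -0.5, 0.8, 1.9, 0.2),
                   X1 = c(1.2, -0.3, 0.5, -1.1, 0.9, 0.1))
  data <- make_manual_data(df)
  op <- outcome_params(c(0, 0), c(0, 0), c(0, 0), eta = rep(0, 6),
                       sigma2 = 1, tau2 = 1e8)
  priors <- sace_priors(coef_prior_var = 1e10)
  set.seed(1)
  draws <- t(replicate(3000, {
    gibbs_update_coefficients(data, rep("11", 6), op, priors)$alpha_11_1
  }))
  ols <- unname(coef(lm(Y ~ X1, df)))
  expect_equal(colMeans(draws), ols, tolerance = 0.05)
})

test_that("cluster-effect Gibbs update follows the stated formulas", {
  # cluster 1: 4 observed rows engineered so residuals sum to 2 with
  # sigma2 = 2, tau2 = 1 -> posterior N(1/3, 1/3)
  # cluster 2: no observed rows -> prior N(0, tau2)
  df <- data.frame(cluster = rep(1:2, c(4, 2)), D = rep(c(1, 0), c(4, 2)),
                   S = rep(c(1, 0), c(4, 2)),
                   Y = c(0.5, 0.5, 0.5, 0.5, NA, NA),
                   X1 = 0)
  data <- make_manual_data(df)
  g <- c(rep("11", 4), rep("00", 2))
  op <- outcome_params(c(0, 0), c(0, 0), c(0, 0), eta = c(0, 0),
                       sigma2 = 2, tau2 = 1)
  set.seed(8)
  draws <- t(replicate(4000, {
    gibbs_update_cluster_effects(data, g, op)$eta
  }))
  expect_equal(mean(draws[, 1]), 1 / 3, tolerance = 3 * sqrt(1 / 3 / 4000))
  expect_equal(var(draws[, 1]), 1 / 3, tolerance = 0.05)
  expect_equal(mean(draws[, 2]), 0, tolerance = 3 * sqrt(1 / 4000))
  expect_equal(var(draws[, 2]), 1, tolerance = 0.1)
})

test_that("variance Gibbs updates use the conjugate inverse-gamma laws", {
  # two observed residuals (1, -1) with alpha = 0, eta = 0 -> SSR = 2;
  # sigma2 ~ InvGamma(0.01 + 1, 0.01 + 1)
  df <- data.frame(cluster = c(1, 1, 2), D = c(1, 1, 0), S = c(1, 1, 0),
                   Y = c(1, -1, NA), X1 = 0)
  data <- make_manual_data(df)
  g <- c("11", "11", "00")
  op <- outcome_params(c(0, 0), c(0, 0), c(0, 0), eta = c(0, 0),
                       sigma2 = 1, tau2 = 1)
  priors <- sace_priors(ig_shape = 0.01, ig_rate = 0.01)
  set.seed(21)
  draws <- replicate(6000, {
    gibbs_update_variances(data, g, op, priors)$sigma2
  })
  expect_true(all(draws > 0))
  # InvGamma(1.01, 1.01): mean of 1/sigma2 is shape/rate = 1
  expect_equal(mean(1 / draws), 1.01 / 1.01,
               tolerance = 3 * sqrt(1.01 / 1.01^2 / 6000))

  # eta identically zero over I clusters -> tau2 ~ InvGamma(a + I/2, b)
  set.seed(22)
  tdraws <- replicate(6000, {
    gibbs_update_variances(data, g, op, priors)$tau2
  })
  expect_true(all(tdraws > 0))
  expect_equal(mean(1 / tdraws), (0.01 + 1) / 0.01, tolerance = 3)
})

test_that("outcome ICC is the variance ratio", {
  expect_equal(outcome_icc(1, 5), 1 / 6, tolerance = 1e-12)
  expect_equal(outcome_icc(1e-12, 5), 0, tolerance = 1e-9)
  expect_equal(outcome_icc(5, 1e-12), 1, tolerance = 1e-9)
  expect_error(outcome_icc(0, 1), "tau2")
  expect_error(outcome_icc(1, -1), "sigma2")
})
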