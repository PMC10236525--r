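#' Principal-strata membership parameters
#'
#' Container for the multinomial logistic model of principal-stratum
#' membership. Always-survivors (`G = 11`) are the reference category:
#' `beta` holds the log-odds-ratio coefficients of never-survivors (`00`)
#' versus always-survivors and `gamma` those of the protected stratum (`10`)
#' versus always-survivors. Optionally a shared cluster-level random intercept
#' `chi[i] ~ N(0, phi2)` enters both non-reference linear predictors.
#'
#' @param beta,gamma Numeric coefficient vectors of equal length `p`; the
#'   first element multiplies the intercept column of the design matrix.
#' @param chi Optional numeric vector of per-cluster intercepts.
#' @param phi2 Variance of `chi`; required (and `> 0`) when `chi` is given.
#' @return An object of class `strata_params`.
#' @export
strata_params <- function(beta, gamma, chi = NULL, phi2 = NULL) {
  beta <- as.numeric(beta); gamma <- as.numeric(gamma)
  if (length(beta) != length(gamma)) {
    stop("beta and gamma must have the same length")
  }
  if (!all(is.finite(beta)) || !all(is.finite(gamma))) {
    stop("strata coefficients must be finite")
  }
  if (!is.null(chi)) {
    if (is.null(phi2) || !is.finite(phi2) || phi2 <= 0) {
      stop("phi2 must be a positive number when chi is present")
    }
    chi <- as.numeric(chi)
    if (!all(is.finite(chi))) stop("chi must be finite")
  }
  structure(list(beta = beta, gamma = gamma, chi = chi, phi2 = phi2),
            class = "strata_params")
}

# Log-probability matrix of stratum membership for a design matrix.
# Columns: log p00, log p10, log p11. Log-sum-exp with max subtraction keeps
# the computation finite for linear predictors up to +/- ~700.
strata_log_probs <- function(X, params, cluster = NULL) {
  p <- length(params$beta)
  if (ncol(X) != p) {
    stop("design matrix has ", ncol(X), " columns but coefficients length ", p)
  }
  a <- drop(X %*% params$beta)   # 00 vs 11
  b <- drop(X %*% params$gamma)  # 10 vs 11
  if (!is.null(params$chi)) {
    if (is.null(cluster)) stop("cluster index required when chi is present")
    a <- a + params$chi[cluster]
    b <- b + params$chi[cluster]
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("non-finite linear predictor in strata model")
  }
  m <- pmax(a, b, 0)
  log_den <- m + log(exp(-m) + exp(a - m) + exp(b - m))
  cbind(`00` = a - log_den, `10` = b - log_den, `11` = -log_den)
}

#' Stratum membership probabilities for one participant
#'
#' Evaluates the three-category multinomial logistic model
#' `P(G = 00) = e^a / (1 + e^a + e^b)`, `P(G = 10) = e^b / (1 + e^a + e^b)`,
#' `P(G = 11) = 1 / (1 + e^a + e^b)` with `a = x'beta (+ chi_i)` and
#' `b = x'gamma (+ chi_i)`, computed on the log scale so large linear
#' predictors do not overflow.
#'
#' @param x Covariate row (first element must be the constant 1).
#' @param params A [strata_params] object.
#' @param cluster_index Cluster index of the participant; required when
#'   `params` carries cluster intercepts.
#' @return Named numeric vector `c(p00, p10, p11)` summing to one.
#' @examples
#' stratum_probabilities(c(1, 0, 0), strata_params(rep(0, 3), rep(0, 3)))
#' @export
stratum_probabilities <- function(x, params, cluster_index = NULL) {
  x <- as.numeric(x)
  if (abs(x[1] - 1) > 0) stop("first element of x must be the constant 1")
  if (!all(is.finite(x))) stop("covariate row must be finite")
  lp <- strata_log_probs(matrix(x, nrow = 1), params, cluster = cluster_index)
  p <- exp(drop(lp))
  names(p) <- c("p00", "p10", "p11")
  p
}

#' Log-likelihood of a latent membership configuration
#'
#' Sums, over participants, the log of the stratum probability the membership
#' model assigns to each participant's current latent label. This is the
#' Metropolis target (up to the prior) for the strata coefficients.
#'
#' @param memberships Character vector of labels in `c("00", "10", "11")`,
#'   one per row of `data`.
#' @param data A [crt_data] object.
#' @param params A [strata_params] object.
#' @return A scalar log-likelihood (always `<= 0`); `-Inf` only if some
#'   assigned probability underflows to zero.
#' @export
membership_log_likelihood <- function(memberships, data, params) {
  g <- membership_codes(memberships)
  lp <- strata_log_probs(data$X, params, cluster = data$cluster)
  sum(pmax(lp[cbind(seq_along(g), g)], log(1e-300)))
}

# "00"/"10"/"11" -> 1/2/3 with validation
membership_codes <- function(memberships) {
  g <- match(as.character(memberships), c("00", "10", "11"))
  if (anyNA(g)) stop("memberships must be '00', '10' or '11'")
  g
}

#' Convert a latent-scale ICC to a random-intercept variance
#'
#' On the latent response scale of a logistic model the residual variance is
#' `pi^2 / 3`, so an intracluster correlation `icc` for stratum membership
#' corresponds to a cluster-intercept variance
#' `phi2 = icc / (1 - icc) * pi^2 / 3`.
#'
#' @param icc Intracluster correlation on the latent scale, in `[0, 1)`.
#' @return The implied variance `phi2 >= 0`.
#' @export
latent_icc_to_phi2 <- function(icc) {
  if (!is.finite(icc) || icc < 0 || icc >= 1) stop("icc must lie in [0, 1)")
  icc / (1 - icc) * pi^2 / 3
}
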