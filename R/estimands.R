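#' SACE draw from a membership/parameter state
#'
#' Given the current latent memberships and outcome parameters, computes the
#' survivor-average-causal-effect draw over the finite always-survivor set:
#' `ybar1` and `ybar0` are the means of the two counterfactual linear
#' predictors `x'alpha + eta_i` over rows currently labeled `11`, and
#' `delta = ybar1 - ybar0`. Using linear predictors rather than posterior-
#' predictive outcome draws removes the residual Monte-Carlo noise without
#' changing the posterior mean; the shared cluster effect cancels in `delta`.
#'
#' @param data A [crt_data] object.
#' @param memberships Character membership labels.
#' @param outcome_params An [outcome_params] object.
#' @return A list with `delta`, `ybar1`, `ybar0` (all `NA` when no row is
#'   currently an always-survivor).
#' @export
sace_draw <- function(data, memberships, outcome_params) {
  g <- membership_codes(memberships)
  idx <- which(g == 3L)
  if (length(idx) == 0L) {
    return(list(delta = NA_real_, ybar1 = NA_real_, ybar0 = NA_real_))
  }
  X <- data$X[idx, , drop = FALSE]
  e <- outcome_params$eta[data$cluster[idx]]
  ybar1 <- mean(drop(X %*% outcome_params$alpha_11_1) + e)
  ybar0 <- mean(drop(X %*% outcome_params$alpha_11_0) + e)
  list(delta = ybar1 - ybar0, ybar1 = ybar1, ybar0 = ybar0)
}

#' Stratum proportions of a membership state
#'
#' @param memberships Character membership labels.
#' @return Named vector `c(prop00, prop10, prop11)` of empirical shares,
#'   summing to one.
#' @export
strata_proportion_draw <- function(memberships) {
  g <- membership_codes(memberships)
  p <- tabulate(g, 3L) / length(g)
  names(p) <- c("prop00", "prop10", "prop11")
  p
}

#' Posterior baseline profile of the always-survivors
#'
#' For each baseline covariate: the across-draw average of the within-draw
#' covariate mean over rows labeled always-survivors. A byproduct of the
#' augmentation — the latent stratum is a pre-treatment characteristic, so
#' this describes who the always-survivors are.
#'
#' @param fit A [sace_fit] object.
#' @return Named numeric vector, one entry per covariate.
#' @export
always_survivor_profile <- function(fit) {
  stopifnot(inherits(fit, "sace_fit"))
  cols <- grep("^as_mean\\[", colnames(fit$draws), value = TRUE)
  out <- colMeans(fit$draws[, cols, drop = FALSE], na.rm = TRUE)
  names(out) <- sub("^as_mean\\[(.*)\\]$", "\\1", cols)
  out
}

#' Posterior summary of a draw sequence
#'
#' Posterior mean and central 95% credible interval (empirical 2.5% and
#' 97.5% percentiles, linear interpolation). `NA` draws (e.g. iterations with
#' an empty always-survivor set) are dropped.
#'
#' @param draws Numeric vector of posterior draws (at least 2 non-missing).
#' @return Named vector `c(point, lower, upper)`.
#' @export
posterior_summary <- function(draws) {
  draws <- draws[!is.na(draws)]
  if (length(draws) < 2L) stop("need at least two draws to summarize")
  q <- stats::quantile(draws, c(0.025, 0.975), names = FALSE, type = 7)
  c(point = mean(draws), lower = q[1], upper = q[2])
}

#' Posterior estimand table
#'
#' Summarizes the fitted model's headline quantities — SACE, the two
#' counterfactual means among always-survivors, the three stratum
#' proportions, and the outcome ICC — and optionally appends the
#' complete-case linear mixed-model treatment effect for contrast. The
#' comparator conditions on observed survival and therefore mixes principal
#' strata; it lacks the causal interpretation the SACE has.
#'
#' @param fit A [sace_fit] object.
#' @param comparator Logical: append the complete-case LMM row (default
#'   `TRUE`).
#' @return A data.frame with columns `estimand`, `point`, `lower`, `upper`.
#' @export
sace_summary <- function(fit, comparator = TRUE) {
  stopifnot(inherits(fit, "sace_fit"))
  rows <- c(SACE = "delta", `Ybar(1)` = "ybar1", `Ybar(0)` = "ybar0",
            `Proportion never-survivors` = "prop00",
            `Proportion protected` = "prop10",
            `Proportion always-survivors` = "prop11",
            ICC = "rho")
  tab <- t(vapply(rows, function(cn) posterior_summary(fit$draws[, cn]),
                  numeric(3)))
  out <- data.frame(estimand = names(rows), point = tab[, 1],
                    lower = tab[, 2], upper = tab[, 3])
  if (isTRUE(comparator)) {
    cc <- complete_case_lmm(fit$data)
    out <- rbind(out, data.frame(estimand = "Complete-case LMM",
                                 point = cc$estimate, lower = cc$lower,
                                 upper = cc$upper))
  }
  rownames(out) <- NULL
  out
}

#' @export
summary.sace_fit <- function(object, ...) sace_summary(object, ...)

#' Complete-case linear mixed-model comparator
#'
#' The analysis a practitioner might run absent the principal-stratification
#' machinery: a linear mixed model on survivors only, regressing the outcome
#' on treatment and the baseline covariates with a cluster random intercept.
#' Provided for contrast in reports; because the survivor set differs by arm
#' it has no causal interpretation under truncation by death.
#'
#' @param data A [crt_data] object.
#' @return A list with the treatment `estimate`, Wald 95% `lower`/`upper`
#'   bounds, and its standard error.
#' @export
complete_case_lmm <- function(data) {
  stopifnot(inherits(data, "crt_data"))
  idx <- data$S == 1
  df <- data.frame(y = data$Y[idx], D = data$D[idx],
                   cl = data$cluster[idx],
                   data$X[idx, -1, drop = FALSE], check.names = FALSE)
  fml <- stats::reformulate(c("D", sprintf("`%s`", data$covariates),
                              "(1 | cl)"), response = "y")
  fit <- lme4::lmer(fml, data = df, REML = TRUE)
  est <- lme4::fixef(fit)[["D"]]
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))[["D"]]
  list(estimate = est, lower = est - 1.96 * se, upper = est + 1.96 * se,
       se = se)
}
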