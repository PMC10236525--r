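#' Replicated-trial recovery study
#'
#' The simulation harness: generates `reps` synthetic trials from `config`,
#' fits each with the joint Bayesian model, and reports — per tracked
#' parameter — the truth, the average posterior mean, the percent relative
#' bias `100 * (mean posterior mean - truth) / truth`, the empirical
#' coverage of the 95% credible intervals, and a Monte-Carlo standard error
#' of the average posterior mean. The SACE truth comes from
#' [true_sace_oracle()]; stratum-proportion truths from
#' [marginal_strata_proportions()]; coefficient and ICC truths directly from
#' `config`.
#'
#' @param config A [sim_config] object (the data-generating process).
#' @param run_config A [sace_config] object used for every fit; defaults to
#'   a single chain of 2000 iterations with 500 burn-in, the harness's
#'   reduced-scale setting.
#' @param reps Number of replicated trials (at least 2; default 30).
#' @param seed Integer master seed; replicate `r` simulates with
#'   `seed + r` and fits with `seed + 10000 + r`.
#' @param oracle_draws Monte-Carlo size for the SACE truth (default `1e6`).
#' @return An object of class `recovery_report`: a data.frame with one row
#'   per parameter (columns `parameter`, `truth`, `mean_posterior_mean`,
#'   `pct_bias`, `coverage`, `mc_se`), with attributes `reps` (completed),
#'   `failures`, and `oracle` (the SACE oracle output).
#' @export
run_recovery_study <- function(config, run_config = NULL, reps = 30,
                               seed = 1L, oracle_draws = 1e6) {
  stopifnot(inherits(config, "sim_config"), reps >= 2)
  if (is.null(run_config)) {
    run_config <- sace_config(iterations = 2000, burn_in = 500, chains = 1)
  }
  oracle <- true_sace_oracle(config, n_draws = oracle_draws, seed = seed)
  props <- marginal_strata_proportions(config, n_draws = oracle_draws,
                                       seed = seed)
  p <- length(config$beta)
  truth <- c(delta = oracle$value,
             rho = outcome_icc(config$tau2, config$sigma2),
             stats::setNames(config$alpha_11_1,
                             paste0("alpha_11_1[", 1:p, "]")),
             stats::setNames(config$alpha_11_0,
                             paste0("alpha_11_0[", 1:p, "]")),
             stats::setNames(config$alpha_10_1,
                             paste0("alpha_10_1[", 1:p, "]")),
             prop00 = unname(props["p00"]), prop10 = unname(props["p10"]),
             prop11 = unname(props["p11"]))

  draw_cols <- function(d) {
    cn <- colnames(d)
    # map report names to draw-matrix column names
    map <- names(truth)
    map[map == "delta"] <- "delta"; map[map == "rho"] <- "rho"
    alpha_cols <- grep("^alpha_", cn, value = TRUE)
    map[grep("^alpha_", names(truth))] <- alpha_cols
    map
  }

  post_means <- covered <- NULL
  failures <- 0L
  for (r in seq_len(reps)) {
    res <- tryCatch({
      sim <- simulate_crt(config, seed = seed + r)
      fit <- sace_fit(sim$data, run_config, seed = seed + 10000L + r)
      cols <- draw_cols(fit$draws)
      pm <- vapply(cols, function(cn) mean(fit$draws[, cn], na.rm = TRUE),
                   numeric(1))
      ci <- vapply(cols, function(cn) {
        stats::quantile(fit$draws[, cn][!is.na(fit$draws[, cn])],
                        c(0.025, 0.975), names = FALSE)
      }, numeric(2))
      cov <- as.numeric(truth >= ci[1, ] & truth <= ci[2, ])
      list(pm = pm, cov = cov)
    }, error = function(e) {
      message("replicate ", r, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) {
      failures <- failures + 1L
      if (failures > 0.2 * reps) {
        stop("more than 20% of replicates failed; aborting")
      }
      next
    }
    post_means <- rbind(post_means, res$pm)
    covered <- rbind(covered, res$cov)
  }

  mpm <- colMeans(post_means)
  report <- data.frame(
    parameter = names(truth),
    truth = unname(truth),
    mean_posterior_mean = unname(mpm),
    pct_bias = unname(100 * (mpm - truth) / truth),
    coverage = unname(colMeans(covered)),
    mc_se = unname(apply(post_means, 2, stats::sd) / sqrt(nrow(post_means)))
  )
  attr(report, "reps") <- nrow(post_means)
  attr(report, "failures") <- failures
  attr(report, "oracle") <- oracle
  class(report) <- c("recovery_report", "data.frame")
  report
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery study over", attr(x, "reps"), "replicates (",
      attr(x, "failures"), "failures )\n")
  cat("SACE oracle truth:", signif(attr(x, "oracle")$value, 5),
      "(MC se", signif(attr(x, "oracle")$se, 3), ")\n\n")
  df <- as.data.frame(x)
  df$truth <- signif(df$truth, 4)
  df$mean_posterior_mean <- signif(df$mean_posterior_mean, 4)
  df$pct_bias <- round(df$pct_bias, 2)
  df$mc_se <- signif(df$mc_se, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
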