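# sacecrt

Bayesian estimation of the **survivor average causal effect (SACE)** in
two-arm **cluster-randomized trials (CRTs)** where a nonmortality outcome —
quality of life, a functional score — is **truncated by death**: undefined,
not merely missing, for participants who die before it is measured.

Comparing observed survivors between arms is not a causal comparison,
because treatment changes who survives. `sacecrt` targets the estimand that
remains well-defined without extra assumptions: the mean treatment effect
among *always-survivors*, the principal stratum of participants who would
survive under either assignment,

δ = E[ Y(1) − Y(0) | G = 11 ].

It is written for biostatisticians analyzing CRTs with non-trivial
mortality, and for methodologists who want a transparent, fully seeded
reference implementation with a built-in simulation laboratory.

## The model

Under monotonicity (treatment never worsens survival) each participant
belongs to one of three latent strata — always-survivors (`11`), protected
(`10`, survive only if treated), never-survivors (`00`). Membership follows
multinomial logistic regression with always-survivors as reference:

    P(G=00) = exp(x'β) / (1 + exp(x'β) + exp(x'γ))
    P(G=10) = exp(x'γ) / (1 + exp(x'β) + exp(x'γ))

optionally with a shared cluster intercept χ_i ~ N(0, φ²). Potential
outcomes in the three observable (stratum, arm) cells follow linear mixed
models with a shared cluster effect and common residual variance,

    Y(d) = N( x' α_d^g + η_i , σ² ),   η_i ~ N(0, τ²),

so the outcome ICC is ρ = τ² / (τ² + σ²). Inference is a data-augmentation
MCMC: latent memberships are drawn from their exact conditionals (the
observed groups that monotonicity pins down stay deterministic), outcome
parameters by
conjugate Gibbs steps, and the strata coefficients by adaptive random-walk
Metropolis with multivariate-t proposals tuned from the burn-in history.
See the methods vignette (`vignettes/sace-in-crts.Rmd`) for assumptions,
tuning parameters, initialization, and known limitations.

## Worked example

Simulate the package's benchmark trial (100 clusters of 15, ~35% of
outcomes truncated by death), fit the joint model with two chains, and
compare against the generating truth:

```r
library(sacecrt)

cfg <- sim_config()                      # benchmark generating process
sim <- simulate_crt(cfg, seed = 42)
true_sace_oracle(cfg, n_draws = 1e6, seed = 42)$value
#> [1] 0.9228  (Monte-Carlo truth of this generating process)

fit <- sace_fit(sim$data, sace_config(iterations = 2000, burn_in = 500,
                                      chains = 2), seed = 1)
fit
#> <sace_fit> 2 chain(s) x 1500 retained draws
#>   MH acceptance: beta 0.232, gamma 0.15
#>   split-Rhat (key parameters): delta = 1, rho = 1, sigma2 = 1.003, tau2 = 1
#>                     estimand      point       lower      upper
#>                         SACE  0.6628771  0.13040045  1.1709352
#>                      Ybar(1)  0.1125975 -0.27066744  0.4606865
#>                      Ybar(0) -0.5502796 -0.82745974 -0.2762550
#>   Proportion never-survivors  0.2203220  0.20133333  0.2393333
#>         Proportion protected  0.2689604  0.23731667  0.3000000
#>  Proportion always-survivors  0.5107176  0.49333333  0.5280000
#>                          ICC  0.1276512  0.07292949  0.1953959
```

The SACE posterior mean is 0.66 with 95% credible interval (0.13, 1.17),
covering this generating process's true value 0.92; the posterior stratum
shares track the generator's 21.1 / 26.5 / 52.4 percent split, and the ICC
posterior brackets the true 0.167. The complete-case mixed model on
survivors — `complete_case_lmm(sim$data)` — returns −0.07 (95% CI −0.53,
0.38) for the same data: conditioning on observed survival mixes protected
individuals (whose treated outcomes are systematically lower here) into
the treated arm, wiping out the causal contrast. `always_survivor_profile(fit)`
reports who the always-survivors are at baseline (here X1 ≈ −0.69,
X2 ≈ −1.33: survival is selective on both covariates).

A simulation harness repeats simulate-and-fit to measure calibration:

```r
run_recovery_study(sim_config(), sace_config(iterations = 2000,
                   burn_in = 500, chains = 1), reps = 30, seed = 1)
```

reporting truth, average posterior mean, % bias, and 95% credible-interval
coverage per parameter. A thin command-line front end with verbs
`simulate`, `fit`, `recover` lives at `inst/cli/sacecrt` (YAML configs;
CSV outputs).

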