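---
title: "Estimating the survivor average causal effect in cluster-randomized trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the survivor average causal effect in cluster-randomized trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

In trials among the elderly or seriously ill, a nonmortality outcome such as
quality of life is undefined — not merely missing — for participants who die
before it is measured. Comparing observed survivors between arms is then not
a causal comparison: survival itself responds to treatment, so the treated
and control survivor populations differ. Principal stratification resolves
this by classifying participants by the joint pair of potential survival
statuses $(S_{ij}(1), S_{ij}(0))$, a pre-treatment characteristic. Under
*monotonicity* (treatment never worsens survival) three strata remain:

* always-survivors, $G_{ij} = 11$: survive under either assignment;
* protected, $G_{ij} = 10$: survive only if treated;
* never-survivors, $G_{ij} = 00$: die under either assignment.

Only always-survivors have both potential outcomes defined, so the target
estimand is the survivor average causal effect

$$\delta = E\{Y_{ij}(1) - Y_{ij}(0) \mid G_{ij} = 11\}.$$

Cluster randomization adds a second complication: outcomes are correlated
within clusters, and ignoring the intracluster correlation coefficient (ICC)
inflates type-I error. `sacecrt` estimates $\delta$ in two-arm
cluster-randomized trials (CRTs) by a joint Bayesian mixture model that
accounts for both truncation by death and clustering.

## The model

**Membership.** With covariate row $X_{ij}$ (intercept first) and
always-survivors as the reference category,

$$P(G_{ij}=00) = \frac{e^{X_{ij}^\top\beta}}{1+e^{X_{ij}^\top\beta}+e^{X_{ij}^\top\gamma}},\qquad
  P(G_{ij}=10) = \frac{e^{X_{ij}^\top\gamma}}{1+e^{X_{ij}^\top\beta}+e^{X_{ij}^\top\gamma}},$$

with $P(G_{ij}=11)$ the remainder. Each component of $\beta$ and $\gamma$ is
a log odds ratio against the always-survivor stratum. Optionally a
cluster-level random intercept $\chi_i \sim N(0, \phi^2)$ can be added for
correlated membership within clusters. Where exactly such an intercept
enters is genuinely open when only one variance $\phi^2$ is carried; this
package adds the *same* $\chi_i$ to both non-reference linear predictors — a
shared deviation of the non-always-survivor log-odds — which keeps a single
variance parameter and a clean latent-scale ICC interpretation via
$\phi^2/(\phi^2 + \pi^2/3)$ (`latent_icc_to_phi2()` converts the other way).

**Outcomes.** Three (stratum, arm) cells carry a linear mixed model with a
shared cluster effect and common residual variance:

| stratum | treated | control |
|---|---|---|
| always-survivors | $Y_{ij}(1) = N(X_{ij}^\top\alpha_1^{11} + \eta_i, \sigma^2)$ | $Y_{ij}(0) = N(X_{ij}^\top\alpha_0^{11} + \eta_i, \sigma^2)$ |
| protected | $Y_{ij}(1) = N(X_{ij}^\top\alpha_1^{10} + \eta_i, \sigma^2)$ | — |
| never-survivors | — | — |

with $\eta_i \sim N(0, \tau^2)$ and outcome ICC
$\rho = \tau^2 / (\tau^2 + \sigma^2)$. Using one $\eta_i$ and one $\sigma^2$
across cells is a deliberate parsimony: stratum-specific variances would be
weakly identified in the truncated cells.

**Identification.** Under monotonicity the observed $(D, S)$ pairs pin down
membership for two of the four observed groups (control survivors are
always-survivors; treated deaths are never-survivors); the other two groups
are two-component mixtures. Control survivors anchor $\alpha_0^{11}$
directly, and the membership model transports that anchor to the treated
arm through the covariates.

## Posterior computation

Each MCMC sweep performs, in order:

1. **Membership augmentation.** Deterministic rows are set; a treated
   survivor is always-survivor with probability
   $p_{11} N(y \mid X^\top\alpha_1^{11}+\eta_i, \sigma^2)$ over the
   two-component sum against
   $p_{10} N(y \mid X^\top\alpha_1^{10}+\eta_i, \sigma^2)$; a control death
   is protected with probability $p_{10}/(p_{10}+p_{00})$ (the outcome is
   truncated, so no outcome-density term exists).
2. **Conjugate Gibbs updates** of the three coefficient vectors (ridge-form
   multivariate-normal conditionals; empty cells draw from the prior so the
   chain stays irreducible), the cluster effects, and the two variances
   (inverse gamma).
3. **Adaptive random-walk Metropolis** for $\beta$ then $\gamma$ as separate
   blocks, using symmetric multivariate-$t$ proposals centred at the current
   value with scale $s_\beta T_\beta$ (resp. $s_\gamma T_\gamma$).
4. Optionally, scalar random-walk updates of each $\chi_i$ (the membership
   likelihood factorizes over clusters, so these are independent
   one-dimensional walks, which mix better than a joint $I$-dimensional
   block when clusters are small) followed by a conjugate draw of $\phi^2$.
5. **Estimand recording** (after burn-in): the SACE draw, counterfactual
   means, stratum shares, and ICC, computed from the *current* memberships
   and parameters.

**Proposal tuning.** $T$ is tuned to the empirical covariance of past
draws plus $10^{-6} I$ (Haario-style), and $s$ — initialized at the
classical $2.38^2/p$ — is multiplied by
$\exp(\text{acceptance} - \text{target})$ at each adaptation event
(target 0.234). Adaptation starts at iteration 200, repeats every 100, and
is frozen at the end of burn-in so the retained chain is a fixed Markov
kernel. Only the trailing half of the history enters the covariance: the
initial transient otherwise inflates $T$ and depresses acceptance. The
proposal uses $t_4$ tails — heavy enough to escape local modes, with finite
variance so adaptation is stable. A degenerate history (no variation)
leaves $T$ unchanged and halves $s$.

**Initialization.** The treated-survivor mixture posterior has a
label-swapped local mode — the two outcome components exchange roles, with
the "protected" intercept taking the always-survivors' place — and chains
started from unseparated components can fall into it by chance and stay
for many thousands of iterations. Initialization therefore chooses the
membership-consistent pairing deliberately, using only observed data:
membership probabilities for the ambiguous rows come from logistic fits of
survival on covariates in the control arm (which identifies
$P(G=11 \mid x)$) and of death in the treated arm (identifying
$P(G=00 \mid x)$), and a short EM pass for the two-component regression
mixture among treated survivors — with those anchored probabilities as
per-row prior weights — separates the two cells in the direction the
membership model supports. Latent labels are then drawn from the EM
responsibilities, coefficients start at per-cell least squares with small
jitter, $\beta, \gamma$ at $N(0, 0.1^2)$ jitter around zero, and variances
at residual moments. All randomness flows from one integer seed, so runs
are exactly reproducible; `sace_fit()` runs multiple chains from
consecutive seeds and reports split-$\widehat R$, which is also the
diagnostic that exposes the swapped mode if it is ever visited.

**Priors.** The defaults are diffuse proper priors: $N(0, 10^4)$ per
regression coefficient (also used as the Metropolis prior for $\beta,
\gamma$, keeping the target proper) and inverse gamma $(0.01, 0.01)$ for
$\sigma^2$, $\tau^2$, $\phi^2$. These hyperparameters are package decisions
— reasonable defaults for outcomes on a scale of a few units — and are
configurable through `sace_priors()`; informative ICC priors are not
implemented.

**Numerical policy.** Stratum probabilities are computed on the log scale
with max-subtraction, so linear predictors up to $\pm 700$ neither overflow
nor produce `NaN`; probabilities are floored at $10^{-300}$ before logging.
If both mixture components underflow for a treated survivor (an outcome
hundreds of residual SDs from both cell means), the row is assigned by the
membership probabilities alone with a warning. An iteration whose
always-survivor set is empty yields a missing SACE draw, excluded from
summaries with a logged count.

## Estimand conventions

The SACE draw uses the finite-sample always-survivor set of the current
iteration and the *linear predictor* contrast
$\overline{X^\top(\alpha_1^{11} - \alpha_0^{11})}$: the shared $\eta_i$
cancels, and relative to posterior-predictive outcome draws this removes
residual noise from each draw without changing the posterior mean.
$\bar Y(1)$ and $\bar Y(0)$ are likewise averaged over always-survivors
only, so $\delta = \bar Y(1) - \bar Y(0)$ holds draw by draw. The
complete-case comparator (`complete_case_lmm()`, an `lme4` fit on survivors
adjusting for treatment and covariates) is reported alongside for contrast;
it conditions on post-treatment survival and has no causal interpretation.

## The synthetic generator and what it does (not) emulate

`simulate_crt()` draws the full counterfactual table — stratum, both
potential outcomes where defined — and masks it by the realized cluster
assignment, so the observed data are a deterministic function of the truth
and every replicate carries its own ground truth. The default configuration
is the package's benchmark: 100 clusters of 15 (1,500 participants, 1:1
cluster allocation), $X_1 \sim N(0, 4)$ (variance 4), $X_2 \sim
\mathrm{Unif}(-5, 5)$, $\beta = (-1, 0.3, 0.5)$, $\gamma = (-0.8, 0.6,
0.4)$ — marginal stratum shares of about 21.1% never-survivors, 26.5%
protected, 52.4% always-survivors — $\alpha_1^{11} = (1.5, 0.5, 0.8)$,
$\alpha_0^{11} = (0.2, 0.3, 0.6)$, $\alpha_1^{10} = (-1.5, 0.9, 0.5)$,
$\sigma^2 = 5$, $\tau^2 = 1$ (outcome ICC $1/6 \approx 0.167$). Variable
cluster sizes use a gamma distribution with mean $\bar m$ and standard
deviation $\mathrm{CV}\cdot\bar m$ — the conventional definition
$\mathrm{CV} = \mathrm{sd}/\mathrm{mean}$ — rounded and floored at 2, the
floor avoiding degenerate single-participant clusters that are known to
destabilize the clustered membership model.

The generator matches the model family exactly. Passing recovery tests
therefore demonstrates computational correctness of the posterior, not
robustness: real trials have non-normal outcomes, covariate-dependent
residual spread, membership processes outside the multinomial-logit family,
informative cluster sizes, and post-baseline missingness that is not
truncation. None of these are emulated, and ignorable missingness is
assumed handled upstream (e.g., by imputation) before the data reach
`crt_data()`.

**The oracle.** `true_sace_oracle()` computes the generating process's true
SACE, $E[X^\top(\alpha_1^{11}-\alpha_0^{11}) \mid G = 11]$, by direct
Monte-Carlo integration over the covariate (and latent intercept)
distribution, weighting each draw by its always-survivor probability — the
exact conditional expectation given the draw, so its standard error at
$10^6$ draws is well under 0.001. Under the benchmark configuration the
true SACE is approximately 0.923: selection into the always-survivor
stratum pushes both covariates downward, so the effect sits below the
intercept contrast of 1.3. Note the estimand is small relative to the
residual SD ($\sqrt 5 \approx 2.24$), which makes *relative* bias a
demanding scale for this benchmark: a 0.09 absolute error is already 10%.

## The recovery harness

`run_recovery_study()` repeats simulate-and-fit, reporting per parameter
the truth, average posterior mean, percent relative bias, 95%
credible-interval coverage, and the Monte-Carlo standard error of the
average posterior mean. The package's reduced-scale default — 30
replicates, single chains of 2,000 iterations with 500 burn-in — completes
in a few minutes on one CPU; at that size the Monte-Carlo SE of the SACE
bias estimate is roughly 7 percentage points, so individual runs scatter
around the method's true bias. The package's own validation runs the same
study at 60 replicates, halving that SE while staying within a few minutes.
Full-scale studies (hundreds of replicates, $10^4$ iterations) are the
same call with larger arguments.

Two caveats the report itself surfaces. First, the posterior for the
treated always-survivor coefficients is mildly attenuated toward the
protected cell — the two treated-survivor mixture components overlap
heavily under the benchmark (component means roughly 1.8 units apart at
residual SD 2.24) — visible as a few percent negative bias on
$\alpha_1^{11}$ that largely cancels in the SACE contrast. Second,
coverage for the realized stratum *proportions* is computed against the
marginal truth, while the posterior concentrates on the replicate's
finite-sample shares; those rows under-cover by construction and are
reported for completeness, not as a calibration claim.

## Known limitations

* Monotonicity is assumed, not testable from the data; a harmed stratum is
  not modeled.
* The mixture is identified through distributional assumptions
  (normality, shared $\sigma^2$) and covariates; weak covariate signal in
  the membership model widens and can bias the SACE posterior.
* The clustered membership model needs non-tiny clusters; `run_chain()`
  warns when single-participant clusters meet `strata_clustering = TRUE`.
* Repeated outcome measurements, informative priors on the ICC, and
  missing-covariate imputation inside the sampler are out of scope.
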