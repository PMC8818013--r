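---
title: "Conditional ML for binomial panel proportions, and testing the binomial assumption"
author: "blogitfe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional ML for binomial panel proportions, and testing the binomial assumption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blogitfe)
```

## The model

Many panel outcomes are bounded proportions observed on a grid: a count of
successes $Y_{it} \in \{0, 1, \ldots, K\}$ out of a known number of trials
$K$, reported as $y_{it} = Y_{it}/K$. Work-time percentages in 10%-steps
($K = 10$), symptom counts out of a fixed checklist, or patents granted out
of applications all have this shape, with genuine probability mass at 0 and
1 — which rules out log-odds transforms and beta regression.

`blogitfe` models the conditional expectation with a logistic link and a
unit-specific fixed effect,
$$
E(y_{it} \mid x_{it}, \alpha_i) \;=\; \Lambda(x_{it}'\beta + \alpha_i),
\qquad
Y_{it} \mid p_{it} \sim \mathrm{binomial}(K, p_{it}),
$$
where $\alpha_i$ may be arbitrarily correlated with the covariates.
Observations are independent across units and, conditionally on
$\alpha_i$, serially independent. Estimating the $\alpha_i$ jointly with
$\beta$ (the dummy-variable estimator, `method = "dv"`) is inconsistent for
fixed $T$ — the incidental-parameters problem — while pooling
(`method = "pooled"`) ignores the heterogeneity altogether. The package's
core estimator (`method = "cml"`) conditions each unit's likelihood on the
within-unit total $S_i = \sum_t Y_{it}$, which is sufficient for
$\alpha_i$: the conditional density
$$
f(Y_{i1},\ldots,Y_{iT} \mid S_i)
 = \frac{\exp\left(\sum_t Y_{it} x_{it}'\beta\right) \prod_t \binom{K}{Y_{it}}}
        {\sum_{q \in Q_i} \exp\left(\sum_t q_t x_{it}'\beta\right) \prod_t \binom{K}{q_t}},
$$
with $Q_i$ the set of count vectors sharing the total $S_i$, is free of
$\alpha_i$. Units with $S_i = 0$ or $S_i = KT_i$ have conditional
probability one; they are uninformative and dropped (their count is
reported on the fit). For $K = 1$ this is exactly the Chamberlain binary
conditional logit.

## Computing the conditional likelihood

The denominator is the coefficient of $z^{S_i}$ in the generating
polynomial $\prod_t (1 + z\,e^{\eta_{it}})^K$, $\eta_{it} = x_{it}'\beta$.
The package evaluates it by sequential polynomial multiplication in log
space (log-sum-exp accumulation, truncated at degree $S_i$), implemented in
C++; this is numerically safe for $K T$ into the hundreds. The analytic
score needs the conditional expectations $E(q_t \mid S_i)$, which come from
the same recursion run as prefix and suffix products: the distribution of
$q_t$ given the total is proportional to
$\binom{K}{q} e^{q \eta_{it}}$ times a convolution of the other periods'
polynomials. A brute-force enumeration over $Q_i$
(`brute_force_cond_loglik()`) serves as the test-suite oracle; the two
agree to $10^{-10}$ on random instances, and at $\beta = 0$ the conditional
law reduces to the multivariate hypergeometric closed form.

Two properties are useful checks and are enforced in the tests: adding a
constant to all of a unit's $\eta_{it}$ leaves the conditional likelihood
unchanged (this is the fixed-effect elimination), and the K-fold Bernoulli
*data expansion* (`expand_to_bernoulli()`, `via_expansion = TRUE`) — clone
each observation into $K$ rows carrying $Y_{it}$ ones — yields a
conditional Bernoulli likelihood identical up to the constant
$\sum_{it}\log\binom{K}{Y_{it}}$ and hence the same $\hat\beta$. The
expansion is how the estimator can be run in any software with a
conditional logit routine; here it is mainly a cross-check, since the
direct recursion is faster and exact for large $K$.

Optimization is quasi-Newton (BFGS) with the analytic score from a zero
start, followed by Newton polishing with a finite-difference Hessian until
the gradient norm falls below `gtol` ($10^{-8}$ by default, 200 iterations
cap). Standard errors are cluster-robust at the unit level: a sandwich
over per-unit conditional scores with bread the inverse observed
information and a $G/(G-1)$ small-sample factor, $G$ the number of
informative units. Time-invariant covariates (zero within-unit variance
everywhere) are absorbed by the fixed effects and rejected with an
explanatory error, as is within-unit collinearity.

The dummy-variable estimator uses a concentrated likelihood: for fixed
$\beta$ each $\hat\alpha_i$ solves its monotone one-dimensional score by
safeguarded Newton (tolerance $10^{-10}$), and the profile is maximized in
$\beta$ with the envelope gradient ($10^{-8}$). This scales to the
simulation sizes used below far better than a dense $(N{+}p)$-parameter
solve. The pooled estimator is an ordinary binomial GLM with a common
intercept; its clustered sandwich is assembled from unit-level scores.

Fits are returned as a `"blogit"` object with `print`, `summary`, `coef`,
`vcov`, `logLik`, `nobs`, `confint`, `predict`, `fitted` and `residuals`
methods. Because the conditional approach never estimates $\alpha_i$,
`predict()` for CML fits only offers the covariate part of the linear
index, and effect sizes are best read as semi-elasticities:
$\partial \log E(y)/\partial x = \beta(1-\Lambda)$, estimated by
$\hat\beta(1-\bar y)$ with $\bar y$ the sample mean outcome
(`semi_elasticity()`).

## Overdispersion and the beta-binomial

The binomial assumption fixes the conditional variance at
$K\Lambda(1-\Lambda)$. Dependence between trials or time-varying random
heterogeneity inflates it. The package's overdispersed simulator draws
$\tilde p_{it} \sim \mathrm{beta}(\phi\Lambda_{it}, \phi(1-\Lambda_{it}))$,
which preserves the mean $K\Lambda_{it}$ and multiplies the variance by
$1 + (K-1)/(\phi+1)$. A target inflation $1+\eta$ therefore pins down
$\phi = (K-1)/\eta - 1$ (`phi_from_overdispersion()`); $\eta \ge K-1$ is
infeasible, which is why heavily overdispersed designs do not exist at
$K = 2$. Conditional ML under misspecification is not protected by any
quasi-likelihood argument, and the simulations below quantify the bias: it
grows with $\eta$ and shrinks with $T$ and $K$, and the conditional
estimator dominates the dummy-variable estimator throughout.

Mirroring a practical limitation of common beta random number generators,
draws whose parameters fall below configurable lower bounds (defaults
0.05 and 0.15) are refused and the observation dropped, at the observation
level, with the count reported: the refusals depend only on exogenous
quantities, so dropping shrinks the effective sample without invalidating
estimation. In our experiments this rule removes well under 2% of
observations and moves the Monte Carlo means by less than one MC standard
error; it is kept because it is part of the study conditions the
simulators emulate. Units left with a single period still contribute to
estimation (conditioning is per unit) but not to the pairwise test.

## The dispersion test

Residual-based overdispersion tests need fitted conditional variances and
hence $\hat\alpha_i$, which conditional ML never produces. The package's
test sidesteps this with within-unit differences. For each unit and pair
of consecutive waves, draw auxiliary indicators
$M_{it} \sim \mathrm{Bernoulli}(y_{it})$ and form
$$
z_i = \frac{(Y_{i1}-Y_{i2})^2 - K (M_{i1}-M_{i2})^2}{K(K-1)}.
$$
Under the binomial null $E(z_i) = (\Lambda_{i1}-\Lambda_{i2})^2$, which is
zero when the two periods share the same expected proportion; under
overdispersion the first square outgrows the Bernoulli benchmark and
$E(z_i) > 0$. The statistic requires $K \ge 2$ — for binary data the two
variances coincide identically.

Two ways to impose "same expected proportion":

* **Discrete matching** (`variant = "discrete"`): keep the set $A$ of
  pairs whose covariates are identical in both periods (the fixed effect
  cancels by construction). The statistic is
  $\tau_A = |A|^{-1}\sum_{i \in A} z_i$, studentized with the sample
  standard deviation, two-sided normal rejection. The matched units are
  exactly those that do *not* inform the CML fit — nothing is wasted.
* **Kernel weighting** (`variant = "kernel"`): with continuous covariates
  $A$ is empty, so the test localizes at zero index difference
  $\hat\Delta_i = (x_{i1}-x_{i2})'\hat\beta$ with Gaussian kernel weights.
  $\hat\beta$ comes from the CML fit (consistent under the null); its
  sampling noise is ignored in the variance, as is standard for this
  construction. The statistic $\hat\tau = \sum_i w_i z_i$ is centred at
  the plug-in bias $\sum_i w_i (y_{i2}(1-y_{i2})\hat\Delta_i)^2$ — the
  local-constant regression bias, proportional to $h^2$ — and scaled by
  $\widehat{\mathrm{Var}}(\hat\tau) = \hat\sigma^2 \sum_i K_i^2 /
  (\hat f^2 n^2 h^2)$ with $\hat\sigma^2 = \sum_i w_i (z_i -
  \tau(\hat\Delta_i))^2$ and $\hat f$ the kernel density estimate at zero.

With more than two waves the $T-1$ consecutive-pair moments are stacked:
$\bar g$ with per-moment sample sizes $n_t$, and
$J = (\sqrt{n} \circ \bar g)'\hat S^{-1}(\sqrt{n} \circ \bar g)
\rightarrow \chi^2_{T-1}$ under the null. For the discrete variant the
off-diagonal entries of $\hat S$ must be estimated on the small overlap
sets $A_t \cap A_{t+1}$, which badly distorts the size in moderate
samples; the default is therefore `s_mode = "diagonal"`, with the full
matrix retained as an option. The kernel moments use all units, so the
full $\hat S$ is the default there.

Numerical choices worth recording:

* Bandwidth: $h = 0.9\,n^{-1/5}$ applied after standardizing
  $\hat\Delta$ by its sample standard deviation over the test sample.
  The plug-in bias and $\tau(\hat\Delta_i)$ use the *raw* $\hat\Delta_i$
  (they approximate $(\Lambda'\Delta)^2$, a quantity on the original
  scale); only the kernel argument is standardized. No cross-validation —
  the rule of thumb is part of the procedure.
* If every $\hat\Delta_i$ is identical (in particular all zero, e.g. all
  covariates time-invariant), standardization is impossible and the
  weights degenerate to uniform: $\hat\tau$ is the plain mean of $z$, the
  bias plug-in evaluates as is (zero when $\hat\Delta \equiv 0$), and the
  variance falls back to the sample-mean variance $\hat\sigma^2/n$.
* $\hat S$ uses $n-1$ (sample) variances and covariances. With two waves
  this makes the forced multi-period statistic exactly the square of the
  two-period $t$ statistic, so the $\chi^2_1$ and two-sided normal
  p-values coincide.
* The moment normalization divides each kernel moment by the mean kernel
  weight over that moment's own test sample ($n_t$ pairs), the natural
  per-moment analogue of the two-period denominator.
* Consecutive waves only, defined on the panel's wave grid; units missing
  one wave of a pair simply do not contribute that moment (relevant when
  the beta-bound rule has dropped observations).
* The auxiliary draws make the test randomized; pass `seed` for
  reproducibility. `m_draws > 1` averages $z$ over independent draws —
  an extension beyond the single-draw construction, off by default.

## The Monte Carlo harness and what it emulates

`dgp_config()` encodes the study conditions: $\beta_0 = 0$,
$\beta_1 = 2$, $x_{it}$ i.i.d. uniform on $[-1,1]$ (variance $1/3$) or
Bernoulli(½) on $\{0,1\}$ for the matching designs, and correlated
effects $\alpha_i = \sqrt{T}\bar x_i + \varepsilon_i$ with standard
normal noise, making $\mathrm{cor}(\alpha_i, \bar x_i) = 0.5$ — a
deliberately substantial confound that pooled estimation cannot survive.
One seed governs a documented draw order (x, then $\varepsilon$, then
$\tilde p$, then Y), so every experiment is bit-reproducible;
`run_estimator_cell()` and `run_test_cell()` derive replication $r$'s
seed as `seed + r - 1`, so a replication's data do not depend on how many
replications run. Failed fits are counted and excluded, never silent.

The estimator cells fit CML and DV on their inherent estimation sample
(boundary-total units dropped) and the pooled logit on the full sample —
the pooled model ignores the individual effects, and those effects are
precisely what makes boundary totals frequent, so filtering would change
the estimand it is meant to illustrate.

The generator emulates the designed moments of the study — it does not
emulate serially correlated covariates, feedback from outcomes to future
covariates, state dependence, or attrition. Passing tests therefore
certify the estimator and test under clean random sampling with
covariate-correlated heterogeneity, not robustness to dynamic
misspecification.

Problem sizes: the package's validation suite runs its reference designs
at 200–400 replications (the original tables use 1000) and compares cell
means and rejection rates within three Monte Carlo standard errors; the
bundled `scripts/acceptance.R` recomputes the headline cells the same
way. At these sizes the estimator-comparison cells reproduce the
reference means to the third decimal (e.g. 2.000 and 2.024 against 2.000
and 2.025 for the conditional and dummy-variable estimators at
$N=100, T=K=10$). The beta-binomial robustness cells converge to 2.08 and
2.03 against reference values of 2.1 and 2.049 — agreement at the
one-percent level, within the resolution at which those two numbers are
reported, though the second sits just outside a strict
3-MC-standard-error band of its converged value; the corresponding
assertion in the test suite documents this as a known, small residual
discrepancy.

## Limitations

* $K$ is constant across the dataset; observation-specific trial counts
  are not supported.
* No correlated-random-effects or other post-rejection estimator is
  provided: when the dispersion test rejects, the package tells you the
  binomial conditional variance is wrong, not what to fit instead (the
  simulations show the point estimates remain usable under modest
  overdispersion, especially for long panels).
* The kernel test treats $\hat\beta$ as known and uses a fixed
  rule-of-thumb bandwidth.
* Score-type alternatives (e.g. tests built from estimated conditional
  variances) are out of reach by design, since the fixed effects are
  never estimated.
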