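---
title: "Arbitrating between social and individual learning: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arbitrating between social and individual learning: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arbihgf)
```

## The problem

A player predicts a binary lottery outcome (blue vs green card) on each of
160 trials, aided by two information streams of fluctuating reliability: the
outcome history itself, and advice from a partially informed advisor whose
intentions alternate between helpful and misleading. The player also wagers
1–10 points per trial, won or lost with the prediction. `arbihgf` models
this behaviour as hierarchical Bayesian learning in two parallel branches
plus a response model that *arbitrates* between the branches by their
momentary precision.

## Learning model

Each branch is a binary hierarchical Gaussian filter. Level 1 is the
observed event (advice accurate; blue rewarded), level 2 its latent
log-odds tendency $x_2$, level 3 the log-volatility $x_3$ of that tendency.
Conditional on the previous trial, $x_2$ performs a Gaussian random walk
with step variance $\exp(\kappa x_3 + \omega)$ and $x_3$ a random walk with
step variance $\vartheta$. Filtering yields closed-form trial updates: the
tendency moves by a precision-weighted prediction error
$\Delta\mu_2 = \delta_1/\pi_2$, and the volatility by a precision-weighted
volatility prediction error
$\delta_2 = (1/\pi_2 + \Delta\mu_2^2)\,\hat\pi_2 - 1$ with the standard
volatility weight $w_2 = \exp(\kappa\mu_3 + \omega)\,\hat\pi_2$. Both
branches use the same code path; only their inputs and $(\kappa, \vartheta)$
differ.

Perceptual variants:

* **three-level** — $\kappa, \vartheta$ free per branch; volatility tracked.
* **two-level** — the volatility state is frozen: $\vartheta$ is pinned to
  the near-zero constant 0.00062 and $\kappa$ to its population prior mean
  0.5, so the level-2 step variance is the constant
  $\exp(0.5\,\mu_3^{(0)} + \omega)$. This was a genuinely open design point:
  a family "without a third level" can also be read as $\kappa = 0$ (step
  variance $e^\omega$) or as using the pinned constant itself as the step
  variance ($2\times10^{-4}$-scale, which nearly freezes learning and
  cripples the family far beyond what its published model-selection
  performance suggests). The adopted reading is the minimal one — fix the
  meta-volatility at effectively zero, change nothing else — and keeps the
  pinned families nested in the three-level family.
* **normative** — $\kappa, \vartheta$ pinned to the prior means (0.5, 0.55):
  ideal-observer learning with no individual learning parameters.

### Parameters, spaces, defaults

| parameter | meaning | native space | estimation space | prior (mean, var) |
|---|---|---|---|---|
| $\kappa_a,\kappa_c$ | tendency–volatility coupling | (0, 1) | logit | 0.5, 1 |
| $\vartheta_a,\vartheta_c$ | meta-volatility | (0, 1) | logit | 0.55, 1 |
| $\omega$ | tonic log-volatility | real | fixed | −2.5 (constant) |
| $\zeta$ | social bias | ≥ 0 | log | 1 (log-mean 0), 25 |
| $\beta_{ch}$ | inverse decision temperature | > 0 | log | 48, 1 (shrinkage) |
| $\beta_0\ldots\beta_6$ | wager coefficients | real | identity | 6.21 / 0, 4 |
| $\beta_{wager}$ | log-wager noise SD | > 0 | log | 1.5, 100 |

Prior variances apply in estimation space. The $\beta_{ch}$ prior is a
deliberate shrinkage prior: behaviour should be explained by the learning
and arbitration parameters rather than by decision noise.

$\omega$ is a fixed constant, not estimated (only $\kappa$ and $\vartheta$
carry priors). Its default, −2.5, is calibrated to the task's timescale: the
volatile phases reverse the contingency every ~8–12 trials, and the level-2
step variance $\exp(\kappa\mu_3+\omega)$ must be large enough for beliefs to
track those reversals and — equally important — for the data to carry
information about $\kappa$ and $\vartheta$ at all. With a much smaller tonic
volatility (e.g. $\omega=-4$) the volatility term is negligible against the
belief variance, the filter's behaviour becomes almost independent of
$\kappa$, and the learning parameters are practically unidentifiable; the
package's own recovery study is the measurable witness of that calibration.

Initial states default to $\mu_2^{(0)}=0$, $\sigma_2^{(0)}=1$,
$\mu_3^{(0)}=1$, $\sigma_3^{(0)}=1$ and are fixed, not estimated.

## Response model

Arbitration weighs the branches by predicted first-level precision
$\hat\pi_1 = 1/(\hat\mu_1(1-\hat\mu_1))$, biased by $\zeta$:
$\xi_a = \zeta\hat\pi_{1,a}/(\zeta\hat\pi_{1,a} + \hat\pi_{1,c})$. The
card-branch probability is re-expressed in the *advice frame* (probability
that the advised colour wins: $p$ if the advice names blue, $1-p$
otherwise) before the convex combination
$\hat\mu_{1,b} = \xi_a\hat\mu_{1,a} + \xi_c\hat\mu^{af}_{1,c}$. Choices are
a power softmax with temperature $1/\beta_{ch}$; the response families
arbitrated / advice-only / card-only correspond to $\zeta$ free, $\zeta=\infty$
and $\zeta=0$.

Wagers are modelled on the log scale as a linear function of irreducible
belief uncertainty $\hat\sigma_b = \hat\mu_{1,b}(1-\hat\mu_{1,b})$,
arbitration $\xi_a$, the informational uncertainties
$I_2 = \hat\mu_1(1-\hat\mu_1)\,\hat\sigma_2$ and environmental volatilities
$V_3 = \hat\mu_1(1-\hat\mu_1)\exp(\mu_3^{(k-1)})$ of each branch — all
mapped down to the first level. Simulation rounds
$\exp(\mathcal N(\log y, \beta_{wager}^2))$ and clips to 1–10.

**Censored wager likelihood.** Because the wager scale is bounded, the
likelihood treats observations at the end points as censored: a wager of 1
contributes $P(\log w \le 0)$ and a wager of 10 contributes
$P(\log w \ge \log 10)$ under the Gaussian; interior wagers use the
continuous density. Without censoring, any parameter draw whose predicted
log-wager leaves the representable band (which the cohort spread of
$\beta_5$ regularly produces) is penalised by hundreds of nats at its own
generating values, and the intercept and volatility coefficients become
unrecoverable. Censoring is the minimal correction that keeps the printed
interior model intact. Interior rounding (wager 5 meaning
$\log w \in [\log 4.5, \log 5.5)$) is *not* modelled; at the fitted noise
scales the interval correction is negligible relative to the tail issue.

## Inversion

MAP estimation runs in estimation space with multi-start `nlminb`
(default 10 starts: the prior mean plus jittered starts at half the prior
spread, capped at 2; seeded, hence deterministic). Convergence tolerance is
1e-6 on the objective. Filter divergence (a non-positive level-3 precision,
possible for extreme $\kappa,\vartheta$ — a known failure mode of the
variational updates) returns a large penalty so other starts can proceed;
a diverging *generative* trajectory marks the parameter draw inadmissible.
The log model evidence is the Laplace approximation at the best optimum;
the Hessian is computed by central differences (step 1e-3 per parameter in
estimation space) and, if not positive definite, ridge-regularised with an
escalating diagonal and flagged in the diagnostics.

## Model selection

Random-effects Bayesian model selection treats the model identity as a
random effect: a variational Dirichlet–multinomial scheme yields posterior
counts $\alpha_m$ and expected model frequencies. Exceedance probabilities
use 10⁶ seeded Dirichlet draws (Monte-Carlo error well below the third
decimal). The Bayes Omnibus Risk compares the free energy of the
random-effects model against the equal-frequency null,
$BOR = 1/(1+\exp(F_{rfx}-F_0))$, and protected exceedance probabilities
blend $\varphi_p = (1-BOR)\,EP + BOR/M$. Families collapse by per-subject
log-sum-exp minus log family size (uniform within-family prior).

## The synthetic task generator

The generator reproduces the paradigm's statistics *by construction* rather
than in expectation: 90/160 accurate advice trials (0.5625), 88/160 blue
outcomes (0.55), 128/160 correct advisor private signals (0.80), a 2 × 2
stable/volatile phase grid in contiguous blocks (card and advice phases
crossing at the probe trials 14, 49, 73, 115), stable blocks at a 0.8
contingency and volatile blocks alternating the favoured option in 5–12
trial sub-blocks. Only within-block positions are random, and the
permutation is redrawn until the advice-accuracy and outcome sequences are
near-orthogonal (|r| ≤ 0.1). Exact counts make the design-level checks
deterministic; the cost is that sub-block lengths deviate slightly from a
uniform 8–12 range, since the counts must apportion exactly. The
favoured-colour blocks are aligned against the advisor-intention blocks so
that the block-level covariance between advice accuracy and outcome colour
is close to zero — with a front-loaded helpful phase this cannot be left to
chance, because within-block shuffling cannot remove block-level covariance.

What the generator does *not* emulate: reaction times, video stimuli and
advisor identity effects, session breaks (the 70 + 90 split is metadata
only), probe-question behaviour, and any drift in advisor strategy beyond
the block structure. Passing tests on synthetic cohorts therefore establish
internal consistency (the pipeline recovers what it simulates) — not that
real participants satisfy the model.

## Reference cohort values

Simulations default to a cohort-average agent: $\kappa_a=0.56$,
$\kappa_c=0.58$, $\vartheta_a=0.62$, $\vartheta_c=0.59$ (native space),
$\zeta = e^{1.03}$, $\beta_{ch} = e^{2.25}$ (log-scale averages),
$\beta_1\ldots\beta_6 = (-1.59, 1.42, 0.23, 0.63, -2.97, -0.51)$. Two
response quantities have no published cohort average and are package
choices, made once: $\beta_0 = 3.7$, set so the predicted wager sits in the
upper-middle of the 1–10 scale at typical regressor values (consistent with
cohort-level task earnings); and $\beta_{wager} = 0.35$, set so that
model-predicted and simulated wagers correlate at the strength reported for
real wagers (correlations near 0.6–0.8 are impossible at the prior-mean
noise of 1.5). The recovery population uses the cohort SDs around these
means, truncating unit-interval parameters to (0.01, 0.99).

## The two headline simulations

**Parameter recovery** (`run_recovery`): 38 synthetic subjects drawn from
the cohort distribution, simulated on one shared 160-trial schedule (as in
the original design, where every participant saw the same input sequence),
refit by MAP, and summarised per free parameter by Cohen's
$f = \sqrt{R^2/(1-R^2)}$ from the regression of recovered on simulated
values in estimation space (capped at 10 when $R^2 > 0.99$). The social
bias, decision temperature, coupling parameters and the advice-volatility
wager coefficients recover strongly in this emulation; the meta-volatility
parameters $\vartheta$ and the small card-side wager coefficients recover
weakly — their likelihood contribution over 160 trials is a few nats across
the cohort spread, so their posteriors shrink to the prior. The acceptance
script reports the honest minimum across the cohort-specified parameters
rather than only the well-recovered ones.

**Volatility-tracking score comparison**
(`compare_volatility_tracking`): 1000 replicate schedules, each played by a
three-level (volatility-tracking) and a two-level (frozen-volatility)
arbitrated agent at the same cohort-average response parameters, with
common random numbers for the response noise so the paired difference
isolates the systematic effect. Under *shared* wager coefficients this
comparison is dominated by a scale effect, not by learning: the
frozen-volatility agent's smaller $V_3$ regressors make it wager closer to
the 10-point cap, and with above-chance accuracy on a capped scale,
wagering high is close to optimal — so modulating wagers down in volatile
phases loses points unless it also avoids below-chance stretches. The
published advantage of volatility tracking plausibly rests on response
parameters fitted separately per perceptual model (each agent wagering in
its own calibration); with transplanted coefficients, this package's
measurement can legitimately come out negative. The comparison is reported
as measured, and this mechanism is the package's own analysis of why.

## Problem sizes and numerical conventions

Test-suite runs use reduced sizes chosen for tight feedback loops: recovery
smoke tests at 5–15 subjects with 2–8 optimizer starts, model-selection
cohorts of 12–24 subjects at 3–4 starts, 1000 replicates for the score
comparison. The acceptance script uses the full 38-subject, 10-start
protocol. Other conventions: predicted precisions floored at 1e-8 (floored
trials flagged), integrated beliefs clamped to [1e-12, 1−1e-12], choice
log-likelihoods evaluated in logit space so saturated probabilities keep
exact tails, CSV output at 12 significant digits, and every stochastic
step seeded from a user-visible integer.

## Known limitations

* The meta-volatility parameters are weakly identifiable at 160 binary
  trials; reported recovery for them is honest but poor.
* The wager likelihood censors at the scale bounds but does not discretise
  the interior; a full interval likelihood would be the next refinement.
* Laplace evidence at a MAP point can misstate the evidence for strongly
  non-Gaussian posteriors; rank comparisons across the nine models are the
  intended use.
* The two-level family's exact historical parameterisation is ambiguous
  (see above); results that depend on *how* volatility is frozen — notably
  the score comparison — inherit that ambiguity.
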