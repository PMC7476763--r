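#' Response-model parameters
#'
#' Maps beliefs to the two behavioural readouts: the binary decision to take
#' or reject the advice, and the 1-10 point wager. `zeta` is a multiplicative
#' social bias on the advice branch's precision in arbitration (`zeta = 0`
#' reduces to card-only, `zeta = Inf` to advice-only weighting). `beta_ch` is
#' the inverse decision temperature of the choice softmax. `beta0`-`beta6`
#' are the coefficients of the log-wager regression on belief uncertainty,
#' arbitration, informational uncertainty and volatility of each branch, and
#' `beta_wager` is the standard deviation of log-wager noise.
#'
#' @param zeta Social bias, >= 0 (log-space estimation; Inf allowed for the
#'   advice-only variant).
#' @param beta_ch Inverse decision temperature, > 0 (log-space estimation).
#' @param beta0,beta1,beta2,beta3,beta4,beta5,beta6 Wager regression
#'   coefficients (intercept; belief uncertainty; arbitration; informational
#'   uncertainty advice/card; volatility advice/card).
#' @param beta_wager Wager stochasticity: SD of the Gaussian noise on the log
#'   wager, > 0 (log-space estimation).
#' @return A list of class `response_params`.
#' @export
response_params <- function(zeta = 1, beta_ch = 48,
                            beta0 = 6.21, beta1 = 0, beta2 = 0, beta3 = 0,
                            beta4 = 0, beta5 = 0, beta6 = 0,
                            beta_wager = 1.5) {
  stopifnot(zeta >= 0, beta_ch > 0, beta_wager > 0)
  structure(list(zeta = zeta, beta_ch = beta_ch, beta0 = beta0,
                 beta1 = beta1, beta2 = beta2, beta3 = beta3, beta4 = beta4,
                 beta5 = beta5, beta6 = beta6, beta_wager = beta_wager),
            class = "response_params")
}

#' Precision-ratio arbitration between advice and card information
#'
#' The weight given to the advice is its (bias-scaled) predicted first-level
#' precision over the total: `xi_a = zeta * pihat_a / (zeta * pihat_a +
#' pihat_c)`, and `xi_c = 1 - xi_a`.
#'
#' @param pihat1_a,pihat1_c Predicted first-level precisions of the advice
#'   and card branch (positive; vectors recycle).
#' @param zeta Social bias, >= 0; `Inf` yields pure advice weighting.
#' @return Tibble with columns `xi_a`, `xi_c` summing to one.
#' @examples
#' arbitrate(1, 1, zeta = 2)  # xi_a = 2/3
#' @export
arbitrate <- function(pihat1_a, pihat1_c, zeta) {
  stopifnot(zeta >= 0)
  if (any(pihat1_a < 0 | pihat1_c < 0)) {
    stop("precisions must be positive", call. = FALSE)
  }
  if (is.infinite(zeta)) {
    xi_a <- rep(1, length(pihat1_a))
  } else {
    tot <- zeta * pihat1_a + pihat1_c
    if (any(tot == 0)) stop("undefined arbitration: total precision is zero",
                            call. = FALSE)
    xi_a <- zeta * pihat1_a / tot
  }
  tibble::tibble(xi_a = xi_a, xi_c = 1 - xi_a)
}

#' Integrate branch predictions into one outcome probability
#'
#' Convex combination of the predicted advice accuracy and the card-colour
#' probability re-expressed in the advice frame (probability that the advised
#' colour wins).
#'
#' @param xi_a,xi_c Arbitration weights (must sum to 1).
#' @param muhat1_a Predicted probability the advice is accurate.
#' @param muhat1_c_adviceframe Predicted probability that the advised colour
#'   is rewarded, from the card branch.
#' @return Integrated probability that following the advice wins.
#' @export
integrate_belief <- function(xi_a, muhat1_a, xi_c, muhat1_c_adviceframe) {
  stopifnot(all(abs(xi_a + xi_c - 1) < 1e-12))
  xi_a * muhat1_a + xi_c * muhat1_c_adviceframe
}

#' Choice probability of taking the advice
#'
#' Softmax over the integrated belief: `p = m^b / (m^b + (1-m)^b)` with
#' inverse decision temperature `b`, evaluated in logit space for numerical
#' stability.
#'
#' @param muhat1_b Integrated probability that following the advice wins.
#' @param beta_ch Inverse decision temperature, > 0.
#' @return Probability of taking the advice.
#' @examples
#' choice_probability(0.7, 1)  # 0.7: probability matching at unit temperature
#' @export
choice_probability <- function(muhat1_b, beta_ch) {
  stopifnot(beta_ch > 0, all(muhat1_b > 0), all(muhat1_b < 1))
  plogis(beta_ch * qlogis(muhat1_b))
}

#' Expected log wager from trial-wise uncertainty quantities
#'
#' Linear model of the log wager: intercept plus weighted belief uncertainty,
#' arbitration in favour of advice, informational uncertainty of each branch
#' and environmental volatility of each branch.
#'
#' @param sigma_b_hat Irreducible belief uncertainty `m(1-m)` of the
#'   integrated prediction.
#' @param xi_a Arbitration weight of the advice.
#' @param I2_a,I2_c First-level-mapped informational uncertainties.
#' @param V3_a,V3_c First-level-mapped environmental volatilities.
#' @param response A [response_params()].
#' @return Expected log wager (vector).
#' @export
wager_mean <- function(sigma_b_hat, xi_a, I2_a, I2_c, V3_a, V3_c, response) {
  stopifnot(all(is.finite(c(sigma_b_hat, xi_a, I2_a, I2_c, V3_a, V3_c))))
  response$beta0 + response$beta1 * sigma_b_hat + response$beta2 * xi_a +
    response$beta3 * I2_a + response$beta4 * I2_c +
    response$beta5 * V3_a + response$beta6 * V3_c
}

#' Log density of an observed wager
#'
#' The log of the observed integer wager (1-10) is modelled as Gaussian
#' around the expected log wager with standard deviation `beta_wager`.
#' Because the wager scale is bounded, observations at the end points are
#' treated as censored: a wager of 1 contributes the lower Gaussian tail
#' mass (`P(log w <= 0)`) and a wager of 10 the upper tail mass
#' (`P(log w >= log 10)`), so predicted wagers beyond the scale are not
#' penalised as if the scale were unbounded. Interior wagers use the
#' continuous density.
#'
#' @param wager Observed integer wagers in 1..10.
#' @param wager_mean_log Expected log wager per trial.
#' @param beta_wager Standard deviation of the log-wager noise.
#' @return Log density (or censored log mass) per trial.
#' @export
wager_loglik <- function(wager, wager_mean_log, beta_wager) {
  if (any(wager != round(wager) | wager < 1 | wager > 10)) {
    stop("wagers must be integers in 1..10", call. = FALSE)
  }
  wager_loglik_impl(as.numeric(wager), wager_mean_log, beta_wager)
}

wager_loglik_impl <- function(wager, wager_mean_log, beta_wager) {
  out <- dnorm(log(wager), mean = wager_mean_log, sd = beta_wager,
               log = TRUE)
  lo <- wager == 1
  hi <- wager == 10
  if (any(lo)) {
    out[lo] <- stats::pnorm(0, wager_mean_log[lo], beta_wager, log.p = TRUE)
  }
  if (any(hi)) {
    out[hi] <- stats::pnorm(log(10), wager_mean_log[hi], beta_wager,
                            lower.tail = FALSE, log.p = TRUE)
  }
  out
}

#' Trial-wise response-model predictions from branch trajectories
#'
#' Combines the advice- and card-branch trajectories into per-trial
#' predictions: arbitration weights, the integrated outcome probability, the
#' probability of taking the advice, the wager regressors (all mapped to the
#' first level) and the expected log wager. Variant `advice_only` behaves as
#' arbitrated with `zeta = Inf`, `card_only` as `zeta = 0`.
#'
#' @param traj_a,traj_c `hgf_trajectory` objects for the advice and card
#'   branch (same length).
#' @param advice_color Binary vector of advised colours (1 = blue), aligned
#'   to the trajectories.
#' @param response A [response_params()].
#' @param variant One of "arbitrated", "advice_only", "card_only".
#' @return Tibble with columns `trial`, `xi_a`, `xi_c`, `muhat1_a`,
#'   `muhat1_c`, `muhat1_c_af`, `muhat1_b`, `p_take_advice`, `sigma_b_hat`,
#'   `I2_a`, `I2_c`, `V3_a`, `V3_c`, `wager_mean_log`.
#' @export
predict_trials <- function(traj_a, traj_c, advice_color, response,
                           variant = c("arbitrated", "advice_only",
                                       "card_only")) {
  variant <- match.arg(variant)
  if (nrow(traj_a) != nrow(traj_c) ||
      length(advice_color) != nrow(traj_a)) {
    stop("misaligned trajectories / advice sequence", call. = FALSE)
  }
  zeta <- switch(variant,
                 arbitrated = response$zeta,
                 advice_only = Inf,
                 card_only = 0)
  w <- arbitrate(traj_a$pihat1, traj_c$pihat1, zeta)
  # card-branch probability that the *advised* colour wins
  muhat1_c_af <- ifelse(advice_color == 1, traj_c$muhat1, 1 - traj_c$muhat1)
  mu_b <- integrate_belief(w$xi_a, traj_a$muhat1, w$xi_c, muhat1_c_af)
  mu_b <- pmin(pmax(mu_b, 1e-12), 1 - 1e-12)
  sigma_b_hat <- mu_b * (1 - mu_b)
  I2_a <- traj_a$muhat1 * (1 - traj_a$muhat1) / traj_a$pihat2
  I2_c <- traj_c$muhat1 * (1 - traj_c$muhat1) / traj_c$pihat2
  V3_a <- traj_a$muhat1 * (1 - traj_a$muhat1) * exp(traj_a$muhat3)
  V3_c <- traj_c$muhat1 * (1 - traj_c$muhat1) * exp(traj_c$muhat3)
  tibble::tibble(
    trial = traj_a$trial,
    xi_a = w$xi_a, xi_c = w$xi_c,
    muhat1_a = traj_a$muhat1, muhat1_c = traj_c$muhat1,
    muhat1_c_af = muhat1_c_af, muhat1_b = mu_b,
    choice_logit = response$beta_ch * qlogis(mu_b),
    p_take_advice = choice_probability(mu_b, response$beta_ch),
    sigma_b_hat = sigma_b_hat, I2_a = I2_a, I2_c = I2_c,
    V3_a = V3_a, V3_c = V3_c,
    wager_mean_log = wager_mean(sigma_b_hat, w$xi_a, I2_a, I2_c, V3_a, V3_c,
                                response))
}

#' Joint log-likelihood of choices and wagers under the response model
#'
#' Sum of the Bernoulli choice log-likelihood (advice taken or not) and the
#' Gaussian log-wager likelihood over trials.
#'
#' @param predictions Output of [predict_trials()].
#' @param choice Binary vector, 1 = advice taken.
#' @param wager Integer wagers 1..10.
#' @param beta_wager Log-wager noise SD.
#' @return Scalar log-likelihood.
#' @export
response_loglik <- function(predictions, choice, wager, beta_wager) {
  if (length(choice) != nrow(predictions) ||
      length(wager) != nrow(predictions)) {
    stop("responses misaligned with predictions", call. = FALSE)
  }
  if ("choice_logit" %in% names(predictions)) {
    # evaluate in logit space so saturated probabilities keep exact tails
    eta <- predictions$choice_logit
    lp1 <- ifelse(eta > -30, -log1p(exp(-pmin(eta, 700))), eta)
    lp0 <- ifelse(eta < 30, -log1p(exp(pmax(eta, -700))), -eta)
    ll_choice <- sum(ifelse(choice == 1, lp1, lp0))
  } else {
    p <- pmin(pmax(predictions$p_take_advice, 1e-15), 1 - 1e-15)
    ll_choice <- sum(ifelse(choice == 1, log(p), log1p(-p)))
  }
  ll_wager <- sum(wager_loglik(wager, predictions$wager_mean_log, beta_wager))
  ll_choice + ll_wager
}
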