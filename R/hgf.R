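#' Perceptual (learning) parameters for one two-branch filter
#'
#' Both information branches — advice accuracy and card colour — use the same
#' filter with their own coupling `kappa` and meta-volatility `theta`. In
#' native space both lie in (0, 1); estimation happens in logit space. The
#' tonic log-volatility offset `omega` is a fixed constant (not estimated),
#' as are the initial belief states.
#'
#' @param kappa_a,kappa_c Coupling between tendency and volatility levels,
#'   per branch; native space (0, 1).
#' @param theta_a,theta_c Meta-volatility (variability of the volatility
#'   level), per branch; native space (0, 1).
#' @param omega Tonic log-volatility offset entering
#'   `exp(kappa * mu3 + omega)`; real-valued constant, default -2.5.
#' @param mu2_0,sigma2_0 Initial mean / variance of the tendency level.
#' @param mu3_0,sigma3_0 Initial mean / variance of the volatility level.
#' @return A list of class `hgf_params`.
#' @export
hgf_params <- function(kappa_a = 0.5, kappa_c = 0.5,
                       theta_a = 0.55, theta_c = 0.55,
                       omega = -2.5,
                       mu2_0 = 0, sigma2_0 = 1,
                       mu3_0 = 1, sigma3_0 = 1) {
  stopifnot(kappa_a >= 0, kappa_a < 1, kappa_c >= 0, kappa_c < 1,
            theta_a > 0, theta_a < 1, theta_c > 0, theta_c < 1,
            sigma2_0 > 0, sigma3_0 > 0)
  structure(list(kappa_a = kappa_a, kappa_c = kappa_c,
                 theta_a = theta_a, theta_c = theta_c,
                 omega = omega, mu2_0 = mu2_0, sigma2_0 = sigma2_0,
                 mu3_0 = mu3_0, sigma3_0 = sigma3_0),
            class = "hgf_params")
}

#' Predicted outcome probability from the tendency belief
#'
#' Logistic sigmoid of the previous-trial tendency mean: the filter's
#' prediction, before seeing the trial's input, that the binary event occurs.
#'
#' @param mu2_prev Tendency mean carried over from the previous trial.
#' @return Probability in (0, 1).
#' @examples
#' predict_probability(0)       # 0.5
#' predict_probability(log(4))  # 0.8
#' @export
predict_probability <- function(mu2_prev) {
  stopifnot(all(is.finite(mu2_prev)))
  plogis(mu2_prev)
}

#' Run the binary hierarchical Gaussian filter over an input sequence
#'
#' Computes the full trial-wise belief trajectory for one information branch
#' given binary inputs (1 = advice accurate / blue rewarded). Three variants
#' are supported: `three_level` (volatility is tracked), `two_level`
#' (volatility frozen at its initial value; `theta` pinned to 0.00062) and
#' `normative` (three-level updates with `kappa`, `theta` pinned to the
#' population prior means 0.5 and 0.55).
#'
#' @param u Binary input vector.
#' @param kappa,theta Branch coupling and meta-volatility (native space).
#' @param params An [hgf_params()] supplying `omega` and initial states.
#' @param variant One of "three_level", "two_level", "normative".
#' @param precision_floor Lower bound applied to predicted precisions before
#'   division; trials hitting the floor are flagged in the `floored`
#'   attribute.
#' @return A tibble of class `hgf_trajectory`, one row per trial, with the
#'   predictions (`muhat1`, `muhat2`, `muhat3`, `pihat1`, `pihat2`,
#'   `pihat3`), posteriors (`mu2`, `pi2`, `mu3`, `pi3`), prediction errors
#'   (`delta1`, `delta2`) and precision-weighted prediction errors (`eps2`,
#'   `eps3`).
#' @export
hgf_filter <- function(u, kappa = 0.5, theta = 0.55,
                       params = hgf_params(),
                       variant = c("three_level", "two_level", "normative"),
                       precision_floor = 1e-8) {
  variant <- match.arg(variant)
  if (!all(u %in% c(0, 1))) stop("inputs must be binary 0/1", call. = FALSE)
  if (variant == "two_level") {
    # meta-volatility pinned to ~0: the volatility state is frozen at its
    # initial value and only the tonic component drives learning
    kappa <- 0.5
    theta <- 0.00062
    update3 <- FALSE
  } else if (variant == "normative") {
    kappa <- 0.5
    theta <- 0.55
    update3 <- TRUE
  } else {
    update3 <- TRUE
  }
  res <- hgf_binary_filter_cpp(as.numeric(u), kappa, theta, params$omega,
                               params$mu2_0, params$sigma2_0,
                               params$mu3_0, params$sigma3_0,
                               update3, precision_floor)
  if (res$diverged_at > 0) {
    stop(filter_divergence_condition(res$diverged_at))
  }
  out <- tibble::tibble(
    trial = seq_along(u), input = as.numeric(u),
    muhat1 = res$muhat1, pihat1 = res$pihat1, delta1 = res$delta1,
    muhat2 = res$muhat2, pihat2 = res$pihat2, pi2 = res$pi2, mu2 = res$mu2,
    eps2 = res$eps2, delta2 = res$delta2, muhat3 = res$muhat3,
    pihat3 = res$pihat3, pi3 = res$pi3, mu3 = res$mu3, eps3 = res$eps3)
  attr(out, "variant") <- variant
  attr(out, "floored") <- res$floored
  class(out) <- c("hgf_trajectory", class(out))
  out
}

filter_divergence_condition <- function(trial) {
  structure(
    class = c("arbihgf_filter_divergence", "error", "condition"),
    list(message = paste0("filter divergence: non-positive predicted ",
                          "precision at trial ", trial),
         call = NULL, trial = trial))
}

#' Run both branches of the two-branch filter on a schedule
#'
#' The advice branch filters the advice-accuracy sequence and the card branch
#' the outcome-colour sequence; both use identical update code.
#'
#' @param schedule A [generate_schedule()] result (or any data frame with
#'   `advice_accurate` and `outcome_color` columns).
#' @inheritParams hgf_filter
#' @return Named list with elements `advice` and `card`, each an
#'   `hgf_trajectory`.
#' @export
hgf_filter_schedule <- function(schedule, params = hgf_params(),
                                variant = "three_level",
                                precision_floor = 1e-8) {
  list(
    advice = hgf_filter(schedule$advice_accurate, params$kappa_a,
                        params$theta_a, params, variant, precision_floor),
    card = hgf_filter(schedule$outcome_color, params$kappa_c,
                      params$theta_c, params, variant, precision_floor))
}
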