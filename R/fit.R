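# MAP inversion of one subject's choices and wagers.

# Build a fast negative-joint-log-posterior closure over free parameters in
# estimation space. Works on raw vectors (no tibbles) since the optimiser
# calls it thousands of times. Filter divergence returns a large penalty
# rather than an error so multi-start optimisation can continue.
make_objective <- function(data, schedule, model, priors, omega = -2.5,
                           penalty = 1e12, precision_floor = 1e-8) {
  free <- priors[!priors$fixed, , drop = FALSE]
  fixed <- priors[priors$fixed, , drop = FALSE]
  base <- setNames(fixed$mean_native, fixed$param)
  free_names <- free$param
  free_tr <- free$transform
  mean_est <- free$mean_est
  sd_est <- sqrt(free$var_est)
  u_a <- as.numeric(schedule$advice_accurate)
  u_c <- as.numeric(schedule$outcome_color)
  advice_blue <- schedule$advice_color == 1
  choice <- as.numeric(data$choice)
  wager <- as.numeric(data$wager)
  logw <- log(wager)
  update3 <- model$perceptual != "two_level"

  neg_logpost <- function(par) {
    val <- base
    for (i in seq_along(par)) {
      val[[free_names[i]]] <- to_native(par[i], free_tr[i])
    }
    fa <- hgf_binary_filter_cpp(u_a, val[["kappa_a"]], val[["theta_a"]],
                                omega, 0, 1, 1, 1, update3, precision_floor)
    if (fa$diverged_at > 0) return(penalty)
    fc <- hgf_binary_filter_cpp(u_c, val[["kappa_c"]], val[["theta_c"]],
                                omega, 0, 1, 1, 1, update3, precision_floor)
    if (fc$diverged_at > 0) return(penalty)
    zeta <- val[["zeta"]]
    if (is.infinite(zeta)) {
      xi_a <- rep(1, length(u_a))
    } else {
      tot <- zeta * fa$pihat1 + fc$pihat1
      xi_a <- zeta * fa$pihat1 / tot
    }
    mu_c_af <- ifelse(advice_blue, fc$muhat1, 1 - fc$muhat1)
    mu_b <- xi_a * fa$muhat1 + (1 - xi_a) * mu_c_af
    mu_b <- pmin(pmax(mu_b, 1e-12), 1 - 1e-12)
    ll_choice <- 0
    if (length(choice)) {
      eta <- val[["beta_ch"]] * qlogis(mu_b)
      # log plogis(eta) = -log1p(exp(-eta)), stable in both tails
      lp1 <- ifelse(eta > -30, -log1p(exp(-pmin(eta, 700))), eta)
      lp0 <- ifelse(-eta > -30, -log1p(exp(pmax(eta, -700))), -eta)
      ll_choice <- sum(choice * lp1 + (1 - choice) * lp0)
    }
    ll_wager <- 0
    if (length(logw)) {
      sb <- mu_b * (1 - mu_b)
      i2a <- fa$muhat1 * (1 - fa$muhat1) / fa$pihat2
      i2c <- fc$muhat1 * (1 - fc$muhat1) / fc$pihat2
      v3a <- fa$muhat1 * (1 - fa$muhat1) * exp(fa$muhat3)
      v3c <- fc$muhat1 * (1 - fc$muhat1) * exp(fc$muhat3)
      wm <- val[["beta0"]] + val[["beta1"]] * sb + val[["beta2"]] * xi_a +
        val[["beta3"]] * i2a + val[["beta4"]] * i2c +
        val[["beta5"]] * v3a + val[["beta6"]] * v3c
      ll_wager <- sum(wager_loglik_impl(wager, wm, val[["beta_wager"]]))
    }
    lp_prior <- if (length(par)) {
      sum(dnorm(par, mean_est, sd_est, log = TRUE))
    } else 0
    out <- -(ll_choice + ll_wager + lp_prior)
    if (!is.finite(out)) penalty else out
  }
  attr(neg_logpost, "free") <- free
  neg_logpost
}

#' Joint log posterior of a model given one subject's data
#'
#' Sum of the choice log-likelihood, the wager log-likelihood and the
#' Gaussian log priors of the free parameters, all in estimation space.
#' Fixed (zero-prior-variance) parameters are pinned to their prior means
#' and contribute no prior term. Filter divergence yields a large negative
#' sentinel so optimisers can recover.
#'
#' @param par Named or ordered numeric vector of free parameters in
#'   estimation space (order of the non-fixed rows of `priors`).
#' @param data Subject responses (`choice`, `wager`), aligned to `schedule`.
#' @param schedule A task schedule.
#' @param model A [model_spec()].
#' @param priors A [default_priors()] table.
#' @return Scalar joint log posterior.
#' @export
joint_log_posterior <- function(par, data, schedule, model,
                                priors = default_priors(model)) {
  if (nrow(data) != nrow(schedule)) {
    stop("data are not aligned to the schedule", call. = FALSE)
  }
  obj <- make_objective(data, schedule, model, priors)
  -obj(par)
}

# Central-difference Hessian (per-parameter step h in estimation space).
hessian_cd <- function(f, x, h = 1e-3) {
  d <- length(x)
  H <- matrix(0, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    for (j in i:d) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + h
        xm <- x; xm[i] <- x[i] - h
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h^2
      } else {
        xpp <- x; xpp[i] <- x[i] + h; xpp[j] <- x[j] + h
        xpm <- x; xpm[i] <- x[i] + h; xpm[j] <- x[j] - h
        xmp <- x; xmp[i] <- x[i] - h; xmp[j] <- x[j] + h
        xmm <- x; xmm[i] <- x[i] - h; xmm[j] <- x[j] - h
        H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h^2)
      }
    }
  }
  H
}

# Laplace log evidence given the negative log posterior, its minimiser and
# the Hessian of the negative log posterior at the minimum.
laplace_evidence <- function(neg_logpost_at_map, H) {
  d <- nrow(H)
  if (d == 0) {
    return(list(lme = -neg_logpost_at_map, regularized = FALSE))
  }
  ridge <- 0
  for (k in 0:8) {
    ch <- tryCatch(chol(H + diag(ridge, d)), error = function(e) NULL)
    if (!is.null(ch)) {
      logdet <- 2 * sum(log(diag(ch)))
      return(list(lme = -neg_logpost_at_map + 0.5 * d * log(2 * pi) -
                    0.5 * logdet,
                  regularized = ridge > 0))
    }
    ridge <- if (ridge == 0) 1e-6 * max(1, max(abs(diag(H)))) else ridge * 10
  }
  # hopeless curvature: fall back to the diagonal
  dg <- pmax(abs(diag(H)), 1e-6)
  list(lme = -neg_logpost_at_map + 0.5 * d * log(2 * pi) -
         0.5 * sum(log(dg)),
       regularized = TRUE)
}

#' Maximum-a-posteriori fit of a model to one subject
#'
#' Multi-start quasi-Newton optimisation of the joint log posterior in
#' estimation space. The first start is the prior mean; the remaining starts
#' jitter it by a fraction of the prior spread (seeded, so the fit is
#' deterministic). The log model evidence is the Laplace approximation at
#' the best optimum, with the Hessian computed by central differences over
#' the free parameters.
#'
#' @param data Subject responses (tibble with `choice`, `wager`).
#' @param schedule The task schedule the responses were collected on.
#' @param model A [model_spec()].
#' @param priors Prior table, default [default_priors()] for the model.
#' @param n_starts Number of optimisation restarts (default 10).
#' @param seed Seed for the start jitter.
#' @param omega Fixed tonic log-volatility.
#' @return Object of class `hgf_fit`: MAP estimates in native and estimation
#'   space, joint log posterior, Laplace log model evidence and optimiser
#'   diagnostics. Use [tidy()] / [glance()] to extract tables.
#' @export
map_fit <- function(data, schedule, model, priors = default_priors(model),
                    n_starts = 10L, seed = 1L, omega = -2.5) {
  stopifnot(inherits(model, "model_spec"))
  if (nrow(data) != nrow(schedule)) {
    stop("data are not aligned to the schedule", call. = FALSE)
  }
  obj <- make_objective(data, schedule, model, priors, omega = omega)
  free <- attr(obj, "free")
  d <- nrow(free)

  if (d == 0L) {
    nlp <- obj(numeric(0))
    est <- fit_estimates(numeric(0), free, priors)
    return(new_hgf_fit(est, -nlp, laplace_evidence(nlp, matrix(0, 0, 0))$lme,
                       model, priors,
                       diagnostics = list(converged = TRUE, n_starts = 0L,
                                          starts = tibble::tibble(),
                                          hessian_regularized = FALSE,
                                          message = "no free parameters"),
                       data = data, schedule = schedule, omega = omega))
  }

  mean_est <- free$mean_est
  jitter_sd <- pmin(sqrt(free$var_est), 2) * 0.5
  set.seed(seed)
  starts <- cbind(mean_est,
                  if (n_starts > 1)
                    mean_est + matrix(rnorm(d * (n_starts - 1)), d) * jitter_sd)
  runs <- purrr::map(seq_len(ncol(starts)), function(s) {
    r <- tryCatch(
      nlminb(starts[, s], obj,
             control = list(rel.tol = 1e-6, iter.max = 500, eval.max = 2000)),
      error = function(e) NULL)
    if (is.null(r) || !is.finite(r$objective)) return(NULL)
    list(par = r$par, objective = r$objective,
         convergence = r$convergence, iterations = r$iterations)
  })
  ok <- !purrr::map_lgl(runs, is.null)
  start_tbl <- tibble::tibble(
    start = seq_len(ncol(starts)),
    objective = purrr::map_dbl(runs, function(r) r$objective %||% NA_real_),
    converged = purrr::map_lgl(runs, function(r) !is.null(r) &&
                                 r$convergence == 0))
  if (!any(ok)) {
    est <- fit_estimates(mean_est, free, priors)
    return(new_hgf_fit(est, NA_real_, NA_real_, model, priors,
                       diagnostics = list(converged = FALSE,
                                          n_starts = n_starts,
                                          starts = start_tbl,
                                          hessian_regularized = FALSE,
                                          message = "no start converged"),
                       data = data, schedule = schedule, omega = omega))
  }
  best <- which.min(start_tbl$objective)
  par <- runs[[best]]$par
  nlp <- runs[[best]]$objective
  H <- hessian_cd(obj, par, h = 1e-3)
  ev <- laplace_evidence(nlp, H)
  est <- fit_estimates(par, free, priors)
  new_hgf_fit(est, -nlp, ev$lme, model, priors,
              diagnostics = list(converged = TRUE, n_starts = n_starts,
                                 best_start = best,
                                 iterations = runs[[best]]$iterations,
                                 starts = start_tbl,
                                 hessian_regularized = ev$regularized),
              data = data, schedule = schedule, omega = omega)
}

fit_estimates <- function(par, free, priors) {
  est <- priors
  est$estimate_est <- NA_real_
  est$estimate <- est$mean_native
  if (length(par)) {
    idx <- match(free$param, est$param)
    est$estimate_est[idx] <- par
    est$estimate[idx] <- purrr::map2_dbl(par, free$transform, to_native)
  }
  est[, c("param", "estimate", "estimate_est", "transform", "fixed",
          "mean_native", "var_est")]
}

new_hgf_fit <- function(estimates, logpost, lme, model, priors, diagnostics,
                        data, schedule, omega) {
  structure(list(estimates = estimates, logpost = logpost, lme = lme,
                 model = model, priors = priors, diagnostics = diagnostics,
                 data = data, schedule = schedule, omega = omega),
            class = "hgf_fit")
}

#' Laplace-approximate log model evidence of a fit
#'
#' @param fit An `hgf_fit`.
#' @return Scalar log model evidence.
#' @export
log_model_evidence <- function(fit) {
  stopifnot(inherits(fit, "hgf_fit"))
  fit$lme
}

#' Native-space MAP parameter objects from a fit
#'
#' @param fit An `hgf_fit`.
#' @return List with `perceptual` and `response` parameter objects at the
#'   MAP estimate.
#' @export
fit_params <- function(fit) {
  vals <- setNames(as.list(fit$estimates$estimate), fit$estimates$param)
  params_from_row(vals, omega = fit$omega)
}

#' Trial predictions at the MAP estimate
#'
#' @param fit An `hgf_fit`.
#' @return The [predict_trials()] table at the fitted parameters.
#' @export
fit_predictions <- function(fit) {
  p <- fit_params(fit)
  traj <- hgf_filter_schedule(fit$schedule, p$perceptual,
                              fit$model$perceptual)
  predict_trials(traj$advice, traj$card, fit$schedule$advice_color,
                 p$response, fit$model$response)
}

#' @export
print.hgf_fit <- function(x, ...) {
  cat("<hgf_fit> model:", x$model$name, "\n")
  cat("  log posterior:", format(x$logpost), " LME:", format(x$lme), "\n")
  cat("  free parameters:", sum(!x$estimates$fixed), "\n")
  invisible(x)
}

#' @rdname map_fit
#' @param x An `hgf_fit`.
#' @param ... Unused.
#' @method tidy hgf_fit
#' @export
tidy.hgf_fit <- function(x, ...) {
  dplyr::mutate(x$estimates,
                prior_mean = .data$mean_native,
                prior_sd_est = sqrt(.data$var_est))[,
    c("param", "estimate", "estimate_est", "transform", "fixed",
      "prior_mean", "prior_sd_est")]
}

#' @rdname map_fit
#' @method glance hgf_fit
#' @export
glance.hgf_fit <- function(x, ...) {
  tibble::tibble(model = x$model$name,
                 n_free = sum(!x$estimates$fixed),
                 n_trials = nrow(x$data),
                 logpost = x$logpost,
                 lme = x$lme,
                 converged = isTRUE(x$diagnostics$converged))
}
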