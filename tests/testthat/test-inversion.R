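# helper: pin every parameter except `keep` to `at` (native values)
pin_priors <- function(model, keep, at = list()) {
  pr <- default_priors(model)
  for (i in seq_len(nrow(pr))) {
    p <- pr$param[i]
    if (!p %in% keep) {
      pr$fixed[i] <- TRUE
      pr$var_est[i] <- 0
      if (!is.null(at[[p]])) pr$mean_native[i] <- at[[p]]
      pr$mean_est[i] <- NA_real_
    }
  }
  pr
}

empty_data <- function() {
  tibble::tibble(trial_index = integer(), choice = integer(),
                 wager = integer())
}

empty_schedule <- function() {
  tibble::tibble(trial_index = integer(), advice_accurate = integer(),
                 outcome_color = integer(), advice_color = integer())
}

test_that("with no data the joint posterior is the sum of the log priors", {
  m <- model_spec("three_level", "arbitrated")
  pr <- default_priors(m)
  free <- pr[!pr$fixed, ]
  par <- free$mean_est
  lp <- joint_log_posterior(par, empty_data(), empty_schedule(), m, pr)
  expect_equal(lp, sum(dnorm(0, 0, sqrt(free$var_est), log = TRUE)),
               tolerance = 1e-12)
  # one prior-SD away in a single coordinate costs exactly one half
  par2 <- par
  par2[1] <- par2[1] + sqrt(free$var_est[1])
  expect_equal(lp - joint_log_posterior(par2, empty_data(),
                                        empty_schedule(), m, pr),
               0.5, tolerance = 1e-10)
})

test_that("the fast objective agrees with the exported likelihood path", {
  s <- small_sched(60)
  sub <- ref_subject(s, seed = 13)
  m <- model_spec("three_level", "arbitrated")
  pr <- default_priors(m)
  free <- pr[!pr$fixed, ]
  set.seed(8)
  for (i in 1:5) {
    par <- free$mean_est + rnorm(nrow(free), 0, 0.3)
    native <- purrr::map2_dbl(par, free$transform,
                              arbihgf:::to_native)
    names(native) <- free$param
    pars <- arbihgf:::params_from_row(as.list(native))
    tr <- hgf_filter_schedule(s, pars$perceptual, "three_level")
    pred <- predict_trials(tr$advice, tr$card, s$advice_color,
                           pars$response, "arbitrated")
    ll <- response_loglik(pred, sub$choice, sub$wager,
                          pars$response$beta_wager)
    lp_ref <- ll + sum(dnorm(par, free$mean_est, sqrt(free$var_est),
                             log = TRUE))
    expect_equal(joint_log_posterior(par, sub, s, m, pr), lp_ref,
                 tolerance = 1e-8)
  }
})

test_that("the log posterior is additive over trials", {
  s <- default_sched()
  sub <- ref_subject(s, seed = 17)
  m <- model_spec("three_level", "arbitrated")
  pr <- default_priors(m)
  par <- pr$mean_est[!pr$fixed]
  lp_all <- joint_log_posterior(par, sub, s, m, pr)
  lp_head <- joint_log_posterior(par, sub[1:159, ], s[1:159, ], m, pr)
  # the final trial's own likelihood closes the gap (filters are causal,
  # so truncating the future does not change earlier predictions)
  pars <- arbihgf:::params_from_row(
    setNames(as.list(pr$mean_native), pr$param))
  tr <- hgf_filter_schedule(s, pars$perceptual)
  pred <- predict_trials(tr$advice, tr$card, s$advice_color, pars$response,
                         "arbitrated")
  ll160 <- response_loglik(pred[160, ], sub$choice[160], sub$wager[160],
                           pars$response$beta_wager)
  expect_equal(lp_all - lp_head, ll160, tolerance = 1e-9)
})

test_that("a fully pinned model returns the prior means without optimising", {
  m <- model_spec("normative", "card_only")
  pr <- pin_priors(m, keep = character(0))
  s <- small_sched(60)
  sub <- ref_subject(s, seed = 23)
  fit <- map_fit(sub, s, m, pr)
  expect_true(fit$diagnostics$converged)
  expect_equal(fit$diagnostics$n_starts, 0L)
  expect_equal(fit$estimates$estimate, pr$mean_native)
  # with no free parameters the evidence is the data likelihood itself
  expect_equal(fit$lme, joint_log_posterior(numeric(0), sub, s, m, pr))
  expect_equal(log_model_evidence(fit), fit$lme)
})

test_that("MAP on a two-parameter model matches an exhaustive grid search", {
  m <- model_spec("three_level", "arbitrated")
  gp <- ref_params()
  at <- list(kappa_a = 0.56, kappa_c = 0.58, theta_a = 0.62, theta_c = 0.59,
             beta_ch = gp$response$beta_ch, beta1 = -1.59, beta2 = 1.42,
             beta3 = 0.23, beta4 = 0.63, beta5 = -2.97, beta6 = -0.51,
             beta_wager = 0.35)
  pr <- pin_priors(m, keep = c("zeta", "beta0"), at = at)
  s <- small_sched(60, seed = 41)
  pars <- arbihgf:::params_from_row(c(at, list(zeta = 2, beta0 = 2.2)))
  sub <- simulate_agent(s, pars$perceptual, pars$response, m, seed = 42)
  fit <- map_fit(sub, s, m, pr, n_starts = 5, seed = 2)
  obj <- arbihgf:::make_objective(sub, s, m, pr)
  grid <- expand.grid(log_zeta = seq(-2, 2, length.out = 81),
                      beta0 = seq(0, 4.5, length.out = 81))
  vals <- mapply(function(a, b) obj(c(a, b)), grid$log_zeta, grid$beta0)
  best <- grid[which.min(vals), ]
  map <- fit$estimates$estimate_est[!fit$estimates$fixed]
  # the optimiser should do at least as well as the grid, with the same mode
  expect_lte(fit$logpost * -1, min(vals) + 1e-6)
  expect_lt(abs(map[1] - best$log_zeta), 0.06)
  expect_lt(abs(map[2] - best$beta0), 0.06)
})

test_that("a known social bias is recovered from low-noise data", {
  m <- model_spec("three_level", "arbitrated")
  s <- default_sched(51)
  gp <- ref_params()
  truth <- gp
  truth$response$zeta <- 2.8
  truth$response$beta_ch <- 40
  truth$response$beta_wager <- 0.2
  sub <- simulate_agent(s, truth$perceptual, truth$response, m, seed = 52)
  fit <- map_fit(sub, s, m, n_starts = 6, seed = 3)
  zeta_hat <- fit$estimates$estimate[fit$estimates$param == "zeta"]
  expect_lt(abs(log(zeta_hat) - log(2.8)), 0.7)
})

test_that("the optimum does not depend on the start jitter", {
  m <- model_spec("two_level", "arbitrated")
  s <- default_sched(61)
  sub <- ref_subject(s, seed = 62)
  f1 <- map_fit(sub, s, m, n_starts = 4, seed = 1)
  f2 <- map_fit(sub, s, m, n_starts = 4, seed = 99)
  expect_equal(f1$logpost, f2$logpost, tolerance = 1e-4)
  expect_equal(f1$estimates$estimate_est, f2$estimates$estimate_est,
               tolerance = 0.05)
  # and the whole fit is deterministic given its seed
  f3 <- map_fit(sub, s, m, n_starts = 4, seed = 1)
  expect_identical(f1$estimates, f3$estimates)
})

test_that("the Laplace evidence is exact for a Gaussian posterior", {
  set.seed(5)
  for (i in 1:5) {
    d <- sample(1:4, 1)
    mu <- rnorm(d)
    sd <- runif(d, 0.3, 3)
    c0 <- runif(1, -5, 5)
    f <- function(x) c0 + 0.5 * sum(((x - mu) / sd)^2)
    H <- arbihgf:::hessian_cd(f, mu)
    ev <- arbihgf:::laplace_evidence(f(mu), H)
    expect_equal(ev$lme, -c0 + sum(log(sd)) + d / 2 * log(2 * pi),
                 tolerance = 1e-5)
    expect_false(ev$regularized)
  }
})

test_that("an unused free parameter lowers the evidence", {
  # data generated by a card-only responder: the arbitrated model's extra
  # social-bias parameter is pure complexity
  m_gen <- model_spec("three_level", "card_only")
  m_rival <- model_spec("three_level", "arbitrated")
  gp <- ref_params()
  lme_gen <- lme_rival <- 0
  for (i in 1:3) {
    s <- default_sched(70 + i)
    sub <- simulate_agent(s, gp$perceptual, gp$response, m_gen,
                          seed = 80 + i)
    lme_gen <- lme_gen + map_fit(sub, s, m_gen, n_starts = 3,
                                 seed = i)$lme
    lme_rival <- lme_rival + map_fit(sub, s, m_rival, n_starts = 3,
                                     seed = i)$lme
  }
  expect_gt(lme_gen, lme_rival)
})

test_that("misaligned data are rejected", {
  s <- small_sched(60)
  sub <- ref_subject(s)
  expect_error(map_fit(sub[1:30, ], s, model_spec()), "aligned")
  expect_error(joint_log_posterior(numeric(0), sub[1:30, ], s,
                                   model_spec()), "aligned")
})
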