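test_that("arbitration is the biased precision ratio", {
  expect_equal(arbitrate(1, 1, zeta = 1)$xi_a, 0.5)
  expect_equal(arbitrate(3, 3, zeta = 0)$xi_a, 0)     # card-only limit
  expect_equal(arbitrate(3, 3, zeta = Inf)$xi_a, 1)   # advice-only limit
  expect_equal(arbitrate(1, 1, zeta = 2)$xi_a, 2 / 3)
  w <- arbitrate(c(2, 5), c(3, 1), zeta = 1.5)
  expect_equal(w$xi_a + w$xi_c, c(1, 1))
  expect_error(arbitrate(0, 0, zeta = 1), "undefined arbitration")
})

test_that("arbitration is monotone in precisions and bias", {
  pa <- seq(0.5, 5, length.out = 10)
  expect_true(all(diff(arbitrate(pa, 2, zeta = 1)$xi_a) > 0))
  expect_true(all(diff(arbitrate(2, pa, zeta = 1)$xi_a) < 0))
  zs <- seq(0.1, 5, length.out = 10)
  xi <- vapply(zs, function(z) arbitrate(2, 3, z)$xi_a, 1)
  expect_true(all(diff(xi) > 0))
})

test_that("belief integration is a convex combination in the advice frame", {
  expect_equal(integrate_belief(1, 0.8, 0, 0.3), 0.8)
  for (xi in c(0.2, 0.5, 0.9)) {
    expect_equal(integrate_belief(xi, 0.6, 1 - xi, 0.6), 0.6)
  }
  # advice says green while the card branch favours blue at 0.7:
  # in the advice frame the card prediction becomes 0.3
  mu_c_af <- ifelse(0 == 1, 0.7, 1 - 0.7)
  expect_equal(mu_c_af, 0.3)
  expect_equal(integrate_belief(0.5, 0.5, 0.5, mu_c_af), 0.4)
})

test_that("choice probability is a power softmax of the integrated belief", {
  expect_equal(choice_probability(0.7, 1), 0.7)
  for (b in c(0.5, 1, 4, 20)) expect_equal(choice_probability(0.5, b), 0.5)
  expect_gt(choice_probability(0.6, 200), 1 - 1e-6)
  # matches the direct formula away from the tails
  for (m in c(0.2, 0.45, 0.65, 0.9)) {
    for (b in c(0.7, 2, 7)) {
      expect_equal(choice_probability(m, b),
                   m^b / (m^b + (1 - m)^b), tolerance = 1e-12)
    }
  }
})

test_that("the wager regression responds to its uncertainty inputs", {
  rp <- response_params(beta0 = 1.2)
  expect_equal(wager_mean(0.1, 0.5, 0.1, 0.1, 0.3, 0.3, rp), 1.2)
  # a negative volatility weight lowers the expected wager as advisor
  # volatility rises
  rp5 <- response_params(beta0 = 1.2, beta5 = -2.97)
  v <- seq(0.1, 0.9, length.out = 5)
  wm <- wager_mean(0.2, 0.5, 0.1, 0.1, v, 0.3, rp5)
  expect_true(all(diff(wm) < 0))
  # irreducible uncertainty of a fair belief is maximal at 1/4
  expect_equal(0.5 * (1 - 0.5), 0.25)
  m <- seq(0.01, 0.99, 0.01)
  expect_true(all(m * (1 - m) <= 0.25))
})

test_that("wager likelihood is a bounded-scale Gaussian on the log wager", {
  # maximal at the mode...
  ll_mode <- wager_loglik(5, log(5), 0.4)
  expect_gt(ll_mode, wager_loglik(5, log(5) + 0.3, 0.4))
  # ...and doubling the scale costs log 2 at the mode
  expect_equal(wager_loglik(5, log(5), 0.8) - ll_mode, -log(2),
               tolerance = 1e-12)
  # end points are censored tail masses
  expect_equal(wager_loglik(1, 0.2, 0.4), pnorm(0, 0.2, 0.4, log.p = TRUE))
  expect_equal(wager_loglik(10, 2.5, 0.4),
               pnorm(log(10), 2.5, 0.4, lower.tail = FALSE, log.p = TRUE))
  # a far-out-of-range predicted wager is not catastrophically penalised
  expect_gt(wager_loglik(10, 6, 0.4), -1e-3)
  expect_error(wager_loglik(0, 1, 0.4), "1..10")
  expect_error(wager_loglik(5.5, 1, 0.4), "1..10")
})

test_that("a three-trial fixture matches the hand-computed likelihood", {
  # frozen from an independent arbitrary-precision evaluation:
  # mu_b = (.6, .3, .8), beta_ch = 2, choices (1, 0, 1);
  # wagers (5, 1, 10), wager mean log (1.5, .2, 2.5), scale 0.4
  pred <- tibble::tibble(
    p_take_advice = choice_probability(c(0.6, 0.3, 0.8), 2),
    wager_mean_log = c(1.5, 0.2, 2.5))
  ll <- response_loglik(pred, choice = c(1, 0, 1), wager = c(5, 1, 10),
                        beta_wager = 0.4)
  expect_equal(ll, -2.185206455002144, tolerance = 1e-12)
})

test_that("degenerate response variants ignore the other branch", {
  s <- small_sched(60)
  gp <- ref_params()
  tr <- hgf_filter_schedule(s, gp$perceptual)
  pc <- predict_trials(tr$advice, tr$card, s$advice_color, gp$response,
                       "card_only")
  # perturbing the advice branch leaves card-only choices untouched
  tr_perturbed <- hgf_filter_schedule(s, hgf_params(kappa_a = 0.2,
                                                    theta_a = 0.2))
  pc2 <- predict_trials(tr_perturbed$advice, tr$card, s$advice_color,
                        gp$response, "card_only")
  expect_equal(pc$p_take_advice, pc2$p_take_advice)
  # advice-only is the softmax of the advice prediction
  pa <- predict_trials(tr$advice, tr$card, s$advice_color, gp$response,
                       "advice_only")
  expect_equal(pa$p_take_advice,
               choice_probability(tr$advice$muhat1, gp$response$beta_ch),
               tolerance = 1e-9)
  # a huge social bias reproduces advice-only
  rp_big <- ref_params()$response
  rp_big$zeta <- 1e12
  pb <- predict_trials(tr$advice, tr$card, s$advice_color, rp_big,
                       "arbitrated")
  expect_equal(pb$p_take_advice, pa$p_take_advice, tolerance = 1e-8)
  # weights always sum to one
  for (p in list(pc, pa, pb)) expect_equal(p$xi_a + p$xi_c, rep(1, nrow(p)))
})

test_that("the choice likelihood is invariant to relabelling the colours", {
  s <- default_sched(8)
  sub <- ref_subject(s, seed = 9)
  m <- model_spec("three_level", "arbitrated")
  pr <- default_priors(m)
  par <- pr$mean_est[!pr$fixed] + 0.1
  flipped <- s
  flipped$outcome_color <- 1L - s$outcome_color
  flipped$advice_color <- 1L - s$advice_color
  flipped$advisor_info <- 1L - s$advisor_info
  flipped$p_blue <- 1 - s$p_blue
  # advice accuracy, and hence advice taking, are colour-neutral
  expect_equal(flipped$advice_accurate, s$advice_accurate)
  expect_equal(joint_log_posterior(par, sub, flipped, m, pr),
               joint_log_posterior(par, sub, s, m, pr), tolerance = 1e-10)
})

test_that("arbitration favours advice more in stable-advice phases", {
  xs <- xv <- numeric(20)
  gp <- ref_params()
  for (i in 1:20) {
    s <- default_sched(100 + i)
    tr <- hgf_filter_schedule(s, gp$perceptual)
    p <- predict_trials(tr$advice, tr$card, s$advice_color, gp$response,
                        "arbitrated")
    xs[i] <- mean(p$xi_a[s$advice_phase == "stable"])
    xv[i] <- mean(p$xi_a[s$advice_phase == "volatile"])
  }
  expect_gt(mean(xs), mean(xv))
})
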