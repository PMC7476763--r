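test_that("identical evidences give uniform frequencies and a high omnibus risk", {
  lme <- matrix(-100, nrow = 38, ncol = 9,
                dimnames = list(NULL, paste0("m", 1:9)))
  b <- rfx_bms(lme, n_samples = 1e5, seed = 1)
  expect_equal(unname(b$expected_frequency), rep(1 / 9, 9), tolerance = 1e-6)
  expect_equal(unname(b$exceedance_prob), rep(1 / 9, 9), tolerance = 0.01)
  expect_gt(b$bor, 0.9)
  expect_equal(unname(b$protected_exceedance_prob), rep(1 / 9, 9),
               tolerance = 0.01)
})

test_that("a dominant model attracts the exceedance mass", {
  set.seed(2)
  lme <- matrix(rnorm(10 * 4, -200, 2), 10, 4,
                dimnames = list(NULL, paste0("m", 1:4)))
  lme[, 2] <- lme[, 2] + 20   # one model ahead by 20 nats in every subject
  b <- rfx_bms(lme, seed = 3)
  expect_gte(b$exceedance_prob[["m2"]], 0.99)
  expect_equal(glance(b)$winning_model, "m2")
  expect_lt(b$bor, 0.01)
  # Dirichlet count conservation: sum(alpha) = sum(prior) + N
  expect_equal(sum(b$alpha), 4 + 10, tolerance = 1e-6)
})

test_that("two-model exceedance matches the closed-form beta oracle", {
  set.seed(4)
  lme <- matrix(rnorm(16, -150, 3), 8, 2,
                dimnames = list(NULL, c("a", "b")))
  b <- rfx_bms(lme, n_samples = 4e6, seed = 5)
  # with a Dirichlet(a1, a2) posterior, P(r1 > 1/2) is a regularised
  # incomplete beta integral
  ep_exact <- 1 - pbeta(0.5, b$alpha[["a"]], b$alpha[["b"]])
  expect_equal(b$exceedance_prob[["a"]], unname(ep_exact), tolerance = 1e-3)
})

test_that("adding a constant to one subject's row changes nothing", {
  set.seed(6)
  lme <- matrix(rnorm(15, -100, 5), 5, 3,
                dimnames = list(NULL, c("x", "y", "z")))
  lme2 <- lme
  lme2[3, ] <- lme2[3, ] + 137
  b1 <- rfx_bms(lme, n_samples = 1e5, seed = 7)
  b2 <- rfx_bms(lme2, n_samples = 1e5, seed = 7)
  expect_equal(b1$alpha, b2$alpha, tolerance = 1e-8)
  expect_equal(b1$exceedance_prob, b2$exceedance_prob)
  expect_equal(b1$bor, b2$bor, tolerance = 1e-8)
})

test_that("results are equivariant under model reordering", {
  set.seed(8)
  lme <- matrix(rnorm(24, -100, 4), 8, 3,
                dimnames = list(NULL, c("x", "y", "z")))
  perm <- c(3, 1, 2)
  b1 <- rfx_bms(lme, n_samples = 1e6, seed = 9)
  b2 <- rfx_bms(lme[, perm], n_samples = 1e6, seed = 9)
  expect_equal(b1$expected_frequency[perm], b2$expected_frequency,
               tolerance = 1e-8)
  expect_equal(b1$exceedance_prob[perm], b2$exceedance_prob,
               tolerance = 3e-3)
  expect_equal(b1$bor, b2$bor, tolerance = 1e-8)
})

test_that("invalid evidences and degenerate cohorts are flagged", {
  lme <- matrix(c(-1, NA, -2, -3), 2, 2,
                dimnames = list(NULL, c("a", "b")))
  expect_error(rfx_bms(lme), "subject 2, model a")
  expect_warning(rfx_bms(matrix(c(-1, -2), 1, 2,
                                dimnames = list(NULL, c("a", "b"))),
                         n_samples = 1e4),
                 "single subject")
})

test_that("family collapse is a uniform-prior log-sum-exp", {
  lme <- matrix(c(-10, -12, -11, -13, -9, -14), 2, 3,
                dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  # singleton families reproduce the input
  fam1 <- setNames(c("fa", "fb", "fc"), c("a", "b", "c"))
  expect_equal(unname(family_collapse(lme, fam1)), unname(lme))
  # two identical members give the member value back
  lme_dup <- cbind(lme, a2 = lme[, "a"])
  fam2 <- setNames(c("f1", "f2", "f2", "f1"), c("a", "b", "c", "a2"))
  out <- family_collapse(lme_dup, fam2)
  expect_equal(out[, "f1"], lme[, "a"])
  # hand computation: f2 = log((e^b + e^c) / 2) per subject
  expect_equal(out[, "f2"],
               log((exp(lme[, "b"]) + exp(lme[, "c"])) / 2))
  # column order follows first appearance; unassigned models error
  expect_equal(colnames(out), c("f1", "f2"))
  expect_error(family_collapse(lme, fam1[1:2]), "not assigned")
})

test_that("the nine-model space collapses into its three perceptual families", {
  lme <- matrix(rnorm(18, -100, 3), 2, 9,
                dimnames = list(NULL, names(model_space())))
  out <- family_collapse(lme, model_families("perceptual"))
  expect_equal(colnames(out), c("three_level", "two_level", "normative"))
  out_r <- family_collapse(lme, model_families("response"))
  expect_equal(colnames(out_r), c("arbitrated", "advice_only", "card_only"))
})
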