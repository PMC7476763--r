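#' Specify one model from the 3 x 3 model space
#'
#' Perceptual families: `three_level` (volatility tracked, `kappa`/`theta`
#' free), `two_level` (volatility frozen, `theta` pinned to 0.00062) and
#' `normative` (three-level updates with `kappa`/`theta` pinned to the prior
#' means, i.e. ideal-observer learning). Response families: `arbitrated`
#' (social bias `zeta` free), `advice_only` (`zeta = Inf`) and `card_only`
#' (`zeta = 0`).
#'
#' @param perceptual One of "three_level", "two_level", "normative".
#' @param response One of "arbitrated", "advice_only", "card_only".
#' @return A list of class `model_spec` with a canonical `name`.
#' @export
model_spec <- function(perceptual = c("three_level", "two_level", "normative"),
                       response = c("arbitrated", "advice_only", "card_only")) {
  perceptual <- match.arg(perceptual)
  response <- match.arg(response)
  structure(list(perceptual = perceptual, response = response,
                 name = paste(perceptual, response, sep = "_")),
            class = "model_spec")
}

#' The full 3 x 3 model space
#'
#' @return Named list of nine [model_spec()] objects.
#' @export
model_space <- function() {
  specs <- purrr::map(
    c("three_level", "two_level", "normative"),
    function(p) purrr::map(c("arbitrated", "advice_only", "card_only"),
                           function(r) model_spec(p, r)))
  specs <- purrr::flatten(specs)
  names(specs) <- purrr::map_chr(specs, "name")
  specs
}

#' Family membership of the nine models
#'
#' @param by Group by "perceptual" or "response" family.
#' @return Named character vector mapping model name to family label.
#' @export
model_families <- function(by = c("perceptual", "response")) {
  by <- match.arg(by)
  specs <- model_space()
  fam <- purrr::map_chr(specs, by)
  setNames(fam, names(specs))
}

# parameter transform helpers -------------------------------------------------

to_est <- function(x, transform) {
  switch(transform,
         logit = qlogis(x),
         log = log(x),
         identity = x,
         stop("unknown transform", call. = FALSE))
}

to_native <- function(x, transform) {
  switch(transform,
         logit = plogis(x),
         log = exp(x),
         identity = x,
         stop("unknown transform", call. = FALSE))
}

#' Prior specification for a model's parameters
#'
#' One row per parameter with its native-space prior mean, prior variance in
#' estimation space, transform and fixed flag. `kappa` and `theta` are
#' estimated in logit space (priors 0.5 and 0.55, variance 1); `zeta`,
#' `beta_ch` and `beta_wager` in log space; the wager coefficients in native
#' space. Zero-variance parameters are pinned to the prior mean and excluded
#' from optimisation: the `normative` family pins `kappa`/`theta` to the
#' prior means;
#' `advice_only`/`card_only` pin `zeta` to `Inf`/`0`. `beta_ch` carries a
#' shrinkage prior (mean 48, variance 1 in log space) so that behaviour is
#' attributed to the remaining parameters rather than decision noise.
#' The `two_level` family removes the volatility coupling (`kappa` pinned
#' to 0) alongside the pinned `theta`.
#'
#' @param model A [model_spec()].
#' @return Tibble of class `prior_spec` with columns `param`, `mean_native`,
#'   `var_est`, `transform`, `fixed`.
#' @export
default_priors <- function(model) {
  stopifnot(inherits(model, "model_spec"))
  perc <- switch(model$perceptual,
    three_level = tibble::tribble(
      ~param, ~mean_native, ~var_est, ~transform, ~fixed,
      "kappa_a", 0.5, 1, "logit", FALSE,
      "kappa_c", 0.5, 1, "logit", FALSE,
      "theta_a", 0.55, 1, "logit", FALSE,
      "theta_c", 0.55, 1, "logit", FALSE),
    normative = tibble::tribble(
      ~param, ~mean_native, ~var_est, ~transform, ~fixed,
      "kappa_a", 0.5, 0, "logit", TRUE,
      "kappa_c", 0.5, 0, "logit", TRUE,
      "theta_a", 0.55, 0, "logit", TRUE,
      "theta_c", 0.55, 0, "logit", TRUE),
    two_level = tibble::tribble(
      ~param, ~mean_native, ~var_est, ~transform, ~fixed,
      "kappa_a", 0.5, 0, "logit", TRUE,
      "kappa_c", 0.5, 0, "logit", TRUE,
      "theta_a", 0.00062, 0, "logit", TRUE,
      "theta_c", 0.00062, 0, "logit", TRUE))
  zeta_row <- switch(model$response,
    arbitrated = tibble::tibble(param = "zeta", mean_native = 1,
                                var_est = 25, transform = "log",
                                fixed = FALSE),
    advice_only = tibble::tibble(param = "zeta", mean_native = Inf,
                                 var_est = 0, transform = "log",
                                 fixed = TRUE),
    card_only = tibble::tibble(param = "zeta", mean_native = 0,
                               var_est = 0, transform = "log", fixed = TRUE))
  resp <- tibble::tribble(
    ~param, ~mean_native, ~var_est, ~transform, ~fixed,
    "beta_ch", 48, 1, "log", FALSE,
    "beta0", 6.21, 4, "identity", FALSE,
    "beta1", 0, 4, "identity", FALSE,
    "beta2", 0, 4, "identity", FALSE,
    "beta3", 0, 4, "identity", FALSE,
    "beta4", 0, 4, "identity", FALSE,
    "beta5", 0, 4, "identity", FALSE,
    "beta6", 0, 4, "identity", FALSE,
    "beta_wager", 1.5, 100, "log", FALSE)
  out <- dplyr::bind_rows(perc, zeta_row, resp)
  out$mean_est <- purrr::pmap_dbl(
    out[, c("mean_native", "transform", "fixed")],
    function(mean_native, transform, fixed) {
      if (fixed) return(NA_real_)
      to_est(mean_native, transform)
    })
  class(out) <- c("prior_spec", class(out))
  out
}

#' Reference cohort-average parameter values
#'
#' Group-average parameter set used as the package's default for simulations
#' of a typical participant under the winning (arbitrated three-level) model:
#' coupling and meta-volatility per branch in native space, social bias and
#' inverse decision temperature given on their log estimation scale, wager
#' coefficients in native space. `beta0` and `beta_wager` are set so that
#' simulated wagers occupy the middle of the 1-10 scale (see the methods
#' vignette).
#'
#' @return List with elements `perceptual` ([hgf_params()]) and `response`
#'   ([response_params()]).
#' @export
group_mean_params <- function() {
  list(
    perceptual = hgf_params(kappa_a = 0.56, kappa_c = 0.58,
                            theta_a = 0.62, theta_c = 0.59),
    response = response_params(zeta = exp(1.03), beta_ch = exp(2.25),
                               beta0 = 3.7, beta1 = -1.59, beta2 = 1.42,
                               beta3 = 0.23, beta4 = 0.63, beta5 = -2.97,
                               beta6 = -0.51, beta_wager = 0.35))
}

#' Reference cohort population distribution
#'
#' Per-parameter generating distributions for synthetic cohorts: Gaussians
#' with the cohort means and SDs, expressed in the space given by `space`
#' ("native" with truncation to the admissible range for the logit-scaled
#' learning parameters, or "est" for log-scale parameters) and truncated to
#' the admissible range.
#'
#' @return Tibble with columns `param`, `mean`, `sd`, `space`.
#' @export
default_population <- function() {
  tibble::tribble(
    ~param, ~mean, ~sd, ~space,
    "kappa_a", 0.56, 0.28, "native",
    "kappa_c", 0.58, 0.17, "native",
    "theta_a", 0.62, 0.09, "native",
    "theta_c", 0.59, 0.07, "native",
    "zeta", 1.03, 1.24, "est",
    "beta_ch", 2.25, 0.92, "est",
    "beta0", 3.7, 1.0, "native",
    "beta1", -1.59, 0.94, "native",
    "beta2", 1.42, 1.69, "native",
    "beta3", 0.23, 1.37, "native",
    "beta4", 0.63, 1.24, "native",
    "beta5", -2.97, 2.47, "native",
    "beta6", -0.51, 1.83, "native",
    "beta_wager", log(0.35), 0.4, "est")
}

#' Draw a synthetic cohort from a population specification
#'
#' Truncated-Gaussian draws per parameter: unit-interval parameters
#' (`kappa`, `theta`) are truncated to (0.01, 0.99) in native space; log-space
#' draws are exponentiated to native space.
#'
#' @param n Number of subjects.
#' @param population Tibble as returned by [default_population()].
#' @param seed Integer seed.
#' @return Tibble of native-space parameter values, one row per subject,
#'   with a `subject` column.
#' @export
draw_population <- function(n, population = default_population(), seed = 1L) {
  set.seed(seed)
  cols <- purrr::pmap(population, function(param, mean, sd, space) {
    x <- rnorm(n, mean, sd)
    if (space == "est") {
      tr <- param_transform(param)
      x <- to_native(x, tr)
    }
    if (param %in% c("kappa_a", "kappa_c", "theta_a", "theta_c")) {
      x <- pmin(pmax(x, 0.01), 0.99)
    }
    if (param %in% c("beta_ch", "beta_wager", "zeta")) {
      x <- pmax(x, 1e-3)
    }
    x
  })
  names(cols) <- population$param
  dplyr::bind_cols(tibble::tibble(subject = seq_len(n)),
                   tibble::as_tibble(cols))
}

param_transform <- function(param) {
  dplyr::case_when(
    param %in% c("kappa_a", "kappa_c", "theta_a", "theta_c") ~ "logit",
    param %in% c("zeta", "beta_ch", "beta_wager") ~ "log",
    TRUE ~ "identity")
}

# Assemble hgf_params / response_params from a named list or one-row tibble
# of native-space values, filling unset entries with defaults.
params_from_row <- function(row, omega = -2.5) {
  row <- as.list(row)
  perc <- hgf_params(kappa_a = row$kappa_a %||% 0.5,
                     kappa_c = row$kappa_c %||% 0.5,
                     theta_a = row$theta_a %||% 0.55,
                     theta_c = row$theta_c %||% 0.55,
                     omega = omega)
  resp <- response_params(zeta = row$zeta %||% 1,
                          beta_ch = row$beta_ch %||% 48,
                          beta0 = row$beta0 %||% 6.21,
                          beta1 = row$beta1 %||% 0, beta2 = row$beta2 %||% 0,
                          beta3 = row$beta3 %||% 0, beta4 = row$beta4 %||% 0,
                          beta5 = row$beta5 %||% 0, beta6 = row$beta6 %||% 0,
                          beta_wager = row$beta_wager %||% 1.5)
  list(perceptual = perc, response = resp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
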