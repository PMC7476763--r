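# Random-effects Bayesian model selection over a subjects x models
# log-evidence matrix, with protected exceedance probabilities.

#' Random-effects Bayesian model selection
#'
#' Treats the model identity as a random effect across subjects and infers a
#' Dirichlet posterior over model frequencies by variational Bayes. Reports
#' expected posterior model frequencies `p(m|y)`, exceedance probabilities
#' (Monte-Carlo over Dirichlet draws), the Bayes Omnibus Risk (posterior
#' probability that all models are equally frequent, from the free-energy
#' comparison of the random-effects model against the equal-frequency null)
#' and protected exceedance probabilities
#' `phi_p = (1 - BOR) * EP + BOR / M`.
#'
#' @param lme Numeric matrix or data frame of log model evidences, subjects
#'   in rows, models in columns (column names name the models).
#' @param prior_alpha Prior Dirichlet count per model (default 1, uniform).
#' @param n_samples Dirichlet Monte-Carlo draws for the exceedance
#'   probabilities (default 1e6).
#' @param seed Seed for the Monte-Carlo draws.
#' @param max_iter,tol Variational iteration controls.
#' @return Object of class `bms_result` with elements `alpha`,
#'   `expected_frequency` (the reported `p(m|y)`), `exceedance_prob`,
#'   `protected_exceedance_prob`, `bor`, `assignment` (subjects x models
#'   posterior model attributions) and free energies `F_rfx`, `F_null`.
#' @export
rfx_bms <- function(lme, prior_alpha = 1, n_samples = 1e6, seed = 1L,
                    max_iter = 500L, tol = 1e-8) {
  lme <- as.matrix(lme)
  if (!is.numeric(lme) || any(!is.finite(lme))) {
    bad <- which(!is.finite(lme), arr.ind = TRUE)
    stop("non-finite log evidence for subject ", bad[1, 1], ", model ",
         if (!is.null(colnames(lme))) colnames(lme)[bad[1, 2]] else bad[1, 2],
         call. = FALSE)
  }
  n <- nrow(lme)
  m <- ncol(lme)
  stopifnot(n >= 1, m >= 2)
  if (n == 1) {
    warning("random-effects BMS on a single subject is degenerate; ",
            "results reduce to that subject's evidence ratios")
  }
  if (is.null(colnames(lme))) colnames(lme) <- paste0("model", seq_len(m))
  alpha0 <- rep(prior_alpha, m)

  alpha <- alpha0 + n / m
  for (it in seq_len(max_iter)) {
    elogr <- digamma(alpha) - digamma(sum(alpha))
    lu <- sweep(lme, 2, elogr, `+`)
    lu <- lu - apply(lu, 1, max)
    u <- exp(lu)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  expected_freq <- alpha / sum(alpha)

  # exceedance probabilities by seeded Dirichlet Monte Carlo
  set.seed(seed)
  draws <- matrix(rgamma(n_samples * m, shape = rep(alpha, each = n_samples)),
                  nrow = n_samples)
  win <- max.col(draws, ties.method = "first")
  ep <- tabulate(win, nbins = m) / n_samples

  # free energies: random-effects model vs equal-frequency null
  elogr <- digamma(alpha) - digamma(sum(alpha))
  f_rfx <- sum(u * (lme + matrix(elogr, n, m, byrow = TRUE))) -
    sum(u * log(pmax(u, 1e-300))) - dirichlet_kl(alpha, alpha0)
  f_null <- sum(apply(lme, 1, logsumexp) - log(m))
  bor <- 1 / (1 + exp(f_rfx - f_null))
  pep <- (1 - bor) * ep + bor / m

  structure(list(
    models = colnames(lme),
    alpha = setNames(alpha, colnames(lme)),
    expected_frequency = setNames(expected_freq, colnames(lme)),
    exceedance_prob = setNames(ep, colnames(lme)),
    protected_exceedance_prob = setNames(pep, colnames(lme)),
    bor = bor, F_rfx = f_rfx, F_null = f_null,
    assignment = u, n_subjects = n, prior_alpha = alpha0,
    n_samples = n_samples),
    class = "bms_result")
}

logsumexp <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

# KL divergence between two Dirichlet distributions KL(q || p).
dirichlet_kl <- function(aq, ap) {
  lgamma(sum(aq)) - sum(lgamma(aq)) - lgamma(sum(ap)) + sum(lgamma(ap)) +
    sum((aq - ap) * (digamma(aq) - digamma(sum(aq))))
}

#' Collapse a log-evidence matrix over model families
#'
#' Per-subject family evidence is the log-sum-exp of the member models'
#' evidences under a uniform within-family prior (minus the log family
#' size).
#'
#' @param lme Subjects x models log-evidence matrix (named columns).
#' @param family_map Named character vector mapping every model (column
#'   name) to a family label, e.g. [model_families()].
#' @return Subjects x families log-evidence matrix; column order follows
#'   the order in which families first appear in `family_map`.
#' @export
family_collapse <- function(lme, family_map) {
  lme <- as.matrix(lme)
  if (is.null(colnames(lme))) {
    stop("lme needs model names as column names", call. = FALSE)
  }
  missing <- setdiff(colnames(lme), names(family_map))
  if (length(missing)) {
    stop("models not assigned to a family: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  fams <- unique(unname(family_map[colnames(lme)]))
  out <- vapply(fams, function(f) {
    members <- colnames(lme)[family_map[colnames(lme)] == f]
    apply(lme[, members, drop = FALSE], 1, logsumexp) - log(length(members))
  }, numeric(nrow(lme)))
  out <- matrix(out, nrow = nrow(lme),
                dimnames = list(rownames(lme), fams))
  out
}

#' @export
print.bms_result <- function(x, ...) {
  cat("<bms_result>", x$n_subjects, "subjects,", length(x$models),
      "models\n")
  print(tidy(x), ...)
  cat("Bayes Omnibus Risk:", format(x$bor), "\n")
  invisible(x)
}

#' @rdname rfx_bms
#' @param x A `bms_result`.
#' @param ... Unused.
#' @method tidy bms_result
#' @export
tidy.bms_result <- function(x, ...) {
  tibble::tibble(model = x$models,
                 alpha = unname(x$alpha),
                 p_m_y = unname(x$expected_frequency),
                 exceedance_prob = unname(x$exceedance_prob),
                 protected_exceedance_prob =
                   unname(x$protected_exceedance_prob))
}

#' @rdname rfx_bms
#' @method glance bms_result
#' @export
glance.bms_result <- function(x, ...) {
  best <- which.max(x$protected_exceedance_prob)
  tibble::tibble(n_subjects = x$n_subjects,
                 n_models = length(x$models),
                 winning_model = x$models[best],
                 winning_pep = unname(x$protected_exceedance_prob[best]),
                 bor = x$bor)
}
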