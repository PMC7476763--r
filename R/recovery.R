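# Parameter-recovery study: simulate a synthetic cohort, refit, and
# quantify recoverability with Cohen's f per parameter.

#' Cohen's f from a simulated-vs-recovered regression
#'
#' Least-squares regression of recovered on simulated values;
#' `f = sqrt(R^2 / (1 - R^2))`. The statistic is invariant to affine
#' rescaling of either axis and is capped at 10 when `R^2 > 0.99` so that
#' near-perfect recovery reports a bounded value.
#'
#' @param simulated,recovered Equal-length numeric vectors (n >= 3); the
#'   simulated values need nonzero variance.
#' @param cap Reporting cap (default 10).
#' @return Scalar Cohen's f.
#' @examples
#' # R^2 = 0.5 gives f = 1
#' @export
cohens_f <- function(simulated, recovered, cap = 10) {
  if (length(simulated) != length(recovered) || length(simulated) < 3) {
    stop("need equal-length vectors of at least 3 values", call. = FALSE)
  }
  if (var(simulated) == 0) {
    stop("undefined effect size: simulated values have zero variance",
         call. = FALSE)
  }
  r2 <- r_squared(simulated, recovered)
  if (r2 > 0.99) return(cap)
  min(sqrt(r2 / (1 - r2)), cap)
}

r_squared <- function(simulated, recovered) {
  if (var(recovered) == 0) return(0)
  fit <- lm(recovered ~ simulated)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((recovered - mean(recovered))^2)
  max(0, 1 - ss_res / ss_tot)
}

#' Simulate-and-refit parameter recovery study
#'
#' Draws a synthetic cohort from the population specification, simulates each
#' subject's choices and wagers on the task schedule, refits the model by
#' MAP, and regresses recovered on simulated values per free parameter in
#' estimation space (the space the optimiser works in). Subjects whose fit
#' fails are excluded with a logged count; more than 20% failures aborts.
#'
#' @param n_subjects Number of synthetic subjects (default 38).
#' @param model A [model_spec()] (default: arbitrated three-level).
#' @param population Population tibble (see [default_population()]), or a
#'   data frame of per-subject native-space parameter values with a
#'   `subject` column to use a fixed cohort.
#' @param config Task configuration for the shared schedule; every subject
#'   sees the same input sequence, as in the original design.
#' @param seed Master seed (population draw, response sampling, fits).
#' @param n_starts Optimisation restarts per fit.
#' @param f_threshold Pass mark for Cohen's f (default 0.4, the conventional
#'   large-effect bound).
#' @return Object of class `recovery_report`: `summary` (per-parameter
#'   R-squared, Cohen's f, pass flag), `values` (per-subject simulated and
#'   recovered values in both spaces) and bookkeeping fields.
#' @export
run_recovery <- function(n_subjects = 38L,
                         model = model_spec("three_level", "arbitrated"),
                         population = default_population(),
                         config = task_config(),
                         seed = 1L,
                         n_starts = 10L,
                         f_threshold = 0.4) {
  priors <- default_priors(model)
  free <- priors$param[!priors$fixed]
  if ("subject" %in% names(population)) {
    cohort <- tibble::as_tibble(population)
    n_subjects <- nrow(cohort)
  } else {
    cohort <- draw_population(n_subjects, population, seed = seed)
  }
  schedule <- generate_schedule(config, seed = seed)

  fits <- purrr::map(seq_len(n_subjects), function(i) {
    # a diverging simulation (inadmissible draw) counts as a failed subject
    tryCatch({
      pars <- params_from_row(cohort[i, setdiff(names(cohort), "subject")])
      sim <- simulate_agent(schedule, pars$perceptual, pars$response, model,
                            seed = seed + 1000L + i)
      map_fit(sim, schedule, model, priors, n_starts = n_starts,
              seed = seed + 2000L + i)
    }, error = function(e) NULL)
  })
  failed <- purrr::map_lgl(fits, function(f) {
    is.null(f) || !isTRUE(f$diagnostics$converged)
  })
  if (mean(failed) > 0.2) {
    stop("parameter recovery aborted: ", sum(failed), " of ", n_subjects,
         " fits failed", call. = FALSE)
  }

  values <- purrr::map_dfr(which(!failed), function(i) {
    est <- fits[[i]]$estimates
    est <- est[!est$fixed, ]
    sim_native <- unlist(cohort[i, est$param])
    tibble::tibble(
      subject = cohort$subject[i],
      param = est$param,
      simulated = unname(sim_native),
      recovered = est$estimate,
      simulated_est = purrr::map2_dbl(unname(sim_native), est$transform,
                                      to_est),
      recovered_est = est$estimate_est)
  })

  summary <- values |>
    dplyr::group_by(.data$param) |>
    dplyr::summarise(
      n = dplyr::n(),
      r_squared = r_squared(.data$simulated_est, .data$recovered_est),
      cohens_f = cohens_f(.data$simulated_est, .data$recovered_est),
      .groups = "drop") |>
    dplyr::mutate(pass = .data$cohens_f >= f_threshold)
  summary <- summary[match(free, summary$param), ]

  structure(list(summary = summary, values = values,
                 n_subjects = n_subjects, n_failed = sum(failed),
                 model = model$name, f_threshold = f_threshold,
                 seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>", x$model, "-", x$n_subjects, "subjects (",
      x$n_failed, "failed )\n")
  print(x$summary, ...)
  invisible(x)
}

#' @rdname run_recovery
#' @param x A `recovery_report`.
#' @param ... Unused.
#' @method tidy recovery_report
#' @export
tidy.recovery_report <- function(x, ...) x$summary

#' @rdname run_recovery
#' @method glance recovery_report
#' @export
glance.recovery_report <- function(x, ...) {
  tibble::tibble(model = x$model,
                 n_subjects = x$n_subjects,
                 n_failed = x$n_failed,
                 min_cohens_f = min(x$summary$cohens_f),
                 all_pass = all(x$summary$pass))
}
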