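# Delimited-table I/O and the end-to-end pipeline.
#
# All tables are comma-separated with a header row; floating-point values
# are serialised with 12 significant digits, which round-trips the
# quantities used in reproducibility checks.

fmt_cols <- function(df) {
  dplyr::mutate(df, dplyr::across(
    dplyr::where(function(x) is.double(x) && !is.integer(x)),
    function(x) formatC(x, digits = 12, format = "g")))
}

write_table12 <- function(df, path) {
  readr::write_csv(fmt_cols(df), path, progress = FALSE)
  invisible(path)
}

#' Write / read a task schedule
#'
#' One row per trial with the `task_schedule` field names as header.
#'
#' @param schedule A `task_schedule`.
#' @param path File path.
#' @return The schedule (invisibly for write; a validated tibble for read).
#' @export
write_schedule <- function(schedule, path) {
  write_table12(tibble::as_tibble(schedule), path)
  invisible(schedule)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("trial_index", "card_phase", "advice_phase", "p_blue",
            "outcome_color", "advisor_info", "advice_color",
            "advice_accurate")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("schedule file is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("outcome_color", "advisor_info", "advice_color",
                "advice_accurate")) {
    if (!all(df[[col]] %in% c(0, 1))) {
      stop("column ", col, " must be binary", call. = FALSE)
    }
  }
  class(df) <- c("task_schedule", class(df))
  df
}

#' Read / write subject responses
#'
#' Responses are a table with columns `trial_index`, `choice` (1 = advice
#' taken) and `wager` (integer 1..10). Reading validates the schema and
#' names the offending row on failure.
#'
#' @param path File path.
#' @return Tibble of class `subject_data`.
#' @export
read_responses <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("trial_index", "choice", "wager")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("responses file is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- which(!(df$choice %in% c(0, 1)))
  if (length(bad)) {
    stop("non-binary choice in row ", bad[1], call. = FALSE)
  }
  bad <- which(df$wager != round(df$wager) | df$wager < 1 | df$wager > 10)
  if (length(bad)) {
    stop("wager out of range 1..10 in row ", bad[1], call. = FALSE)
  }
  df$choice <- as.integer(df$choice)
  df$wager <- as.integer(df$wager)
  class(df) <- c("subject_data", class(df))
  df
}

#' @rdname read_responses
#' @param responses A `subject_data` tibble.
#' @export
write_responses <- function(responses, path) {
  write_table12(tibble::as_tibble(responses)[,
    intersect(c("trial_index", "choice", "wager", "prediction", "correct"),
              names(responses))], path)
  invisible(responses)
}

#' Read a subjects x models log-evidence matrix
#'
#' Expects a delimited table whose first column holds subject identifiers
#' and whose remaining columns are named after models. A deposited
#' log-evidence table with a differently named identifier column is
#' ingested by renaming that first column (the one-line mapping
#' `dplyr::rename(subject = 1)` is applied automatically).
#'
#' @param path File path.
#' @return Numeric matrix with subject IDs as row names.
#' @export
read_lme_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 3) stop("need a subject column and at least two models",
                         call. = FALSE)
  df <- dplyr::rename(df, subject = 1)
  m <- as.matrix(df[, -1])
  if (!is.numeric(m)) stop("log evidences must be numeric", call. = FALSE)
  rownames(m) <- as.character(df$subject)
  m
}

#' @rdname read_lme_matrix
#' @param lme Matrix of log evidences (named columns).
#' @export
write_lme_matrix <- function(lme, path) {
  df <- dplyr::bind_cols(
    tibble::tibble(subject = rownames(lme) %||% seq_len(nrow(lme))),
    tibble::as_tibble(lme))
  write_table12(df, path)
  invisible(lme)
}

#' Export a branch trajectory (or a pair) as a delimited table
#'
#' @param traj An `hgf_trajectory` or the list returned by
#'   [hgf_filter_schedule()] (columns get branch suffixes `_a`, `_c`).
#' @param path File path.
#' @export
write_trajectories <- function(traj, path) {
  if (inherits(traj, "hgf_trajectory")) {
    write_table12(tibble::as_tibble(traj), path)
  } else {
    a <- dplyr::rename_with(tibble::as_tibble(traj$advice),
                            function(x) paste0(x, "_a"), -"trial")
    c_ <- dplyr::rename_with(tibble::as_tibble(traj$card),
                             function(x) paste0(x, "_c"), -"trial")
    write_table12(dplyr::left_join(a, c_, by = "trial"), path)
  }
  invisible(traj)
}

#' Run the full pipeline: simulate, fit the model space, select
#'
#' Simulates a cohort under the arbitrated three-level model (parameters
#' drawn from the population specification), fits all nine models to every
#' subject, assembles the log-evidence matrix, runs random-effects model
#' selection and writes every stage's table plus a manifest to `out_dir`.
#' Stage failures abort with the stage name; completed outputs persist.
#'
#' @param out_dir Output directory (created if missing).
#' @param n_subjects Cohort size (default 5).
#' @param config Task configuration.
#' @param population Population specification for the simulated cohort.
#' @param models List of [model_spec()]s to fit (default: the 3 x 3 space).
#' @param seed Master seed; recorded in the manifest.
#' @param n_starts Optimisation restarts per fit.
#' @return Invisibly, a list with the LME matrix and the `bms_result`.
#' @export
pipeline_run <- function(out_dir,
                         n_subjects = 5L,
                         config = task_config(),
                         population = default_population(),
                         models = model_space(),
                         seed = 1L,
                         n_starts = 10L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  gen_model <- model_spec("three_level", "arbitrated")

  schedule <- stage("simulate", {
    s <- generate_schedule(config, seed = seed)
    write_schedule(s, file.path(out_dir, "schedule.csv"))
    s
  })
  cohort <- stage("simulate", draw_population(n_subjects, population,
                                              seed = seed))
  sims <- stage("simulate", {
    purrr::map(seq_len(n_subjects), function(i) {
      pars <- params_from_row(cohort[i, setdiff(names(cohort), "subject")])
      sim <- simulate_agent(schedule, pars$perceptual, pars$response,
                            gen_model, seed = seed + 1000L + i)
      write_responses(sim, file.path(out_dir,
                                     sprintf("responses_s%02d.csv", i)))
      sim
    })
  })

  lme <- stage("fit", {
    rows <- purrr::map(seq_len(n_subjects), function(i) {
      purrr::map_dbl(models, function(m) {
        fit <- map_fit(sims[[i]], schedule, m, n_starts = n_starts,
                       seed = seed + 3000L + i)
        fit$lme
      })
    })
    mat <- do.call(rbind, rows)
    rownames(mat) <- sprintf("s%02d", seq_len(n_subjects))
    colnames(mat) <- names(models)
    write_lme_matrix(mat, file.path(out_dir, "lme_matrix.csv"))
    mat
  })

  bms <- stage("compare", {
    b <- rfx_bms(lme, seed = seed)
    write_table12(tidy(b), file.path(out_dir, "bms.csv"))
    write_table12(glance(b), file.path(out_dir, "bms_summary.csv"))
    b
  })

  stage("manifest", {
    jsonlite::write_json(
      list(package = "arbihgf",
           version = as.character(utils::packageVersion("arbihgf")),
           seed = seed, n_subjects = n_subjects,
           n_trials = config$n_trials,
           models = names(models),
           config_hash = rlang::hash(config)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  })
  invisible(list(lme = lme, bms = bms, schedule = schedule))
}
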