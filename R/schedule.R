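#' Configuration for the synthetic task-schedule generator
#'
#' Describes the binary lottery paradigm: a sequence of card draws (blue vs
#' green) whose reward contingency switches between stable and volatile
#' phases, and a stream of advice from an advisor who privately knows the
#' outcome with fixed accuracy but alternates between helpful and misleading
#' intentions. Card contingencies and advisor intentions vary independently,
#' giving a 2 x 2 factorial phase structure in contiguous blocks.
#'
#' Aggregate design targets (advice accuracy, card-colour base rate, private
#' signal accuracy) are enforced by exact count construction: the number of
#' accurate-advice trials, correct private signals and blue outcomes are fixed
#' integers apportioned across blocks, and only their positions within blocks
#' are randomised. This makes design-level checks deterministic.
#'
#' @param n_trials Number of trials (default 160, split into sessions of 70
#'   and 90 recorded as metadata).
#' @param target_advice_accuracy Long-run probability that the advice names
#'   the rewarded colour (default 0.56).
#' @param target_card_probability Long-run probability that blue is the
#'   rewarded colour (default 0.55).
#' @param advisor_info_accuracy Accuracy of the advisor's private signal
#'   about the outcome (default 0.80).
#' @param stable_contingency Probability of the favoured colour within a
#'   block (default 0.8; volatile phases alternate the favoured colour in
#'   short sub-blocks at the same contingency).
#' @param card_blocks,advice_blocks Optional data frames overriding the
#'   default block layout. `card_blocks` needs columns `phase`
#'   ("stable"/"volatile"), `favored` ("blue"/"green") and `length`;
#'   `advice_blocks` needs `phase`, `intent` ("helpful"/"misleading") and
#'   `length`. Lengths must sum to `n_trials`.
#' @return A list of class `task_config`.
#' @export
task_config <- function(n_trials = 160L,
                        target_advice_accuracy = 0.56,
                        target_card_probability = 0.55,
                        advisor_info_accuracy = 0.80,
                        stable_contingency = 0.8,
                        card_blocks = NULL,
                        advice_blocks = NULL) {
  n_trials <- as.integer(n_trials)
  stopifnot(n_trials >= 8L)
  for (p in c(target_advice_accuracy, target_card_probability,
              advisor_info_accuracy, stable_contingency)) {
    if (!is.numeric(p) || p <= 0 || p > 1) {
      stop("probabilities must lie in (0, 1]", call. = FALSE)
    }
  }
  if (is.null(card_blocks)) card_blocks <- default_card_blocks(n_trials)
  if (is.null(advice_blocks)) advice_blocks <- default_advice_blocks(n_trials)
  card_blocks <- tibble::as_tibble(card_blocks)
  advice_blocks <- tibble::as_tibble(advice_blocks)
  if (sum(card_blocks$length) != n_trials ||
      sum(advice_blocks$length) != n_trials) {
    stop("block lengths must sum to n_trials", call. = FALSE)
  }
  structure(
    list(n_trials = n_trials,
         target_advice_accuracy = target_advice_accuracy,
         target_card_probability = target_card_probability,
         advisor_info_accuracy = advisor_info_accuracy,
         stable_contingency = stable_contingency,
         card_blocks = card_blocks,
         advice_blocks = advice_blocks,
         sessions = c(round(n_trials * 7 / 16), n_trials - round(n_trials * 7 / 16))),
    class = "task_config")
}

# Default card layout (proportions of the 160-trial design): a long stable
# green-favoured opening block, a volatile mid-phase alternating the
# favoured colour, and a closing stable blue-favoured block. Favoured-colour
# totals give a blue base rate averaging ~0.55 at contingency 0.8, and the
# alignment with the advisor-intention layout keeps the advice-accuracy and
# outcome sequences close to orthogonal.
default_card_blocks <- function(n_trials) {
  base <- tibble::tribble(
    ~phase,     ~favored, ~length,
    "stable",   "green",  48L,
    "volatile", "blue",   12L,
    "volatile", "green",   8L,
    "volatile", "blue",   12L,
    "volatile", "green",   6L,
    "volatile", "blue",   12L,
    "volatile", "green",   5L,
    "volatile", "blue",   11L,
    "stable",   "blue",   46L)
  rescale_blocks(base, n_trials)
}

# Default advisor-intention layout: stable helpful opening, then volatile
# alternation of misleading/helpful sub-blocks. Helpful trials total 96/160
# so that, with an 80%-accurate private signal, overall advice accuracy
# lands on 90/160 = 0.5625.
default_advice_blocks <- function(n_trials) {
  base <- tibble::tribble(
    ~phase,     ~intent,      ~length,
    "stable",   "helpful",    60L,
    "volatile", "misleading", 12L,
    "volatile", "helpful",     8L,
    "volatile", "misleading", 10L,
    "volatile", "helpful",     7L,
    "volatile", "misleading", 11L,
    "volatile", "helpful",     7L,
    "volatile", "misleading", 10L,
    "volatile", "helpful",     7L,
    "volatile", "misleading", 11L,
    "volatile", "helpful",     7L,
    "volatile", "misleading", 10L)
  rescale_blocks(base, n_trials)
}

# Proportionally rescale block lengths to a new trial count (largest
# remainder, every block kept at length >= 1).
rescale_blocks <- function(blocks, n_trials) {
  if (sum(blocks$length) == n_trials) return(blocks)
  ideal <- blocks$length * n_trials / sum(blocks$length)
  len <- pmax(1L, floor(ideal))
  rem <- n_trials - sum(len)
  if (rem > 0) {
    ord <- order(ideal - floor(ideal), decreasing = TRUE)
    len[ord[seq_len(rem)]] <- len[ord[seq_len(rem)]] + 1L
  } else if (rem < 0) {
    ord <- order(ideal - floor(ideal))
    i <- 1
    while (rem < 0) {
      j <- ord[((i - 1) %% length(ord)) + 1]
      if (len[j] > 1L) { len[j] <- len[j] - 1L; rem <- rem + 1 }
      i <- i + 1
    }
  }
  blocks$length <- as.integer(len)
  blocks
}

# Integer apportionment: distribute `total` successes over blocks with
# expected counts `expected` (capped by block length), largest remainder.
apportion_counts <- function(expected, caps, total) {
  x <- pmin(pmax(expected, 0), caps)
  cnt <- floor(x)
  rem <- total - sum(cnt)
  frac <- x - cnt
  if (rem > 0) {
    ord <- order(frac, decreasing = TRUE)
    for (j in ord) {
      if (rem == 0) break
      if (cnt[j] < caps[j]) { cnt[j] <- cnt[j] + 1L; rem <- rem - 1 }
    }
    # second pass ignoring fractions if still short
    while (rem > 0) {
      j <- which(cnt < caps)[1]
      if (is.na(j)) stop("infeasible design targets", call. = FALSE)
      cnt[j] <- cnt[j] + 1L; rem <- rem - 1
    }
  } else if (rem < 0) {
    ord <- order(frac)
    for (j in ord) {
      if (rem == 0) break
      if (cnt[j] > 0) { cnt[j] <- cnt[j] - 1L; rem <- rem + 1 }
    }
    while (rem < 0) {
      j <- which(cnt > 0)[1]
      if (is.na(j)) stop("infeasible design targets", call. = FALSE)
      cnt[j] <- cnt[j] - 1L; rem <- rem + 1
    }
  }
  as.integer(cnt)
}

# Place `k` ones among `len` slots at seeded-random positions.
place_ones <- function(len, k) {
  v <- integer(len)
  if (k > 0) v[sample.int(len, k)] <- 1L
  v
}

#' Generate a synthetic task schedule
#'
#' Builds the per-trial generative truth of the paradigm: phase labels for
#' card and advice, the trial-wise probability that blue is rewarded, the
#' drawn outcome colour, the advisor's private signal, the advice colour and
#' whether the advice named the rewarded colour. Counts of accurate advice,
#' correct private signals and blue outcomes are fixed by the design targets;
#' only within-block positions are random. The within-block permutation is
#' redrawn (up to 100 times) until the advice-accuracy and outcome sequences
#' are close to orthogonal (|Pearson r| <= 0.1), preserving the factorial
#' design's independence of the two information sources.
#'
#' @param config A [task_config()].
#' @param seed Integer seed; the schedule is bit-reproducible given the seed.
#' @return A tibble of class `task_schedule` with one row per trial and
#'   columns `trial_index`, `card_phase`, `advice_phase`, `p_blue`,
#'   `outcome_color`, `advisor_info`, `advice_color`, `advice_accurate`.
#'   Session split and the config are attached as attributes.
#' @examples
#' sched <- generate_schedule(task_config(), seed = 1)
#' mean(sched$advice_accurate)  # 0.5625
#' mean(sched$outcome_color)    # 0.55
#' @export
generate_schedule <- function(config = task_config(), seed = 1L) {
  stopifnot(inherits(config, "task_config"))
  n <- config$n_trials
  cb <- config$card_blocks
  ab <- config$advice_blocks
  cc <- config$stable_contingency

  # --- card branch: exact blue-outcome counts per block ---
  p_blue_block <- ifelse(cb$favored == "blue", cc, 1 - cc)
  blue_total <- round(config$target_card_probability * n)
  blue_cnt <- apportion_counts(p_blue_block * cb$length, cb$length, blue_total)

  # --- advice branch: exact accurate-advice and signal-correct counts ---
  p_info <- config$advisor_info_accuracy
  m_tot <- sum(ab$length[ab$intent == "misleading"])
  h_tot <- n - m_tot
  acc_total <- round(config$target_advice_accuracy * n)
  sig_total <- round(p_info * n)
  if ((acc_total + sig_total - m_tot) %% 2 != 0) {
    cand <- c(acc_total - 1, acc_total + 1)
    acc_total <- cand[which.min(abs(cand - config$target_advice_accuracy * n))]
  }
  h_acc <- (acc_total + sig_total - m_tot) / 2   # accurate among helpful
  m_acc <- acc_total - h_acc                     # accurate among misleading
  if (h_acc < 0 || h_acc > h_tot || m_acc < 0 || m_acc > m_tot ||
      sig_total > n || sig_total < 0) {
    stop("infeasible design targets: block structure cannot realise the ",
         "requested advice-accuracy / signal-accuracy means", call. = FALSE)
  }
  helpful <- ab$intent == "helpful"
  acc_exp <- ifelse(helpful, p_info, 1 - p_info) * ab$length
  acc_cnt <- integer(nrow(ab))
  acc_cnt[helpful] <- apportion_counts(acc_exp[helpful], ab$length[helpful], h_acc)
  acc_cnt[!helpful] <- apportion_counts(acc_exp[!helpful], ab$length[!helpful], m_acc)

  # --- realise per-trial sequences, re-drawing until near-orthogonal ---
  withr_seed <- seed
  set.seed(withr_seed)
  for (try in seq_len(100L)) {
    outcome <- unlist(purrr::map2(cb$length, blue_cnt, place_ones))
    accurate <- unlist(purrr::map2(ab$length, acc_cnt, place_ones))
    r <- suppressWarnings(cor(accurate, outcome))
    if (is.na(r) || abs(r) <= 0.1) break
  }

  intent_trial <- rep(helpful, ab$length)
  advice <- ifelse(accurate == 1L, outcome, 1L - outcome)
  advisor_info <- ifelse(intent_trial, advice, 1L - advice)

  out <- tibble::tibble(
    trial_index = seq_len(n),
    card_phase = rep(cb$phase, cb$length),
    advice_phase = rep(ab$phase, ab$length),
    p_blue = rep(p_blue_block, cb$length),
    outcome_color = as.integer(outcome),
    advisor_info = as.integer(advisor_info),
    advice_color = as.integer(advice),
    advice_accurate = as.integer(accurate))
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  attr(out, "sessions") <- config$sessions
  class(out) <- c("task_schedule", class(out))
  out
}

#' Summarise a task schedule's realised design
#'
#' @param schedule A `task_schedule`.
#' @return One-row tibble with trial count, realised advice accuracy, blue
#'   base rate, private-signal accuracy and the mean generative blue
#'   probability.
#' @export
schedule_design <- function(schedule) {
  tibble::tibble(
    n_trials = nrow(schedule),
    advice_accuracy = mean(schedule$advice_accurate),
    blue_rate = mean(schedule$outcome_color),
    advisor_info_accuracy = mean(schedule$advisor_info == schedule$outcome_color),
    mean_p_blue = mean(schedule$p_blue),
    cor_advice_outcome = suppressWarnings(
      cor(schedule$advice_accurate, schedule$outcome_color)))
}
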