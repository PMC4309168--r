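#' Lottery profile grid
#'
#' Enumerates the full factorial of delayed lotteries used throughout the
#' package: every combination of a delay (days until the lottery resolves)
#' and a probability of payment, at a fixed nominal amount. The default
#' grid is the 3 x 3 study design: delays of 1 week, 3 months and 2 years
#' ({7, 90, 730} days) crossed with payment probabilities {0.01, 0.1, 0.7},
#' amount 1000 currency units, giving 9 profiles.
#'
#' Profiles are returned in canonical delay-major order (all probabilities
#' for the shortest delay first) with stable `profile_id`s, so designs,
#' codings and utilities indexed by id line up across modules.
#'
#' @param delays integer vector of delays in days, sorted ascending.
#' @param probabilities numeric vector of payment probabilities in (0, 1].
#' @param amount nominal lottery amount (> 0), identical for all profiles.
#' @return data.frame with columns `profile_id`, `amount`, `probability`,
#'   `delay_days`, one row per profile.
#' @examples
#' lottery_grid()            # the 9-profile study grid
#' lottery_grid(c(7, 30, 180, 730), c(0.01, 0.1, 0.35, 0.7))  # 4 x 4
#' @export
lottery_grid <- function(delays = c(7L, 90L, 730L),
                         probabilities = c(0.01, 0.1, 0.7),
                         amount = 1000) {
  if (length(delays) < 1L || length(probabilities) < 1L)
    stop("need at least one delay and one probability level")
  if (any(delays < 0) || any(duplicated(delays)))
    stop("delays must be distinct and non-negative")
  if (any(probabilities <= 0) || any(probabilities > 1) ||
      any(duplicated(probabilities)))
    stop("probabilities must be distinct values in (0, 1]")
  if (amount <= 0) stop("amount must be positive")
  grid <- expand.grid(probability = probabilities, delay_days = delays,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("delay_days", "probability")]
  data.frame(
    profile_id = sprintf("d%d_p%g", grid$delay_days, grid$probability),
    amount = amount,
    probability = grid$probability,
    delay_days = as.integer(grid$delay_days),
    stringsAsFactors = FALSE
  )
}

#' External choice-task items
#'
#' The three fixed binary choices between delayed lotteries used as the
#' external criterion for predictive validity: (1) 0.01 in 1 week vs 0.1 in
#' 3 months, (2) 0.01 in 3 months vs 0.1 in 2 years, (3) 0.1 in 3 months vs
#' 0.7 in 2 years. Both options always carry the same nominal amount.
#'
#' @param amount nominal amount of every lottery.
#' @return data.frame with one row per decision: `decision`, and
#'   probability/delay columns for options A and B.
#' @export
choice_task_items <- function(amount = 1000) {
  data.frame(
    decision = 1:3,
    amount = amount,
    prob_a = c(0.01, 0.01, 0.1),
    delay_a = c(7L, 90L, 90L),
    prob_b = c(0.1, 0.1, 0.7),
    delay_b = c(90L, 730L, 730L),
    stringsAsFactors = FALSE
  )
}

#' Subjective value of a delayed lottery
#'
#' Ground-truth generative model for simulated respondents: a multiplicative
#' hyperbolic discount in delay and in odds-against,
#' \deqn{V = A / ((1 + k_d \cdot D)(1 + k_o \cdot \theta)), \quad
#'       \theta = (1 - p)/p,}
#' where \eqn{A} is the amount, \eqn{D} the delay in days and \eqn{p} the
#' payment probability. \eqn{V} lies in \eqn{(0, A]}; it equals \eqn{A}
#' exactly when both rates are zero or the lottery is certain and immediate.
#' All arguments are vectorized and recycled.
#'
#' @param k_delay per-day hyperbolic delay discount rate, >= 0.
#' @param k_odds odds-against probability discount rate, >= 0.
#' @param amount nominal amount(s) > 0.
#' @param probability payment probability in (0, 1].
#' @param delay_days delay in days >= 0.
#' @return numeric vector of subjective values.
#' @examples
#' subjective_value(0.01, 0.5, 1000, 0.1, 90)  # ~95.69
#' @export
subjective_value <- function(k_delay, k_odds, amount, probability, delay_days) {
  if (any(probability <= 0) || any(probability > 1))
    stop("probability must lie in (0, 1]")
  if (any(k_delay < 0) || any(k_odds < 0))
    stop("discount rates must be non-negative")
  if (any(amount <= 0)) stop("amount must be positive")
  if (any(delay_days < 0)) stop("delay_days must be non-negative")
  theta <- (1 - probability) / probability
  amount / ((1 + k_delay * delay_days) * (1 + k_odds * theta))
}

#' Softmax choice probabilities over option values
#'
#' Choice rule used by simulated respondents. With temperature 0 all mass
#' sits on the maximizing option(s) (split uniformly over exact ties);
#' otherwise probabilities are softmax over logits `values / (temperature *
#' amount_scale)`, where `amount_scale` defaults to the largest nominal
#' amount among the options so that the noise level is scale-free.
#'
#' @param values numeric vector of subjective values, one per option.
#' @param temperature choice-noise scale >= 0.
#' @param amount_scale nominal-amount normalizer; defaults to `max(values)`
#'   being inappropriate, callers pass the option amounts' maximum.
#' @return numeric vector of choice probabilities summing to 1.
#' @export
choice_probs <- function(values, temperature, amount_scale) {
  if (length(values) < 2L) stop("need at least two options")
  if (temperature < 0) stop("temperature must be non-negative")
  if (temperature == 0) {
    best <- values == max(values)
    return(best / sum(best))
  }
  z <- values / (temperature * amount_scale)
  z <- z - max(z)
  exp(z) / sum(exp(z))
}

#' Sample one choice among options
#'
#' Draws a single choice index from [choice_probs()]. Uses the current RNG
#' state; seed management is the caller's job.
#'
#' @inheritParams choice_probs
#' @return integer index of the chosen option (1-based).
#' @export
choose_option <- function(values, temperature, amount_scale) {
  p <- choice_probs(values, temperature, amount_scale)
  sample.int(length(values), 1L, prob = p)
}

#' Default population configuration for synthetic cohorts
#'
#' Location/scale of the log-normal trait distributions and the shared
#' noise parameters. Defaults describe a cohort with median delay rate
#' ~0.01/day and median odds-against rate 0.5 (wide log-normal spread,
#' matching the large between-person SDs of published equivalent tables),
#' a 3-week retest jitter of 0.3 on the log scale, and a choice-noise
#' temperature of 0.01 (logistic scale of 1% of the nominal amount),
#' calibrated so the simulated external choice task reproduces the order
#' of magnitude of reported choice-task repeatability (kappa roughly
#' 0.3-0.6 on the decisions the trait model differentiates) and choice
#' shares.
#'
#' @param k_delay_meanlog,k_delay_sdlog log-normal parameters of `k_delay`.
#' @param k_odds_meanlog,k_odds_sdlog log-normal parameters of `k_odds`.
#' @param temperature shared softmax temperature (>= 0; 0 = deterministic).
#' @param retest_sd shared log-scale SD of the wave-2 trait jitter (>= 0).
#' @param adjusting_noise multiplier (>= 0) applied to the temperature in
#'   staircase-titration choices only. Respondents are modelled as noisier
#'   in the adjusting task than in pick-the-best choice tasks, encoding the
#'   documented method-specific error sources of titration with abstract
#'   probabilistic content (high irrational-choice rates, the incentive to
#'   "sell" the constant alternative high, low attention to near-identical
#'   repeated screens). Set to 1 for identical noise in every task.
#' @return list of class `population_config`.
#' @export
population_config <- function(k_delay_meanlog = -4.6, k_delay_sdlog = 1,
                              k_odds_meanlog = log(0.5), k_odds_sdlog = 0.7,
                              temperature = 0.01, retest_sd = 0.3,
                              adjusting_noise = 10) {
  stopifnot(k_delay_sdlog >= 0, k_odds_sdlog >= 0,
            temperature >= 0, retest_sd >= 0, adjusting_noise >= 0)
  structure(list(k_delay_meanlog = k_delay_meanlog,
                 k_delay_sdlog = k_delay_sdlog,
                 k_odds_meanlog = k_odds_meanlog,
                 k_odds_sdlog = k_odds_sdlog,
                 temperature = temperature,
                 retest_sd = retest_sd,
                 adjusting_noise = adjusting_noise),
            class = "population_config")
}

#' Generate a synthetic cohort
#'
#' Draws `n` respondents with log-normally distributed discount rates and
#' fixed noise parameters. Deterministic given `seed`.
#'
#' @param n cohort size (>= 1).
#' @param population a [population_config()].
#' @param seed integer seed; if `NULL` the current RNG state is used.
#' @return data.frame with columns `agent_id`, `k_delay`, `k_odds`,
#'   `temperature`, `retest_sd`.
#' @export
generate_cohort <- function(n, population = population_config(), seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a positive integer")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    agent_id = sprintf("a%03d", seq_len(n)),
    k_delay = stats::rlnorm(n, population$k_delay_meanlog,
                            population$k_delay_sdlog),
    k_odds = stats::rlnorm(n, population$k_odds_meanlog,
                           population$k_odds_sdlog),
    temperature = population$temperature,
    retest_sd = population$retest_sd,
    adjusting_noise = population$adjusting_noise,
    stringsAsFactors = FALSE
  )
}

#' Perturb a cohort for the retest wave
#'
#' Multiplies each respondent's `k_delay` and `k_odds` by independent
#' LogNormal(0, `retest_sd`) factors, emulating stable-but-jittered traits
#' over a 3-week gap. Temperature is left unchanged; `retest_sd = 0`
#' returns the cohort untouched. Rates stay strictly positive.
#'
#' @param agents cohort data.frame from [generate_cohort()].
#' @return data.frame of the same shape with jittered rates.
#' @export
jitter_for_retest <- function(agents) {
  sd <- agents$retest_sd
  agents$k_delay <- agents$k_delay * stats::rlnorm(nrow(agents), 0, sd)
  agents$k_odds <- agents$k_odds * stats::rlnorm(nrow(agents), 0, sd)
  agents
}

#' Simulate the external choice task for a cohort
#'
#' Each respondent answers the three fixed binary lottery choices using the
#' softmax rule on subjective values.
#'
#' @param agents cohort data.frame.
#' @param items choice-task items, see [choice_task_items()].
#' @return data.frame `agent_id`, `decision`, `chose_a` (1 if option A).
#' @export
simulate_choice_task <- function(agents, items = choice_task_items()) {
  out <- expand.grid(decision = items$decision, agent_id = agents$agent_id,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("agent_id", "decision")]
  out$chose_a <- NA_integer_
  for (i in seq_len(nrow(agents))) {
    ag <- agents[i, ]
    for (d in seq_len(nrow(items))) {
      it <- items[d, ]
      va <- subjective_value(ag$k_delay, ag$k_odds, it$amount,
                             it$prob_a, it$delay_a)
      vb <- subjective_value(ag$k_delay, ag$k_odds, it$amount,
                             it$prob_b, it$delay_b)
      pick <- choose_option(c(va, vb), ag$temperature, it$amount)
      out$chose_a[out$agent_id == ag$agent_id & out$decision == it$decision] <-
        as.integer(pick == 1L)
    }
  }
  out
}
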