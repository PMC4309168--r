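#' Start a staircase titration for a delayed lottery
#'
#' The adjusting procedure pits a fixed delayed lottery against a certain,
#' immediate amount that is retitrated after every choice. The first certain
#' offer is half the lottery amount; the adjustment applied after the first
#' choice is a quarter of the amount and halves after every subsequent
#' choice (amount/4, /8, /16, ...), the standard bisection schedule. For a
#' $5,000 lottery the first offer is $2,500 and the second offer is either
#' $1,250 (if the certain option was taken) or $3,750 (if the lottery was).
#'
#' @param lottery one-row data.frame with at least `amount` (and typically
#'   `profile_id`, `probability`, `delay_days`), as from [lottery_grid()].
#' @return a `staircase_state` list: `lottery`, `step` (1-based index of the
#'   offer about to be answered), `certain_amount` (current offer),
#'   `adjustment` (applied after the upcoming choice), `history` (data.frame
#'   of answered offers).
#' @export
staircase_init <- function(lottery) {
  amount <- lottery$amount
  if (is.null(amount) || amount <= 0) stop("lottery must have amount > 0")
  structure(list(
    lottery = lottery,
    step = 1L,
    certain_amount = amount / 2,
    adjustment = amount / 4,
    history = data.frame(step = integer(), certain_amount = numeric(),
                         chose_certain = integer())
  ), class = "staircase_state")
}

#' Apply one choice to a staircase state
#'
#' Choosing the certain offer lowers the next offer by the current
#' adjustment; choosing the lottery raises it. The adjustment then halves
#' and the step counter advances. Offers remain strictly inside
#' (0, amount) because the adjustments form a geometric series bounded by
#' the initial offer.
#'
#' @param state a `staircase_state`.
#' @param chose_certain logical; `TRUE` if the certain immediate offer was
#'   taken.
#' @param n_steps total number of titration steps; applying a choice beyond
#'   it is an error.
#' @return updated `staircase_state`.
#' @export
staircase_update <- function(state, chose_certain, n_steps = 6L) {
  if (state$step > n_steps)
    stop("staircase already completed (", n_steps, " steps)")
  if (!is.logical(chose_certain) || is.na(chose_certain))
    stop("chose_certain must be TRUE or FALSE")
  state$history <- rbind(state$history, data.frame(
    step = state$step,
    certain_amount = state$certain_amount,
    chose_certain = as.integer(chose_certain)))
  delta <- if (chose_certain) -state$adjustment else state$adjustment
  state$certain_amount <- state$certain_amount + delta
  state$adjustment <- state$adjustment / 2
  state$step <- state$step + 1L
  state
}

#' Indifference point of a completed staircase
#'
#' The mean of the last two certain offers actually presented. For the
#' 6-step schedule this lands within amount/32 of a noiseless respondent's
#' internal equivalent.
#'
#' @param history the `history` data.frame of a completed staircase.
#' @return numeric indifference point.
#' @export
staircase_indifference <- function(history) {
  n <- nrow(history)
  if (n < 2L) stop("staircase must have at least two answered steps")
  mean(history$certain_amount[c(n - 1L, n)])
}

#' Respondent callback for a simulated agent
#'
#' Returns a function `(certain_amount, lottery) -> logical` implementing
#' the agent's choice between the certain offer (value = its face amount)
#' and the lottery (value = [subjective_value()]), with softmax noise at
#' the agent's temperature times the population's adjusting-task noise
#' multiplier (see [population_config()]). At zero effective temperature
#' ties go to the certain offer.
#'
#' @param agent one-row cohort data.frame.
#' @return a responder function.
#' @export
agent_responder <- function(agent) {
  force(agent)
  mult <- if (is.null(agent$adjusting_noise)) 1 else agent$adjusting_noise
  temp <- agent$temperature * mult
  function(certain_amount, lottery) {
    v <- subjective_value(agent$k_delay, agent$k_odds, lottery$amount,
                          lottery$probability, lottery$delay_days)
    if (temp == 0) return(certain_amount >= v)
    p_certain <- choice_probs(c(certain_amount, v), temp,
                              lottery$amount)[1L]
    stats::runif(1L) < p_certain
  }
}

#' Run one full staircase
#'
#' Administers `n_steps` titration choices of a delayed lottery against the
#' adjusting certain offer and computes the indifference point.
#'
#' @param responder function `(certain_amount, lottery)` returning `TRUE`
#'   when the certain offer is chosen — an [agent_responder()] or a replay
#'   of recorded answers.
#' @param lottery one-row lottery data.frame.
#' @param n_steps number of titration steps (default 6).
#' @return list with `lottery`, `history` (`n_steps` rows) and
#'   `indifference_point`.
#' @examples
#' ag <- data.frame(k_delay = 0.01, k_odds = 0.5, temperature = 0)
#' lot <- lottery_grid()[5, ]  # 0.1 chance in 3 months
#' run_staircase(agent_responder(ag), lot)$indifference_point
#' @export
run_staircase <- function(responder, lottery, n_steps = 6L) {
  state <- staircase_init(lottery)
  for (s in seq_len(n_steps)) {
    ans <- responder(state$certain_amount, lottery)
    if (!is.logical(ans) || length(ans) != 1L || is.na(ans))
      stop("responder must return a single TRUE/FALSE")
    state <- staircase_update(state, ans, n_steps = n_steps)
  }
  list(lottery = lottery,
       history = state$history,
       indifference_point = staircase_indifference(state$history))
}

#' Titrate a battery of lotteries
#'
#' Runs one staircase per lottery, in an administration order randomized
#' under the current RNG state, and collects both the full choice log and
#' the indifference points ("equivalents"). Nine 6-step staircases record
#' 9 x 6 = 54 binary choices.
#'
#' @inheritParams run_staircase
#' @param lotteries lottery data.frame, e.g. [lottery_grid()].
#' @param randomize_order randomize administration order (default `TRUE`).
#' @return list of two data.frames: `choices` (`lottery_id`, `step`,
#'   `certain_amount`, `chose_certain`) and `equivalents` (`lottery_id`,
#'   `indifference_point`), the latter in canonical lottery order.
#' @export
run_adjusting_battery <- function(responder, lotteries, n_steps = 6L,
                                  randomize_order = TRUE) {
  if (nrow(lotteries) < 1L) stop("empty lottery battery")
  order_idx <- if (randomize_order) sample.int(nrow(lotteries))
               else seq_len(nrow(lotteries))
  choices <- vector("list", nrow(lotteries))
  ip <- stats::setNames(numeric(nrow(lotteries)), lotteries$profile_id)
  for (j in order_idx) {
    rec <- run_staircase(responder, lotteries[j, ], n_steps = n_steps)
    h <- rec$history
    h$lottery_id <- lotteries$profile_id[j]
    choices[[j]] <- h[, c("lottery_id", "step", "certain_amount",
                          "chose_certain")]
    ip[lotteries$profile_id[j]] <- rec$indifference_point
  }
  list(
    choices = do.call(rbind, c(choices, list(make.row.names = FALSE))),
    equivalents = data.frame(lottery_id = lotteries$profile_id,
                             indifference_point = unname(ip),
                             stringsAsFactors = FALSE)
  )
}
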