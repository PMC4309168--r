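#' Scale indifference points to relative subjective value
#'
#' Divides each monetary indifference point by the lottery amount, giving a
#' relative subjective value e in (0, 1]. (A $4,850 equivalent of a $5,000
#' lottery scales to 0.97.)
#'
#' @param indifference_points numeric vector in (0, amount].
#' @param amount lottery amount (> 0).
#' @return numeric vector of scaled equivalents.
#' @export
scale_equivalents <- function(indifference_points, amount) {
  if (amount <= 0) stop("amount must be positive")
  if (any(indifference_points <= 0) || any(indifference_points > amount))
    stop("indifference points must lie in (0, amount]")
  indifference_points / amount
}

#' Scale delays to the unit interval
#'
#' Default `"minmax"` convention maps the studied range to [0, 1]:
#' `(d - d_min) / (d_max - d_min)`, so 7 days -> 0 and 730 days -> 1.
#' The alternative `"max"` convention divides by the longest delay
#' (`d / d_max`).
#'
#' @param delays_days numeric vector of delays, sorted ascending, >= 2
#'   distinct values.
#' @param convention `"minmax"` (default) or `"max"`.
#' @return numeric vector of scaled times.
#' @export
scale_times <- function(delays_days, convention = c("minmax", "max")) {
  convention <- match.arg(convention)
  if (length(delays_days) < 2L) stop("need at least two delays")
  if (is.unsorted(delays_days, strictly = TRUE))
    stop("delays must be strictly increasing")
  if (convention == "minmax")
    (delays_days - delays_days[1L]) / diff(range(delays_days))
  else
    delays_days / delays_days[length(delays_days)]
}

#' Trapezoidal area under a discount curve
#'
#' \deqn{AUC = \sum_i (e_i + e_{i+1}) (t_{i+1} - t_i) / 2} over consecutive
#' curve points; with e and t in [0, 1] the area lies in [0, 1], and a
#' smaller area means steeper discounting.
#'
#' @param e scaled subjective values at the curve points.
#' @param t scaled times, strictly increasing, same length as `e`.
#' @return scalar area.
#' @examples
#' auc_trapezoid(c(1, 0.5, 0.25), c(0, 0.5, 1))  # 0.5625
#' @export
auc_trapezoid <- function(e, t) {
  if (length(e) < 2L || length(e) != length(t))
    stop("need matching e and t with at least two points")
  if (is.unsorted(t, strictly = TRUE)) stop("t must be strictly increasing")
  sum((e[-length(e)] + e[-1L]) * diff(t) / 2)
}

# Internal: per-probability AUC triple from a 9-cell (delay x probability)
# value table already scaled to [0, 1].
auc_by_probability <- function(values, delays, probabilities,
                               time_convention = "minmax") {
  t <- scale_times(delays, time_convention)
  vapply(probabilities, function(p) {
    e <- vapply(delays, function(d)
      values$value[values$delay_days == d & values$probability == p],
      numeric(1))
    auc_trapezoid(e, t)
  }, numeric(1))
}

#' Discounting-strength profile from adjusting equivalents
#'
#' Builds one discount curve per probability level from a respondent's
#' indifference points over the delay grid (subjective value scaled by the
#' amount, time scaled per `time_convention`) and integrates each by
#' [auc_trapezoid()]. The result is the respondent's discounting strength:
#' one AUC per probability level, larger = shallower discounting.
#'
#' @param equivalents data.frame `lottery_id`, `indifference_point` (one
#'   row per profile of `spec`).
#' @param spec a [cbc_design_spec()] (supplies grid and amount).
#' @param time_convention `"minmax"` or `"max"`, see [scale_times()].
#' @return data.frame `probability`, `auc`.
#' @export
adjusting_profile <- function(equivalents, spec,
                              time_convention = "minmax") {
  profiles <- spec$profiles
  idx <- match(profiles$profile_id, equivalents$lottery_id)
  if (anyNA(idx)) stop("missing equivalents for some lotteries")
  values <- data.frame(
    delay_days = profiles$delay_days,
    probability = profiles$probability,
    value = scale_equivalents(equivalents$indifference_point[idx],
                              spec$amount))
  data.frame(
    probability = spec$probabilities,
    auc = auc_by_probability(values, spec$delays, spec$probabilities,
                             time_convention))
}

#' Discounting-strength profile from conjoint utilities
#'
#' Cumulative profile utilities are first min-max rescaled to [0, 1] within
#' the respondent (across all 9 profiles) — which makes the AUC invariant
#' to affine transformations of the utility scale — then integrated per
#' probability level exactly as in [adjusting_profile()]. If all utilities
#' are identical the curve is flat by convention (all e = 1, AUC = 1) and
#' the result is flagged via the `degenerate` attribute.
#'
#' @param utilities named numeric vector of cumulative utilities, names =
#'   profile ids of `spec`.
#' @inheritParams adjusting_profile
#' @return data.frame `probability`, `auc`; attribute `degenerate`.
#' @export
conjoint_profile <- function(utilities, spec, time_convention = "minmax") {
  profiles <- spec$profiles
  u <- utilities[profiles$profile_id]
  if (anyNA(u)) stop("missing utilities for some profiles")
  rng <- range(u)
  degenerate <- diff(rng) == 0
  e <- if (degenerate) rep(1, length(u)) else (u - rng[1L]) / diff(rng)
  values <- data.frame(delay_days = profiles$delay_days,
                       probability = profiles$probability, value = e)
  out <- data.frame(
    probability = spec$probabilities,
    auc = auc_by_probability(values, spec$delays, spec$probabilities,
                             time_convention))
  attr(out, "degenerate") <- degenerate
  out
}

#' Cohort discounting profiles from both measurement methods
#'
#' Convenience assembler used by the pipeline: stacks per-respondent AUC
#' triples into the long `auc` schema.
#'
#' @param per_agent named list mapping `agent_id` to a profile data.frame
#'   from [adjusting_profile()] / [conjoint_profile()].
#' @param method `"adjusting"` or `"conjoint"`.
#' @param wave wave label.
#' @return data.frame `agent_id`, `wave`, `method`, `probability`, `auc`.
#' @export
bind_discount_profiles <- function(per_agent, method, wave = 1L) {
  rows <- lapply(names(per_agent), function(id) {
    p <- per_agent[[id]]
    data.frame(agent_id = id, wave = wave, method = method,
               probability = p$probability, auc = p$auc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
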