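#' Conjoint design specification
#'
#' Levels of the two lottery attributes plus choice-set geometry: `set_size`
#' profiles per task (default 3) and `n_tasks` tasks per respondent
#' (default 25).
#'
#' @param delays,probabilities attribute levels; their product must be at
#'   least `set_size`.
#' @param amount nominal amount of every profile.
#' @param set_size profiles shown per task (>= 2).
#' @param n_tasks tasks per respondent (>= 1).
#' @return list of class `cbc_design_spec` with the above plus the profile
#'   grid (`profiles`).
#' @export
cbc_design_spec <- function(delays = c(7L, 90L, 730L),
                            probabilities = c(0.01, 0.1, 0.7),
                            amount = 1000, set_size = 3L, n_tasks = 25L) {
  if (set_size < 2L) stop("set_size must be at least 2")
  if (n_tasks < 1L) stop("n_tasks must be at least 1")
  profiles <- lottery_grid(delays, probabilities, amount)
  if (nrow(profiles) < set_size)
    stop("fewer profiles than set_size: design infeasible")
  structure(list(delays = delays, probabilities = probabilities,
                 amount = amount, set_size = as.integer(set_size),
                 n_tasks = as.integer(n_tasks), profiles = profiles),
            class = "cbc_design_spec")
}

#' Enumerate all possible choice sets
#'
#' All distinct unordered subsets of `set_size` profiles; C(9, 3) = 84 for
#' the study grid.
#'
#' @param profiles profile data.frame.
#' @param set_size subset size.
#' @return integer matrix, one column per subset, rows sorted ascending.
#' @export
enumerate_choice_sets <- function(profiles, set_size) {
  n <- nrow(profiles)
  if (set_size > n) stop("set_size exceeds the number of profiles")
  utils::combn(n, set_size)
}

#' Balance and orthogonality diagnostics of a design
#'
#' A design is balanced when each attribute level appears the same number of
#' times across a respondent's tasks, and (near-)orthogonal when levels of
#' one attribute co-occur with levels of the other a similar number of
#' times. For a full-profile design the delay x probability co-occurrence
#' table is exactly the per-profile exposure table, so the objective sums
#' squared deviations of the attribute-level counts and the profile counts
#' from their ideals, plus a penalty of 10 per duplicated task.
#'
#' @param design integer matrix `n_tasks` x `set_size` of profile row
#'   indices into `spec$profiles`.
#' @param spec a [cbc_design_spec()].
#' @return list: `delay_counts`, `prob_counts`, `profile_counts`,
#'   `cooccurrence` (delay x probability matrix), `n_duplicate_tasks`,
#'   `objective`.
#' @export
design_diagnostics <- function(design, spec) {
  if (length(design) == 0L) stop("empty design")
  profiles <- spec$profiles
  exp_idx <- as.vector(design)
  pc <- tabulate(exp_idx, nbins = nrow(profiles))
  names(pc) <- profiles$profile_id
  dlev <- factor(profiles$delay_days[exp_idx], levels = spec$delays)
  plev <- factor(profiles$probability[exp_idx], levels = spec$probabilities)
  dc <- table(dlev)
  qc <- table(plev)
  co <- table(dlev, plev)
  n_exp <- length(exp_idx)
  ideal_d <- n_exp / length(spec$delays)
  ideal_p <- n_exp / length(spec$probabilities)
  ideal_prof <- n_exp / nrow(profiles)
  key <- apply(design, 1L, function(r) paste(sort(r), collapse = "-"))
  ndup <- sum(duplicated(key))
  obj <- sum((dc - ideal_d)^2) + sum((qc - ideal_p)^2) +
    sum((pc - ideal_prof)^2) + 10 * ndup
  list(delay_counts = dc, prob_counts = qc, profile_counts = pc,
       cooccurrence = co, n_duplicate_tasks = ndup, objective = obj)
}

#' Generate one respondent's choice-based-conjoint design
#'
#' Random-start, pairwise-swap hill climbing on the balance + orthogonality
#' objective of [design_diagnostics()]: starting from tasks drawn uniformly
#' from the distinct choice sets, single profile slots are repeatedly
#' swapped for profiles outside the task and the move is kept when the
#' objective does not worsen. Deterministic given `(seed, respondent_id)`;
#' different respondents get different task sequences under the same master
#' seed.
#'
#' @param spec a [cbc_design_spec()].
#' @param respondent_id integer or string identifying the respondent
#'   (sub-seeds the RNG when `seed` is given).
#' @param seed master design seed; `NULL` uses the current RNG state.
#' @param n_moves number of candidate swaps evaluated (default 400).
#' @return integer matrix `n_tasks` x `set_size` of profile row indices,
#'   each row sorted ascending; attribute `diagnostics` holds the final
#'   [design_diagnostics()].
#' @export
generate_cbc_design <- function(spec, respondent_id = 1L, seed = NULL,
                                n_moves = 400L) {
  if (!is.null(seed))
    set.seed(derive_seed(seed, respondent_id))
  profiles <- spec$profiles
  n_prof <- nrow(profiles)
  n_tasks <- spec$n_tasks
  dlev <- match(profiles$delay_days, spec$delays)
  plev <- match(profiles$probability, spec$probabilities)
  design <- t(replicate(n_tasks, sort(sample.int(n_prof, spec$set_size))))

  # incremental bookkeeping: per-profile / per-level exposure counts plus a
  # numeric key per task for the duplicate penalty
  n_exp <- length(design)
  pc <- tabulate(design, n_prof)
  dc <- tabulate(dlev[design], length(spec$delays))
  qc <- tabulate(plev[design], length(spec$probabilities))
  ideal_d <- n_exp / length(spec$delays)
  ideal_p <- n_exp / length(spec$probabilities)
  ideal_prof <- n_exp / n_prof
  task_key <- function(row) sum(sort(row) * (n_prof + 1)^(seq_along(row) - 1))
  keys <- apply(design, 1L, task_key)
  objective <- function(pc, dc, qc, keys)
    sum((dc - ideal_d)^2) + sum((qc - ideal_p)^2) +
    sum((pc - ideal_prof)^2) + 10 * sum(duplicated(keys))
  obj <- objective(pc, dc, qc, keys)

  for (m in seq_len(n_moves)) {
    task <- sample.int(n_tasks, 1L)
    slot <- sample.int(spec$set_size, 1L)
    old <- design[task, slot]
    candidates <- seq_len(n_prof)[-design[task, ]]
    if (length(candidates) == 0L) next
    repl <- candidates[sample.int(length(candidates), 1L)]
    pc2 <- pc; dc2 <- dc; qc2 <- qc
    pc2[old] <- pc2[old] - 1L; pc2[repl] <- pc2[repl] + 1L
    dc2[dlev[old]] <- dc2[dlev[old]] - 1L
    dc2[dlev[repl]] <- dc2[dlev[repl]] + 1L
    qc2[plev[old]] <- qc2[plev[old]] - 1L
    qc2[plev[repl]] <- qc2[plev[repl]] + 1L
    row2 <- design[task, ]
    row2[slot] <- repl
    keys2 <- keys
    keys2[task] <- task_key(row2)
    trial_obj <- objective(pc2, dc2, qc2, keys2)
    if (trial_obj <= obj) {
      design[task, ] <- sort(row2)
      pc <- pc2; dc <- dc2; qc <- qc2; keys <- keys2
      obj <- trial_obj
    }
  }
  attr(design, "diagnostics") <- design_diagnostics(design, spec)
  design
}

#' Simulate a respondent's conjoint answers
#'
#' For each task the agent picks one of the presented profiles by softmax
#' over subjective values.
#'
#' @param agent one-row cohort data.frame.
#' @param design design matrix from [generate_cbc_design()].
#' @param spec the matching [cbc_design_spec()].
#' @return integer vector of chosen slots (1..set_size), one per task.
#' @export
simulate_cbc_choices <- function(agent, design, spec) {
  profiles <- spec$profiles
  vals <- subjective_value(agent$k_delay, agent$k_odds, profiles$amount,
                           profiles$probability, profiles$delay_days)
  vapply(seq_len(nrow(design)), function(tk) {
    choose_option(vals[design[tk, ]], agent$temperature, spec$amount)
  }, integer(1L))
}

#' Long-format design and choice tables for a cohort
#'
#' Generates every respondent's design and simulated answers, returning the
#' on-disk schemas used by the pipeline.
#'
#' @param agents cohort data.frame.
#' @param spec a [cbc_design_spec()].
#' @param seed master design seed (per-respondent sub-seeded).
#' @return list: `design` (`agent_id`, `task_index`, `slot`, `profile_id`)
#'   and `choices` (`agent_id`, `task_index`, `chosen_profile_id`).
#' @export
simulate_cbc_wave <- function(agents, spec, seed = NULL) {
  des_rows <- vector("list", nrow(agents))
  cho_rows <- vector("list", nrow(agents))
  for (i in seq_len(nrow(agents))) {
    ag <- agents[i, ]
    design <- generate_cbc_design(spec, respondent_id = i, seed = seed)
    picks <- simulate_cbc_choices(ag, design, spec)
    des_rows[[i]] <- data.frame(
      agent_id = ag$agent_id,
      task_index = rep(seq_len(spec$n_tasks), each = spec$set_size),
      slot = rep(seq_len(spec$set_size), times = spec$n_tasks),
      profile_id = spec$profiles$profile_id[as.vector(t(design))],
      stringsAsFactors = FALSE)
    cho_rows[[i]] <- data.frame(
      agent_id = ag$agent_id,
      task_index = seq_len(spec$n_tasks),
      chosen_profile_id =
        spec$profiles$profile_id[design[cbind(seq_len(spec$n_tasks), picks)]],
      stringsAsFactors = FALSE)
  }
  list(design = do.call(rbind, des_rows), choices = do.call(rbind, cho_rows))
}

# Deterministic 32-bit sub-seed from a master seed and an id.
derive_seed <- function(seed, id) {
  idnum <- if (is.character(id)) sum(utf8ToInt(paste(id, collapse = ""))) else
    as.numeric(id)
  as.integer((as.numeric(seed) * 69069 + idnum * 1013904223) %% 2147483629)
}
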