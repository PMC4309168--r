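#' Dummy coding of lottery attributes
#'
#' Maps each profile of a conjoint design to a predictor vector. Main
#' effects use treatment (dummy) coding with the first level of each
#' attribute — the shortest delay and the lowest probability — as
#' reference, so the reference profile codes to the zero vector and the
#' main-effects dimension is (number of delays - 1) + (number of
#' probabilities - 1). Second-order delay x probability interactions can be
#' added behind a flag.
#'
#' @param spec a [cbc_design_spec()].
#' @param interactions include delay x probability interaction columns.
#' @return list of class `cbc_coding`: `X` (profiles x predictors matrix,
#'   rownames = profile ids), `spec`, `interactions`, and per-attribute
#'   level/reference bookkeeping.
#' @export
cbc_coding <- function(spec, interactions = FALSE) {
  profiles <- spec$profiles
  df <- data.frame(
    delay = factor(profiles$delay_days, levels = spec$delays),
    prob = factor(profiles$probability, levels = spec$probabilities))
  form <- if (interactions) ~ delay * prob else ~ delay + prob
  X <- stats::model.matrix(form, df)[, -1L, drop = FALSE]
  rownames(X) <- profiles$profile_id
  structure(list(X = X, spec = spec, interactions = interactions,
                 delay_levels = spec$delays,
                 prob_levels = spec$probabilities),
            class = "cbc_coding")
}

#' Cumulative utility of profiles
#'
#' A profile's utility is the sum of the part-worths of its attribute
#' levels: the dot product of its coded predictor row with the part-worth
#' vector `b` (interaction terms included when the coding has them). The
#' reference profile has utility 0 under main-effects dummy coding.
#'
#' @param b part-worth vector, length `ncol(coding$X)`.
#' @param coding a [cbc_coding()].
#' @param profile_id profiles to evaluate (default: all).
#' @return named numeric vector of utilities.
#' @export
cumulative_utility <- function(b, coding, profile_id = rownames(coding$X)) {
  if (length(b) != ncol(coding$X))
    stop("b has length ", length(b), ", coding expects ", ncol(coding$X))
  miss <- setdiff(profile_id, rownames(coding$X))
  if (length(miss)) stop("unknown profile(s): ", paste(miss, collapse = ", "))
  drop(coding$X[profile_id, , drop = FALSE] %*% b)
}

#' Win ratios of profiles and attribute levels
#'
#' The win ratio of a profile is the proportion of times it was chosen out
#' of the times it was shown; the win ratio of an attribute level pools the
#' counts over all profiles carrying that level. Profiles never shown get
#' `NA` and are flagged.
#'
#' @param choices long choice table (`agent_id`, `task_index`,
#'   `chosen_profile_id`).
#' @param design long design table (`agent_id`, `task_index`, `slot`,
#'   `profile_id`).
#' @param coding a [cbc_coding()] (supplies the profile grid and levels).
#' @param agent_id optionally restrict to one respondent.
#' @return list: `profile` (data.frame `profile_id`, `shown`, `chosen`,
#'   `ratio`), `delay` and `probability` (per-level equivalents),
#'   `unshown_profiles` (character).
#' @export
win_ratios <- function(choices, design, coding, agent_id = NULL) {
  profiles <- coding$spec$profiles
  if (!is.null(agent_id)) {
    design <- design[design$agent_id %in% agent_id, , drop = FALSE]
    choices <- choices[choices$agent_id %in% agent_id, , drop = FALSE]
  }
  if (!all(choices$chosen_profile_id %in% profiles$profile_id))
    stop("choices reference unknown profiles")
  shown <- tabulate(match(design$profile_id, profiles$profile_id),
                    nbins = nrow(profiles))
  won <- tabulate(match(choices$chosen_profile_id, profiles$profile_id),
                  nbins = nrow(profiles))
  ratio <- ifelse(shown > 0, won / shown, NA_real_)
  prof <- data.frame(profile_id = profiles$profile_id, shown = shown,
                     chosen = won, ratio = ratio, stringsAsFactors = FALSE)
  by_level <- function(values, levels) {
    s <- vapply(levels, function(l) sum(shown[values == l]), numeric(1))
    w <- vapply(levels, function(l) sum(won[values == l]), numeric(1))
    data.frame(level = levels, shown = s, chosen = w,
               ratio = ifelse(s > 0, w / s, NA_real_))
  }
  list(profile = prof,
       delay = by_level(profiles$delay_days, coding$delay_levels),
       probability = by_level(profiles$probability, coding$prob_levels),
       unshown_profiles = profiles$profile_id[shown == 0])
}

#' Multinomial-logit log-likelihood of conjoint choices
#'
#' For tasks indexed by `task`, option rows `X` and a one-chosen-per-task
#' indicator, returns \eqn{\sum_t [x_{c(t)} b - \log \sum_j \exp(x_j b)]}.
#' Always <= 0; equals `-n_tasks * log(set_size)` at `b = 0`.
#'
#' @param b part-worth vector.
#' @param X numeric matrix, one row per presented option.
#' @param task integer task index per row (1-based, contiguous groups).
#' @param chosen logical per row, exactly one `TRUE` per task.
#' @return scalar log-likelihood.
#' @export
mnl_loglik <- function(b, X, task, chosen) {
  if (ncol(X) != length(b)) stop("dimension mismatch between X and b")
  if (!all(tapply(chosen, task, sum) == 1L))
    stop("exactly one option must be chosen per task")
  u <- drop(X %*% b)
  m <- tapply(u, task, max)
  lse <- m + log(tapply(exp(u - m[as.character(task)]), task, sum))
  sum(u[chosen]) - sum(lse)
}

#' Gradient of the multinomial-logit log-likelihood
#'
#' @inheritParams mnl_loglik
#' @return numeric gradient vector, length `length(b)`.
#' @export
mnl_grad <- function(b, X, task, chosen) {
  u <- drop(X %*% b)
  m <- tapply(u, task, max)
  w <- exp(u - as.vector(m[as.character(task)]))
  p <- w / as.vector(tapply(w, task, sum)[as.character(task)])
  colSums(X[chosen, , drop = FALSE]) - colSums(X * p)
}

#' Hierarchical Bayes sampler configuration
#'
#' @param n_iterations total MCMC iterations (default 20000).
#' @param burn_in iterations discarded and used for proposal adaptation
#'   (default half of `n_iterations`).
#' @param proposal_sd initial scale of the random-walk proposal (the
#'   proposal covariance is `proposal_sd^2 * D`).
#' @param adapt_interval iterations between proposal-scale adaptations
#'   during burn-in; adaptation targets an acceptance rate of about 0.3 and
#'   stops at the end of burn-in so the retained chain satisfies detailed
#'   balance.
#' @param prior_df inverse-Wishart prior degrees of freedom for the
#'   covariance `D`; `NULL` resolves to predictor dimension + 5 at run time.
#' @param prior_scale inverse-Wishart prior scale matrix; `NULL` means the
#'   identity ("initial variance is unity, covariance zero").
#' @param thin thinning interval for stored post-burn-in draws.
#' @param seed RNG seed for the whole chain.
#' @return list of class `hb_config`.
#' @export
hb_config <- function(n_iterations = 20000L, burn_in = n_iterations %/% 2L,
                      proposal_sd = 0.5, adapt_interval = 25L,
                      prior_df = NULL, prior_scale = NULL, thin = 10L,
                      seed = NULL) {
  stopifnot(n_iterations >= 2L, burn_in >= 0L, burn_in < n_iterations,
            proposal_sd >= 0, adapt_interval >= 1L, thin >= 1L)
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in),
                 proposal_sd = proposal_sd,
                 adapt_interval = as.integer(adapt_interval),
                 prior_df = prior_df, prior_scale = prior_scale,
                 thin = as.integer(thin), seed = seed),
            class = "hb_config")
}

# Internal: stack choices + design into the sampler's flat representation.
# Respondent set is taken from the design, so respondents without recorded
# choices are kept (their posterior is the population prior).
hb_build_data <- function(choices, design, coding) {
  resp <- unique(design$agent_id)
  d <- design[order(match(design$agent_id, resp), design$task_index,
                    design$slot), , drop = FALSE]
  ch <- choices[order(match(choices$agent_id, resp), choices$task_index), ,
                drop = FALSE]
  keyd <- paste(d$agent_id, d$task_index, sep = "\r")
  keyc <- paste(ch$agent_id, ch$task_index, sep = "\r")
  keep <- keyd %in% keyc
  d <- d[keep, , drop = FALSE]
  keyd <- keyd[keep]
  rl <- rle(keyd)
  if (!identical(rl$values, keyc))
    stop("design and choices tables do not describe the same tasks")
  S <- unique(rl$lengths)
  if (length(S) != 1L)
    stop("all tasks must present the same number of profiles")
  n_task <- length(keyc)
  task_of_row <- rep(seq_len(n_task), each = S)
  chosen <- d$profile_id == ch$chosen_profile_id[task_of_row]
  if (!all(tapply(chosen, task_of_row, sum) == 1L))
    stop("each chosen profile must appear exactly once in its task")
  Xrow <- coding$X[match(d$profile_id, rownames(coding$X)), , drop = FALSE]
  if (anyNA(Xrow)) stop("design references profiles missing from the coding")
  resp_of_task <- match(ch$agent_id, resp)
  list(respondents = resp, n_resp = length(resp), set_size = S,
       n_task = n_task, X = Xrow, task_of_row = task_of_row,
       resp_of_task = resp_of_task,
       resp_of_row = resp_of_task[task_of_row], chosen = chosen,
       chosen_rows = which(chosen))
}

# Internal: per-respondent MNL log-likelihood for a matrix of part-worths
# (one row per respondent), vectorized over all tasks at once.
hb_loglik_all <- function(B, dat) {
  ll <- numeric(dat$n_resp)
  if (dat$n_task == 0L) return(ll)
  u <- rowSums(dat$X * B[dat$resp_of_row, , drop = FALSE])
  um <- matrix(u, nrow = dat$set_size)
  m <- um[1L, ]
  for (s in seq_len(dat$set_size)[-1L]) m <- pmax(m, um[s, ])
  lse <- m + log(.colSums(exp(um - rep(m, each = dat$set_size)),
                          dat$set_size, dat$n_task))
  ll_task <- u[dat$chosen_rows] - lse
  agg <- rowsum(ll_task, dat$resp_of_task)
  ll[as.integer(rownames(agg))] <- agg[, 1L]
  ll
}

#' Gibbs update of the population mean
#'
#' Draws the population part-worth mean `a` from its full conditional under
#' a flat prior: N(column means of `b_all`, `D / n`).
#'
#' @param b_all respondents x predictors matrix of current part-worths.
#' @param D current covariance matrix (positive-definite).
#' @return numeric vector, one draw of `a`.
#' @export
update_alpha <- function(b_all, D) {
  n <- nrow(b_all)
  if (is.null(n) || n == 0L) stop("b_all must have at least one row")
  U <- chol(D)
  colMeans(b_all) + drop(t(U) %*% stats::rnorm(ncol(b_all))) / sqrt(n)
}

#' Gibbs update of the population covariance
#'
#' Draws `D` from its inverse-Wishart full conditional with degrees of
#' freedom `prior_df + n` and scale `prior_scale + sum of (b - a)(b - a)'`.
#'
#' @inheritParams update_alpha
#' @param a current population mean vector.
#' @param prior_df prior degrees of freedom (>= dimension + 2 recommended).
#' @param prior_scale prior scale matrix (identity by default).
#' @return symmetric positive-definite matrix draw.
#' @export
update_D <- function(b_all, a, prior_df = ncol(b_all) + 5,
                     prior_scale = diag(ncol(b_all))) {
  n <- nrow(b_all)
  centered <- sweep(b_all, 2L, a)
  scale_post <- prior_scale + crossprod(centered)
  W <- stats::rWishart(1L, df = prior_df + n, Sigma = solve(scale_post))[, , 1L]
  D <- solve(W)
  (D + t(D)) / 2
}

#' Metropolis-Hastings update of individual part-worths
#'
#' One Gaussian random-walk step per respondent on the posterior
#' proportional to MNL-likelihood x N(b | a, D). The proposal covariance is
#' `proposal_sd^2 * D`; the symmetric proposal makes the plain
#' likelihood-ratio acceptance rule satisfy detailed balance. A respondent
#' with no recorded tasks is driven by the prior alone.
#'
#' @inheritParams update_alpha
#' @param a population mean vector.
#' @param dat internal data object from choices/design (see [run_hb()]);
#'   built once per fit.
#' @param proposal_sd random-walk scale (0 keeps the chain constant and
#'   always accepts).
#' @param ll_current optional cached per-respondent log-likelihood at
#'   `b_all` (recomputed when `NULL`).
#' @return list: `b` (updated matrix), `accepted` (logical per respondent),
#'   `loglik` (per-respondent MNL log-likelihood at the new state).
#' @export
update_betas <- function(b_all, a, D, dat, proposal_sd, ll_current = NULL) {
  n <- nrow(b_all)
  k <- ncol(b_all)
  if (is.null(ll_current)) ll_current <- hb_loglik_all(b_all, dat)
  U <- chol(D)
  prop <- b_all + proposal_sd *
    (matrix(stats::rnorm(n * k), n, k) %*% U)
  ll_prop <- hb_loglik_all(prop, dat)
  Dinv <- chol2inv(U)
  qf <- function(B) {
    cb <- sweep(B, 2L, a)
    rowSums((cb %*% Dinv) * cb)
  }
  log_ratio <- (ll_prop - 0.5 * qf(prop)) - (ll_current - 0.5 * qf(b_all))
  accepted <- log(stats::runif(n)) < log_ratio
  b_all[accepted, ] <- prop[accepted, ]
  ll_current[accepted] <- ll_prop[accepted]
  list(b = b_all, accepted = accepted, loglik = ll_current)
}

# Internal: initial part-worths from each respondent's attribute-level win
# ratios, clipped to [0.05, 0.95] and mapped through the logit so the
# coefficient of a non-reference level is logit(wr_level) - logit(wr_ref).
# Interaction columns (if any) start at zero.
hb_init_betas <- function(choices, design, coding, respondents) {
  k <- ncol(coding$X)
  B <- matrix(0, length(respondents), k,
              dimnames = list(respondents, colnames(coding$X)))
  main_cols <- !grepl(":", colnames(coding$X), fixed = TRUE)
  for (i in seq_along(respondents)) {
    wr <- win_ratios(choices, design, coding, agent_id = respondents[i])
    lv <- function(tab) {
      r <- ifelse(is.na(tab$ratio), 0.5, pmin(pmax(tab$ratio, 0.05), 0.95))
      stats::qlogis(r) - stats::qlogis(r[1L])
    }
    init <- c(lv(wr$delay)[-1L], lv(wr$probability)[-1L])
    B[i, which(main_cols)] <- init
  }
  B
}

#' Fit the hierarchical Bayes multinomial-logit model
#'
#' Individual part-worth vectors `b_i` are modelled as draws from
#' N(`a`, `D`); choices follow a multinomial logit in the coded profile
#' utilities. The sampler iterates the three conditional updates — draw
#' `a` given `b, D` ([update_alpha()]), draw `D` given `b, a`
#' ([update_D()]), and one Metropolis-Hastings step per respondent on `b`
#' given `a, D` ([update_betas()]) — for `config$n_iterations` iterations.
#' Initialization: `b` from each respondent's logit-transformed attribute
#' level win ratios, `a = 0`, `D = I`. The proposal scale is adapted toward
#' ~30% acceptance during burn-in only. Fully reproducible given
#' `config$seed`.
#'
#' @param choices long choice table (`agent_id`, `task_index`,
#'   `chosen_profile_id`).
#' @param design long design table (`agent_id`, `task_index`, `slot`,
#'   `profile_id`).
#' @param coding a [cbc_coding()].
#' @param config an [hb_config()].
#' @return object of class `hb_fit`: `beta_mean` (posterior means,
#'   respondents x predictors), `beta_draws` (thinned array), `alpha_chain`
#'   and `D_draws` (post burn-in, thinned), `acceptance` (per-respondent
#'   post-burn-in MH acceptance rate), `loglik_trace`, `proposal_sd_final`,
#'   `respondents`, `coding`, `config`.
#' @export
run_hb <- function(choices, design, coding, config = hb_config()) {
  if (nrow(choices) == 0L) stop("empty choice data")
  if (!is.null(config$seed)) set.seed(config$seed)
  dat <- hb_build_data(choices, design, coding)
  k <- ncol(coding$X)
  prior_df <- if (is.null(config$prior_df)) k + 5 else config$prior_df
  prior_scale <- if (is.null(config$prior_scale)) diag(k) else
    config$prior_scale

  B <- hb_init_betas(choices, design, coding, dat$respondents)
  a <- rep(0, k)
  D <- diag(k)
  s <- config$proposal_sd
  ll <- hb_loglik_all(B, dat)

  n_iter <- config$n_iterations
  burn <- config$burn_in
  keep_iters <- seq.int(burn + 1L, n_iter, by = config$thin)
  n_keep <- length(keep_iters)
  alpha_chain <- matrix(NA_real_, n_keep, k,
                        dimnames = list(NULL, colnames(coding$X)))
  D_draws <- array(NA_real_, c(k, k, n_keep))
  beta_draws <- array(NA_real_, c(dat$n_resp, k, n_keep))
  beta_sum <- matrix(0, dat$n_resp, k)
  acc_count <- numeric(dat$n_resp)
  loglik_trace <- numeric(n_iter)
  acc_window <- 0
  kept <- 0L

  for (it in seq_len(n_iter)) {
    a <- update_alpha(B, D)
    D <- update_D(B, a, prior_df, prior_scale)
    step <- update_betas(B, a, D, dat, s, ll_current = ll)
    B <- step$b
    ll <- step$loglik
    loglik_trace[it] <- sum(ll)
    acc_window <- acc_window + mean(step$accepted)
    if (it <= burn && it %% config$adapt_interval == 0L && s > 0) {
      rate <- acc_window / config$adapt_interval
      s <- min(10, max(1e-3, s * exp(rate - 0.3)))
      acc_window <- 0
    } else if (it %% config$adapt_interval == 0L) {
      acc_window <- 0
    }
    if (it > burn) {
      beta_sum <- beta_sum + B
      acc_count <- acc_count + step$accepted
      if (it %in% keep_iters) {
        kept <- kept + 1L
        alpha_chain[kept, ] <- a
        D_draws[, , kept] <- D
        beta_draws[, , kept] <- B
      }
    }
  }
  n_post <- n_iter - burn
  structure(list(
    beta_mean = beta_sum / n_post,
    beta_draws = beta_draws,
    alpha_chain = alpha_chain,
    D_draws = D_draws,
    acceptance = acc_count / n_post,
    loglik_trace = loglik_trace,
    proposal_sd_final = s,
    respondents = dat$respondents,
    coding = coding,
    config = config
  ), class = "hb_fit")
}

#' @export
print.hb_fit <- function(x, ...) {
  cat("Hierarchical Bayes MNL fit\n")
  cat("  respondents:", length(x$respondents),
      " predictors:", ncol(x$beta_mean), "\n")
  cat("  iterations:", x$config$n_iterations,
      " burn-in:", x$config$burn_in, "\n")
  cat("  mean MH acceptance:", round(mean(x$acceptance), 3), "\n")
  cat("  population mean (posterior):\n")
  print(round(colMeans(x$alpha_chain), 3))
  invisible(x)
}

#' Posterior-mean cumulative utilities for all respondents
#'
#' @param fit an `hb_fit`.
#' @return matrix respondents x profiles of utilities
#'   (`beta_mean %*% t(X)`).
#' @export
profile_utilities <- function(fit) {
  out <- fit$beta_mean %*% t(fit$coding$X)
  rownames(out) <- fit$respondents
  out
}

#' Part-worth summary table
#'
#' @param fit an `hb_fit`.
#' @return data.frame `agent_id`, `coefficient_name`, `posterior_mean`,
#'   `posterior_sd` (SD over thinned stored draws).
#' @export
partworth_table <- function(fit) {
  k <- ncol(fit$beta_mean)
  sds <- apply(fit$beta_draws, c(1L, 2L), stats::sd)
  data.frame(
    agent_id = rep(fit$respondents, each = k),
    coefficient_name = rep(colnames(fit$coding$X), times = length(fit$respondents)),
    posterior_mean = as.vector(t(fit$beta_mean)),
    posterior_sd = as.vector(t(sds)),
    stringsAsFactors = FALSE)
}
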