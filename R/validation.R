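#' Cohen's kappa for paired binary ratings
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} from the
#' 2 x 2 cross-classification of two waves of binary answers, with the
#' large-sample z test of kappa = 0 (Fleiss standard error under the null).
#' Undefined (flagged `NA`) when the expected agreement is 1, i.e. neither
#' margin varies.
#'
#' @param ratings_wave1,ratings_wave2 equal-length binary vectors (any two
#'   distinct values; coerced to factor over the union of levels).
#' @return list: `kappa`, `z`, `p_value`, `table`, `n`, `undefined` flag.
#' @export
cohen_kappa <- function(ratings_wave1, ratings_wave2) {
  if (length(ratings_wave1) != length(ratings_wave2))
    stop("rating vectors must have equal length")
  n <- length(ratings_wave1)
  if (n < 2L) stop("need at least two paired ratings")
  lev <- sort(unique(c(ratings_wave1, ratings_wave2)))
  f1 <- factor(ratings_wave1, levels = lev)
  f2 <- factor(ratings_wave2, levels = lev)
  tab <- table(f1, f2)
  p <- tab / n
  po <- sum(diag(p))
  prow <- rowSums(p)
  pcol <- colSums(p)
  pe <- sum(prow * pcol)
  if (1 - pe < .Machine$double.eps^0.5)
    return(list(kappa = NA_real_, z = NA_real_, p_value = NA_real_,
                table = tab, n = n, undefined = TRUE))
  kappa <- (po - pe) / (1 - pe)
  se0 <- sqrt(pe + pe^2 - sum(prow * pcol * (prow + pcol))) /
    ((1 - pe) * sqrt(n))
  z <- kappa / se0
  list(kappa = kappa, z = z, p_value = 2 * stats::pnorm(-abs(z)),
       table = tab, n = n, undefined = FALSE)
}

#' Binary logistic regression with fit statistics
#'
#' Maximum-likelihood logistic fit (IRLS via [stats::glm()]) reporting the
#' coefficients, maximized and null log-likelihoods, AIC (intercept
#' counted) and Nagelkerke pseudo R squared
#' \deqn{R^2 = \frac{1 - \exp(2(\ell_0 - \ell_1)/n)}{1 - \exp(2\ell_0/n)}.}
#' Quasi-perfect separation is detected from divergent coefficient norms
#' and flagged.
#'
#' @param data data.frame holding response and predictors.
#' @param response name of the 0/1 response column.
#' @param predictors character vector of predictor column names (may be
#'   empty for the intercept-only model).
#' @return list of class `logistic_fit`: `coefficients`, `loglik`,
#'   `null_loglik`, `aic`, `nagelkerke`, `n`, `predictors`, `separation`,
#'   `fit` (the glm object).
#' @export
logistic_fit <- function(data, response, predictors = character()) {
  y <- data[[response]]
  if (length(unique(y)) < 2L)
    stop("response must contain both classes")
  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  form <- stats::as.formula(paste(response, "~", rhs))
  fit <- suppressWarnings(stats::glm(form, data = data,
                                     family = stats::binomial()))
  ll <- as.numeric(stats::logLik(fit))
  fit0 <- stats::glm(stats::as.formula(paste(response, "~ 1")), data = data,
                     family = stats::binomial())
  ll0 <- as.numeric(stats::logLik(fit0))
  n <- nrow(data)
  nk <- (1 - exp(2 * (ll0 - ll) / n)) / (1 - exp(2 * ll0 / n))
  structure(list(
    coefficients = stats::coef(fit),
    loglik = ll, null_loglik = ll0,
    aic = 2 * length(stats::coef(fit)) - 2 * ll,
    nagelkerke = min(max(nk, 0), 1),
    n = n, predictors = predictors,
    separation = any(abs(stats::coef(fit)[-1L]) > 15) && length(predictors) > 0,
    fit = fit), class = "logistic_fit")
}

#' Backward elimination on likelihood-ratio tests
#'
#' Starting from the full logistic model, repeatedly drops the predictor
#' with the largest likelihood-ratio p-value above `alpha_remove` and
#' refits, until every retained predictor tests at p <= `alpha_remove`.
#' This is the likelihood-ratio analogue of the "conditional backwards"
#' stepwise option of standard statistical GUIs (removal threshold 0.10).
#'
#' @inheritParams logistic_fit
#' @param alpha_remove removal threshold on the LR p-value (default 0.10).
#' @return a `logistic_fit` of the final model with extra fields
#'   `eliminated` (names, in removal order) and `retained`.
#' @export
backward_eliminate <- function(data, response, predictors,
                               alpha_remove = 0.10) {
  retained <- predictors
  eliminated <- character()
  repeat {
    fit <- logistic_fit(data, response, retained)
    if (length(retained) == 0L) break
    dr <- suppressWarnings(stats::drop1(fit$fit, test = "LRT"))
    pvals <- dr[["Pr(>Chi)"]][-1L]
    names(pvals) <- rownames(dr)[-1L]
    # an inestimable predictor (aliased or constant) contributes nothing:
    # treat its test as maximally removable
    pvals[is.na(pvals)] <- 1
    worst <- names(pvals)[which.max(pvals)]
    if (max(pvals) <= alpha_remove) break
    retained <- setdiff(retained, worst)
    eliminated <- c(eliminated, worst)
  }
  fit$eliminated <- eliminated
  fit$retained <- retained
  fit
}

#' Predictive-validity comparison of the two measurement methods
#'
#' For each external choice-task decision and each measurement method,
#' fits a backward-eliminated logistic regression of the binary decision on
#' that method's three AUC discounting parameters. A method "predicts" a
#' decision when at least one AUC predictor survives elimination. Decisions
#' with a degenerate response (everyone chose the same option) are skipped
#' and flagged.
#'
#' @param profiles long AUC table (`agent_id`, `method`, `probability`,
#'   `auc`) for one wave, both methods.
#' @param choice_responses choice-task table (`agent_id`, `decision`,
#'   `chose_a`).
#' @param alpha_remove removal threshold passed to [backward_eliminate()].
#' @param pooled also fit, per decision, a model pooling both methods' six
#'   AUC predictors (reported under method `"pooled"`).
#' @return data.frame, one row per decision x method: `decision`, `method`,
#'   `skipped`, `n_retained`, `retained` (comma-separated), `aic`,
#'   `nagelkerke`, `predicts`.
#' @export
validity_comparison <- function(profiles, choice_responses,
                                alpha_remove = 0.10, pooled = FALSE) {
  wide <- auc_wide(profiles)
  methods <- unique(profiles$method)
  rows <- list()
  for (d in sort(unique(choice_responses$decision))) {
    resp <- choice_responses[choice_responses$decision == d, ]
    dat <- merge(wide, resp[, c("agent_id", "chose_a")], by = "agent_id")
    degenerate <- length(unique(dat$chose_a)) < 2L
    sets <- lapply(methods, function(m) grep(paste0("^", m, "_"),
                                             names(wide), value = TRUE))
    names(sets) <- methods
    if (pooled) sets$pooled <- unlist(sets[methods], use.names = FALSE)
    for (m in names(sets)) {
      if (degenerate) {
        rows[[length(rows) + 1L]] <- data.frame(
          decision = d, method = m, skipped = TRUE, n_retained = NA_integer_,
          retained = NA_character_, aic = NA_real_, nagelkerke = NA_real_,
          predicts = NA, stringsAsFactors = FALSE)
        next
      }
      fit <- backward_eliminate(dat, "chose_a", sets[[m]], alpha_remove)
      rows[[length(rows) + 1L]] <- data.frame(
        decision = d, method = m, skipped = FALSE,
        n_retained = length(fit$retained),
        retained = paste(fit$retained, collapse = ","),
        aic = fit$aic, nagelkerke = fit$nagelkerke,
        predicts = length(fit$retained) > 0, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Internal: long AUC table -> one row per agent, columns method_probability.
auc_wide <- function(profiles) {
  profiles$key <- paste0(profiles$method, "_auc",
                         gsub("[^0-9]", "", sprintf("%.2f", profiles$probability)))
  out <- stats::reshape(
    profiles[, c("agent_id", "key", "auc")],
    idvar = "agent_id", timevar = "key", direction = "wide")
  names(out) <- sub("^auc\\.", "", names(out))
  out
}

#' Test-retest stability of discounting parameters
#'
#' Pearson correlation, per measurement method and probability level, of
#' each respondent's AUC across the two waves, with the two-sided t-test
#' p-value. Cells with zero variance in either wave are flagged `NA`.
#'
#' @param profiles_wave1,profiles_wave2 long AUC tables (`agent_id`,
#'   `method`, `probability`, `auc`) for paired respondents.
#' @return data.frame `method`, `probability`, `r`, `p_value`, `n`,
#'   `undefined`.
#' @export
retest_stability <- function(profiles_wave1, profiles_wave2) {
  m <- merge(profiles_wave1, profiles_wave2,
             by = c("agent_id", "method", "probability"),
             suffixes = c("_w1", "_w2"))
  cells <- unique(m[, c("method", "probability")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- m[m$method == cells$method[i] &
               m$probability == cells$probability[i], ]
    v1 <- sub$auc_w1
    v2 <- sub$auc_w2
    if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
      return(data.frame(method = cells$method[i],
                        probability = cells$probability[i],
                        r = NA_real_, p_value = NA_real_, n = nrow(sub),
                        undefined = TRUE, stringsAsFactors = FALSE))
    ct <- stats::cor.test(v1, v2, method = "pearson")
    data.frame(method = cells$method[i], probability = cells$probability[i],
               r = unname(ct$estimate), p_value = ct$p.value, n = nrow(sub),
               undefined = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Choice-task repeatability across waves
#'
#' Cohen's kappa per choice-task decision between the two waves' answers.
#'
#' @param responses_wave1,responses_wave2 choice-task tables (`agent_id`,
#'   `decision`, `chose_a`); paired on `agent_id` within decision.
#' @return data.frame `decision`, `kappa`, `z`, `p_value`, `n`,
#'   `undefined`.
#' @export
choice_stability <- function(responses_wave1, responses_wave2) {
  m <- merge(responses_wave1, responses_wave2,
             by = c("agent_id", "decision"), suffixes = c("_w1", "_w2"))
  rows <- lapply(sort(unique(m$decision)), function(d) {
    sub <- m[m$decision == d, ]
    kp <- cohen_kappa(sub$chose_a_w1, sub$chose_a_w2)
    data.frame(decision = d, kappa = kp$kappa, z = kp$z,
               p_value = kp$p_value, n = kp$n, undefined = kp$undefined)
  })
  do.call(rbind, rows)
}
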