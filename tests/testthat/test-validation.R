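test_that("Cohen's kappa matches the 2x2 hand formula and its limits", {
  # identical vectors with both categories present
  x <- c(0, 0, 1, 1, 0, 1)
  expect_equal(cohen_kappa(x, x)$kappa, 1)
  # hand oracle for table a=10, b=5, c=5, d=20:
  # p_o = 30/40, p_e = (15/40)^2 + (25/40)^2, kappa = 0.4666...
  w1 <- rep(c(0, 0, 1, 1), times = c(10, 5, 5, 20))
  w2 <- rep(c(0, 1, 0, 1), times = c(10, 5, 5, 20))
  kp <- cohen_kappa(w1, w2)
  expect_equal(kp$kappa, (0.75 - 0.53125) / (1 - 0.53125), tolerance = 1e-12)
  expect_lt(kp$p_value, 0.05)
  # independent margins with p_o = p_e give kappa 0
  a1 <- rep(c(0, 0, 1, 1), times = c(9, 3, 3, 1))
  a2 <- rep(c(0, 1, 0, 1), times = c(9, 3, 3, 1))
  expect_equal(cohen_kappa(a1, a2)$kappa, 0, tolerance = 1e-12)
  # symmetry and label invariance
  expect_equal(cohen_kappa(w2, w1)$kappa, kp$kappa)
  expect_equal(cohen_kappa(1 - w1, 1 - w2)$kappa, kp$kappa)
  # no marginal variation is flagged undefined
  expect_true(cohen_kappa(rep(1, 5), rep(1, 5))$undefined)
})

test_that("logistic fits report the right coefficients and fit indices", {
  # intercept-only with a 50/50 response: Nagelkerke 0
  d0 <- data.frame(y = rep(c(0, 1), 25))
  f0 <- logistic_fit(d0, "y")
  expect_equal(unname(f0$coefficients[1]), 0, tolerance = 1e-8)
  expect_equal(f0$nagelkerke, 0, tolerance = 1e-8)
  expect_equal(f0$aic, 2 - 2 * f0$loglik)
  # textbook 2x2 table: slope = log odds ratio
  d1 <- data.frame(x = rep(c(0, 0, 1, 1), times = c(30, 10, 15, 25)),
                   y = rep(c(0, 1, 0, 1), times = c(30, 10, 15, 25)))
  f1 <- logistic_fit(d1, "y", "x")
  expect_equal(unname(f1$coefficients["x"]),
               log((25 * 30) / (15 * 10)), tolerance = 1e-6)
  # maximum agrees with a direct numerical optimizer
  set.seed(81)
  d2 <- data.frame(a = rnorm(40), b = rnorm(40))
  d2$y <- rbinom(40, 1, plogis(0.5 * d2$a - 0.8 * d2$b))
  f2 <- logistic_fit(d2, "y", c("a", "b"))
  nll <- function(th) -sum(dbinom(d2$y, 1,
    plogis(th[1] + th[2] * d2$a + th[3] * d2$b), log = TRUE))
  opt <- optim(c(0, 0, 0), nll, method = "BFGS")
  expect_equal(f2$loglik, -opt$value, tolerance = 1e-6)
  # nested submodel never beats the full model on log-likelihood
  expect_lte(logistic_fit(d2, "y", "a")$loglik, f2$loglik + 1e-10)
})

test_that("backward elimination drops noise and keeps signal", {
  set.seed(82)
  n <- 400
  drops_noise <- 0L
  keeps_signal <- 0L
  n_sim <- 30L
  for (i in seq_len(n_sim)) {
    d <- data.frame(signal = rnorm(n), noise = rnorm(n))
    d$y <- rbinom(n, 1, plogis(1.5 * d$signal))
    fit <- backward_eliminate(d, "y", c("signal", "noise"))
    if (!"noise" %in% fit$retained) drops_noise <- drops_noise + 1L
    if ("signal" %in% fit$retained) keeps_signal <- keeps_signal + 1L
  }
  expect_gte(drops_noise / n_sim, 0.9)
  expect_equal(keeps_signal, n_sim)
  # two strong predictors both survive
  set.seed(83)
  d <- data.frame(u = rnorm(n), v = rnorm(n))
  d$y <- rbinom(n, 1, plogis(1.2 * d$u - 1.2 * d$v))
  expect_setequal(backward_eliminate(d, "y", c("u", "v"))$retained,
                  c("u", "v"))
  # a single null predictor collapses to the intercept-only model
  set.seed(84)
  d <- data.frame(w = rnorm(n), y = rbinom(n, 1, 0.5))
  fit0 <- backward_eliminate(d, "y", "w")
  expect_length(fit0$retained, 0)
  expect_equal(fit0$eliminated, "w")
})

test_that("validity comparison recognizes the generating method", {
  set.seed(85)
  n <- 150
  mk_prof <- function(auc, method) {
    data.frame(agent_id = rep(sprintf("a%03d", 1:n), each = 3),
               method = method, probability = rep(c(0.01, 0.1, 0.7), n),
               auc = as.vector(t(auc)), stringsAsFactors = FALSE)
  }
  auc_true <- cbind(runif(n, 0, 0.3), runif(n, 0.2, 0.7), runif(n, 0.5, 1))
  auc_noise <- cbind(runif(n, 0, 0.3), runif(n, 0.2, 0.7), runif(n, 0.5, 1))
  profiles <- rbind(mk_prof(auc_true, "conjoint"),
                    mk_prof(auc_noise, "adjusting"))
  # decisions generated from the conjoint AUCs through a logistic link
  resp <- do.call(rbind, lapply(1:3, function(d) {
    eta <- -2 + 6 * auc_true[, d]
    data.frame(agent_id = sprintf("a%03d", 1:n), decision = d,
               chose_a = rbinom(n, 1, plogis(eta)), stringsAsFactors = FALSE)
  }))
  tab <- validity_comparison(profiles, resp)
  cj <- tab[tab$method == "conjoint", ]
  ad <- tab[tab$method == "adjusting", ]
  expect_true(all(cj$predicts))
  # AIC favors the generating method on every decision
  expect_true(all(cj$aic < ad$aic))
  # degenerate decisions are skipped
  resp_deg <- resp
  resp_deg$chose_a[resp_deg$decision == 2] <- 1L
  tab_deg <- validity_comparison(profiles, resp_deg)
  expect_true(all(tab_deg$skipped[tab_deg$decision == 2]))
  expect_false(any(tab_deg$skipped[tab_deg$decision != 2]))
})

test_that("retest stability recovers the attenuation formula and its limits", {
  set.seed(86)
  n <- 1000
  mk <- function(auc) {
    data.frame(agent_id = rep(sprintf("a%04d", 1:n), each = 1),
               method = "conjoint", probability = 0.1, auc = auc,
               stringsAsFactors = FALSE)
  }
  x <- rnorm(n)
  same <- retest_stability(mk(x), mk(x))
  expect_equal(same$r, 1)
  indep <- retest_stability(mk(x), mk(rnorm(n)))
  expect_lt(abs(indep$r), 0.2)
  # wave2 = wave1 + noise with var ratio 1: E[r] = 1/sqrt(2)
  att <- retest_stability(mk(x), mk(x + rnorm(n)))
  expect_equal(att$r, 1 / sqrt(2), tolerance = 0.1)
  # zero variance is flagged
  const <- retest_stability(mk(rep(0.5, n)), mk(x))
  expect_true(const$undefined)
})
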