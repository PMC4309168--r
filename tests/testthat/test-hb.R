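spec9 <- cbc_design_spec()
coding9 <- cbc_coding(spec9)

test_that("dummy coding has the documented dimension and reference profile", {
  expect_equal(ncol(coding9$X), 4L)
  expect_equal(unname(coding9$X["d7_p0.01", ]), rep(0, 4))
  withx <- cbc_coding(spec9, interactions = TRUE)
  expect_equal(ncol(withx$X), 4L + 4L)  # (3-1)(3-1) interaction columns
  # cumulative utility is the coded dot product
  b <- c(-1, -3, 2, 5)
  expect_equal(unname(cumulative_utility(b, coding9, "d90_p0.7")), 4)
  expect_equal(unname(cumulative_utility(rep(0, 4), coding9)), rep(0, 9))
  expect_error(cumulative_utility(b, coding9, "nope"), "unknown")
})

test_that("win ratios count chosen over shown at profile and level grain", {
  design <- data.frame(agent_id = "a1", task_index = rep(1:3, each = 3),
                       slot = rep(1:3, 3),
                       profile_id = c("d7_p0.01", "d7_p0.1", "d7_p0.7",
                                      "d7_p0.1", "d90_p0.1", "d90_p0.7",
                                      "d7_p0.1", "d730_p0.1", "d730_p0.7"))
  choices <- data.frame(agent_id = "a1", task_index = 1:3,
                        chosen_profile_id = c("d7_p0.7", "d7_p0.1", "d7_p0.1"))
  wr <- win_ratios(choices, design, coding9)
  p <- wr$profile
  expect_equal(p$ratio[p$profile_id == "d7_p0.1"], 2 / 3)
  expect_equal(p$ratio[p$profile_id == "d7_p0.7"], 1)
  expect_equal(p$ratio[p$profile_id == "d90_p0.1"], 0)
  expect_true(is.na(p$ratio[p$profile_id == "d90_p0.01"]))
  expect_true("d90_p0.01" %in% wr$unshown_profiles)
  # level grain pools profiles: delay 7 shown 5 times, chosen 3
  expect_equal(wr$delay$ratio[wr$delay$level == 7], 3 / 5)
})

test_that("MNL log-likelihood and gradient agree with closed forms and finite differences", {
  set.seed(61)
  spec <- cbc_design_spec(n_tasks = 25L)
  sim <- simulate_mnl_cohort(matrix(c(-1, -2, 1, 2), 1L), spec)
  dat <- delaydisc:::hb_build_data(sim$choices, sim$design, sim$coding)
  X <- dat$X
  task <- dat$task_of_row
  chosen <- dat$chosen
  # uniform model: -n_tasks * log(set_size)
  expect_equal(mnl_loglik(rep(0, 4), X, task, chosen), -25 * log(3),
               tolerance = 1e-12)
  expect_lt(mnl_loglik(c(0.3, -0.4, 1.2, 0.1), X, task, chosen), 0)
  # location invariance: a constant added to every option's utility (an
  # intercept column) leaves the likelihood unchanged
  b <- c(0.5, -1.5, 0.8, 2.2)
  expect_equal(mnl_loglik(c(b, 7), cbind(X, 1), task, chosen),
               mnl_loglik(b, X, task, chosen), tolerance = 1e-9)
  # gradient vs central finite differences
  for (trial in 1:5) {
    b0 <- rnorm(4)
    g <- mnl_grad(b0, X, task, chosen)
    h <- 1e-5
    gfd <- vapply(1:4, function(j) {
      e <- rep(0, 4); e[j] <- h
      (mnl_loglik(b0 + e, X, task, chosen) -
         mnl_loglik(b0 - e, X, task, chosen)) / (2 * h)
    }, numeric(1))
    expect_equal(unname(g), gfd, tolerance = 1e-6)
  }
})

test_that("population-mean draws follow N(mean(b), D/n)", {
  set.seed(62)
  B <- matrix(rnorm(12 * 2, sd = 2), 12L, 2L)
  D <- matrix(c(1, 0.4, 0.4, 0.8), 2L)
  draws <- t(replicate(10000, update_alpha(B, D)))
  expect_equal(colMeans(draws), colMeans(B), tolerance = 0.02)
  expect_equal(cov(draws), D / 12, tolerance = 0.1)
  # near-degenerate D pins the draw at the sample mean
  expect_equal(update_alpha(B, diag(1e-18, 2L)), colMeans(B),
               tolerance = 1e-6)
})

test_that("covariance draws are SPD inverse-Wishart with the right concentration", {
  set.seed(63)
  k <- 3L
  a <- rep(0, k)
  B <- matrix(0, 200L, k)  # all b equal to a: posterior scale = prior scale
  prior_df <- k + 5
  prior_scale <- diag(k) * 2
  draws <- replicate(400, update_D(B, a, prior_df, prior_scale))
  expect_true(all(apply(draws, 3L, function(m) {
    ok <- TRUE
    tryCatch(chol(m), error = function(e) ok <<- FALSE)
    ok
  })))
  # inverse-Wishart mean: scale / (df - k - 1)
  mean_draw <- apply(draws, c(1L, 2L), mean)
  expect_equal(mean_draw, prior_scale / (prior_df + 200 - k - 1),
               tolerance = 0.15)
  set.seed(9); d1 <- update_D(B, a, prior_df, prior_scale)
  set.seed(9); d2 <- update_D(B, a, prior_df, prior_scale)
  expect_identical(d1, d2)
})

test_that("MH beta updates satisfy the stated limits", {
  set.seed(64)
  spec <- toy_spec()
  sim <- simulate_mnl_cohort(matrix(c(-1, 1.5), 1L), spec)
  dat <- delaydisc:::hb_build_data(sim$choices, sim$design, sim$coding)
  B <- matrix(c(0.3, -0.2), 1L)
  a <- c(0, 0)
  D <- diag(2)
  # zero proposal keeps the chain constant and always accepts
  step <- update_betas(B, a, D, dat, proposal_sd = 0)
  expect_identical(step$b, B)
  expect_true(all(step$accepted))
})

test_that("MH posterior mean matches dense-grid integration on a 2-parameter toy", {
  set.seed(65)
  spec <- toy_spec()
  b_true <- c(-1, 1.5)
  sim <- simulate_mnl_cohort(matrix(b_true, 1L), spec)
  dat <- delaydisc:::hb_build_data(sim$choices, sim$design, sim$coding)
  a <- c(0, 0)
  D <- diag(2) * 2
  # dense-grid oracle over [-5, 5]^2
  g <- seq(-5, 5, by = 0.025)
  grid <- as.matrix(expand.grid(b1 = g, b2 = g))
  U <- dat$X %*% t(grid)
  um1 <- U[dat$chosen_rows, , drop = FALSE]
  nt <- dat$n_task
  S <- dat$set_size
  ll <- numeric(nrow(grid))
  for (t in seq_len(nt)) {
    rows <- which(dat$task_of_row == t)
    mt <- pmax(U[rows[1], ], U[rows[2], ])
    ll <- ll + U[rows[dat$chosen[rows]], ] -
      (mt + log(exp(U[rows[1], ] - mt) + exp(U[rows[2], ] - mt)))
  }
  lp <- ll - 0.5 * rowSums((grid %*% solve(D)) * grid)
  w <- exp(lp - max(lp))
  grid_mean <- unname(colSums(grid * w) / sum(w))
  # MH chain with the same fixed prior
  B <- matrix(0, 1L, 2L)
  llc <- NULL
  keep <- matrix(NA_real_, 4000L, 2L)
  for (it in 1:9000) {
    st <- update_betas(B, a, D, dat, proposal_sd = 0.8, ll_current = llc)
    B <- st$b
    llc <- st$loglik
    if (it > 5000) keep[it - 5000, ] <- B
  }
  mh_mean <- colMeans(keep)
  expect_equal(mh_mean, grid_mean, tolerance = 0.02 * max(1, max(abs(grid_mean))))
})

test_that("a data-free respondent's accepted draws recover the prior", {
  set.seed(66)
  spec <- toy_spec(n_tasks = 10L)
  sim <- simulate_mnl_cohort(matrix(c(-1, 1.5), 1L), spec)
  # add a second respondent that appears in the design with no choices
  ghost <- sim$design
  ghost$agent_id <- "ghost"
  dat <- delaydisc:::hb_build_data(sim$choices, rbind(sim$design, ghost),
                                   sim$coding)
  expect_equal(dat$n_resp, 2L)
  a <- c(0.5, -0.25)
  D <- matrix(c(1, 0.3, 0.3, 0.6), 2L)
  B <- matrix(0, 2L, 2L)
  llc <- NULL
  keep <- matrix(NA_real_, 6000L, 2L)
  for (it in 1:8000) {
    st <- update_betas(B, a, D, dat, proposal_sd = 1.2, ll_current = llc)
    B <- st$b
    llc <- st$loglik
    if (it > 2000) keep[it - 2000, ] <- B[2L, ]
  }
  expect_equal(colMeans(keep), a, tolerance = 0.12)
  expect_equal(cov(keep), D, tolerance = 0.25)
})

test_that("the full sampler is seed-reproducible and shrinks random answerers", {
  set.seed(67)
  spec <- cbc_design_spec(n_tasks = 25L)
  n <- 15L
  B_true <- sweep(matrix(rnorm(n * 4, sd = 1), n, 4L), 2L,
                  c(-1.5, -3.5, 1.5, 4), "+")
  sim <- simulate_mnl_cohort(B_true, spec)
  # respondent 1 answers uniformly at random
  set.seed(68)
  rnd <- sim$design[sim$design$agent_id == "a001", ]
  pick <- tapply(rnd$profile_id, rnd$task_index, function(p) sample(p, 1L))
  sim$choices$chosen_profile_id[sim$choices$agent_id == "a001"] <-
    unname(pick[as.character(1:25)])
  cfg <- hb_config(n_iterations = 1500L, burn_in = 750L, seed = 99L)
  fit <- run_hb(sim$choices, sim$design, sim$coding, cfg)
  fit2 <- run_hb(sim$choices, sim$design, sim$coding, cfg)
  expect_identical(fit$beta_mean, fit2$beta_mean)
  expect_identical(fit$alpha_chain, fit2$alpha_chain)
  expect_true(all(fit$acceptance > 0 & fit$acceptance < 1))
  expect_true(all(apply(fit$D_draws, 3L, function(m)
    all(eigen(m, symmetric = TRUE, only.values = TRUE)$values > 0))))
  # shrinkage: the random answerer's posterior mean sits closer to the
  # population mean than their unpenalized MLE does
  a_hat <- colMeans(fit$alpha_chain)
  dat1 <- delaydisc:::hb_build_data(
    sim$choices[sim$choices$agent_id == "a001", ],
    sim$design[sim$design$agent_id == "a001", ], sim$coding)
  mle <- optim(rep(0, 4), function(b)
    -mnl_loglik(b, dat1$X, dat1$task_of_row, dat1$chosen),
    method = "BFGS")$par
  expect_lt(sqrt(sum((fit$beta_mean[1L, ] - a_hat)^2)),
            sqrt(sum((mle - a_hat)^2)))
})

test_that("two long chains with different seeds agree within Monte Carlo error", {
  set.seed(70)
  spec <- cbc_design_spec(n_tasks = 20L)
  n <- 12L
  B_true <- sweep(matrix(rnorm(n * 4), n, 4L), 2L, c(-1, -2.5, 1, 3), "+")
  sim <- simulate_mnl_cohort(B_true, spec)
  f1 <- run_hb(sim$choices, sim$design, sim$coding,
               hb_config(3000L, 1500L, seed = 1L, thin = 2L))
  f2 <- run_hb(sim$choices, sim$design, sim$coding,
               hb_config(3000L, 1500L, seed = 2L, thin = 2L))
  m1 <- colMeans(f1$alpha_chain)
  m2 <- colMeans(f2$alpha_chain)
  # batch-means MCSE per chain, combined in quadrature
  mcse <- function(ch) {
    nb <- 25L
    bm <- apply(ch, 2L, function(x)
      tapply(x, rep(seq_len(nb), each = length(x) / nb), mean))
    apply(bm, 2L, sd) / sqrt(nb)
  }
  tol <- 3 * sqrt(mcse(f1$alpha_chain)^2 + mcse(f2$alpha_chain)^2)
  expect_true(all(abs(m1 - m2) < pmax(tol, 0.15)))
})
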