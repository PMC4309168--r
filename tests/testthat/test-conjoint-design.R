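test_that("profile enumeration is the attribute cartesian product", {
  expect_equal(nrow(cbc_design_spec()$profiles), 9L)
  expect_equal(nrow(lottery_grid(7L, 0.5)), 1L)
  expect_equal(nrow(lottery_grid(c(7, 30, 180, 730), c(0.01, 0.1, 0.35, 0.7))),
               16L)
})

test_that("choice-set enumeration counts binomial coefficients", {
  spec <- cbc_design_spec()
  expect_equal(ncol(enumerate_choice_sets(spec$profiles, 3L)), 84L)
  expect_equal(ncol(enumerate_choice_sets(spec$profiles[1:3, ], 3L)), 1L)
  expect_equal(ncol(enumerate_choice_sets(spec$profiles[1:5, ], 2L)), 10L)
  expect_error(enumerate_choice_sets(spec$profiles[1:2, ], 3L), "exceeds")
})

test_that("generated designs are balanced, near-orthogonal and deterministic", {
  spec <- cbc_design_spec()
  d <- generate_cbc_design(spec, respondent_id = 1L, seed = 10)
  expect_equal(dim(d), c(25L, 3L))
  expect_true(all(apply(d, 1L, function(r) !any(duplicated(r)))))
  dg <- attr(d, "diagnostics")
  # 75 exposures over 9 profiles: every profile 8 or 9 times
  expect_true(all(dg$profile_counts %in% c(8L, 9L)))
  # each attribute level exactly at the ideal 75/3 = 25
  expect_true(all(abs(dg$delay_counts - 25) <= 1))
  expect_true(all(abs(dg$prob_counts - 25) <= 1))
  # every task is one of the 84 enumerable subsets
  sets <- apply(enumerate_choice_sets(spec$profiles, 3L), 2L, paste,
                collapse = "-")
  expect_true(all(apply(d, 1L, paste, collapse = "-") %in% sets))
  # determinism and per-respondent variation under one master seed
  expect_identical(d, generate_cbc_design(spec, respondent_id = 1L, seed = 10))
  expect_false(identical(unclass(d),
                         unclass(generate_cbc_design(spec, 2L, seed = 10))))
})

test_that("the optimizer dominates purely random designs", {
  spec <- cbc_design_spec()
  set.seed(33)
  wins <- 0L
  n_trials <- 40L
  for (i in seq_len(n_trials)) {
    rnd <- t(replicate(spec$n_tasks, sort(sample.int(9L, 3L))))
    obj_rnd <- design_diagnostics(rnd, spec)$objective
    obj_opt <- attr(generate_cbc_design(spec, i, seed = i),
                    "diagnostics")$objective
    if (obj_opt <= obj_rnd) wins <- wins + 1L
  }
  expect_gte(wins / n_trials, 0.95)
})

test_that("design diagnostics count exposures and co-occurrences", {
  spec <- cbc_design_spec()
  one <- matrix(c(1L, 2L, 3L), nrow = 1L)
  dg <- design_diagnostics(one, spec)
  expect_equal(unname(dg$profile_counts[1:3]), c(1L, 1L, 1L))
  expect_equal(unname(dg$profile_counts[4:9]), rep(0L, 6L))
  expect_equal(sum(dg$cooccurrence), 3L)
  # a perfectly level-balanced design has zero balance contribution
  balanced <- matrix(c(1L, 5L, 9L, 2L, 6L, 7L, 3L, 4L, 8L), 3L, 3L,
                     byrow = TRUE)
  dgb <- design_diagnostics(balanced, spec)
  expect_equal(sum((dgb$delay_counts - 3)^2) + sum((dgb$prob_counts - 3)^2), 0)
})

test_that("simulated conjoint waves expose the long schemas", {
  set.seed(55)
  spec <- cbc_design_spec(n_tasks = 6L)
  agents <- generate_cohort(3, seed = 5)
  w <- simulate_cbc_wave(agents, spec, seed = 9)
  expect_equal(nrow(w$design), 3L * 6L * 3L)
  expect_equal(nrow(w$choices), 3L * 6L)
  expect_named(w$design, c("agent_id", "task_index", "slot", "profile_id"))
  expect_named(w$choices, c("agent_id", "task_index", "chosen_profile_id"))
  # chosen profile always among the presented ones
  key <- paste(w$design$agent_id, w$design$task_index, w$design$profile_id)
  expect_true(all(paste(w$choices$agent_id, w$choices$task_index,
                        w$choices$chosen_profile_id) %in% key))
})
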