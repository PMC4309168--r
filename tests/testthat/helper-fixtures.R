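# Shared fixture builders. Everything is generated in code at test time.

# Deterministic responder with a fixed internal equivalent v:
# chooses the certain offer iff offer >= v (ties to certain).
fixed_value_responder <- function(v) {
  force(v)
  function(certain_amount, lottery) certain_amount >= v
}

# A noiseless value-maximizing agent row.
noiseless_agent <- function(k_delay = 0.01, k_odds = 0.5) {
  data.frame(agent_id = "nx", k_delay = k_delay, k_odds = k_odds,
             temperature = 0, retest_sd = 0, adjusting_noise = 1,
             stringsAsFactors = FALSE)
}

# Simulate MNL conjoint data for known part-worths B (n x k), one optimal
# design per respondent; returns the long design/choices tables.
simulate_mnl_cohort <- function(B, spec, design_seed = 123) {
  coding <- cbc_coding(spec)
  X <- coding$X
  n <- nrow(B)
  des <- vector("list", n)
  cho <- vector("list", n)
  for (i in seq_len(n)) {
    d <- generate_cbc_design(spec, respondent_id = i, seed = design_seed)
    u <- drop(X %*% B[i, ])
    picks <- vapply(seq_len(nrow(d)), function(t) {
      z <- u[d[t, ]]
      p <- exp(z - max(z))
      sample(length(z), 1L, prob = p / sum(p))
    }, integer(1L))
    id <- sprintf("a%03d", i)
    des[[i]] <- data.frame(
      agent_id = id,
      task_index = rep(seq_len(spec$n_tasks), each = spec$set_size),
      slot = rep(seq_len(spec$set_size), times = spec$n_tasks),
      profile_id = spec$profiles$profile_id[as.vector(t(d))],
      stringsAsFactors = FALSE)
    cho[[i]] <- data.frame(
      agent_id = id, task_index = seq_len(spec$n_tasks),
      chosen_profile_id =
        spec$profiles$profile_id[d[cbind(seq_len(spec$n_tasks), picks)]],
      stringsAsFactors = FALSE)
  }
  list(design = do.call(rbind, des), choices = do.call(rbind, cho),
       coding = coding)
}

# Tiny 2-parameter toy problem (2 delays x 2 probabilities, paired tasks)
# for sampler-vs-grid comparisons.
toy_spec <- function(n_tasks = 15L) {
  cbc_design_spec(delays = c(7L, 730L), probabilities = c(0.1, 0.7),
                  set_size = 2L, n_tasks = n_tasks)
}
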