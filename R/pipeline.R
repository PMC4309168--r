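#' Study configuration
#'
#' Bundles every knob of the in-silico two-wave method-comparison study:
#' cohort size and population, the conjoint design, the HB sampler, the
#' staircase depth, the time-scaling convention, the external choice task
#' and the number of replicates. The two-wave design administers the choice
#' task first, then the adjusting battery and the conjoint task (in a
#' randomized, recorded order), on each of two occasions with jittered
#' traits in between.
#'
#' @param n cohort size (the study sessions used 27 and 60 respondents).
#' @param population a [population_config()].
#' @param design a [cbc_design_spec()].
#' @param hb an [hb_config()].
#' @param n_steps staircase steps per lottery (default 6).
#' @param time_convention `"minmax"` or `"max"`, see [scale_times()].
#' @param interactions include delay x probability interactions in the HB
#'   coding.
#' @param retest_n if not `NULL`, stability analyses use a random
#'   subsample of this many respondents (emulating retest dropout, 60 ->
#'   22 in the second study session).
#' @param validity_wave2 also run the validity analysis on wave 2
#'   (off by default; validity is assessed on the first wave).
#' @param n_replicates independent replicates of the whole study.
#' @return list of class `study_config`.
#' @export
study_config <- function(n = 60L, population = population_config(),
                         design = cbc_design_spec(), hb = hb_config(),
                         n_steps = 6L, time_convention = "minmax",
                         interactions = FALSE, retest_n = 22L,
                         validity_wave2 = FALSE, n_replicates = 1L) {
  stopifnot(n >= 1L, n_steps >= 2L, n_replicates >= 1L)
  if (!is.null(retest_n)) stopifnot(retest_n >= 3L)
  structure(list(n = as.integer(n), population = population, design = design,
                 hb = hb, n_steps = as.integer(n_steps),
                 time_convention = time_convention,
                 interactions = interactions,
                 retest_n = retest_n, validity_wave2 = validity_wave2,
                 n_replicates = as.integer(n_replicates),
                 choice_task = choice_task_items(design$amount)),
            class = "study_config")
}

# Internal: simulate one wave of data collection for a cohort — external
# choice task first, then (per respondent, in a randomized recorded order)
# the adjusting battery and the conjoint task.
simulate_wave_data <- function(agents, config, wave) {
  profiles <- config$design$profiles
  ct <- simulate_choice_task(agents, config$choice_task)
  ct$wave <- wave
  adj_choices <- vector("list", nrow(agents))
  adj_equiv <- vector("list", nrow(agents))
  method_order <- character(nrow(agents))
  cbc <- simulate_cbc_wave(agents, config$design)
  for (i in seq_len(nrow(agents))) {
    ag <- agents[i, ]
    method_order[i] <- sample(c("adjusting-first", "conjoint-first"), 1L)
    battery <- run_adjusting_battery(agent_responder(ag), profiles,
                                     n_steps = config$n_steps)
    battery$choices$agent_id <- ag$agent_id
    battery$equivalents$agent_id <- ag$agent_id
    adj_choices[[i]] <- battery$choices
    adj_equiv[[i]] <- battery$equivalents
  }
  list(
    choice_task = ct,
    adjusting_choices = do.call(rbind, adj_choices),
    equivalents = do.call(rbind, adj_equiv),
    cbc_design = cbc$design,
    cbc_choices = cbc$choices,
    method_order = data.frame(agent_id = agents$agent_id,
                              wave = wave, order = method_order,
                              stringsAsFactors = FALSE)
  )
}

# Internal: per-respondent AUC profiles (both methods) for one wave.
wave_discount_profiles <- function(wave_data, hb_fit, config, wave) {
  spec <- config$design
  adj <- lapply(split(wave_data$equivalents, wave_data$equivalents$agent_id),
                adjusting_profile, spec = spec,
                time_convention = config$time_convention)
  util <- profile_utilities(hb_fit)
  cj <- lapply(stats::setNames(rownames(util), rownames(util)), function(id)
    conjoint_profile(util[id, ], spec,
                     time_convention = config$time_convention))
  rbind(bind_discount_profiles(adj, "adjusting", wave),
        bind_discount_profiles(cj, "conjoint", wave))
}

# Internal: one full replicate of the two-wave study.
run_replicate <- function(config) {
  coding <- cbc_coding(config$design, config$interactions)
  agents <- generate_cohort(config$n, config$population)
  wave1 <- simulate_wave_data(agents, config, wave = 1L)
  agents2 <- jitter_for_retest(agents)
  wave2 <- simulate_wave_data(agents2, config, wave = 2L)
  fit1 <- run_hb(wave1$cbc_choices, wave1$cbc_design, coding, config$hb)
  fit2 <- run_hb(wave2$cbc_choices, wave2$cbc_design, coding, config$hb)
  prof1 <- wave_discount_profiles(wave1, fit1, config, 1L)
  prof2 <- wave_discount_profiles(wave2, fit2, config, 2L)

  validity <- validity_comparison(prof1, wave1$choice_task)
  if (isTRUE(config$validity_wave2))
    validity <- rbind(cbind(validity, wave = 1L),
                      cbind(validity_comparison(prof2, wave2$choice_task),
                            wave = 2L))

  retest_ids <- agents$agent_id
  if (!is.null(config$retest_n) && config$retest_n < length(retest_ids))
    retest_ids <- sample(retest_ids, config$retest_n)
  stability <- retest_stability(
    prof1[prof1$agent_id %in% retest_ids, ],
    prof2[prof2$agent_id %in% retest_ids, ])
  kappas <- choice_stability(
    wave1$choice_task[wave1$choice_task$agent_id %in% retest_ids, ],
    wave2$choice_task[wave2$choice_task$agent_id %in% retest_ids, ])

  list(agents = agents, wave1 = wave1, wave2 = wave2,
       hb_wave1 = fit1, hb_wave2 = fit2,
       profiles = rbind(prof1, prof2),
       validity = validity, stability = stability, kappas = kappas,
       retest_ids = retest_ids)
}

#' Run the full in-silico method-comparison study
#'
#' Per replicate: generate a cohort with known discounting traits; simulate
#' wave 1 (choice task, 6-step adjusting battery over the 9 lotteries,
#' individually randomized 25-task conjoint); jitter the traits; simulate
#' wave 2 the same way; estimate part-worths by hierarchical Bayes per
#' wave; reduce both methods to per-respondent AUC discounting profiles;
#' compute the wave-1 predictive-validity comparison and the cross-wave
#' stability statistics. Fully reproducible from `(config, seed)`.
#'
#' @param config a [study_config()].
#' @param seed master seed for everything (cohorts, designs, choices,
#'   MCMC).
#' @param out_dir if not `NULL`, write all intermediate CSV tables, the
#'   validity/stability JSON reports and a run manifest there.
#' @return object of class `study_report`: `replicates` (list of
#'   per-replicate results), `aggregates` (see below), `config`, `seed`.
#'   Aggregates: `mean_retest_r` per method (mean Pearson r over
#'   probability levels and replicates), `mean_aic` and
#'   `fraction_predicted` per method from the validity tables, and
#'   `mean_kappa` per decision.
#' @export
run_study <- function(config = study_config(), seed = 1L, out_dir = NULL) {
  set.seed(seed)
  reps <- lapply(seq_len(config$n_replicates),
                 function(r) run_replicate(config))
  validity_all <- do.call(rbind, lapply(seq_along(reps), function(r)
    cbind(replicate = r, reps[[r]]$validity)))
  stability_all <- do.call(rbind, lapply(seq_along(reps), function(r)
    cbind(replicate = r, reps[[r]]$stability)))
  kappa_all <- do.call(rbind, lapply(seq_along(reps), function(r)
    cbind(replicate = r, reps[[r]]$kappas)))

  ok <- !validity_all$skipped
  aggregates <- list(
    mean_retest_r = tapply(stability_all$r, stability_all$method,
                           mean, na.rm = TRUE),
    mean_aic = tapply(validity_all$aic[ok], validity_all$method[ok], mean),
    fraction_predicted = tapply(validity_all$predicts[ok],
                                validity_all$method[ok], mean),
    mean_kappa = tapply(kappa_all$kappa, kappa_all$decision,
                        mean, na.rm = TRUE))

  report <- structure(list(replicates = reps, aggregates = aggregates,
                           validity = validity_all,
                           stability = stability_all, kappas = kappa_all,
                           config = config, seed = seed),
                      class = "study_report")
  if (!is.null(out_dir)) write_study_outputs(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Two-wave discounting method-comparison study\n")
  cat("  cohort n =", x$config$n, ", replicates =", x$config$n_replicates,
      ", seed =", x$seed, "\n")
  cat("  mean test-retest r by method:\n")
  print(round(x$aggregates$mean_retest_r, 3))
  cat("  mean AIC by method (wave-1 validity models):\n")
  print(round(x$aggregates$mean_aic, 2))
  cat("  fraction of decisions predicted by method:\n")
  print(round(x$aggregates$fraction_predicted, 3))
  invisible(x)
}

# Internal: write every on-disk schema plus a run manifest.
write_study_outputs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, file) utils::write.csv(df, file.path(out_dir, file),
                                           row.names = FALSE)
  gather <- function(extract) do.call(rbind, lapply(
    seq_along(report$replicates), function(r)
      cbind(replicate = r, extract(report$replicates[[r]]))))
  w(gather(function(x) x$agents), "agents.csv")
  w(gather(function(x) rbind(x$wave1$choice_task, x$wave2$choice_task)),
    "choice_task.csv")
  w(gather(function(x) rbind(cbind(wave = 1L, x$wave1$adjusting_choices),
                             cbind(wave = 2L, x$wave2$adjusting_choices))),
    "adjusting_choices.csv")
  w(gather(function(x) rbind(cbind(wave = 1L, x$wave1$equivalents),
                             cbind(wave = 2L, x$wave2$equivalents))),
    "equivalents.csv")
  w(gather(function(x) rbind(cbind(wave = 1L, x$wave1$cbc_design),
                             cbind(wave = 2L, x$wave2$cbc_design))),
    "cbc_design.csv")
  w(gather(function(x) rbind(cbind(wave = 1L, x$wave1$cbc_choices),
                             cbind(wave = 2L, x$wave2$cbc_choices))),
    "cbc_choices.csv")
  w(gather(function(x) rbind(cbind(wave = 1L, partworth_table(x$hb_wave1)),
                             cbind(wave = 2L, partworth_table(x$hb_wave2)))),
    "partworths.csv")
  auc <- gather(function(x) x$profiles)
  auc$time_convention <- report$config$time_convention
  w(auc, "auc.csv")
  jsonlite::write_json(report$validity,
                       file.path(out_dir, "validity_report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(kappa = report$kappas,
                            correlations = report$stability),
                       file.path(out_dir, "stability_report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(seed = report$seed,
                            n = report$config$n,
                            n_replicates = report$config$n_replicates,
                            time_convention = report$config$time_convention,
                            aggregates = lapply(report$aggregates, as.list)),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
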