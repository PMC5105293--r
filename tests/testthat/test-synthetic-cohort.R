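test_that("generation is deterministic and extending the cohort is stable", {
  a <- simulate_latent_cohort(cohort_config(n_subjects = 30), seed = 11)
  b <- simulate_latent_cohort(cohort_config(n_subjects = 30), seed = 11)
  expect_identical(a$visits, b$visits)
  expect_identical(a$truth, b$truth)
  # per-subject streams: adding subjects never perturbs existing ones
  big <- simulate_latent_cohort(cohort_config(n_subjects = 45), seed = 11)
  small_ids <- unique(a$visits$subject_id)
  expect_identical(big$visits[big$visits$subject_id %in% small_ids, ],
                   a$visits)
  expect_error(simulate_latent_cohort(cohort_config(n_subjects = 5)),
               "seed")
})

test_that("noise-free zero-decline cohorts have constant, exactly recovered states", {
  p <- zero_decline_params(cv = 0)
  co <- simulate_latent_cohort(cohort_config(n_subjects = 120), p, seed = 12)
  cl <- suppressWarnings(classify_visits(co$visits))
  expect_identical(as.character(cl$state), as.character(co$truth$true_state))
  per_subj <- tapply(as.character(cl$state), cl$subject_id,
                     function(s) length(unique(s)))
  expect_true(all(per_subj == 1))
  u <- build_units(cl)
  s <- summarize_transitions(u)
  expect_equal(s$p_beneficial[s$state == "normal"], 1)
  expect_true(all(s$p_resolution[-1] %in% 0 | is.na(s$p_resolution[-1])))
  expect_equal(unname(diag(estimate_transition_matrix(u)$probabilities)),
               rep(1, 4), tolerance = 1e-12)
})

test_that("covariate marginals track the configuration at scale", {
  cfg <- cohort_config(n_subjects = 1200)
  co <- simulate_latent_cohort(cfg, seed = 13)
  v <- co$visits[!duplicated(co$visits$subject_id), ]
  expect_lt(abs(mean(v$sex == "female") - cfg$pct_female), 0.04)
  expect_lt(abs(mean(v$ethnicity == "hispanic") - cfg$pct_hispanic), 0.04)
  expect_lt(abs(mean(v$hypertension) - cfg$pct_hypertension), 0.05)
  expect_true(all(v$pack_years >= cfg$pack_years_min))
  expect_true(all(v$age >= 40 & v$age <= 75))
  nv <- table(co$visits$subject_id)
  expect_true(all(nv >= 2 & nv <= cfg$max_visits))
  expect_equal(mean(nv), 4, tolerance = 0.25)
  # baseline true states follow the configured mix
  bt <- co$truth[!duplicated(co$truth$subject_id), "baseline_state"]
  expect_lt(max(abs(as.numeric(prop.table(table(bt))) -
                      cfg$baseline_state_mix)), 0.05)
})

test_that("markov mode round-trips the chain through classification", {
  Q <- null_beneficial_q()
  co <- simulate_markov_cohort(cohort_config(n_subjects = 250), Q, seed = 14)
  cl <- suppressWarnings(classify_visits(co$visits))
  expect_identical(as.character(cl$state), as.character(co$truth$true_state))

  # identity chain: no transitions ever
  co_id <- simulate_markov_cohort(cohort_config(n_subjects = 150), diag(4),
                                  seed = 15, n_visits = 4)
  cl_id <- suppressWarnings(classify_visits(co_id$visits))
  u <- build_units(cl_id)
  s <- summarize_transitions(u)
  expect_equal(s$p_beneficial[s$state == "normal"], 1)
  expect_true(all(s$p_beneficial[-1] == 0))
  expect_error(simulate_markov_cohort(cohort_config(n_subjects = 5),
                                      matrix(1, 4, 4), seed = 1),
               "row")
})

test_that("infeasible truncation regions raise a diagnostic error", {
  p <- trajectory_params()
  p$pctpred_mean[3] <- 300   # unclassified region is (30, 80): no mass
  p$pctpred_sd[3] <- 1
  expect_error(simulate_latent_cohort(cohort_config(n_subjects = 60), p,
                                      seed = 16),
               "infeasible truncation")
})

test_that("injecting a unit odds ratio of 1 is a distributional no-op", {
  cfg <- cohort_config(n_subjects = 100)
  Q <- null_beneficial_q()
  base <- simulate_markov_cohort(cfg, Q, seed = 17)
  noop <- simulate_markov_cohort(cfg, Q, seed = 17,
                                 predictor_effects = list(hispanic = 1))
  expect_identical(base$visits, noop$visits)
  expect_error(inject_predictor_effect(trajectory_params(), "shoe_size", 2),
               "unknown predictor")
  expect_error(inject_predictor_effect(trajectory_params(), "hispanic", -1),
               "true_or")
})

test_that("injected effects shift beneficial odds in the intended direction", {
  cfg <- cohort_config(n_subjects = 800)
  Q <- null_beneficial_q()
  eff <- inject_predictor_effect(trajectory_params(), "hispanic", 3)
  co <- simulate_markov_cohort(cfg, Q, seed = 18, predictor_effects = eff)
  cl <- suppressWarnings(classify_visits(co$visits))
  u <- unit_predictors(build_units(cl))
  p_his <- mean(u$beneficial[u$hispanic])
  p_not <- mean(u$beneficial[!u$hispanic])
  expect_gt(p_his, p_not + 0.1)
})

test_that("covariate-dependent dropout removes younger smokers preferentially", {
  cfg <- cohort_config(n_subjects = 1000, dropout_covariate_dependent = TRUE)
  co <- simulate_latent_cohort(cfg, seed = 19)
  v <- co$visits[!duplicated(co$visits$subject_id), ]
  nv <- tapply(co$visits$visit, co$visits$subject_id, max)[v$subject_id]
  short <- nv <= 2
  expect_lt(mean(v$age[short]), mean(v$age[!short]))
  expect_gt(mean(v$current_smoker[short]), mean(v$current_smoker[!short]) - 0.02)
})
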