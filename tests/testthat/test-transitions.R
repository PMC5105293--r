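test_that("units form between consecutive classifiable visits in the window", {
  v <- make_classified_visits(rep("s1", 3), c(0, 1.5, 3.0),
                              c("normal", "normal", "gold1"))
  u <- build_units(v)
  expect_equal(nrow(u), 2)
  expect_equal(u$unit_index, c(0L, 1L))
  expect_equal(u$interval_years, c(1.5, 1.5))

  # a 3-year gap is never split or chained across a missed visit
  v2 <- make_classified_visits(rep("s1", 2), c(0, 3.0), c("normal", "gold1"))
  expect_equal(nrow(build_units(v2, tolerance = 0.5)), 0)

  # 100 subjects x 4 perfectly spaced visits -> exactly 300 units
  v3 <- make_classified_visits(rep(sprintf("s%03d", 1:100), each = 4),
                               rep(c(0, 1.5, 3, 4.5), 100), "normal")
  expect_equal(nrow(build_units(v3)), 300)
})

test_that("unclassifiable visits, singletons and duplicates are accounted", {
  v <- make_classified_visits(c("a", "a", "a", "b", "c", "c"),
                              c(0, 1.5, 1.5, 0, 0, 1.4),
                              c("normal", "gold1", "gold1", "normal",
                                "unclassified", "normal"))
  v$state[4] <- NA  # b's only visit unclassifiable
  expect_warning(u <- build_units(v), "duplicate")
  excl <- attr(u, "exclusions")
  expect_equal(excl$duplicate_sessions, 1L)
  expect_equal(excl$unclassifiable_sessions, 1L)
  expect_equal(excl$subjects_lt2_visits, 1L)     # b
  expect_equal(nrow(u), 2)                        # a and c each give one unit
})

test_that("unordered visit times are rejected, interleaved subjects accepted", {
  bad <- make_classified_visits(rep("s1", 3), c(0, 3.0, 1.5),
                                c("normal", "normal", "gold1"))
  expect_error(build_units(bad), "time-ordered")
  # interleaving subjects is fine as long as each subject is ordered
  ok <- make_classified_visits(c("a", "b", "a", "b"), c(0, 0, 1.5, 1.5),
                               "normal")
  expect_equal(nrow(build_units(ok)), 2)
})

test_that("baseline group comes from the first classifiable visit", {
  v <- make_classified_visits(c("a", "a", "b", "b"), c(0, 1.5, 0, 1.5),
                              c("normal", "gold1", "gold2plus", "normal"))
  u <- build_units(v)
  expect_identical(u$baseline_group[u$subject_id == "a"],
                   "normal_at_baseline")
  expect_identical(u$baseline_group[u$subject_id == "b"],
                   "abnormal_at_baseline")
})

test_that("transition taxonomy matches the 16-row hand-written oracle", {
  oracle <- taxonomy_oracle()
  got <- label_transition(oracle$start, oracle$end)
  expect_identical(got$beneficial, oracle$beneficial)
  expect_identical(got$resolution, oracle$resolution)
  expect_identical(got$harmful, oracle$harmful)
  # partition properties over all 16 cells
  expect_false(any(got$beneficial & got$harmful))
  expect_true(all(!got$resolution | got$beneficial))   # resolution => beneficial
  neutral <- !got$beneficial & !got$harmful
  expect_identical(paste(oracle$start[neutral], oracle$end[neutral]),
                   c("gold1 gold1", "unclassified unclassified"))
})

test_that("transition matrix counts and row-normalisation are exact", {
  v <- make_classified_visits(rep("s", 2), c(0, 1.5), c("normal", "gold1"))
  m1 <- estimate_transition_matrix(build_units(v))
  expect_equal(unname(m1$probabilities["normal", ]), c(0, 1, 0, 0))
  expect_true(all(is.na(m1$probabilities["gold1", ])))  # empty row: NA not 0

  # hand count: units N->N, N->N, N->U, U->N
  v2 <- make_classified_visits(
    rep(c("a", "b", "c", "d"), each = 2), rep(c(0, 1.5), 4),
    c("normal", "normal", "normal", "normal", "normal", "unclassified",
      "unclassified", "normal"))
  m2 <- estimate_transition_matrix(build_units(v2))
  expect_equal(unname(m2$probabilities["normal", ]), c(2 / 3, 0, 1 / 3, 0))
  expect_equal(unname(m2$probabilities["unclassified", ]), c(1, 0, 0, 0))
  rows <- m2$row_totals > 0
  expect_equal(unname(rowSums(m2$probabilities)[rows]), rep(1, sum(rows)),
               tolerance = 1e-12)
  expect_error(estimate_transition_matrix(NULL), "no observation units")
})

test_that("summaries equal an independent per-unit recount", {
  # 20-unit fixture with a known label mix
  states <- spiro_states()
  set.seed(7)
  se <- data.frame(start = sample(states, 20, TRUE),
                   end = sample(states, 20, TRUE))
  v <- make_classified_visits(rep(sprintf("u%02d", 1:20), each = 2),
                              rep(c(0, 1.5), 20),
                              as.vector(rbind(se$start, se$end)))
  u <- build_units(v)
  s <- summarize_transitions(u)
  # brute-force recount straight from the fixture
  for (st in states) {
    i <- se$start == st
    lab <- label_transition(se$start[i], se$end[i])
    expect_equal(s$n[s$state == st], sum(i))
    expect_equal(s$p_beneficial[s$state == st],
                 if (sum(i)) mean(lab$beneficial) else NA_real_)
    if (st != "normal") {
      expect_equal(s$p_resolution[s$state == st],
                   if (sum(i)) mean(lab$resolution) else NA_real_)
    }
  }
  expect_true(is.na(s$p_resolution[s$state == "normal"]))  # NA by definition

  # trivial case: every unit unclassified -> normal
  v4 <- make_classified_visits(rep(sprintf("x%d", 1:4), each = 2),
                               rep(c(0, 1.5), 4),
                               rep(c("unclassified", "normal"), 4))
  s4 <- summarize_transitions(build_units(v4))
  expect_equal(s4$p_beneficial[s4$state == "unclassified"], 1)
  expect_equal(s4$p_resolution[s4$state == "unclassified"], 1)
})

test_that("subject-level 'ever' summary differs from pooled units as expected", {
  # subject s starts in U twice (one resolution), subject t once (none):
  # pooled P(res|U) = 1/3 over units, "ever" = 1/2 over subjects
  v <- make_classified_visits(rep("s", 4), c(0, 1.5, 3, 4.5),
                              c("unclassified", "normal", "unclassified",
                                "gold2plus"))
  v2 <- make_classified_visits(rep("t", 2), c(0, 1.5),
                               c("unclassified", "gold2plus"))
  u <- build_units(rbind(v, v2))
  pooled <- summarize_transitions(u, any_time = "unit")
  ever <- summarize_transitions(u, any_time = "subject")
  expect_equal(pooled$p_resolution[pooled$state == "unclassified"], 1 / 3)
  expect_equal(ever$p_resolution[ever$state == "unclassified"], 1 / 2)
  expect_equal(ever$n[ever$state == "unclassified"], 2)  # subjects, not units
})

test_that("group comparison is null-calibrated and powered", {
  set.seed(31)
  mk_units <- function(n_per_group, p_norm, p_abn) {
    mk <- function(prefix, n, p, bg) {
      data.frame(subject_id = paste0(prefix, seq_len(n)),
                 start_state = "gold1",
                 beneficial = runif(n) < p, resolution = FALSE,
                 baseline_group = bg, stringsAsFactors = FALSE)
    }
    rbind(mk("n", n_per_group, p_norm, "normal_at_baseline"),
          mk("a", n_per_group, p_abn, "abnormal_at_baseline"))
  }
  null_res <- compare_baseline_groups(mk_units(400, 0.5, 0.5))
  expect_lt(abs(null_res$estimate), 0.5)
  strong <- compare_baseline_groups(mk_units(500, 0.8, 0.2))
  expect_lt(strong$p_value, 0.001)
  expect_error(
    compare_baseline_groups(
      mk_units(10, .5, .5)[1:10, ]), "both baseline groups")
})

test_that("duplicating all units leaves estimate and robust SE stable", {
  set.seed(32)
  u <- data.frame(subject_id = rep(sprintf("s%03d", 1:150), each = 3),
                  start_state = "gold1",
                  baseline_group = rep(c("normal_at_baseline",
                                         "abnormal_at_baseline"), 225),
                  resolution = FALSE, stringsAsFactors = FALSE)
  u$beneficial <- runif(nrow(u)) <
    ifelse(u$baseline_group == "normal_at_baseline", 0.6, 0.4)
  one <- compare_baseline_groups(u)
  two <- compare_baseline_groups(rbind(u, u))
  expect_equal(two$estimate, one$estimate, tolerance = 1e-8)
  # same clusters twice: the cluster-robust SE must not shrink ~1/sqrt(2)
  expect_gt(two$robust_se / one$robust_se, 0.9)
  expect_lt(two$robust_se / one$robust_se, 1.1)
})

test_that("dropout sensitivity filters subjects and compares covariates", {
  # 120 retained subjects (4 visits) + 120 dropouts (2 visits), dropouts
  # 10 years younger by construction
  mk <- function(prefix, n_vis, age) {
    ids <- sprintf("%s%02d", prefix, 1:120)
    make_classified_visits(rep(ids, each = n_vis),
                           rep(1.5 * (seq_len(n_vis) - 1), 120),
                           "normal", age = age)
  }
  v <- rbind(mk("r", 4, 58), mk("d", 2, 48))
  set.seed(33)
  v$age <- v$age + rnorm(nrow(v), 0, 2)
  sens <- sensitivity_exclude_dropouts(v, min_visits = 3)
  expect_equal(sens$n_retained, 120)
  expect_equal(sens$n_excluded, 120)
  cmp <- sens$dropout_comparison
  age_row <- cmp[cmp$covariate == "age", ]
  expect_lt(age_row$p_value, 0.05)
  expect_gt(age_row$retained - age_row$excluded, 5)

  # no-op filter: all subjects have 4 visits
  v_all <- mk("r", 4, 58)
  sens2 <- sensitivity_exclude_dropouts(v_all, min_visits = 2)
  expect_equal(sens2$n_excluded, 0)
  full <- summarize_transitions(build_units(v_all))
  expect_equal(sens2$summary, full)
  expect_error(sensitivity_exclude_dropouts(v_all, min_visits = 9),
               "removes every subject")
})
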