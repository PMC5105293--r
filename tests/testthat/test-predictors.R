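# synthetic unit tables with a known logistic data-generating model
make_or_units <- function(n_subjects = 400, units_per_subject = 3,
                          beta = c(intercept = 0, hispanic = 0),
                          p_x = 0.3, seed = 1) {
  set.seed(seed)
  id <- rep(sprintf("s%04d", seq_len(n_subjects)), each = units_per_subject)
  x <- rep(runif(n_subjects) < p_x, each = units_per_subject)
  eta <- beta[["intercept"]] + beta[["hispanic"]] * x
  y <- runif(length(id)) < plogis(eta)
  data.frame(subject_id = id, start_state = "gold1", hispanic = x,
             beneficial = y, stringsAsFactors = FALSE)
}

test_that("a known odds ratio is recovered and reference swap inverts it", {
  u <- make_or_units(n_subjects = 1200,
                     beta = c(intercept = -0.5, hispanic = log(2)), seed = 4)
  tab <- fit_or_model(u, "hispanic", multivariable = FALSE)
  expect_gt(tab$or, 1.5); expect_lt(tab$or, 2.7)
  expect_true(tab$ci_low < tab$or & tab$or < tab$ci_high)
  # swapping the reference level gives exactly the reciprocal
  u$not_hispanic <- !u$hispanic
  tab2 <- fit_or_model(u, "not_hispanic", multivariable = FALSE)
  expect_equal(tab2$or, 1 / tab$or, tolerance = 1e-8)
})

test_that("null predictors give approximately nominal CI coverage", {
  covered <- p_small <- logical(40)
  for (r in seq_len(40)) {
    u <- make_or_units(n_subjects = 250, seed = 100 + r)
    tab <- fit_or_model(u, "hispanic", multivariable = FALSE)
    covered[r] <- tab$ci_low <= 1 && 1 <= tab$ci_high
    p_small[r] <- tab$p_value < 0.05
  }
  expect_gte(mean(covered), 0.85)   # 95% nominal, binomial noise at 40 reps
  expect_lte(mean(p_small), 0.20)
})

test_that("cluster-robust SEs exceed naive SEs under within-subject correlation", {
  set.seed(9)
  n_sub <- 300
  id <- rep(sprintf("s%03d", 1:n_sub), each = 4)
  x <- rep(runif(n_sub) < 0.4, each = 4)
  re <- rep(rnorm(n_sub, 0, 1.5), each = 4)       # strong shared effect
  y <- runif(length(id)) < plogis(-0.3 + re)
  u <- data.frame(subject_id = id, start_state = "gold1", hispanic = x,
                  beneficial = y)
  tab <- fit_or_model(u, "hispanic", multivariable = FALSE)
  fit <- glm(beneficial ~ hispanic, binomial(), data = u)
  naive_se <- sqrt(vcov(fit)["hispanicTRUE", "hispanicTRUE"])
  robust_se <- (log(tab$ci_high) - log(tab$or)) / qnorm(0.975)
  expect_gt(robust_se, naive_se)
})

test_that("constant predictors are dropped and separation is flagged", {
  u <- make_or_units(n_subjects = 200, seed = 5)
  u$always <- TRUE
  expect_warning(tab <- fit_or_model(u, c("hispanic", "always"),
                                     multivariable = TRUE), "constant")
  expect_identical(tab$predictor, "hispanic")
  # perfectly separating predictor: flagged, not a crash
  u$sep <- u$beneficial
  expect_warning(tab2 <- fit_or_model(u, c("hispanic", "sep"),
                                      multivariable = TRUE), "separation")
  expect_true(tab2$separation[tab2$predictor == "sep"])
  expect_error(fit_or_model(u[u$beneficial, ], "hispanic"), "single class")
})

test_that("exchangeable working correlation agrees with glm when clusters are independent", {
  u <- make_or_units(n_subjects = 500, units_per_subject = 1,
                     beta = c(intercept = -0.4, hispanic = log(1.8)),
                     seed = 6)
  ind <- fit_or_model(u, "hispanic", correlation = "independence")
  exch <- fit_or_model(u, "hispanic", correlation = "exchangeable")
  # single-unit clusters: alpha is inestimable/zero, estimates must coincide
  expect_equal(exch$or, ind$or, tolerance = 1e-6)
  # with repeated units the two stay close under weak correlation
  u2 <- make_or_units(n_subjects = 400, units_per_subject = 3,
                      beta = c(intercept = -0.4, hispanic = log(1.8)),
                      seed = 7)
  ind2 <- fit_or_model(u2, "hispanic", correlation = "independence")
  exch2 <- fit_or_model(u2, "hispanic", correlation = "exchangeable")
  expect_equal(log(exch2$or), log(ind2$or), tolerance = 0.05)
})

test_that("interaction test flags inestimable designs and detects real ones", {
  u <- make_or_units(n_subjects = 300, seed = 8)     # single start state
  res <- test_interaction(u, "hispanic")
  expect_false(res$estimable)

  # strong effect confined to the unclassified state
  set.seed(41)
  n_sub <- 2000
  id <- sprintf("s%04d", 1:n_sub)
  st <- sample(spiro_states(), n_sub, TRUE)
  x <- runif(n_sub) < 0.4
  eta <- -0.5 + 2.0 * x * (st == "unclassified")
  u2 <- data.frame(subject_id = id, start_state = st, hispanic = x,
                   beneficial = runif(n_sub) < plogis(eta))
  res2 <- test_interaction(u2, "hispanic")
  expect_true(res2$estimable)
  expect_lt(res2$p_value, 0.01)

  # no interaction: same model, uniform effect
  eta3 <- -0.5 + 0.5 * x
  u3 <- u2; u3$beneficial <- runif(n_sub) < plogis(eta3)
  res3 <- test_interaction(u3, "hispanic")
  expect_gt(res3$p_value, 0.001)
})

test_that("time-varying smoking handles null, effect, and constant cases", {
  mk <- function(beta_smoke, seed) {
    set.seed(seed)
    n_sub <- 800
    id <- rep(sprintf("s%04d", 1:n_sub), each = 3)
    sm <- runif(length(id)) < 0.5
    y <- runif(length(id)) < plogis(-0.3 + beta_smoke * sm)
    data.frame(subject_id = id, start_state = "gold1", current_smoker = sm,
               beneficial = y)
  }
  null_case <- evaluate_time_varying_smoking(mk(0, 51))
  expect_true(null_case$estimable)
  expect_gt(null_case$p_value, 0.001)
  eff_case <- evaluate_time_varying_smoking(mk(log(0.5), 52))
  expect_lt(eff_case$p_value, 0.01)
  expect_lt(eff_case$or, 1)

  u_const <- mk(0, 53); u_const$current_smoker <- TRUE
  expect_false(evaluate_time_varying_smoking(u_const)$estimable)

  # a time-constant smoking column equals treating it as baseline covariate
  u <- mk(0, 54)
  u$current_smoker <- rep(u$current_smoker[seq(1, nrow(u), 3)], each = 3)
  res_tv <- evaluate_time_varying_smoking(u)
  tab <- fit_or_model(u, "current_smoker", multivariable = TRUE)
  expect_equal(res_tv$or, tab$or, tolerance = 1e-10)
})
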