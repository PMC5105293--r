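# Synthetic longitudinal cohort generator.
#
# Two modes:
#  * latent  -- each subject carries a true lung-function trajectory,
#    parameterised in (FEV1 percent-predicted, FEV1/FVC ratio) space, observed
#    with multiplicative log-normal measurement noise.  Truth in this space
#    makes "zero decline + zero noise => constant state" exact, because the
#    reference prediction itself changes with age between visits.
#  * markov  -- states evolve as a discrete Markov chain with a known
#    row-stochastic matrix Q; spirometry values are emitted at the centroid of
#    each state's decision region so classification recovers the chain exactly.
#
# All randomness flows from one integer seed; each subject gets an
# independent sub-stream (a per-subject seed drawn up-front from the master
# stream), so enlarging the cohort never perturbs existing subjects.

#' Cohort-level configuration for the synthetic generator
#'
#' Defaults emulate the studied cohort of heavy smokers: ~80 % women, ages
#' 40-75 (mean ~56), >= 20 pack-years, visits every 1.5 years with a mean of
#' about four visits per subject (range 2-6) over ~5 years of follow-up, and
#' a baseline state mix of 956:145:191:261
#' (normal : gold1 : unclassified : gold2plus).
#'
#' @param n_subjects number of subjects.
#' @param pct_female fraction of women (default 0.80).
#' @param age_mean,age_sd,age_range baseline-age distribution (truncated
#'   normal, defaults 56 +/- 9 in \[40, 75\]).
#' @param baseline_state_mix length-4 nonnegative weights over
#'   [spiro_states()]; normalised to sum to 1.
#' @param visit_spacing_years nominal inter-visit interval (1.5).
#' @param spacing_jitter_sd SD of Gaussian jitter on visit times (years).
#' @param max_visits maximum scheduled visits (default 6).
#' @param dropout_hazard per-visit probability of dropping out after the
#'   second visit (default 0.25, giving a mean of ~4 visits in 2-6).
#' @param dropout_covariate_dependent if `TRUE`, younger, current-smoking
#'   and lower-lung-function subjects are more likely to drop out.
#' @param pct_hispanic,pct_hypertension,pct_asthma,pct_current_smoker
#'   covariate marginals.
#' @param pack_years_min minimum pack-years (eligibility floor, 20).
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 1553,
                          pct_female = 0.80,
                          age_mean = 56, age_sd = 9, age_range = c(40, 75),
                          baseline_state_mix = c(956, 145, 191, 261),
                          visit_spacing_years = 1.5,
                          spacing_jitter_sd = 0.08,
                          max_visits = 6,
                          dropout_hazard = 0.25,
                          dropout_covariate_dependent = FALSE,
                          pct_hispanic = 0.175,
                          pct_hypertension = 0.33,
                          pct_asthma = 0.18,
                          pct_current_smoker = 0.55,
                          pack_years_min = 20) {
  stopifnot(n_subjects >= 1, length(baseline_state_mix) == 4,
            all(baseline_state_mix >= 0), sum(baseline_state_mix) > 0,
            max_visits >= 2)
  fr <- c(pct_female, pct_hispanic, pct_hypertension, pct_asthma,
          pct_current_smoker, dropout_hazard)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]", call. = FALSE)
  structure(list(
    n_subjects = as.integer(n_subjects), pct_female = pct_female,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    baseline_state_mix = baseline_state_mix / sum(baseline_state_mix),
    visit_spacing_years = visit_spacing_years,
    spacing_jitter_sd = spacing_jitter_sd,
    max_visits = as.integer(max_visits),
    dropout_hazard = dropout_hazard,
    dropout_covariate_dependent = dropout_covariate_dependent,
    pct_hispanic = pct_hispanic, pct_hypertension = pct_hypertension,
    pct_asthma = pct_asthma, pct_current_smoker = pct_current_smoker,
    pack_years_min = pack_years_min), class = "cohort_config")
}

#' Latent-trajectory parameters for the synthetic generator
#'
#' State-conditional baseline distributions follow the cohort's baseline
#' tables: FEV1 percent predicted 97.4 +/- 10.6 / 91.0 +/- 8.9 /
#' 72.0 +/- 8.5 / 61.2 +/- 14.7 and FEV1/FVC ratio (percent)
#' 78.7 +/- 4.5 / 65.4 +/- 3.4 / 76.4 +/- 4.4 / 56.4 +/- 10.1 for
#' normal / gold1 / unclassified / gold2plus, truncated to each state's
#' decision region.  Decline and noise magnitudes are generator choices:
#' a mean FEV1 decline of 30 +/- 15 mL/year (subject random slope), a slow
#' ratio decline, and 4 % multiplicative within-session noise.
#'
#' @param pctpred_mean,pctpred_sd per-state FEV1 %pred baseline mean/SD.
#' @param ratio_mean,ratio_sd per-state FEV1/FVC (percent) baseline mean/SD.
#' @param annual_decline_mean,annual_decline_sd true FEV1 decline in mL/year
#'   (converted per subject to %pred points/year at their predicted FEV1).
#' @param ratio_decline_mean,ratio_decline_sd true ratio decline in
#'   percentage points/year.
#' @param measurement_cv within-session multiplicative noise SD as a
#'   fraction of the true value, in \[0, 0.2\].
#' @param noise_correlation correlation of the FEV1 and FVC measurement
#'   errors within a session (default 0.7; ratio-threshold flips depend on
#'   it).
#' @param reversibility_shape,reversibility_scale gamma parameters of the
#'   per-subject bronchodilator response fraction (mean ~4 %, so ~5 % of
#'   subjects exceed the 12 %/200 mL significance rule).
#' @param sgrq_mean,sgrq_sd per-state SGRQ total score mean/SD (Gaussian,
#'   truncated to \[0, 100\]; reporting only).
#' @param predictor_effects named list of true odds ratios injected via
#'   [inject_predictor_effect()].
#' @return List of class `trajectory_params`.
#' @export
trajectory_params <- function(pctpred_mean = c(97.4, 91.0, 72.0, 61.2),
                              pctpred_sd = c(10.6, 8.9, 8.5, 14.7),
                              ratio_mean = c(78.7, 65.4, 76.4, 56.4),
                              ratio_sd = c(4.5, 3.4, 4.4, 10.1),
                              annual_decline_mean = 30,
                              annual_decline_sd = 15,
                              ratio_decline_mean = 0.20,
                              ratio_decline_sd = 0.15,
                              measurement_cv = 0.04,
                              noise_correlation = 0.7,
                              reversibility_shape = 1.2,
                              reversibility_scale = 1 / 30,
                              sgrq_mean = c(17.0, 17.9, 25.6, 31.6),
                              sgrq_sd = c(15.2, 13.9, 19.2, 19.8),
                              predictor_effects = list()) {
  stopifnot(length(pctpred_mean) == 4, length(ratio_mean) == 4,
            all(pctpred_sd >= 0), all(ratio_sd >= 0),
            annual_decline_sd >= 0, ratio_decline_sd >= 0)
  if (measurement_cv < 0 || measurement_cv > 0.2) {
    stop("measurement_cv must lie in [0, 0.2]", call. = FALSE)
  }
  if (noise_correlation < -1 || noise_correlation > 1) {
    stop("noise_correlation must lie in [-1, 1]", call. = FALSE)
  }
  structure(list(
    pctpred_mean = pctpred_mean, pctpred_sd = pctpred_sd,
    ratio_mean = ratio_mean, ratio_sd = ratio_sd,
    annual_decline_mean = annual_decline_mean,
    annual_decline_sd = annual_decline_sd,
    ratio_decline_mean = ratio_decline_mean,
    ratio_decline_sd = ratio_decline_sd,
    measurement_cv = measurement_cv,
    noise_correlation = noise_correlation,
    reversibility_shape = reversibility_shape,
    reversibility_scale = reversibility_scale,
    sgrq_mean = sgrq_mean, sgrq_sd = sgrq_sd,
    predictor_effects = predictor_effects), class = "trajectory_params")
}

#' Inject a known predictor effect into the generator
#'
#' Records a true odds ratio for one predictor.  In Markov mode the
#' per-unit odds of a beneficial transition are shifted by `log(true_or)`
#' for units where the predictor is true (an exact logistic effect, so the
#' predictor models can recover it without bias); in latent mode the true
#' FEV1 decline slope is shifted by `-20 * log(true_or)` mL/year.
#'
#' @param params `trajectory_params` object (or a bare list of effects).
#' @param predictor one of `hispanic`, `male`, `age_ge_60`, `bmi_ge_25`,
#'   `hypertension`, `asthma_plus_reversibility`, `current_smoker`.
#' @param true_or true odds ratio (> 0).
#' @return `params` with the effect recorded in `predictor_effects`.
#' @export
inject_predictor_effect <- function(params, predictor, true_or) {
  supported <- c("hispanic", "male", "age_ge_60", "bmi_ge_25",
                 "hypertension", "asthma_plus_reversibility",
                 "current_smoker")
  if (!predictor %in% supported) {
    stop("unknown predictor '", predictor, "'; supported: ",
         paste(supported, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(true_or) || true_or <= 0) {
    stop("true_or must be > 0", call. = FALSE)
  }
  params$predictor_effects[[predictor]] <- true_or
  params
}

# inverse-CDF truncated normal; errors when the region carries ~no mass
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) {
    if (mean < lo || mean > hi) {
      stop("degenerate truncation: mean ", mean, " outside [", lo, ", ", hi,
           "]", call. = FALSE)
    }
    return(rep(mean, n))
  }
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  if (phi - plo < 1e-10) {
    stop("infeasible truncation: N(", mean, ", ", sd, ") has no mass in [",
         lo, ", ", hi, "]", call. = FALSE)
  }
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

# per-state truncation regions in (%pred, ratio-percent) space
.pctpred_bounds <- function(state_idx) {
  rbind(c(80, 135), c(80, 135), c(30, 80), c(20, 80))[state_idx, , drop = FALSE]
}
.ratio_bounds <- function(state_idx) {
  rbind(c(70, 92), c(45, 70), c(70, 92), c(28, 70))[state_idx, , drop = FALSE]
}

# follow-up visits can pass age 80; the generator extrapolates knowingly,
# so the reference-equation extrapolation warning is muffled here (the
# classification pipeline still reports it on real inputs)
.quiet_extrapolation <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("extrapolating", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

.subject_seeds <- function(seed, n) {
  if (missing(seed) || is.null(seed) || !is.numeric(seed)) {
    stop("an explicit integer seed is required for reproducibility",
         call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# subject-level covariates shared by both modes; called inside the
# subject's RNG stream, draws in a fixed documented order
.draw_subject <- function(cfg) {
  sex <- if (runif(1) < cfg$pct_female) "female" else "male"
  age0 <- .rtruncnorm(1, cfg$age_mean, cfg$age_sd,
                      cfg$age_range[1], cfg$age_range[2])
  height <- if (sex == "female") .rtruncnorm(1, 162, 6, 142, 185) else
    .rtruncnorm(1, 176, 7, 155, 200)
  bmi <- .rtruncnorm(1, 28, 6, 16, 55)
  ethnicity <- if (runif(1) < cfg$pct_hispanic) "hispanic" else
    "non_hispanic_white"
  hypertension <- runif(1) < cfg$pct_hypertension
  asthma <- runif(1) < cfg$pct_asthma
  smoker0 <- runif(1) < cfg$pct_current_smoker
  pack_years <- cfg$pack_years_min + rgamma(1, shape = 2, scale = 9)
  state0 <- sample.int(4L, 1L, prob = cfg$baseline_state_mix)
  list(sex = sex, age0 = age0, height = height, bmi = bmi,
       ethnicity = ethnicity, hypertension = hypertension, asthma = asthma,
       smoker0 = smoker0, pack_years = pack_years, state0 = state0)
}

# number of attended visits: first two guaranteed (eligibility), then a
# per-visit continuation draw; returns attended count in 2..max_visits
.draw_n_visits <- function(cfg, subj, pctpred0) {
  h <- cfg$dropout_hazard
  if (cfg$dropout_covariate_dependent) {
    lo <- qlogis(min(max(h, 1e-6), 1 - 1e-6))
    lo <- lo + 0.02 * (cfg$age_mean - subj$age0) +      # younger drop out more
      0.4 * subj$smoker0 + 0.01 * (90 - pctpred0)
    h <- plogis(lo)
  }
  u <- runif(cfg$max_visits - 2L)
  n <- 2L
  for (k in seq_along(u)) {
    if (u[k] < h) break
    n <- n + 1L
  }
  n
}

# smoking path: per-visit quit/relapse process starting from smoker0
.smoking_path <- function(smoker0, n, p_quit = 0.08, p_relapse = 0.04) {
  s <- logical(n)
  s[1] <- smoker0
  if (n > 1) {
    u <- runif(n - 1)
    for (k in 2:n) {
      s[k] <- if (s[k - 1]) u[k - 1] >= p_quit else u[k - 1] < p_relapse
    }
  }
  s
}

#' Simulate a latent-trajectory longitudinal cohort
#'
#' Each subject receives a baseline state from the configured mix, a true
#' baseline (FEV1 %pred, FEV1/FVC) pair drawn from that state's truncated
#' state-conditional distribution, and subject-specific linear decline
#' slopes.  Visits at ~18-month intervals emit measured post-bronchodilator
#' FEV1/FVC = truth x correlated log-normal noise, pre-bronchodilator values
#' via a per-subject bronchodilator response fraction, and an SGRQ score.
#' A hidden-truth table (noise-free values and true states per visit) is
#' returned for validation.
#'
#' @param config [cohort_config()].
#' @param params [trajectory_params()].
#' @param seed integer seed (required).
#' @return List of class `spiro_cohort`: `visits` (pipeline input format),
#'   `truth` (hidden truth per visit), `config`, `params`, `seed`,
#'   `mode = "latent"`.
#' @export
simulate_latent_cohort <- function(config = cohort_config(),
                                   params = trajectory_params(),
                                   seed) {
  seeds <- .subject_seeds(seed, config$n_subjects)
  cv <- params$measurement_cv
  sdlog <- sqrt(log(1 + cv^2))
  rho <- params$noise_correlation
  eff <- params$predictor_effects

  acc <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    set.seed(seeds[i])
    subj <- .draw_subject(config)
    pb <- .pctpred_bounds(subj$state0); rb <- .ratio_bounds(subj$state0)
    pctpred0 <- .rtruncnorm(1, params$pctpred_mean[subj$state0],
                            params$pctpred_sd[subj$state0], pb[1], pb[2])
    ratio0 <- .rtruncnorm(1, params$ratio_mean[subj$state0],
                          params$ratio_sd[subj$state0], rb[1], rb[2])
    decline_ml <- rnorm(1, params$annual_decline_mean,
                        params$annual_decline_sd)
    ratio_slope <- rnorm(1, params$ratio_decline_mean,
                         params$ratio_decline_sd)
    rev_frac <- rgamma(1, shape = params$reversibility_shape,
                       scale = params$reversibility_scale)
    n_vis <- .draw_n_visits(config, subj, pctpred0)
    mx <- config$max_visits
    jit <- c(0, rnorm(mx - 1, 0, config$spacing_jitter_sd))[seq_len(n_vis)]
    e1 <- rnorm(mx); e2raw <- rnorm(mx)
    smoke <- .smoking_path(subj$smoker0, n_vis)
    sg_e <- rnorm(mx)

    # injected effects shift the true decline slope
    xval <- c(hispanic = subj$ethnicity == "hispanic",
              male = subj$sex == "male",
              age_ge_60 = subj$age0 >= 60,
              bmi_ge_25 = subj$bmi >= 25,
              hypertension = subj$hypertension,
              asthma_plus_reversibility = subj$asthma && rev_frac >= 0.12,
              current_smoker = subj$smoker0)
    for (p in names(eff)) {
      if (isTRUE(unname(xval[p]))) decline_ml <- decline_ml - 20 * log(eff[[p]])
    }

    t <- config$visit_spacing_years * (seq_len(n_vis) - 1) + jit
    t[1] <- 0
    e1 <- e1[seq_len(n_vis)]
    e2 <- rho * e1 + sqrt(1 - rho^2) * e2raw[seq_len(n_vis)]

    acc[[i]] <- list(
      id = sprintf("S%05d", i), n = n_vis, t = t, sex = subj$sex,
      age0 = subj$age0, height = subj$height, bmi = subj$bmi,
      ethnicity = subj$ethnicity, hypertension = subj$hypertension,
      asthma = subj$asthma, pack_years = subj$pack_years, smoke = smoke,
      state0 = subj$state0, pctpred0 = pctpred0, ratio0 = ratio0,
      decline_ml = decline_ml, ratio_slope = ratio_slope,
      rev_frac = rev_frac, e1 = e1, e2 = e2,
      sg_e = sg_e[seq_len(n_vis)])
  }

  n_vis <- vapply(acc, `[[`, integer(1), "n")
  id <- rep(vapply(acc, `[[`, character(1), "id"), n_vis)
  t <- unlist(lapply(acc, `[[`, "t"))
  visit <- unlist(lapply(n_vis, seq_len))
  sex <- rep(vapply(acc, `[[`, character(1), "sex"), n_vis)
  age <- rep(vapply(acc, `[[`, numeric(1), "age0"), n_vis) + t
  height <- rep(vapply(acc, `[[`, numeric(1), "height"), n_vis)
  bmi <- rep(vapply(acc, `[[`, numeric(1), "bmi"), n_vis)
  ethnicity <- rep(vapply(acc, `[[`, character(1), "ethnicity"), n_vis)
  hypertension <- rep(vapply(acc, `[[`, logical(1), "hypertension"), n_vis)
  asthma <- rep(vapply(acc, `[[`, logical(1), "asthma"), n_vis)
  pack_years <- rep(vapply(acc, `[[`, numeric(1), "pack_years"), n_vis)
  smoke <- unlist(lapply(acc, `[[`, "smoke"))
  pctpred0 <- rep(vapply(acc, `[[`, numeric(1), "pctpred0"), n_vis)
  ratio0 <- rep(vapply(acc, `[[`, numeric(1), "ratio0"), n_vis)
  decline_ml <- rep(vapply(acc, `[[`, numeric(1), "decline_ml"), n_vis)
  ratio_slope <- rep(vapply(acc, `[[`, numeric(1), "ratio_slope"), n_vis)
  rev_frac <- rep(vapply(acc, `[[`, numeric(1), "rev_frac"), n_vis)
  e1 <- unlist(lapply(acc, `[[`, "e1"))
  e2 <- unlist(lapply(acc, `[[`, "e2"))
  sg_e <- unlist(lapply(acc, `[[`, "sg_e"))
  state0 <- rep(vapply(acc, `[[`, integer(1), "state0"), n_vis)

  grp <- .map_ethnicity(ethnicity, default_ethnicity_map())
  ref <- .quiet_extrapolation(predict_reference(age, height, sex, grp))

  # true trajectory in (%pred, ratio) space
  true_pp <- pmax(pctpred0 - (decline_ml / 1000) / ref$fev1_pred * 100 * t, 10)
  true_ratio <- pmin(pmax(ratio0 - ratio_slope * t, 25), 95) / 100
  true_fev1 <- true_pp / 100 * ref$fev1_pred
  true_fvc <- true_fev1 / true_ratio
  true_state <- classify_state(true_ratio, true_pp)

  mu <- -sdlog^2 / 2
  post_fev1 <- true_fev1 * exp(mu + sdlog * e1)
  post_fvc <- true_fvc * exp(mu + sdlog * e2)
  post_fev1 <- pmin(post_fev1, post_fvc)    # instrument constraint FEV1 <= FVC
  pre_fev1 <- post_fev1 / (1 + rev_frac)
  pre_fvc <- post_fvc / (1 + rev_frac)
  sgrq <- pmin(pmax(params$sgrq_mean[state0] + params$sgrq_sd[state0] * sg_e,
                    0), 100)

  rnd <- function(x, d = 4) round(x, d)
  visits <- data.frame(
    subject_id = id, visit = visit, time_years = rnd(t),
    age = rnd(age, 2), sex = sex, height_cm = rnd(height, 1),
    weight_kg = rnd(bmi * (height / 100)^2, 1), bmi = rnd(bmi, 2),
    ethnicity = ethnicity, pack_years = rnd(pack_years, 1),
    current_smoker = smoke, hypertension = hypertension, asthma = asthma,
    pre_fev1 = rnd(pre_fev1), pre_fvc = rnd(pre_fvc),
    post_fev1 = rnd(post_fev1), post_fvc = rnd(post_fvc),
    sgrq_total = rnd(sgrq, 1), stringsAsFactors = FALSE)
  truth <- data.frame(
    subject_id = id, visit = visit, time_years = rnd(t),
    true_fev1 = true_fev1, true_fvc = true_fvc, true_pct_pred = true_pp,
    true_ratio = true_ratio, true_state = true_state,
    baseline_state = spiro_state(state0 - 1L), stringsAsFactors = FALSE)

  structure(list(visits = visits, truth = truth, config = config,
                 params = params, seed = as.integer(seed), mode = "latent"),
            class = "spiro_cohort")
}

#' Simulate a discrete-Markov cohort with a known transition matrix
#'
#' States evolve by the supplied 4x4 row-stochastic matrix `Q` between
#' visits.  Emitted spirometry values sit at the centroid of each state's
#' decision region, so [classify_visits()] recovers the chain exactly; the
#' mode is the estimation oracle for [estimate_transition_matrix()].
#' Injected predictor effects ([inject_predictor_effect()]) shift the
#' per-step odds of a beneficial move on the logit scale, redistributing
#' probability proportionally inside the beneficial and non-beneficial cell
#' sets of each row -- an exact logistic effect on the unit-level beneficial
#' outcome.
#'
#' @param config [cohort_config()].
#' @param Q 4x4 row-stochastic matrix (rows/cols in [spiro_states()] order).
#' @param seed integer seed (required).
#' @param predictor_effects named list of true odds ratios (or a
#'   `trajectory_params` whose `predictor_effects` is used).
#' @param n_visits fixed number of visits per subject; default `NULL` uses
#'   the configured dropout process.
#' @return List of class `spiro_cohort` with `visits`, `truth` (chain
#'   states), `config`, `Q`, `seed`, `mode = "markov"`.
#' @export
simulate_markov_cohort <- function(config = cohort_config(), Q, seed,
                                   predictor_effects = list(),
                                   n_visits = NULL) {
  Q <- as.matrix(Q)
  if (!all(dim(Q) == c(4, 4)) || any(Q < 0) ||
      any(abs(rowSums(Q) - 1) > 1e-9)) {
    stop("Q must be 4x4, nonnegative, with rows summing to 1 (tol 1e-9)",
         call. = FALSE)
  }
  if (inherits(predictor_effects, "trajectory_params")) {
    predictor_effects <- predictor_effects$predictor_effects
  }
  ben_cells <- list(1L, 1L, c(1L, 2L), c(1L, 2L, 3L))  # beneficial to-states
  centroids_pp <- c(95, 90, 70, 60)
  centroids_ratio <- c(0.80, 0.65, 0.80, 0.60)
  seeds <- .subject_seeds(seed, config$n_subjects)

  acc <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    set.seed(seeds[i])
    subj <- .draw_subject(config)
    rev_frac <- rgamma(1, shape = 1.2, scale = 1 / 30)
    n_vis <- if (is.null(n_visits)) {
      .draw_n_visits(config, subj, 90)
    } else as.integer(n_visits)
    smoke <- .smoking_path(subj$smoker0, n_vis)

    xval <- c(hispanic = subj$ethnicity == "hispanic",
              male = subj$sex == "male",
              age_ge_60 = subj$age0 >= 60,
              bmi_ge_25 = subj$bmi >= 25,
              hypertension = subj$hypertension,
              asthma_plus_reversibility = subj$asthma && rev_frac >= 0.12,
              current_smoker = subj$smoker0)
    delta <- 0
    for (p in names(predictor_effects)) {
      if (isTRUE(unname(xval[p]))) delta <- delta + log(predictor_effects[[p]])
    }

    states <- integer(n_vis)
    states[1] <- sample.int(4L, 1L, prob = config$baseline_state_mix)
    if (n_vis > 1) {
      for (k in 2:n_vis) {
        s <- states[k - 1]
        q <- Q[s, ]
        if (delta != 0) {
          bc <- ben_cells[[s]]
          pb <- sum(q[bc])
          if (pb > 0 && pb < 1) {
            pb2 <- plogis(qlogis(pb) + delta)
            q[bc] <- q[bc] * pb2 / pb
            q[-bc] <- q[-bc] * (1 - pb2) / (1 - pb)
          }
        }
        states[k] <- sample.int(4L, 1L, prob = q)
      }
    }
    acc[[i]] <- list(id = sprintf("S%05d", i), n = n_vis, states = states,
                     subj = subj, rev_frac = rev_frac, smoke = smoke)
  }

  n_vis <- vapply(acc, `[[`, integer(1), "n")
  id <- rep(vapply(acc, `[[`, character(1), "id"), n_vis)
  states <- unlist(lapply(acc, `[[`, "states"))
  visit <- unlist(lapply(n_vis, seq_len))
  t <- config$visit_spacing_years * (visit - 1)
  getf <- function(f, fv) rep(vapply(acc, function(a) a$subj[[f]], fv), n_vis)
  sex <- getf("sex", character(1))
  age <- getf("age0", numeric(1)) + t
  height <- getf("height", numeric(1))
  bmi <- getf("bmi", numeric(1))
  ethnicity <- getf("ethnicity", character(1))
  hypertension <- getf("hypertension", logical(1))
  asthma <- getf("asthma", logical(1))
  pack_years <- getf("pack_years", numeric(1))
  rev_frac <- rep(vapply(acc, `[[`, numeric(1), "rev_frac"), n_vis)
  smoke <- unlist(lapply(acc, `[[`, "smoke"))

  grp <- .map_ethnicity(ethnicity, default_ethnicity_map())
  ref <- .quiet_extrapolation(predict_reference(age, height, sex, grp))
  post_fev1 <- centroids_pp[states] / 100 * ref$fev1_pred
  post_fvc <- post_fev1 / centroids_ratio[states]
  pre_fev1 <- post_fev1 / (1 + rev_frac)
  pre_fvc <- post_fvc / (1 + rev_frac)

  visits <- data.frame(
    subject_id = id, visit = visit, time_years = t, age = round(age, 2),
    sex = sex, height_cm = round(height, 1), bmi = round(bmi, 2),
    weight_kg = round(bmi * (height / 100)^2, 1), ethnicity = ethnicity,
    pack_years = round(pack_years, 1), current_smoker = smoke,
    hypertension = hypertension, asthma = asthma,
    pre_fev1 = pre_fev1, pre_fvc = pre_fvc,
    post_fev1 = post_fev1, post_fvc = post_fvc, stringsAsFactors = FALSE)
  truth <- data.frame(subject_id = id, visit = visit, time_years = t,
                      true_state = spiro_state(states - 1L),
                      stringsAsFactors = FALSE)
  structure(list(visits = visits, truth = truth, config = config, Q = Q,
                 predictor_effects = predictor_effects,
                 seed = as.integer(seed), mode = "markov"),
            class = "spiro_cohort")
}

#' @export
print.spiro_cohort <- function(x, ...) {
  cat("Synthetic cohort (", x$mode, " mode): ",
      length(unique(x$visits$subject_id)), " subjects, ",
      nrow(x$visits), " visits, seed ", x$seed, "\n", sep = "")
  invisible(x)
}
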