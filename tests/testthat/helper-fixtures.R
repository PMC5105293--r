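# shared fixtures, built in code

# a minimal classified visit table: one row per (subject, time, state);
# demographics filled with constants so build_units has a covariate snapshot
make_classified_visits <- function(subject_id, time_years, state,
                                   age = 55, sex = "female") {
  n <- length(subject_id)
  data.frame(subject_id = subject_id, time_years = time_years,
             state = spiro_state(state), age = rep_len(age, n),
             sex = rep_len(sex, n), stringsAsFactors = FALSE)
}

# transition matrix with equal beneficial mass (0.4) in every row, so the
# per-unit beneficial outcome is Bernoulli(0.4) regardless of start state --
# the null configuration for calibration checks
null_beneficial_q <- function() {
  rbind(c(0.40, 0.30, 0.20, 0.10),
        c(0.40, 0.35, 0.15, 0.10),
        c(0.25, 0.15, 0.45, 0.15),
        c(0.15, 0.10, 0.15, 0.60))
}

# trajectory parameters with all true decline switched off
zero_decline_params <- function(cv = 0.04) {
  p <- trajectory_params(annual_decline_mean = 0, annual_decline_sd = 0,
                         ratio_decline_mean = 0, ratio_decline_sd = 0)
  p$measurement_cv <- cv
  p
}

# independent brute-force staging oracle: literal 2x2 truth table over the
# printed state-definition grid (kept separate from classify_state's arithmetic)
oracle_classify <- function(ratio, pct_pred, cut = 0.70) {
  out <- character(length(ratio))
  for (i in seq_along(ratio)) {
    out[i] <- if (ratio[i] >= cut && pct_pred[i] >= 80) {
      "normal"
    } else if (ratio[i] < cut && pct_pred[i] >= 80) {
      "gold1"
    } else if (ratio[i] >= cut && pct_pred[i] < 80) {
      "unclassified"
    } else {
      "gold2plus"
    }
  }
  out
}

# hand-written 16-row transition-taxonomy oracle (start, end, beneficial,
# resolution, harmful), transcribed cell by cell from the definitions
taxonomy_oracle <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
start        end          beneficial resolution harmful
normal       normal       TRUE       FALSE      FALSE
normal       gold1        FALSE      FALSE      TRUE
normal       unclassified FALSE      FALSE      TRUE
normal       gold2plus    FALSE      FALSE      TRUE
gold1        normal       TRUE       TRUE       FALSE
gold1        gold1        FALSE      FALSE      FALSE
gold1        unclassified FALSE      FALSE      TRUE
gold1        gold2plus    FALSE      FALSE      TRUE
unclassified normal       TRUE       TRUE       FALSE
unclassified gold1        TRUE       FALSE      FALSE
unclassified unclassified FALSE      FALSE      FALSE
unclassified gold2plus    FALSE      FALSE      TRUE
gold2plus    normal       TRUE       TRUE       FALSE
gold2plus    gold1        TRUE       FALSE      FALSE
gold2plus    unclassified TRUE       FALSE      FALSE
gold2plus    gold2plus    FALSE      FALSE      TRUE
")
}
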