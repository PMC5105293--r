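# GOLD staging of single post-bronchodilator spirometry sessions.
#
# Decision grid (post-bronchodilator values; thresholds inclusive on the
# better-function side, exactly as printed in the state-definition table):
#   ratio >= 0.70, %pred >= 80  -> normal
#   ratio <  0.70, %pred >= 80  -> gold1
#   ratio >= 0.70, %pred <  80  -> unclassified
#   ratio <  0.70, %pred <  80  -> gold2plus
# Under the LLN criterion the 0.70 cut is replaced by the subject's
# NHANES-III FEV1/FVC lower limit of normal; the 80 %-predicted cut is kept.

#' Classify spirometry sessions into GOLD states
#'
#' Vectorised classification from the post-bronchodilator FEV1/FVC ratio and
#' FEV1 percent predicted.  Pre-bronchodilator values play no role here (they
#' only enter [is_reversible()]).
#'
#' @param ratio post-bronchodilator FEV1/FVC ratio (fraction in (0, 1\]).
#' @param pct_pred post-bronchodilator FEV1 percent predicted.
#' @param criterion `"fixed_ratio"` (obstruction iff ratio < 0.70) or
#'   `"lln"` (obstruction iff ratio < `ratio_lln`).
#' @param ratio_lln subject-specific FEV1/FVC lower limit of normal
#'   (fraction); required when `criterion = "lln"`.
#' @param pct_pred_cut low-FEV1 threshold in percent predicted (default 80).
#' @return Ordered factor of states (see [spiro_states()]); `NA` inputs give
#'   `NA` states.
#' @export
#' @examples
#' classify_state(c(0.75, 0.65, 0.75, 0.60), c(95, 85, 70, 55))
classify_state <- function(ratio, pct_pred,
                           criterion = c("fixed_ratio", "lln"),
                           ratio_lln = NULL, pct_pred_cut = 80) {
  criterion <- match.arg(criterion)
  n <- max(length(ratio), length(pct_pred))
  ratio <- rep_len(ratio, n); pct_pred <- rep_len(pct_pred, n)
  ok <- !is.na(ratio) & !is.na(pct_pred)
  if (any(ratio[ok] <= 0 | ratio[ok] > 1.2)) {
    stop("FEV1/FVC ratio outside (0, 1.2]; check units (expects a fraction)",
         call. = FALSE)
  }
  cut <- if (criterion == "fixed_ratio") {
    rep_len(0.70, n)
  } else {
    if (is.null(ratio_lln)) {
      stop("criterion = 'lln' requires ratio_lln", call. = FALSE)
    }
    rep_len(ratio_lln, n)
  }
  obstructed <- ratio < cut
  low_fev1 <- pct_pred < pct_pred_cut
  rank <- ifelse(obstructed, 1L, 0L) + ifelse(low_fev1, 2L, 0L)
  rank[!ok] <- NA_integer_
  spiro_state(rank)
}

#' Significant bronchodilator reversibility
#'
#' A session shows significant reversibility when FEV1 and/or FVC improves by
#' at least 12 % *and* at least 200 mL from the pre-bronchodilator value
#' (both thresholds inclusive).
#'
#' @param pre_fev1,post_fev1 pre/post-bronchodilator FEV1 (litres).
#' @param pre_fvc,post_fvc pre/post-bronchodilator FVC (litres); optional --
#'   when omitted only the FEV1 pair is assessed.
#' @param min_frac,min_litres thresholds (defaults 0.12 and 0.200 L).
#' @return Logical vector.
#' @export
#' @examples
#' is_reversible(2.00, 2.25)              # TRUE: +250 mL, +12.5 %
#' is_reversible(1.00, 1.15)              # FALSE: +15 % but only 150 mL
is_reversible <- function(pre_fev1, post_fev1, pre_fvc = NULL, post_fvc = NULL,
                          min_frac = 0.12, min_litres = 0.200) {
  qualifies <- function(pre, post) {
    if (any(!is.na(pre) & pre <= 0)) {
      stop("pre-bronchodilator value must be > 0", call. = FALSE)
    }
    d <- post - pre
    d >= min_litres & d / pre >= min_frac
  }
  out <- qualifies(pre_fev1, post_fev1)
  if (!is.null(pre_fvc) && !is.null(post_fvc)) {
    out <- out | qualifies(pre_fvc, post_fvc)
  }
  out
}

#' Bronchial hyperresponsiveness proxy
#'
#' Defined as a history of provider-diagnosed asthma together with
#' significant bronchodilator reversibility.
#'
#' @param asthma_history logical.
#' @param reversible logical, from [is_reversible()].
#' @return Logical vector (`asthma_history & reversible`).
#' @export
bronchial_hyperresponsiveness <- function(asthma_history, reversible) {
  if (anyNA(asthma_history) || anyNA(reversible)) {
    stop("asthma_history and reversible must be non-missing", call. = FALSE)
  }
  asthma_history & reversible
}

#' Classify a longitudinal visit table
#'
#' Batch interface over [predict_reference()] and [classify_state()]: computes
#' reference values at each visit's *current* age and height, appends the
#' ratio, percent predicted, state label and rank, per-session reversibility,
#' and the bronchial-hyperresponsiveness proxy.  Sessions with missing
#' post-bronchodilator values are never imputed; they get `NA` state and are
#' excluded downstream (with counts) by [build_units()].
#'
#' @param visits data.frame with columns `subject_id`, `time_years`, `age`,
#'   `sex`, `height_cm`, `ethnicity`, `post_fev1`, `post_fvc` and optionally
#'   `pre_fev1`, `pre_fvc`, `asthma`.
#' @param criterion staging criterion, see [classify_state()].
#' @param ethnicity_map named vector mapping the table's ethnicity labels to
#'   NHANES-III equation groups (default [default_ethnicity_map()]).
#' @param reversibility_at `"baseline"` (default) carries each subject's
#'   first-session reversibility to all visits; `"visit"` assesses every
#'   session separately.
#' @param coefficients reference coefficient table.
#' @return The input with columns `ratio`, `fev1_pct_pred`, `ratio_lln`,
#'   `state`, `state_rank`, `reversible`, `bhr` appended.
#' @export
classify_visits <- function(visits, criterion = c("fixed_ratio", "lln"),
                            ethnicity_map = default_ethnicity_map(),
                            reversibility_at = c("baseline", "visit"),
                            coefficients = reference_coefficients()) {
  criterion <- match.arg(criterion)
  reversibility_at <- match.arg(reversibility_at)
  needed <- c("subject_id", "time_years", "age", "sex", "height_cm",
              "ethnicity", "post_fev1", "post_fvc")
  missing_cols <- setdiff(needed, names(visits))
  if (length(missing_cols)) {
    stop("visit table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad_vol <- with(visits, !is.na(post_fev1) & !is.na(post_fvc) &
                    (post_fev1 <= 0 | post_fvc <= 0 | post_fev1 > post_fvc |
                       post_fvc >= 10))
  if (any(bad_vol)) {
    stop(sum(bad_vol), " session(s) violate 0 < FEV1 <= FVC < 10 L",
         call. = FALSE)
  }
  grp <- .map_ethnicity(visits$ethnicity, ethnicity_map)
  ref <- predict_reference(visits$age, visits$height_cm, visits$sex, grp,
                           coefficients = coefficients)
  visits$ratio <- visits$post_fev1 / visits$post_fvc
  visits$fev1_pct_pred <- 100 * visits$post_fev1 / ref$fev1_pred
  visits$ratio_lln <- ref$ratio_lln
  visits$state <- classify_state(visits$ratio, visits$fev1_pct_pred,
                                 criterion = criterion,
                                 ratio_lln = visits$ratio_lln)
  visits$state_rank <- state_rank(visits$state)

  if (all(c("pre_fev1", "pre_fvc") %in% names(visits))) {
    rev <- is_reversible(visits$pre_fev1, visits$post_fev1,
                         visits$pre_fvc, visits$post_fvc)
    if (reversibility_at == "baseline") {
      ord <- order(visits$subject_id, visits$time_years)
      first <- !duplicated(visits$subject_id[ord])
      base_rev <- setNames(rev[ord][first],
                           as.character(visits$subject_id[ord][first]))
      rev <- unname(base_rev[as.character(visits$subject_id)])
    }
    visits$reversible <- rev
    if ("asthma" %in% names(visits)) {
      visits$bhr <- as.logical(visits$asthma) & rev
    }
  }
  attr(visits, "criterion") <- criterion
  visits
}
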