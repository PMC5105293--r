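# Observation units and the multi-state Markov-like transition model.
#
# Units are formed only between *consecutive* classifiable visits whose
# spacing falls within 1.5 +/- tolerance years; gaps outside the window are
# dropped, never split or imputed.  Probabilities pool all units across
# subjects and visit indices (time-homogeneous first-order model).

#' Build 18-month observation units from a classified visit table
#'
#' @param visits output of [classify_visits()] (needs `subject_id`,
#'   `time_years`, `state`); extra columns are carried over from the unit's
#'   start visit as the covariate snapshot.  Each subject's visits must be
#'   time-ordered (unordered input is an error); exact duplicate timestamps
#'   are deduplicated with a warning.
#' @param target_years nominal inter-visit interval (default 1.5 years).
#' @param tolerance half-width of the accepted spacing window in years
#'   (default 0.5: spacing in \[1.0, 2.0\] years).
#' @return data.frame of units: `subject_id`, `unit_index` (0-based within
#'   subject), `start_state`, `end_state`, `interval_years`,
#'   `baseline_group` (`normal_at_baseline` / `abnormal_at_baseline`, from
#'   the subject's first classifiable visit), transition labels
#'   (`beneficial`, `resolution`, `harmful`) and start-visit covariates.
#'   Attribute `exclusions` counts dropped sessions/subjects/gaps.
#' @export
build_units <- function(visits, target_years = 1.5, tolerance = 0.5) {
  if (!all(c("subject_id", "time_years", "state") %in% names(visits))) {
    stop("visits must carry subject_id, time_years and state ",
         "(run classify_visits first)", call. = FALSE)
  }
  # visit times must already be nondecreasing within each subject (subjects
  # may be interleaved); a violation is an input error, not silently sorted
  g <- match(as.character(visits$subject_id),
             unique(as.character(visits$subject_id)))
  o <- order(g)                    # stable: keeps within-subject input order
  tg <- visits$time_years[o]; gg <- g[o]
  n0 <- length(gg)
  if (n0 > 1 && any(gg[-1] == gg[-n0] & diff(tg) < 0)) {
    stop("visit times are not time-ordered within subject; ",
         "sort each subject's visits by time first", call. = FALSE)
  }
  v <- visits[o, , drop = FALSE]

  # exact duplicate timestamps are dropped with a warning
  dup <- duplicated(data.frame(v$subject_id, v$time_years))
  n_dup <- sum(dup)
  if (n_dup > 0) {
    warning(n_dup, " duplicate visit timestamp(s) dropped", call. = FALSE)
    v <- v[!dup, , drop = FALSE]
  }

  all_ids <- unique(as.character(v$subject_id))
  n_subjects_in <- length(all_ids)
  n_unclassifiable <- sum(is.na(v$state))
  v <- v[!is.na(v$state), , drop = FALSE]

  id <- as.character(v$subject_id)
  cnt <- table(id)
  eligible <- names(cnt)[cnt >= 2]
  n_dropped_subjects <- n_subjects_in - length(eligible)  # < 2 classifiable
  keep <- id %in% eligible
  v <- v[keep, , drop = FALSE]
  id <- id[keep]

  if (nrow(v) == 0) {
    empty <- v[0, , drop = FALSE]
    attr(empty, "exclusions") <- list(
      subjects_in = n_subjects_in, unclassifiable_sessions = n_unclassifiable,
      duplicate_sessions = n_dup, subjects_lt2_visits = n_dropped_subjects,
      gaps_outside_window = 0L)
    return(empty)
  }

  n <- nrow(v)
  same <- id[-n] == id[-1]
  gap <- v$time_years[-1] - v$time_years[-n]
  pair_ok <- same & abs(gap - target_years) <= tolerance
  n_bad_gaps <- sum(same & !pair_ok)

  first_idx <- which(!duplicated(id))
  baseline_state <- v$state[first_idx]
  baseline_group <- ifelse(baseline_state == "normal",
                           "normal_at_baseline", "abnormal_at_baseline")
  names(baseline_group) <- id[first_idx]

  i <- which(pair_ok)               # start rows
  units <- v[i, , drop = FALSE]
  names(units)[names(units) == "state"] <- "start_state"
  units$state_rank <- NULL
  units$end_state <- v$state[i + 1L]
  units$interval_years <- gap[i]
  units$baseline_group <- unname(baseline_group[id[i]])
  units$unit_index <- unlist(lapply(rle(id[i])$lengths, seq_len)) - 1L
  lab <- label_transition(units$start_state, units$end_state)
  units$beneficial <- lab$beneficial
  units$resolution <- lab$resolution
  units$harmful <- lab$harmful
  rownames(units) <- NULL

  attr(units, "exclusions") <- list(
    subjects_in = n_subjects_in, unclassifiable_sessions = n_unclassifiable,
    duplicate_sessions = n_dup, subjects_lt2_visits = n_dropped_subjects,
    gaps_outside_window = n_bad_gaps)
  attr(units, "target_years") <- target_years
  attr(units, "tolerance") <- tolerance
  units
}

#' Label a state transition as beneficial / resolution / harmful
#'
#' Taxonomy of 18-month state changes:
#' * beneficial -- severity decreased, or the normal state was maintained
#'   (primary prevention);
#' * resolution -- a diseased state returned to normal spirometry (a subset
#'   of beneficial);
#' * harmful -- severity increased, or GOLD stage II+ was maintained.
#'
#' Persistence in gold1 or unclassified is neutral (neither label).
#'
#' @param start,end spirometric states (factor or character).
#' @return data.frame with logical columns `beneficial`, `resolution`,
#'   `harmful`.
#' @export
#' @examples
#' label_transition("unclassified", "gold1")  # beneficial, not resolution
label_transition <- function(start, end) {
  rs <- state_rank(start); re <- state_rank(end)
  if (anyNA(rs) || anyNA(re)) stop("states must be defined", call. = FALSE)
  data.frame(
    beneficial = re < rs | (rs == 0L & re == 0L),
    resolution = rs != 0L & re == 0L,
    harmful    = re > rs | (rs == 3L & re == 3L))
}

#' Estimate the transition-probability matrix
#'
#' Pools all observation units (across subjects and unit indices) into a 4x4
#' count matrix and row-normalises it.  Rows with no units are reported as
#' `NA` probabilities, not zeros.
#'
#' @param units data.frame from [build_units()].
#' @return Object of class `transition_matrix`: list with `counts`,
#'   `probabilities`, `row_totals`, `n_units`.
#' @export
estimate_transition_matrix <- function(units) {
  if (is.null(units) || nrow(units) == 0) {
    stop("no observation units; cannot estimate a transition matrix",
         call. = FALSE)
  }
  lv <- spiro_states()
  counts <- table(factor(as.character(units$start_state), levels = lv),
                  factor(as.character(units$end_state), levels = lv))
  counts <- matrix(as.integer(counts), 4, 4, dimnames = list(lv, lv))
  row_totals <- rowSums(counts)
  probabilities <- counts / ifelse(row_totals > 0, row_totals, NA_real_)
  structure(list(counts = counts, probabilities = probabilities,
                 row_totals = row_totals, n_units = sum(counts)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, digits = 3, ...) {
  cat("Transition-probability matrix (", x$n_units, " observation units)\n",
      sep = "")
  p <- round(x$probabilities, digits)
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %-12s [n=%5d] ", rownames(p)[i], x$row_totals[i]),
        paste(formatC(p[i, ], format = "f", digits = digits, width = 6),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' Summarise beneficial and resolution probabilities by start state
#'
#' For each start state, the pooled per-unit conditional probability of a
#' beneficial transition and of resolution ("unit" definition), or the
#' per-subject probability of ever making such a transition from that state
#' ("subject" definition).  Resolution is not applicable from the normal
#' state and is reported as `NA`.
#'
#' @param units data.frame from [build_units()].
#' @param group `"all"` (default), `"normal_at_baseline"` or
#'   `"abnormal_at_baseline"`; filters units on the subject's baseline group.
#' @param any_time `"unit"` (pooled per-unit proportions, default) or
#'   `"subject"` (per-subject "ever" proportions).
#' @return data.frame with one row per state: `state`, `n` (denominator),
#'   `p_beneficial`, `p_resolution`, plus the `group`/`any_time` attributes.
#' @export
summarize_transitions <- function(units,
                                  group = c("all", "normal_at_baseline",
                                            "abnormal_at_baseline"),
                                  any_time = c("unit", "subject")) {
  group <- match.arg(group)
  any_time <- match.arg(any_time)
  if (group != "all") units <- units[units$baseline_group == group, , drop = FALSE]
  lv <- spiro_states()
  start <- factor(as.character(units$start_state), levels = lv)

  if (any_time == "unit") {
    n <- as.integer(table(start))
    p_ben <- tapply(units$beneficial, start, mean)
    p_res <- tapply(units$resolution, start, mean)
  } else {
    key <- paste(units$subject_id, as.character(start))
    agg <- aggregate(cbind(beneficial = units$beneficial,
                           resolution = units$resolution),
                     by = list(subject_id = units$subject_id,
                               state = as.character(start)), FUN = any)
    st <- factor(agg$state, levels = lv)
    n <- as.integer(table(st))
    p_ben <- tapply(agg$beneficial, st, mean)
    p_res <- tapply(agg$resolution, st, mean)
  }
  out <- data.frame(state = lv, n = n,
                    p_beneficial = as.numeric(p_ben),
                    p_resolution = as.numeric(p_res))
  out$p_resolution[out$state == "normal"] <- NA_real_   # not applicable
  attr(out, "group") <- group
  attr(out, "any_time") <- any_time
  out
}

#' Compare beneficial (or resolution) probabilities between baseline groups
#'
#' Unit-level binomial-logit regression of the outcome on the baseline-group
#' indicator with cluster-robust (sandwich) variance by subject, since
#' subjects contribute repeated units.  For `outcome = "resolution"` units
#' starting in the normal state are excluded (resolution is undefined there).
#'
#' @param units data.frame from [build_units()].
#' @param outcome `"beneficial"` (default) or `"resolution"`.
#' @return List with `estimate` (log odds ratio, abnormal vs normal baseline),
#'   `robust_se`, `z`, `p_value`, `n_units`, `n_subjects`.
#' @export
compare_baseline_groups <- function(units,
                                    outcome = c("beneficial", "resolution")) {
  outcome <- match.arg(outcome)
  if (outcome == "resolution") {
    units <- units[units$start_state != "normal", , drop = FALSE]
  }
  grp <- factor(units$baseline_group,
                levels = c("normal_at_baseline", "abnormal_at_baseline"))
  if (nlevels(droplevels(grp)) < 2) {
    stop("both baseline groups must be present", call. = FALSE)
  }
  y <- units[[outcome]]
  fit <- glm(y ~ grp, family = binomial())
  vc <- sandwich::vcovCL(fit, cluster = units$subject_id)
  est <- coef(fit)[["grpabnormal_at_baseline"]]
  se <- sqrt(vc["grpabnormal_at_baseline", "grpabnormal_at_baseline"])
  z <- est / se
  list(estimate = est, robust_se = se, z = z,
       p_value = 2 * pnorm(-abs(z)),
       n_units = nrow(units),
       n_subjects = length(unique(units$subject_id)))
}

#' Sensitivity analysis excluding subjects lost to follow-up
#'
#' Re-runs unit construction and the transition summary on subjects with at
#' least `min_visits` classifiable visits, and compares baseline covariates
#' between retained and excluded subjects (two-sample t-tests for continuous
#' covariates, chi-square for binary ones).
#'
#' @param visits classified visit table ([classify_visits()]).
#' @param min_visits minimum number of classifiable visits (>= 2).
#' @param continuous,categorical covariate column names for the
#'   dropout-vs-retained comparison; defaults cover the standard cohort
#'   columns that are present.
#' @param ... passed to [build_units()].
#' @return List with `summary` (as [summarize_transitions()]), `matrix`
#'   (as [estimate_transition_matrix()]), `n_retained`, `n_excluded`, and
#'   `dropout_comparison` (a data.frame of tests).
#' @export
sensitivity_exclude_dropouts <- function(visits, min_visits = 3,
                                         continuous = c("age", "bmi",
                                                        "pack_years",
                                                        "fev1_pct_pred"),
                                         categorical = c("male", "hispanic",
                                                         "current_smoker"),
                                         ...) {
  if (min_visits < 2) stop("min_visits must be >= 2", call. = FALSE)
  ok <- !is.na(visits$state)
  cnt <- table(as.character(visits$subject_id)[ok])
  retained_ids <- names(cnt)[cnt >= min_visits]
  if (length(retained_ids) == 0) {
    stop("min_visits filter removes every subject", call. = FALSE)
  }
  retained <- as.character(visits$subject_id) %in% retained_ids

  base <- visits[ok, , drop = FALSE]
  base <- base[order(base$subject_id, base$time_years), , drop = FALSE]
  base <- base[!duplicated(base$subject_id), , drop = FALSE]
  base$male <- if ("sex" %in% names(base)) base$sex == "male" else NULL
  base$hispanic <- if ("ethnicity" %in% names(base)) {
    base$ethnicity == "hispanic"
  } else NULL
  base$.retained <- as.character(base$subject_id) %in% retained_ids

  rows <- list()
  for (v in intersect(continuous, names(base))) {
    x <- base[[v]]
    if (length(unique(base$.retained)) == 2 && sum(!is.na(x)) > 3) {
      tt <- t.test(x ~ base$.retained)
      rows[[v]] <- data.frame(
        covariate = v, type = "continuous",
        retained = unname(tt$estimate[2]), excluded = unname(tt$estimate[1]),
        statistic = unname(tt$statistic), p_value = tt$p.value)
    }
  }
  for (v in intersect(categorical, names(base))) {
    x <- as.logical(base[[v]])
    if (length(unique(base$.retained)) == 2 && length(unique(x)) == 2) {
      tab <- table(x, base$.retained)
      ct <- suppressWarnings(chisq.test(tab))
      if (any(ct$expected < 5)) ct <- fisher.test(tab)
      rows[[v]] <- data.frame(
        covariate = v, type = "categorical",
        retained = mean(x[base$.retained]), excluded = mean(x[!base$.retained]),
        statistic = if (!is.null(ct$statistic)) unname(ct$statistic) else NA_real_,
        p_value = ct$p.value)
    }
  }
  comparison <- if (length(rows)) do.call(rbind, rows) else
    data.frame(covariate = character(), type = character(),
               retained = numeric(), excluded = numeric(),
               statistic = numeric(), p_value = numeric())
  rownames(comparison) <- NULL

  units <- build_units(visits[retained, , drop = FALSE], ...)
  list(summary = summarize_transitions(units),
       matrix = estimate_transition_matrix(units),
       units = units,
       n_retained = length(retained_ids),
       n_excluded = length(unique(as.character(visits$subject_id))) -
         length(retained_ids),
       dropout_comparison = comparison)
}
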