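# Baseline-characteristics tables and the end-to-end pipeline.

#' Baseline characteristics by spirometric state
#'
#' Summarises covariates at each subject's first classifiable visit,
#' stratified by baseline state: continuous variables as mean +/- SD with a
#' one-way ANOVA p-value, categorical variables as proportions with a
#' chi-square test (Fisher's exact test when any expected cell count is
#' below 5).
#'
#' @param visits classified visit table ([classify_visits()]).
#' @param continuous,categorical covariate column names (defaults cover the
#'   standard cohort columns that are present).
#' @return data.frame of class `baseline_table`: `variable`, `type`, one
#'   column per state (formatted cell), `p_value`; the first row gives the
#'   per-state denominators.
#' @export
baseline_characteristics <- function(visits,
                                     continuous = c("age", "bmi",
                                                    "pack_years",
                                                    "fev1_pct_pred", "ratio",
                                                    "sgrq_total"),
                                     categorical = c("male", "hispanic",
                                                     "current_smoker",
                                                     "hypertension", "asthma",
                                                     "reversible", "bhr")) {
  b <- visits[!is.na(visits$state), , drop = FALSE]
  b <- b[order(b$subject_id, b$time_years), , drop = FALSE]
  b <- b[!duplicated(b$subject_id), , drop = FALSE]
  if ("sex" %in% names(b)) b$male <- b$sex == "male"
  if ("ethnicity" %in% names(b)) b$hispanic <- b$ethnicity == "hispanic"
  st <- factor(as.character(b$state), levels = spiro_states())
  ns <- table(st)
  present <- names(ns)[ns > 0]
  if (length(present) < length(spiro_states())) {
    message("state(s) with no baseline subjects omitted: ",
            paste(setdiff(spiro_states(), present), collapse = ", "))
  }

  rows <- list(data.frame(
    variable = "n", type = "count",
    t(setNames(sprintf("%d", as.integer(ns)), spiro_states())),
    p_value = NA_real_, check.names = FALSE))

  for (v in intersect(continuous, names(b))) {
    x <- b[[v]]
    m <- tapply(x, st, mean, na.rm = TRUE)
    s <- tapply(x, st, sd, na.rm = TRUE)
    p <- if (length(unique(st[!is.na(x)])) > 1) {
      summary(aov(x ~ st))[[1]][["Pr(>F)"]][1]
    } else NA_real_
    fmt <- if (all(abs(m) < 2, na.rm = TRUE)) "%.3f ± %.3f" else "%.1f ± %.1f"
    cells <- ifelse(is.na(m), "-", sprintf(fmt, m, s))
    rows[[v]] <- data.frame(variable = v, type = "continuous",
                            t(setNames(cells, spiro_states())),
                            p_value = p, check.names = FALSE)
  }
  for (v in intersect(categorical, names(b))) {
    x <- as.logical(b[[v]])
    pr <- tapply(x, st, mean, na.rm = TRUE)
    tab <- table(st[!is.na(x)], x[!is.na(x)])
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    p <- if (nrow(tab) > 1 && ncol(tab) > 1) {
      ct <- suppressWarnings(chisq.test(tab))
      if (any(ct$expected < 5)) {
        ft <- tryCatch(fisher.test(tab, workspace = 2e6),
                       error = function(e)
                         chisq.test(tab, simulate.p.value = TRUE, B = 2000))
        ft$p.value
      } else ct$p.value
    } else NA_real_
    cells <- ifelse(is.na(pr), "-", sprintf("%.1f%%", 100 * pr))
    rows[[v]] <- data.frame(variable = v, type = "categorical",
                            t(setNames(cells, spiro_states())),
                            p_value = p, check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("baseline_table", class(out))
  out
}

#' Fingerprint of a data.frame input
#'
#' md5 of a canonical CSV serialisation; recorded in report metadata so a
#' run can be re-verified against its exact input.
#'
#' @param df data.frame.
#' @return md5 string.
#' @export
cohort_fingerprint <- function(df) {
  tf <- tempfile(fileext = ".csv")
  on.exit(unlink(tf))
  write.csv(df, tf, row.names = FALSE, quote = TRUE, eol = "\n")
  unname(tools::md5sum(tf))
}

#' Run the full transition analysis pipeline
#'
#' Orchestrates staging, unit construction, the transition model, the
#' Table-4-style beneficial/resolution summary for the three analysis groups
#' (all, normal at baseline, abnormal at baseline), the between-group
#' comparison, the predictor odds-ratio models and the baseline
#' characteristics table.  Every exclusion is counted and the accounting
#' identity `subjects_in == subjects_analyzed + subjects_dropped` is
#' asserted.
#'
#' @param visits visit table (data.frame or path to a delimited file), or
#'   `NULL` when `simulate` is given.
#' @param simulate optional simulation request: a list with `mode`
#'   (`"latent"` or `"markov"`) plus `config`, `params`/`Q`, `seed` -- or an
#'   existing `spiro_cohort`.
#' @param criterion staging criterion (see [classify_state()]).
#' @param tolerance unit-spacing tolerance in years (see [build_units()]).
#' @param any_time `"unit"` or `"subject"` summary definition.
#' @param min_visits optional: also run the loss-to-follow-up sensitivity
#'   analysis at this threshold.
#' @param include_smoking include time-varying smoking in the multivariable
#'   model (default `FALSE`, matching its exclusion after a null result).
#' @return Object of class `analysis_report`.
#' @export
run_pipeline <- function(visits = NULL, simulate = NULL,
                         criterion = c("fixed_ratio", "lln"),
                         tolerance = 0.5,
                         any_time = c("unit", "subject"),
                         min_visits = NULL,
                         include_smoking = FALSE) {
  criterion <- match.arg(criterion)
  any_time <- match.arg(any_time)

  sim_spec <- NULL
  if (!is.null(simulate)) {
    if (inherits(simulate, "spiro_cohort")) {
      cohort <- simulate
      sim_spec <- list(mode = cohort$mode, config = cohort$config,
                       params = cohort$params, Q = cohort$Q,
                       seed = cohort$seed)
    } else {
      sim_spec <- simulate
      cohort <- if (identical(simulate$mode, "markov")) {
        simulate_markov_cohort(simulate$config %||% cohort_config(),
                               simulate$Q, simulate$seed)
      } else {
        simulate_latent_cohort(simulate$config %||% cohort_config(),
                               simulate$params %||% trajectory_params(),
                               simulate$seed)
      }
    }
    visits <- cohort$visits
  } else if (is.character(visits)) {
    visits <- read.delim(visits, sep = guess_sep(visits),
                         stringsAsFactors = FALSE)
  }
  if (is.null(visits) || !nrow(visits)) {
    stop("no input: supply a visit table or a simulation request",
         call. = FALSE)
  }

  fingerprint <- cohort_fingerprint(visits)
  classified <- classify_visits(visits, criterion = criterion)
  units <- build_units(classified, tolerance = tolerance)
  if (nrow(units) == 0) stop("no observation units could be formed",
                             call. = FALSE)
  units <- unit_predictors(units)
  excl <- attr(units, "exclusions")
  n_analyzed <- length(unique(units$subject_id))
  n_in <- excl$subjects_in
  n_dropped <- n_in - n_analyzed
  stopifnot(n_in == n_analyzed + n_dropped)   # accounting identity

  tm <- estimate_transition_matrix(units)
  table4 <- list(
    all = summarize_transitions(units, "all", any_time),
    normal_at_baseline = summarize_transitions(units, "normal_at_baseline",
                                               any_time),
    abnormal_at_baseline = summarize_transitions(units,
                                                 "abnormal_at_baseline",
                                                 any_time))
  group_test <- list(
    beneficial = try_or_null(compare_baseline_groups(units, "beneficial")),
    resolution = try_or_null(compare_baseline_groups(units, "resolution")))

  preds <- intersect(default_predictors(), names(units))
  if (include_smoking) preds <- c(preds, "current_smoker")
  or_uni <- fit_or_model(units, preds, multivariable = FALSE)
  or_multi <- fit_or_model(units, preds, multivariable = TRUE)
  smoking <- if ("current_smoker" %in% names(units) &&
                 length(unique(units$current_smoker)) > 1) {
    evaluate_time_varying_smoking(units)
  } else NULL

  sens <- if (!is.null(min_visits)) {
    sensitivity_exclude_dropouts(classified, min_visits,
                                 tolerance = tolerance)
  } else NULL

  baseline <- baseline_characteristics(classified)

  structure(list(
    baseline_characteristics = baseline,
    transition_matrix = tm,
    transition_summary = table4,
    group_comparison = group_test,
    predictors = list(univariate = or_uni, multivariable = or_multi),
    time_varying_smoking = smoking,
    sensitivity = sens,
    units = units,
    metadata = list(
      criterion = criterion, tolerance = tolerance, any_time = any_time,
      seed = if (!is.null(sim_spec)) sim_spec$seed else NA_integer_,
      simulate = sim_spec,
      input_md5 = fingerprint,
      package_version = as.character(packageVersion("spirotrans")),
      counts = c(subjects_in = n_in, subjects_analyzed = n_analyzed,
                 subjects_dropped = n_dropped,
                 unclassifiable_sessions = excl$unclassifiable_sessions,
                 duplicate_sessions = excl$duplicate_sessions,
                 gaps_outside_window = excl$gaps_outside_window,
                 n_units = nrow(units)))),
    class = "analysis_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

try_or_null <- function(expr) {
  tryCatch(expr, error = function(e) NULL)
}

guess_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' @export
print.analysis_report <- function(x, ...) {
  writeLines(format_report(x))
  invisible(x)
}

#' Format an analysis report as fixed-layout text
#'
#' Deterministic rendering (stable number formats, stable ordering) used by
#' [print.analysis_report()] and [write_report()]; two runs on the same
#' input produce byte-identical text.
#'
#' @param x `analysis_report`.
#' @return Character vector of lines.
#' @export
format_report <- function(x) {
  f <- function(...) sprintf(...)
  L <- c("=== Spirometric transition analysis report ===",
         f("criterion: %s | tolerance: %.2f y | any-time: %s | seed: %s",
           x$metadata$criterion, x$metadata$tolerance, x$metadata$any_time,
           as.character(x$metadata$seed)),
         f("input md5: %s | package: %s", x$metadata$input_md5,
           x$metadata$package_version),
         paste0("counts: ", paste(names(x$metadata$counts),
                                  x$metadata$counts, sep = "=",
                                  collapse = " ")),
         "", "--- Baseline characteristics by state ---")
  bt <- x$baseline_characteristics
  L <- c(L, f("%-16s %-12s %-14s %-14s %-14s %-14s %s", "variable", "type",
              "normal", "gold1", "unclassified", "gold2plus", "p"))
  for (i in seq_len(nrow(bt))) {
    L <- c(L, f("%-16s %-12s %-14s %-14s %-14s %-14s %s",
                bt$variable[i], bt$type[i], bt$normal[i], bt$gold1[i],
                bt$unclassified[i], bt$gold2plus[i],
                ifelse(is.na(bt$p_value[i]), "-",
                       f("%.4g", bt$p_value[i]))))
  }
  L <- c(L, "", "--- Transition-probability matrix ---")
  p <- x$transition_matrix$probabilities
  for (i in seq_len(4)) {
    L <- c(L, f("%-12s [n=%6d] %s", rownames(p)[i],
                x$transition_matrix$row_totals[i],
                paste(ifelse(is.na(p[i, ]), "    NA",
                             f("%6.4f", p[i, ])), collapse = " ")))
  }
  L <- c(L, "", "--- Beneficial / resolution probabilities ---")
  for (g in names(x$transition_summary)) {
    s <- x$transition_summary[[g]]
    L <- c(L, f("group: %s", g))
    for (i in seq_len(nrow(s))) {
      L <- c(L, f("  %-12s n=%6d  P(beneficial)=%s  P(resolution)=%s",
                  s$state[i], s$n[i],
                  ifelse(is.na(s$p_beneficial[i]), "NA",
                         f("%.4f", s$p_beneficial[i])),
                  ifelse(is.na(s$p_resolution[i]), "NA",
                         f("%.4f", s$p_resolution[i]))))
    }
  }
  for (o in names(x$group_comparison)) {
    gc <- x$group_comparison[[o]]
    if (!is.null(gc)) {
      L <- c(L, f("group difference (%s): logOR=%.4f rSE=%.4f p=%.4g",
                  o, gc$estimate, gc$robust_se, gc$p_value))
    }
  }
  L <- c(L, "", "--- Predictor odds ratios ---")
  for (m in c("univariate", "multivariable")) {
    tab <- x$predictors[[m]]
    L <- c(L, f("model: %s (n_units=%d, n_subjects=%d)", m,
                tab$n_units[1], tab$n_subjects[1]))
    for (i in seq_len(nrow(tab))) {
      L <- c(L, f("  %-26s OR %6.3f (%6.3f, %6.3f) p=%s%s",
                  tab$predictor[i], tab$or[i], tab$ci_low[i], tab$ci_high[i],
                  f("%.4g", tab$p_value[i]),
                  ifelse(tab$separation[i], " [separation?]", "")))
    }
  }
  if (!is.null(x$time_varying_smoking)) {
    s <- x$time_varying_smoking
    L <- c(L, f("time-varying smoking: OR %.3f (%.3f, %.3f) p=%.4g",
                s$or, s$ci_low, s$ci_high, s$p_value))
  }
  L
}

#' Write an analysis report to delimited-text files
#'
#' Writes `report.txt` (the formatted report), `transition_matrix.tsv`,
#' `transition_summary.tsv`, `predictor_or.tsv`,
#' `baseline_characteristics.tsv` and `metadata.tsv` into `dir`.
#'
#' @param report `analysis_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wl <- function(lines, file) {
    con <- file(file.path(dir, file), open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n")
  }
  wl(format_report(report), "report.txt")

  tm <- report$transition_matrix
  mtab <- data.frame(start_state = rownames(tm$counts),
                     row_total = tm$row_totals,
                     round(tm$probabilities, 6), check.names = FALSE)
  wl(c(paste(names(mtab), collapse = "\t"),
       apply(mtab, 1, paste, collapse = "\t")), "transition_matrix.tsv")

  stab <- do.call(rbind, lapply(names(report$transition_summary), function(g) {
    s <- report$transition_summary[[g]]
    s$group <- g
    s$p_beneficial <- round(s$p_beneficial, 6)
    s$p_resolution <- round(s$p_resolution, 6)
    s
  }))
  wl(c(paste(names(stab), collapse = "\t"),
       apply(stab, 1, function(r) paste(ifelse(is.na(r), "NA", r),
                                        collapse = "\t"))),
     "transition_summary.tsv")

  ptab <- rbind(report$predictors$univariate, report$predictors$multivariable)
  ptab$or <- round(ptab$or, 6); ptab$ci_low <- round(ptab$ci_low, 6)
  ptab$ci_high <- round(ptab$ci_high, 6)
  ptab$p_value <- signif(ptab$p_value, 6)
  wl(c(paste(names(ptab), collapse = "\t"),
       apply(ptab, 1, paste, collapse = "\t")), "predictor_or.tsv")

  bt <- report$baseline_characteristics
  bt$p_value <- signif(bt$p_value, 6)
  wl(c(paste(names(bt), collapse = "\t"),
       apply(bt, 1, function(r) paste(ifelse(is.na(r), "NA", r),
                                      collapse = "\t"))),
     "baseline_characteristics.tsv")

  md <- report$metadata
  wl(c("key\tvalue",
       paste("criterion", md$criterion, sep = "\t"),
       paste("tolerance", md$tolerance, sep = "\t"),
       paste("any_time", md$any_time, sep = "\t"),
       paste("seed", md$seed, sep = "\t"),
       paste("input_md5", md$input_md5, sep = "\t"),
       paste("package_version", md$package_version, sep = "\t"),
       paste(names(md$counts), md$counts, sep = "\t")), "metadata.tsv")
  invisible(dir)
}
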