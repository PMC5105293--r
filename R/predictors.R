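# Unit-level logistic models for predictors of beneficial transition.
#
# The outcome is the per-unit beneficial indicator; repeated units per
# subject are handled with an independence working model plus cluster-robust
# (sandwich) variance by subject, with a hand-rolled exchangeable
# working-correlation option.  Odds ratios are reported because the outcome
# is binary; no multiplicity adjustment is applied.

#' Standard dichotomous predictors at unit start
#'
#' Derives the canonical predictor set from the covariate snapshot carried by
#' each observation unit: abnormal start state, age >= 60 y, male sex,
#' Hispanic ethnicity, BMI >= 25 kg/m2, hypertension history, asthma history
#' plus bronchodilator reversibility, and current smoking at unit start.
#'
#' @param units data.frame from [build_units()] whose start-visit snapshot
#'   carries `age`, `sex`, `ethnicity`, and (optionally) `bmi` or
#'   `weight_kg`+`height_cm`, `hypertension`, `asthma`, `reversible`,
#'   `current_smoker`.
#' @param age_cut,bmi_cut dichotomisation thresholds (defaults 60 y and
#'   25 kg/m2).
#' @return `units` with logical columns `abnormal_start`, `age_ge_60`,
#'   `male`, `hispanic`, `bmi_ge_25`, `hypertension`,
#'   `asthma_plus_reversibility`, `current_smoker` appended (those whose
#'   source columns exist).
#' @export
unit_predictors <- function(units, age_cut = 60, bmi_cut = 25) {
  units$abnormal_start <- units$start_state != "normal"
  if ("age" %in% names(units)) units$age_ge_60 <- units$age >= age_cut
  if ("sex" %in% names(units)) units$male <- units$sex == "male"
  if ("ethnicity" %in% names(units)) {
    units$hispanic <- units$ethnicity == "hispanic"
  }
  if (!"bmi" %in% names(units) &&
      all(c("weight_kg", "height_cm") %in% names(units))) {
    units$bmi <- units$weight_kg / (units$height_cm / 100)^2
  }
  if ("bmi" %in% names(units)) units$bmi_ge_25 <- units$bmi >= bmi_cut
  if ("hypertension" %in% names(units)) {
    units$hypertension <- as.logical(units$hypertension)
  }
  if (all(c("asthma", "reversible") %in% names(units))) {
    units$asthma_plus_reversibility <-
      as.logical(units$asthma) & as.logical(units$reversible)
  }
  if ("current_smoker" %in% names(units)) {
    units$current_smoker <- as.logical(units$current_smoker)
  }
  units
}

#' Default predictor set for the odds-ratio models
#' @return Character vector of predictor column names.
#' @export
default_predictors <- function() {
  c("abnormal_start", "age_ge_60", "male", "hispanic", "bmi_ge_25",
    "hypertension", "asthma_plus_reversibility")
}

#' Fit univariate or multivariable odds-ratio models
#'
#' Binomial-logit regression of a unit-level outcome on dichotomous
#' predictors.  `multivariable = TRUE` fits all predictors jointly (each
#' adjusted for all the others); otherwise one model per predictor.
#' Confidence intervals are Wald intervals on the log-odds scale using
#' cluster-robust variance by subject, exponentiated.
#'
#' @param units data.frame from [unit_predictors()].
#' @param predictors character vector of predictor columns (default
#'   [default_predictors()], intersected with available columns).
#' @param outcome outcome column (default `"beneficial"`).
#' @param multivariable fit jointly (default `TRUE`).
#' @param correlation `"independence"` (glm + sandwich, default) or
#'   `"exchangeable"` (GEE-style IRLS with an exchangeable working
#'   correlation, still with robust variance).
#' @param conf_level confidence level (default 0.95).
#' @return data.frame of class `or_table`: `predictor`, `model`,
#'   `or`, `ci_low`, `ci_high`, `p_value`, `n_units`, `n_subjects`,
#'   `separation` (flag for quasi-separated fits).
#' @export
fit_or_model <- function(units, predictors = NULL, outcome = "beneficial",
                         multivariable = TRUE,
                         correlation = c("independence", "exchangeable"),
                         conf_level = 0.95) {
  correlation <- match.arg(correlation)
  if (is.null(predictors)) {
    predictors <- intersect(default_predictors(), names(units))
  }
  miss <- setdiff(predictors, names(units))
  if (length(miss)) {
    stop("predictor column(s) not found: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  y <- as.numeric(units[[outcome]])
  if (length(unique(y)) < 2) {
    stop("outcome has a single class; nothing to model", call. = FALSE)
  }
  constant <- vapply(predictors, function(p) {
    length(unique(units[[p]])) < 2
  }, logical(1))
  if (any(constant)) {
    warning("dropping constant predictor(s): ",
            paste(predictors[constant], collapse = ", "), call. = FALSE)
    predictors <- predictors[!constant]
  }
  if (!length(predictors)) stop("no usable predictors", call. = FALSE)
  cl <- units$subject_id
  zq <- qnorm(1 - (1 - conf_level) / 2)

  fit_one <- function(preds, label) {
    X <- cbind(`(Intercept)` = 1,
               as.matrix(as.data.frame(lapply(units[preds], as.numeric))))
    res <- if (correlation == "independence") {
      w <- NULL
      f <- withCallingHandlers(
        glm.fit(X, y, family = binomial()),
        warning = function(w) invokeRestart("muffleWarning"))
      list(coef = f$coefficients,
           vcov = .vcov_cluster_logit(X, y, f$coefficients, cl))
    } else {
      .gee_exchangeable_logit(X, y, cl)
    }
    b <- res$coef[preds]
    se <- sqrt(diag(res$vcov)[preds])
    sep <- abs(b) > 10 | se > 50     # quasi-separation heuristic
    data.frame(predictor = preds, model = label,
               or = exp(b), ci_low = exp(b - zq * se),
               ci_high = exp(b + zq * se),
               p_value = 2 * pnorm(-abs(b / se)),
               n_units = nrow(units),
               n_subjects = length(unique(cl)),
               separation = sep, row.names = NULL)
  }

  out <- if (multivariable) {
    fit_one(predictors, "multivariable")
  } else {
    do.call(rbind, lapply(predictors, function(p) fit_one(p, "univariate")))
  }
  if (any(out$separation)) {
    warning("possible separation for: ",
            paste(out$predictor[out$separation], collapse = ", "),
            " (estimates flagged)", call. = FALSE)
  }
  class(out) <- c("or_table", class(out))
  out
}

#' @export
print.or_table <- function(x, digits = 2, ...) {
  cat("Odds ratios for", unique(x$model), "model(s);",
      x$n_units[1], "units,", x$n_subjects[1], "subjects\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-26s OR %5.2f (%4.2f, %5.2f)  p=%s%s\n",
                x$predictor[i], x$or[i], x$ci_low[i], x$ci_high[i],
                format.pval(x$p_value[i], digits = 3, eps = 1e-4),
                if (x$separation[i]) "  [separation?]" else ""))
  }
  invisible(x)
}

# cluster-robust (CR0-with-small-sample-correction) sandwich variance for a
# logistic fit given the design matrix; matches sandwich::vcovCL on glm fits
.vcov_cluster_logit <- function(X, y, beta, cluster) {
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  w <- mu * (1 - mu)
  bread <- solve(crossprod(X * sqrt(w)))
  sc <- X * (y - mu)
  g <- rowsum(sc, cluster)
  K <- nrow(g)
  meat <- crossprod(g) * K / (K - 1)
  V <- bread %*% meat %*% bread
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

# GEE-style IRLS for binomial-logit with exchangeable working correlation;
# moment estimate of alpha from Pearson residuals, robust sandwich variance
.gee_exchangeable_logit <- function(X, y, cluster, maxit = 25, tol = 1e-8) {
  f0 <- withCallingHandlers(glm.fit(X, y, family = binomial()),
                            warning = function(w) invokeRestart("muffleWarning"))
  beta <- f0$coefficients
  idx <- split(seq_along(y), cluster)
  p <- ncol(X)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    v <- mu * (1 - mu)
    r <- (y - mu) / sqrt(v)
    # moment estimator of the exchangeable correlation
    num <- 0; den <- 0
    for (ix in idx) {
      ni <- length(ix)
      if (ni > 1) {
        s <- sum(r[ix])
        num <- num + (s^2 - sum(r[ix]^2)) / 2
        den <- den + ni * (ni - 1) / 2
      }
    }
    alpha <- if (den > 0) max(min(num / (den - p), 0.95), 0) else 0

    U <- numeric(p); H <- matrix(0, p, p)
    Glist <- vector("list", length(idx))
    for (k in seq_along(idx)) {
      ix <- idx[[k]]
      ni <- length(ix)
      Di <- X[ix, , drop = FALSE] * v[ix]          # d mu / d beta
      Ai <- sqrt(v[ix])
      # R^{-1} for exchangeable: (I - J*a/(1+(n-1)a)) / (1-a)
      if (ni == 1 || alpha == 0) {
        Vinv <- diag(1 / v[ix], ni)
      } else {
        fac <- alpha / (1 + (ni - 1) * alpha)
        Rin <- (diag(ni) - matrix(fac, ni, ni)) / (1 - alpha)
        Vinv <- (Rin / tcrossprod(Ai)) # A^-1/2 R^-1 A^-1/2
      }
      DtVi <- crossprod(Di, Vinv)
      U <- U + DtVi %*% (y[ix] - mu[ix])
      H <- H + DtVi %*% Di
      Glist[[k]] <- DtVi %*% (y[ix] - mu[ix])
    }
    step <- solve(H, U)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  G <- do.call(cbind, Glist)
  K <- ncol(G)
  meat <- tcrossprod(G) * K / (K - 1)
  Hi <- solve(H)
  V <- Hi %*% meat %*% Hi
  names(beta) <- colnames(X)
  dimnames(V) <- list(colnames(X), colnames(X))
  list(coef = beta, vcov = V, alpha = alpha)
}

#' Joint test of state-by-predictor interaction
#'
#' Adds (start-state x predictor) product terms to the multivariable model --
#' start state entered as a 4-level factor -- and reports a joint Wald
#' chi-square test of the product terms using cluster-robust variance.
#'
#' @param units data.frame from [unit_predictors()].
#' @param predictor name of the predictor to interact with start state.
#' @param adjust character vector of additional main-effect predictors
#'   (default: the remaining default predictors present in `units`).
#' @param outcome outcome column (default `"beneficial"`).
#' @return List with `statistic`, `df`, `p_value`, `estimable`; when any
#'   state-by-predictor cell is empty, `estimable = FALSE` and the test is
#'   not run.
#' @export
test_interaction <- function(units, predictor, adjust = NULL,
                             outcome = "beneficial") {
  if (!predictor %in% names(units)) {
    stop("predictor not found: ", predictor, call. = FALSE)
  }
  st <- factor(as.character(units$start_state), levels = spiro_states())
  st <- droplevels(st)
  x <- as.numeric(units[[predictor]])
  cells <- table(st, x)
  if (nlevels(st) < 2 || any(cells == 0)) {
    return(list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
                estimable = FALSE,
                reason = if (nlevels(st) < 2) "single start state" else
                  "empty state-by-predictor cell"))
  }
  if (is.null(adjust)) {
    adjust <- setdiff(intersect(default_predictors(), names(units)),
                      c(predictor, "abnormal_start"))
  }
  y <- as.numeric(units[[outcome]])
  Xmain <- model.matrix(~ st)          # state main effects absorb abnormal_start
  Xadj <- if (length(adjust)) {
    as.matrix(as.data.frame(lapply(units[adjust], as.numeric)))
  } else NULL
  Xint <- model.matrix(~ st)[, -1, drop = FALSE] * x
  colnames(Xint) <- paste0(colnames(Xint), ":", predictor)
  X <- cbind(Xmain, x = x, Xadj, Xint)
  fit <- withCallingHandlers(glm.fit(X, y, family = binomial()),
                             warning = function(w) invokeRestart("muffleWarning"))
  V <- .vcov_cluster_logit(X, y, fit$coefficients, units$subject_id)
  k <- colnames(Xint)
  b <- fit$coefficients[k]
  W <- drop(t(b) %*% solve(V[k, k, drop = FALSE]) %*% b)
  list(statistic = W, df = length(k),
       p_value = pchisq(W, df = length(k), lower.tail = FALSE),
       estimable = TRUE)
}

#' Evaluate time-varying smoking status as a predictor
#'
#' Adds current smoking at unit start (updated every unit) to the
#' multivariable model and reports its odds ratio and p-value.  The original
#' analysis excluded it from the final models after finding no association;
#' use `include` to control whether downstream models keep it.
#'
#' @param units data.frame from [unit_predictors()] carrying
#'   `current_smoker`.
#' @param adjust main-effect predictors to adjust for (default: the default
#'   predictor set present in `units`).
#' @return List with `or`, `ci_low`, `ci_high`, `p_value`, `estimable`.
#' @export
evaluate_time_varying_smoking <- function(units, adjust = NULL) {
  if (!"current_smoker" %in% names(units)) {
    stop("units must carry current_smoker", call. = FALSE)
  }
  if (length(unique(units$current_smoker)) < 2) {
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                p_value = NA_real_, estimable = FALSE,
                reason = "smoking status has no variation"))
  }
  if (is.null(adjust)) {
    adjust <- intersect(default_predictors(), names(units))
  }
  tab <- fit_or_model(units, predictors = c(adjust, "current_smoker"),
                      multivariable = TRUE)
  row <- tab[tab$predictor == "current_smoker", ]
  list(or = row$or, ci_low = row$ci_low, ci_high = row$ci_high,
       p_value = row$p_value, estimable = TRUE)
}
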