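# NHANES-III adult reference equations (Hankinson et al. 1999).
# Coefficients live in inst/extdata/nhanes3_adult_coefficients.tsv so that an
# alternate reference set (e.g. GLI) can be dropped in without code changes.

.spirotrans_env <- new.env(parent = emptyenv())

#' Load a spirometry reference coefficient table
#'
#' Reads the NHANES-III adult coefficient table shipped with the package (or a
#' drop-in replacement in the same format).  Each row gives the polynomial
#' coefficients `b0 + b_age*age + b_age2*age^2 + b_ht2*height^2` for one
#' sex x ethnicity x quantity stratum, plus the lower-limit-of-normal
#' intercept.
#'
#' @param path path to a tab-delimited coefficient file; default is the
#'   shipped NHANES-III adult table.
#' @param verify_checksum verify the shipped file's md5 checksum (ignored for
#'   user-supplied paths).
#' @return data.frame of coefficients with attributes `version` and `md5`.
#' @export
reference_coefficients <- function(path = NULL, verify_checksum = TRUE) {
  shipped <- is.null(path)
  if (shipped) {
    if (!is.null(.spirotrans_env$nhanes3)) {
      return(.spirotrans_env$nhanes3)
    }
    path <- system.file("extdata", "nhanes3_adult_coefficients.tsv",
                        package = "spirotrans", mustWork = TRUE)
  }
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("quantity", "sex", "ethnicity", "age_min", "age_max_deriv",
              "b0", "b_age", "b_age2", "b_ht2", "lln_b0")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop("coefficient table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  md5 <- unname(tools::md5sum(path))
  if (shipped && verify_checksum && !identical(md5, nhanes3_table_md5())) {
    warning("shipped NHANES-III coefficient table failed its checksum; ",
            "the file may have been modified", call. = FALSE)
  }
  first <- readLines(path, n = 1L)
  attr(tab, "version") <- sub(".*version: *([^)]*)\\).*", "\\1", first)
  attr(tab, "md5") <- md5
  if (shipped) .spirotrans_env$nhanes3 <- tab
  tab
}

#' @rdname reference_coefficients
#' @export
nhanes3_table_md5 <- function() {
  # recorded at packaging time; guards against silent edits of the constants
  "1fd05544c4ec353df7d1be8220cfeb60"
}

#' Default ethnicity-to-equation-group mapping
#'
#' The cohort records Hispanic vs non-Hispanic white ethnicity; the NHANES-III
#' equations come in caucasian / african_american / mexican_american strata.
#' The conventional mapping sends Hispanic subjects to the mexican_american
#' equations and non-Hispanic whites to the caucasian equations; subjects of
#' other or unknown ethnicity fall back to the caucasian stratum (with a
#' warning at prediction time).  Supply a modified named vector to any
#' function taking `ethnicity_map` to override.
#'
#' @return Named character vector mapping cohort ethnicity labels to
#'   equation groups.
#' @export
default_ethnicity_map <- function() {
  c(hispanic          = "mexican_american",
    non_hispanic_white = "caucasian",
    caucasian          = "caucasian",
    african_american   = "african_american",
    mexican_american   = "mexican_american",
    other              = "caucasian")
}

.map_ethnicity <- function(ethnicity, ethnicity_map) {
  grp <- unname(ethnicity_map[as.character(ethnicity)])
  if (anyNA(grp)) {
    bad <- unique(as.character(ethnicity)[is.na(grp)])
    stop("ethnicity value(s) not in ethnicity_map: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(as.character(ethnicity) == "other")) {
    warning("ethnicity 'other' mapped to the caucasian equation stratum",
            call. = FALSE)
  }
  grp
}

#' Predicted spirometric values and lower limits of normal
#'
#' Evaluates the NHANES-III adult polynomial reference equations for FEV1 and
#' FVC (litres) and the FEV1/FVC ratio, returning predicted values and lower
#' limits of normal (5th percentile).  Vectorised over subjects.
#'
#' @param age age in years (decimal); adult segments only (>= 18 for women,
#'   >= 20 for men).  Ages above the derivation range (80 y) are extrapolated
#'   with a warning.
#' @param height_cm standing height in centimetres, in \[100, 230\].
#' @param sex `"female"` or `"male"`.
#' @param ethnicity_group equation stratum: `"caucasian"`,
#'   `"african_american"` or `"mexican_american"`.
#' @param coefficients coefficient table from [reference_coefficients()].
#' @return data.frame with columns `fev1_pred`, `fvc_pred`, `fev1_lln`,
#'   `fvc_lln` (litres) and `ratio_lln` (fraction, FEV1/FVC).
#' @export
#' @examples
#' predict_reference(55, 163, "female", "caucasian")
predict_reference <- function(age, height_cm, sex, ethnicity_group,
                              coefficients = reference_coefficients()) {
  n <- max(length(age), length(height_cm), length(sex), length(ethnicity_group))
  age <- rep_len(age, n); height_cm <- rep_len(height_cm, n)
  sex <- rep_len(as.character(sex), n)
  ethnicity_group <- rep_len(as.character(ethnicity_group), n)

  if (any(!sex %in% c("female", "male"))) {
    stop("sex must be 'female' or 'male'", call. = FALSE)
  }
  groups <- unique(coefficients$ethnicity)
  if (any(!ethnicity_group %in% groups)) {
    stop("unsupported ethnicity group(s): ",
         paste(setdiff(unique(ethnicity_group), groups), collapse = ", "),
         "; supported: ", paste(groups, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(age)) || any(age < 8 | age > 100)) {
    stop("age must be finite and in [8, 100] years", call. = FALSE)
  }
  if (any(!is.finite(height_cm)) || any(height_cm < 100 | height_cm > 230)) {
    stop("height_cm must be finite and in [100, 230] cm", call. = FALSE)
  }

  eval_quantity <- function(quantity) {
    sub <- coefficients[coefficients$quantity == quantity, , drop = FALSE]
    key <- paste(sex, ethnicity_group)
    idx <- match(key, paste(sub$sex, sub$ethnicity))
    row <- sub[idx, , drop = FALSE]
    below <- age < row$age_min
    if (any(below)) {
      stop("age below the adult equation segment (", paste(
        unique(row$age_min[below]), collapse = "/"),
        " y); paediatric equations are not implemented", call. = FALSE)
    }
    pred <- row$b0 + row$b_age * age + row$b_age2 * age^2 +
      row$b_ht2 * height_cm^2
    lln <- row$lln_b0 + row$b_age * age + row$b_age2 * age^2 +
      row$b_ht2 * height_cm^2
    list(pred = pred, lln = lln, age_max = row$age_max_deriv)
  }

  fev1 <- eval_quantity("fev1")
  fvc  <- eval_quantity("fvc")
  rat  <- eval_quantity("ratio")
  if (any(age > fev1$age_max)) {
    warning(sum(age > fev1$age_max), " age(s) above the derivation range (",
            max(fev1$age_max), " y); extrapolating", call. = FALSE)
  }
  out <- data.frame(fev1_pred = fev1$pred, fvc_pred = fvc$pred,
                    fev1_lln = fev1$lln, fvc_lln = fvc$lln,
                    ratio_lln = rat$lln / 100)
  if (any(out$fev1_pred <= 0 | out$fvc_pred <= 0)) {
    stop("non-positive predicted value; input outside the usable range",
         call. = FALSE)
  }
  out
}

#' Percent of predicted value
#'
#' @param measured measured value (litres), >= 0.
#' @param predicted predicted value (litres), > 0.
#' @return `100 * measured / predicted` (percent).
#' @export
#' @examples
#' percent_predicted(1.6, 2.0) # 80
percent_predicted <- function(measured, predicted) {
  if (any(!is.finite(predicted)) || any(predicted <= 0)) {
    stop("predicted must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(measured)) || any(measured < 0)) {
    stop("measured must be finite and >= 0", call. = FALSE)
  }
  100 * measured / predicted
}
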