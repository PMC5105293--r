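#' Spirometric state labels
#'
#' The four ordinal states used throughout the package, from least to most
#' severe: `normal` (no obstruction, preserved FEV1), `gold1` (obstruction,
#' preserved FEV1), `unclassified` (no obstruction, impaired FEV1; also
#' called restrictive pattern or PRISm) and `gold2plus` (obstruction,
#' impaired FEV1, pooling GOLD stages II-IV).  SGRQ health status and FEV1
#' worsen monotonically along this order, which is what justifies treating
#' it as an ordinal severity scale.
#'
#' @return Character vector of the four state labels in rank order
#'   (rank 0 = `normal` ... rank 3 = `gold2plus`).
#' @export
#' @examples
#' spiro_states()
spiro_states <- function() {
  c("normal", "gold1", "unclassified", "gold2plus")
}

#' Construct a spirometric state factor
#'
#' @param x character vector of state labels, or integer ranks in 0..3.
#' @return Ordered factor with levels `spiro_states()`.
#' @export
spiro_state <- function(x) {
  lv <- spiro_states()
  if (is.numeric(x)) {
    if (any(!is.na(x) & (x < 0 | x > 3 | x != round(x)))) {
      stop("state ranks must be integers in 0..3", call. = FALSE)
    }
    x <- lv[x + 1L]
  }
  if (any(!is.na(x) & !x %in% lv)) {
    stop("unknown state label(s): ",
         paste(unique(setdiff(x, lv)), collapse = ", "), call. = FALSE)
  }
  factor(x, levels = lv, ordered = TRUE)
}

#' Ordinal rank of a spirometric state
#'
#' @param state factor or character vector of state labels.
#' @return Integer vector of ranks (normal = 0, gold1 = 1, unclassified = 2,
#'   gold2plus = 3).
#' @export
state_rank <- function(state) {
  match(as.character(state), spiro_states()) - 1L
}
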