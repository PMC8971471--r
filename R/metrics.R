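#' Coefficient of determination
#'
#' Agreement between a measured series `x` and model estimates `y`.
#' The default `"conventional"` mode returns the squared Pearson
#' correlation, which is what goodness-of-fit tables in crop modelling
#' report. The `"literal"` mode evaluates the ratio
#' `sum((y - ybar)^2) / sum((x - ybar)^2)` (with `ybar` the mean of the
#' estimates); this form is not bounded by 1 and is kept only for
#' fidelity to that printed definition.
#'
#' @param x Measured values.
#' @param y Model estimates, same length as `x` (n >= 2).
#' @param mode `"conventional"` (default) or `"literal"`.
#' @return A dimensionless scalar; in conventional mode in \[0, 1\].
#' @export
r_squared <- function(x, y, mode = c("conventional", "literal")) {
  mode <- match.arg(mode)
  check_paired(x, y)
  if (mode == "conventional") {
    if (stats::var(x) == 0 || stats::var(y) == 0) {
      stop("r_squared undefined: zero variance in x or y", call. = FALSE)
    }
    stats::cor(x, y)^2
  } else {
    ybar <- mean(y)
    denom <- sum((x - ybar)^2)
    if (denom == 0) {
      stop("literal r_squared undefined: zero denominator", call. = FALSE)
    }
    sum((y - ybar)^2) / denom
  }
}

#' Root-mean-square error
#'
#' @param x Measured values.
#' @param y Model estimates, same length as `x`.
#' @return RMSE in the units of the inputs.
#' @export
rmse <- function(x, y) {
  check_paired(x, y, min_n = 1L)
  sqrt(mean((x - y)^2))
}

#' Normalized RMSE (percent)
#'
#' RMSE divided by the mean of the model estimates, times 100.
#'
#' @param x Measured values.
#' @param y Model estimates, same length as `x`; `mean(y)` must be
#'   nonzero.
#' @return nRMSE in percent.
#' @export
nrmse <- function(x, y) {
  check_paired(x, y, min_n = 1L)
  ybar <- mean(y)
  if (ybar == 0) stop("nrmse undefined: mean of estimates is zero",
                      call. = FALSE)
  100 * rmse(x, y) / ybar
}

#' Consistency class of an nRMSE value
#'
#' Standard agronomic interpretation bands: below 10% `"high"`,
#' 10-20% `"good"`, 20-30% `"medium"`, 30% and above `"poor"`.
#' Intervals are left-closed/right-open.
#'
#' @param nrmse_pct nRMSE in percent; vectorized.
#' @return Character vector of class labels.
#' @examples
#' consistency_class(c(9.9, 15, 23.3, 30))
#' @export
consistency_class <- function(nrmse_pct) {
  as.character(cut(nrmse_pct,
                   breaks = c(-Inf, 10, 20, 30, Inf),
                   labels = c("high", "good", "medium", "poor"),
                   right = FALSE))
}

#' Evaluation report for one measured/estimated pair of series
#'
#' @param x Measured values.
#' @param y Model estimates.
#' @return Data frame with columns `metric`, `value`, `class` (class is
#'   filled for nRMSE only).
#' @export
evaluation_report <- function(x, y) {
  nr <- nrmse(x, y)
  r2 <- tryCatch(r_squared(x, y), error = function(e) NA_real_)
  data.frame(
    metric = c("r_squared", "rmse", "nrmse_pct"),
    value = c(r2, rmse(x, y), nr),
    class = c(NA_character_, NA_character_, consistency_class(nr)),
    stringsAsFactors = FALSE
  )
}

check_paired <- function(x, y, min_n = 2L) {
  if (length(x) != length(y)) {
    stop("measured and estimated series must have equal length",
         call. = FALSE)
  }
  if (length(x) < min_n) {
    stop(sprintf("need at least %d paired values", min_n), call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("paired series must not contain missing values", call. = FALSE)
  }
  invisible(TRUE)
}
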