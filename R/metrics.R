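# Agreement metrics: RMSE, relative RMSE (normalised by the reference
# signal's peak absolute value), peak extraction, and the two-way
# random-effects absolute-agreement single-measure intraclass correlation
# ICC(2,1) with its categorical interpretation.

#' Root-mean-square error between two equally sampled series
#'
#' `sqrt(mean((x1 - x2)^2))`, the discrete (rectangle-rule) evaluation of
#' the time-averaged squared difference.
#'
#' @param x1 reference series.
#' @param x2 candidate series, same length.
#' @return scalar, in signal units.
#' @export
rmse <- function(x1, x2) {
  if (length(x1) != length(x2))
    stop("series lengths differ: ", length(x1), " vs ", length(x2))
  sqrt(mean((x1 - x2)^2))
}

#' Relative RMSE in percent
#'
#' `100 * rmse(x1, x2) / max(|x1|)`. The normaliser is the *reference*
#' peak, so the measure is not symmetric in its arguments.
#'
#' @inheritParams rmse
#' @return scalar, percent.
#' @export
rrmse <- function(x1, x2) {
  mx <- max(abs(x1))
  if (mx == 0) stop("reference series is identically zero; rRMSE undefined")
  100 * rmse(x1, x2) / mx
}

#' Intraclass correlation ICC(2,1) of paired peak values
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC from the
#' paired table, computed from the classical mean-squares decomposition:
#' `(MSR - MSE) / (MSR + MSE + 2 (MSC - MSE) / n)` for two raters.
#'
#' @param peaks_ref,peaks_cand paired numeric vectors (>= 3 pairs).
#' @return list with `icc` and `category` (see [icc_category()]).
#' @export
icc <- function(peaks_ref, peaks_cand) {
  n <- length(peaks_ref)
  if (length(peaks_cand) != n) stop("peak lists have different lengths")
  if (n < 3) stop("need at least 3 paired peaks, got ", n)
  y <- cbind(peaks_ref, peaks_cand)
  k <- 2
  grand <- mean(y)
  if (sum((y - grand)^2) == 0)
    stop("zero total variance in paired peaks; ICC undefined")
  row_m <- rowMeans(y)
  col_m <- colMeans(y)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((y - grand)^2) - k * sum((row_m - grand)^2) -
    n * sum((col_m - grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  val <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  list(icc = val, category = icc_category(val))
}

#' Categorise an ICC value
#'
#' Poor (<= 0.5), moderate (<= 0.75), good (<= 0.9), excellent (> 0.9).
#' Boundary values fall in the lower category ("excellent" requires
#' strictly more than 0.9).
#'
#' @param value ICC in `[-1, 1]`.
#' @return one of `"poor"`, `"moderate"`, `"good"`, `"excellent"`.
#' @export
icc_category <- function(value) {
  if (value <= 0.5) "poor"
  else if (value <= 0.75) "moderate"
  else if (value <= 0.9) "good"
  else "excellent"
}

#' Signed peak of a series within a task window
#'
#' The sample with the largest absolute value inside the window, sign
#' preserved.
#'
#' @param series numeric vector.
#' @param window `c(first, last)` indices (1-based, inclusive); default the
#'   whole series.
#' @return scalar peak value.
#' @export
extract_peaks <- function(series, window = NULL) {
  if (is.null(window)) window <- c(1L, length(series))
  idx <- window[1]:window[2]
  if (length(idx) == 0 || window[1] < 1 || window[2] > length(series))
    stop("empty or out-of-range peak window")
  seg <- series[idx]
  seg[which.max(abs(seg))]
}

#' Agreement report between reference and candidate series
#'
#' Bundles RMSE, rRMSE and (when >= 3 paired peaks are supplied) ICC(2,1)
#' with its category, in the layout used for component-wise ground-reaction
#' validation.
#'
#' @param reference,candidate numeric series (same length).
#' @param peaks_ref,peaks_cand optional paired peak lists for the ICC.
#' @param label optional name for printing.
#' @return an `agreement_report` list.
#' @export
agreement_report <- function(reference, candidate,
                             peaks_ref = NULL, peaks_cand = NULL,
                             label = NULL) {
  rep <- list(label = label,
              rmse = rmse(reference, candidate),
              rrmse = rrmse(reference, candidate),
              icc = NA_real_, icc_category = NA_character_)
  if (!is.null(peaks_ref) && length(peaks_ref) >= 3) {
    ic <- icc(peaks_ref, peaks_cand)
    rep$icc <- ic$icc
    rep$icc_category <- ic$category
    rep$peaks_reference <- peaks_ref
    rep$peaks_candidate <- peaks_cand
  }
  structure(rep, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report>%s RMSE = %.4g, rRMSE = %.3f%%",
              if (is.null(x$label)) "" else paste0(" ", x$label, ":"),
              x$rmse, x$rrmse))
  if (!is.na(x$icc))
    cat(sprintf(", ICC(2,1) = %.3f (%s)", x$icc, x$icc_category))
  cat("\n")
  invisible(x)
}
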