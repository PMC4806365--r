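#' Bland-Altman agreement between measured and predicted volumes
#'
#' Computes the paired differences \code{d_i = predicted_i - measured_i}
#' (so a positive bias means the prediction overestimates), their mean
#' (bias), their sample standard deviation sigma (n - 1 denominator) --
#' the agreement measure used to rank landmarks -- and the 95\% limits of
#' agreement \code{bias +/- 1.96 sigma}.
#'
#' @param measured numeric vector of measured total VAT volumes (ml).
#' @param predicted numeric vector of predicted volumes (ml), same length.
#' @return An [AgreementStats-class].
#' @examples
#' blandAltman(c(4000, 5000), c(3900, 5100))
#' @export
blandAltman <- function(measured, predicted) {
  if (length(measured) != length(predicted))
    stop("'measured' and 'predicted' must have equal length")
  if (length(measured) < 2L)
    stop("need at least 2 pairs")
  d <- predicted - measured
  bias <- mean(d)
  sigma <- stats::sd(d)
  new("AgreementStats",
      bias = bias,
      sigma = sigma,
      n = length(d),
      loaLower = bias - 1.96 * sigma,
      loaUpper = bias + 1.96 * sigma)
}

#' Pearson correlation with a two-sided p-value
#'
#' Product-moment correlation between two variables (e.g. BMI and total
#' VAT volume), with the two-sided p-value from the t transform.  Thin
#' wrapper over [stats::cor.test()] that enforces the preconditions used
#' throughout the package.
#'
#' @param x,y numeric vectors of equal length (>= 3) with non-zero
#'   variance.
#' @return A list with elements \code{r} and \code{p.value}.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p.value = ct$p.value)
}

#' Bland-Altman plot
#'
#' Mean of the paired volumes against their difference, with the bias and
#' the 95\% limits of agreement drawn as horizontal lines.
#'
#' @param measured,predicted numeric vectors of paired volumes (ml).
#' @param stats optional precomputed [AgreementStats-class]; computed from
#'   the data when missing.
#' @param ... further arguments passed to [graphics::plot()].
#' @return The [AgreementStats-class] used, invisibly.
#' @export
plotBlandAltman <- function(measured, predicted, stats = NULL, ...) {
  if (is.null(stats)) stats <- blandAltman(measured, predicted)
  m <- (measured + predicted) / 2
  d <- predicted - measured
  graphics::plot(m, d,
                 xlab = "Mean of measured and predicted volume [ml]",
                 ylab = "Predicted - measured volume [ml]", ...)
  graphics::abline(h = stats@bias, lty = 1)
  graphics::abline(h = c(stats@loaLower, stats@loaUpper), lty = 2)
  invisible(stats)
}
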