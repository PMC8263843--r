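# Quantitative evaluation: Dice similarity, physical volumes, volume
# agreement (linear fit + Bland-Altman), and single-measure intraclass
# correlation.

#' Dice similarity coefficient between two binary masks
#'
#' DSC = 2 |P n M| / (|P| + |M|), in [0, 1].  When both masks are empty the
#' DSC is defined as 1 (a label absent from both volumes is perfect
#' agreement).
#'
#' @param P,M logical arrays of identical shape (predicted and manual
#'   masks).
#' @return A number in [0, 1].
#' @examples
#' a <- array(c(TRUE, TRUE, FALSE, FALSE), c(1, 2, 2))
#' b <- array(c(TRUE, FALSE, TRUE, FALSE), c(1, 2, 2))
#' dsc(a, b)  # 2*1 / (2+2) = 0.5
#' @export
dsc <- function(P, M) {
  if (!identical(dim(P), dim(M)))
    stop("geometry mismatch: masks have different shapes")
  p <- sum(P); m <- sum(M)
  if (p + m == 0) return(1)
  2 * sum(P & M) / (p + m)
}

#' Per-label DSC between predicted and manual label volumes
#'
#' Applies \code{\link{dsc}} to each bone label's binary mask.  Labels
#' absent from the manual volume (field-of-view variation: a study may lack
#' the pubis or lumbar vertebra sections) are excluded from both the table
#' and the average; labels present in the manual volume but missing from the
#' prediction score 0.  The average weights labels equally.
#'
#' @param predicted,manual \code{LabelVolume}s of identical geometry.
#' @return A list with \code{perLabel} (named numeric, one entry per label
#'   present in the manual volume) and \code{average}.
#' @export
perLabelDSC <- function(predicted, manual) {
  stopifnot(is(predicted, "LabelVolume"), is(manual, "LabelVolume"))
  checkSameGeometry(predicted, manual)
  pv <- predicted@values; mv <- manual@values
  present <- sort(unique(as.integer(mv)))
  present <- present[present > 0L]
  per <- vapply(present, function(l) dsc(pv == l, mv == l), numeric(1))
  names(per) <- as.character(present)
  list(perLabel = per,
       average = if (length(per)) mean(per) else NA_real_)
}

#' Physical volume of a label in cubic centimetres
#'
#' Voxel count times voxel volume (product of spacings, mm^3), converted to
#' cm^3.
#'
#' @param labels a \code{LabelVolume}.
#' @param label a bone label 1-8, or "all" for all foreground voxels.
#' @return Volume in cm^3.
#' @examples
#' v <- labelVolume(array(rep(1L, 1000), c(10, 10, 10)), c(1, 1, 1))
#' labelVolumeCm3(v, 1)  # 1.0
#' @export
labelVolumeCm3 <- function(labels, label = "all") {
  stopifnot(is(labels, "LabelVolume"))
  nv <- if (identical(label, "all")) sum(labels@values > 0L)
        else sum(labels@values == as.integer(label))
  nv * prod(labels@spacing) / 1000
}

#' Bland-Altman agreement between predicted and manual volumes
#'
#' Differences d = predicted - manual; bias = mean(d); 95% limits of
#' agreement = bias +/- 1.96 x sample standard deviation (n - 1
#' denominator).
#'
#' @param predVolumes,manualVolumes numeric vectors of equal length
#'   \code{n >= 2}.
#' @return A list with \code{mean_bias}, \code{loa_low}, \code{loa_high},
#'   \code{sd_diff} and \code{n}.
#' @examples
#' blandAltman(c(2, 4, 6), c(1, 2, 3))  # bias 2, LoA (0.04, 3.96)
#' @export
blandAltman <- function(predVolumes, manualVolumes) {
  if (length(predVolumes) != length(manualVolumes))
    stop("volume vectors must have equal length")
  n <- length(predVolumes)
  if (n < 2L) stop("Bland-Altman needs n >= 2 (SD undefined for n = 1)")
  d <- predVolumes - manualVolumes
  bias <- mean(d)
  s <- stats::sd(d)
  list(mean_bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s, n = n)
}

#' Ordinary least-squares fit with R-squared
#'
#' @param x,y numeric vectors of equal length \code{n >= 2}; \code{x} must
#'   not be constant.
#' @return A list with \code{slope}, \code{intercept} and \code{r_squared}
#'   (squared Pearson correlation).
#' @export
linearFitR2 <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 2L) stop("linear fit needs n >= 2")
  if (stats::sd(x) == 0) stop("'x' is constant; slope undefined")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  r2 <- if (stats::sd(y) == 0) 1 else stats::cor(x, y)^2
  list(slope = unname(co[2]), intercept = unname(co[1]), r_squared = r2)
}

#' Single-measure intraclass correlation, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC computed
#' from the ANOVA mean squares of a complete subjects x raters grid:
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + k (MS_C - MS_E)/n}}
#' with \eqn{MS_R} the between-subject, \eqn{MS_C} the between-rater and
#' \eqn{MS_E} the residual mean square, for \eqn{n} subjects and \eqn{k}
#' raters.
#'
#' @param ratings numeric matrix, one row per subject, one column per rater;
#'   no missing cells.
#' @return The ICC(2,1) value.
#' @examples
#' m <- cbind(r1 = c(8, 7, 9, 5, 6), r2 = c(8, 7, 9, 5, 6))
#' iccSingle(m)  # 1: raters identical, subjects differ
#' @export
iccSingle <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ratings grid must be complete (no NA)")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 raters")
  grand <- mean(ratings)
  rowm <- rowMeans(ratings)
  colm <- colMeans(ratings)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom == 0) return(1)  # zero variance everywhere: perfect agreement
  (msr - mse) / denom
}
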