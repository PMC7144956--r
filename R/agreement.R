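#' Two-sample Student t-test on IntraMAT percents
#'
#' Classical pooled-variance unpaired t-test (two-tailed), the comparison
#' used throughout the analysis; Welch's correction is available behind a
#' flag. Note that applying an unpaired test to paired within-subject
#' method values discards the pairing; it is implemented this way for
#' fidelity to the original analysis protocol, and callers wanting a paired
#' comparison should use \code{stats::t.test(..., paired = TRUE)}.
#'
#' @param x,y numeric samples (each n >= 2).
#' @param welch use Welch's unequal-variance t-test instead of pooled.
#' @return List with \code{t}, \code{p}, \code{df}.
#' @export
unpairedTTest <- function(x, y, welch = FALSE) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least two observations")
  if (stats::var(x) + stats::var(y) == 0)
    stop("degenerate samples: zero pooled variance")
  tt <- stats::t.test(x, y, var.equal = !welch)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Bland-Altman agreement with proportional-bias test
#'
#' Differences are taken as \code{d = dixon - t1w} (2PD minus T1W) and
#' plotted conceptually against the pair means; limits of agreement are
#' mean difference +/- 1.96 sd. Proportional bias is assessed as the
#' Pearson correlation of d against the mean, declared significant at
#' p < 0.05.
#'
#' @param t1w,dixon paired IntraMAT percents (n >= 3).
#' @return Object of class \code{blandAltman}: n, meanDiff, sdDiff,
#'   loaLow, loaHigh, propBiasR, propBiasP, proportionalBias. The
#'   correlation fields are \code{NA} when the differences or means are
#'   constant.
#' @examples
#' ba <- blandAltman(t1w = c(10, 20, 30), dixon = c(12, 18, 24))
#' ba$meanDiff  # -2
#' @export
blandAltman <- function(t1w, dixon) {
  if (length(t1w) != length(dixon)) stop("unequal pair lengths")
  n <- length(t1w)
  if (n < 3L) stop("need at least three pairs")
  d <- dixon - t1w
  m <- (t1w + dixon) / 2
  meanDiff <- mean(d)
  sdDiff <- stats::sd(d)
  if (sdDiff > 0 && stats::sd(m) > 0) {
    ct <- stats::cor.test(m, d)
    r <- unname(ct$estimate)
    p <- ct$p.value
  } else {
    r <- NA_real_
    p <- NA_real_
  }
  structure(list(n = n, meanDiff = meanDiff, sdDiff = sdDiff,
                 loaLow = meanDiff - 1.96 * sdDiff,
                 loaHigh = meanDiff + 1.96 * sdDiff,
                 propBiasR = r, propBiasP = p,
                 proportionalBias = isTRUE(p < 0.05)),
            class = "blandAltman")
}

#' @export
print.blandAltman <- function(x, ...) {
  cat(sprintf("Bland-Altman (d = 2PD - T1W), n = %d\n", x$n))
  cat(sprintf("  mean diff %.3f%%, LoA [%.3f, %.3f]\n",
              x$meanDiff, x$loaLow, x$loaHigh))
  if (is.na(x$propBiasR)) {
    cat("  proportional bias: undefined (constant differences)\n")
  } else {
    cat(sprintf("  proportional bias: r = %.3f, p = %.3g%s\n",
                x$propBiasR, x$propBiasP,
                if (x$proportionalBias) " (significant)" else ""))
  }
  invisible(x)
}

#' ICC(2,1): two-way random effects, absolute agreement, single measure
#'
#' Computed from the two-way ANOVA mean squares as
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + k (MS_C - MS_E)/n}}
#' with \eqn{MS_R} the between-subject, \eqn{MS_C} the between-session and
#' \eqn{MS_E} the residual mean square. Absolute agreement penalizes
#' systematic session offsets. Sums of squares are accumulated directly
#' from residuals, so identical sessions yield exactly 1.
#'
#' @param ratings numeric matrix, subjects x sessions (no missing cells,
#'   n >= 2 subjects, k >= 2 sessions).
#' @return Object of class \code{icc}: value, n, k, and variance components
#'   (betweenSubject, betweenSession, residual mean squares).
#' @export
icc21 <- function(ratings) {
  x <- as.matrix(ratings)
  if (anyNA(x)) stop("missing cells are not supported")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 sessions")
  grand <- mean(x)
  rowM <- rowMeans(x)
  colM <- colMeans(x)
  if (all(x == x[1])) stop("zero total variance")
  SSR <- k * sum((rowM - grand)^2)
  SSC <- n * sum((colM - grand)^2)
  resid <- x - outer(rowM, rep(1, k)) - outer(rep(1, n), colM) + grand
  SSE <- sum(resid^2)
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  structure(list(value = icc, n = n, k = k,
                 betweenSubject = MSR, betweenSession = MSC,
                 residual = MSE),
            class = "icc")
}

#' @export
print.icc <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.4f  (n = %d subjects, k = %d sessions)\n",
              x$value, x$n, x$k))
  invisible(x)
}

#' Boundary value: the T1W threshold reproducing a target percent
#'
#' The smallest masked intensity t such that the fraction of mask pixels
#' strictly above t is at most \code{targetPercent / 100} — the empirical
#' (1 - target/100) quantile under the strict-exceedance rule, consistent
#' with the "at-threshold counts as muscle" classification. Re-thresholding
#' at the returned value reproduces the target within one pixel quantum
#' (100/N percentage points) when intensities are untied.
#'
#' @param image matrix or \linkS4class{MRImage2D}.
#' @param mask logical matrix (nonempty).
#' @param targetPercent target IntraMAT percent in [0, 100].
#' @return Threshold in a.u., within the masked intensity range.
#' @export
boundaryValue <- function(image, mask, targetPercent) {
  if (!any(mask)) stop("empty mask")
  if (targetPercent < 0 || targetPercent > 100)
    stop("targetPercent must lie in [0, 100]")
  vals <- sort(.asMatrix(image)[mask])
  N <- length(vals)
  kAllowed <- floor(N * targetPercent / 100)
  uv <- unique(vals)
  nAtOrBelow <- findInterval(uv, vals)
  above <- N - nAtOrBelow
  uv[which(above <= kAllowed)[1]]
}

#' Boundary-value discrepancy record for one muscle
#'
#' Assembles the per-muscle comparison underlying the threshold-equivalence
#' analysis: the Otsu threshold actually used on T1W, the boundary value
#' that would reproduce the Dixon percent on the same T1W image, and the
#' two discrepancy deltas. \code{deltaIntensity} is defined as boundary
#' value minus T1W threshold — how far the applied threshold sits below the
#' Dixon-equivalent one — so that T1W overestimation yields positive
#' deltaIntensity and negative deltaIntramat.
#'
#' @param image T1W image (matrix or \linkS4class{MRImage2D}).
#' @param mask logical muscle mask.
#' @param t1wThreshold threshold applied on T1W (a.u.).
#' @param t1wPercent,dixonPercent the two method percents.
#' @param muscle,subject optional identifiers.
#' @return One-row data.frame: subject, muscle, t1wThreshold,
#'   boundaryValue, deltaIntensity, deltaIntramat.
#' @export
boundaryRecord <- function(image, mask, t1wThreshold, t1wPercent,
                           dixonPercent, muscle = NA_character_,
                           subject = NA_character_) {
  bv <- boundaryValue(image, mask, dixonPercent)
  data.frame(subject = subject, muscle = muscle,
             t1wThreshold = t1wThreshold, boundaryValue = bv,
             deltaIntensity = bv - t1wThreshold,
             deltaIntramat = dixonPercent - t1wPercent,
             stringsAsFactors = FALSE)
}

#' Correlation of IntraMAT discrepancy with threshold discrepancy
#'
#' Pearson correlation of \code{deltaIntramat} (2PD minus T1W percent)
#' against \code{deltaIntensity} (boundary value minus T1W threshold)
#' across boundary records; a strong negative correlation localizes the
#' inter-method discrepancy in the threshold setting.
#'
#' @param records data.frame with columns \code{deltaIntramat} and
#'   \code{deltaIntensity} (n >= 3).
#' @return List with \code{r}, \code{p}, \code{n}.
#' @export
discrepancyAnalysis <- function(records) {
  di <- records$deltaIntramat
  dt <- records$deltaIntensity
  if (length(di) < 3L) stop("need at least three records")
  if (stats::sd(dt) == 0 || stats::sd(di) == 0)
    stop("zero variance in discrepancy deltas")
  ct <- stats::cor.test(dt, di)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(di))
}

#' Corner ROIs for subtraction-method SNR
#'
#' Four square ROIs placed in the image corners (ROI 1 = top-left,
#' 2 = top-right, 3 = bottom-left, 4 = bottom-right), inset by a margin.
#'
#' @param dim image dimensions (rows, cols).
#' @param sizePx ROI side in pixels.
#' @param marginPx inset from the image border in pixels.
#' @return Named list of logical masks.
#' @export
cornerROIs <- function(dim, sizePx = 20L, marginPx = 5L) {
  nr <- dim[1]; nc <- dim[2]
  if (2 * (sizePx + marginPx) > min(nr, nc))
    stop("corner ROIs do not fit inside the image")
  mk <- function(r0, c0) {
    m <- matrix(FALSE, nr, nc)
    m[r0:(r0 + sizePx - 1L), c0:(c0 + sizePx - 1L)] <- TRUE
    m
  }
  lo <- marginPx + 1L
  hiR <- nr - marginPx - sizePx + 1L
  hiC <- nc - marginPx - sizePx + 1L
  list(ROI1 = mk(lo, lo), ROI2 = mk(lo, hiC),
       ROI3 = mk(hiR, lo), ROI4 = mk(hiR, hiC))
}

#' Subtraction-method SNR over corner ROIs
#'
#' For each ROI, the signal is the mean of the two-image average and the
#' noise is the standard deviation of the difference image divided by
#' \eqn{\sqrt 2}: \eqn{SNR = \bar S / (sd(A - B) / \sqrt 2)}. A zero
#' difference sd yields an infinite-SNR sentinel.
#'
#' @param imgA,imgB matrices or \linkS4class{MRImage2D}, same geometry.
#' @param rois list of logical ROI masks (e.g. \code{\link{cornerROIs}}).
#' @return data.frame: roi, signalMean, diffSD, snr.
#' @export
snrSubtraction <- function(imgA, imgB, rois) {
  a <- .asMatrix(imgA)
  b <- .asMatrix(imgB)
  if (!identical(dim(a), dim(b)))
    stop("images must share the same geometry")
  rows <- lapply(names(rois), function(nm) {
    msk <- rois[[nm]]
    if (!identical(dim(msk), dim(a))) stop("ROI outside image geometry")
    sm <- mean((a[msk] + b[msk]) / 2)
    dsd <- stats::sd(a[msk] - b[msk])
    data.frame(roi = nm, signalMean = sm, diffSD = dsd,
               snr = if (dsd == 0) Inf else sm / (dsd / sqrt(2)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group comparison table of IntraMAT content
#'
#' Mirrors a per-muscle, per-method comparison between two groups (e.g.
#' younger vs older): group means, sd and ranges plus the unpaired Student
#' t-test between groups.
#'
#' @param data data.frame with columns \code{muscle}, \code{method},
#'   \code{group}, \code{intramatPercent}.
#' @param welch use Welch's t-test.
#' @return data.frame with one row per muscle x method.
#' @export
compareGroups <- function(data, welch = FALSE) {
  stopifnot(all(c("muscle", "method", "group", "intramatPercent") %in%
                names(data)))
  groups <- sort(unique(as.character(data$group)))
  if (length(groups) != 2L) stop("exactly two groups required")
  combos <- unique(data[, c("muscle", "method")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- data$muscle == combos$muscle[i] & data$method == combos$method[i]
    x <- data$intramatPercent[sel & data$group == groups[1]]
    y <- data$intramatPercent[sel & data$group == groups[2]]
    tt <- unpairedTTest(x, y, welch = welch)
    data.frame(muscle = combos$muscle[i], method = combos$method[i],
               group1 = groups[1], mean1 = mean(x), sd1 = stats::sd(x),
               min1 = min(x), max1 = max(x),
               group2 = groups[2], mean2 = mean(y), sd2 = stats::sd(y),
               min2 = min(y), max2 = max(y),
               t = tt$t, p = tt$p, significant = tt$p < 0.05,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bland-Altman plot
#'
#' Scatter of per-pair differences (2PD - T1W) against pair means, with
#' the mean-difference line (solid) and 95\% limits of agreement (dashed).
#'
#' @param t1w,dixon paired IntraMAT percents.
#' @param ... passed to \code{plot} (e.g. \code{main}).
#' @return The \code{\link{blandAltman}} result, invisibly.
#' @export
plotBlandAltman <- function(t1w, dixon, ...) {
  ba <- blandAltman(t1w, dixon)
  d <- dixon - t1w
  m <- (t1w + dixon) / 2
  graphics::plot(m, d, xlab = "Mean of methods (%)",
                 ylab = "2PD - T1W IntraMAT (%)", pch = 19, ...)
  graphics::abline(h = 0, col = "grey70")
  graphics::abline(h = ba$meanDiff)
  graphics::abline(h = c(ba$loaLow, ba$loaHigh), lty = 2)
  invisible(ba)
}
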