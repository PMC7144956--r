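#' Place reference ROIs on the pure-muscle and subcutaneous-fat labels
#'
#' Random fully-interior placement of square ROIs of fixed physical area
#' (default 25 mm^2, i.e. a 5 x 5 px square at 1 mm spacing): three on the
#' pure muscle reference compartment (vastus intermedius) and three on
#' subcutaneous fat, non-overlapping, each lying entirely inside its
#' designated label. Manual ROI drawing is irreproducible; the randomized
#' placement makes trial-to-trial threshold variation mimic the operator
#' variability that repeated trials average out.
#'
#' @param labels a \linkS4class{LabelMask}.
#' @param areaMM2 ROI area in mm^2.
#' @param nPerTissue ROIs per reference tissue.
#' @param muscleRef,fatRef compartment names of the reference tissues.
#' @param seed optional RNG seed (placement is deterministic under a seed).
#' @return A \linkS4class{ROISet}.
#' @export
placeROIs <- function(labels, areaMM2 = 25, nPerTissue = 3L,
                      muscleRef = "VI", fatRef = "subcutaneous_fat",
                      seed = NULL) {
  sp <- pixelSpacing(labels)
  side <- max(1L, as.integer(round(sqrt(areaMM2) / sp)))
  withSeed(seed, {
    tl <- matrix(0L, 0L, 2L)
    tags <- character(0)
    for (ref in c(muscleRef, fatRef)) {
      mask <- compartmentMask(labels, ref)
      cand <- .interiorTopLefts(mask, side)
      if (nrow(cand) < nPerTissue)
        stop("label '", ref, "' is too small to host ", nPerTissue,
             " interior ", side, "x", side, " ROIs")
      picked <- .pickNonOverlapping(cand, side, nPerTissue)
      if (is.null(picked))
        stop("could not place ", nPerTissue,
             " non-overlapping ROIs on label '", ref, "'")
      tl <- rbind(tl, picked)
      tags <- c(tags, rep(if (ref == muscleRef) "muscle_reference"
                          else "fat_reference", nPerTissue))
    }
    new("ROISet", topLeft = tl, side = side, tag = tags, spacing = sp)
  })
}

# All 1-based top-left corners whose side x side square lies fully inside
# the mask, found with an integral image.
.interiorTopLefts <- function(mask, side) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (nr < side || nc < side) return(matrix(0L, 0L, 2L))
  S <- apply(apply(mask * 1L, 2, cumsum), 1, cumsum)  # S[j, i] = sum to (i, j)
  S <- t(S)
  Sp <- matrix(0, nr + 1L, nc + 1L)
  Sp[-1, -1] <- S
  r <- seq_len(nr - side + 1L)
  c_ <- seq_len(nc - side + 1L)
  winsum <- Sp[r + side, c_ + side, drop = FALSE] -
    Sp[r, c_ + side, drop = FALSE] - Sp[r + side, c_, drop = FALSE] +
    Sp[r, c_, drop = FALSE]
  full <- which(winsum == side * side, arr.ind = TRUE)
  matrix(as.integer(full), ncol = 2L)
}

# Shuffle candidates and greedily keep n whose squares do not overlap.
.pickNonOverlapping <- function(cand, side, n) {
  ord <- sample.int(nrow(cand))
  chosen <- matrix(0L, 0L, 2L)
  for (i in ord) {
    tl <- cand[i, ]
    if (nrow(chosen) > 0 &&
        any(abs(chosen[, 1] - tl[1]) < side &
            abs(chosen[, 2] - tl[2]) < side)) next
    chosen <- rbind(chosen, tl)
    if (nrow(chosen) == n) return(chosen)
  }
  NULL
}

#' Pixel values covered by each ROI
#'
#' @param image matrix or \linkS4class{MRImage2D}.
#' @param rois a \linkS4class{ROISet}.
#' @return List of numeric vectors, one per ROI.
#' @export
roiPixels <- function(image, rois) {
  m <- .asMatrix(image)
  s <- rois@side
  lapply(seq_len(nrow(rois@topLeft)), function(i) {
    tl <- rois@topLeft[i, ]
    as.vector(m[tl[1]:(tl[1] + s - 1L), tl[2]:(tl[2] + s - 1L)])
  })
}

#' Pooled reference histogram over all ROIs
#'
#' Bins the pooled intensities of the six reference ROIs into equal-width
#' bins over their range; this frequency distribution is the input to Otsu
#' thresholding.
#'
#' @param image matrix or \linkS4class{MRImage2D}.
#' @param rois a \linkS4class{ROISet}.
#' @param nBins number of bins (default 256, conventional for 8-12 bit MR
#'   magnitude data).
#' @return A \linkS4class{HistogramModel}.
#' @export
buildReferenceHistogram <- function(image, rois, nBins = 256L) {
  pooled <- unlist(roiPixels(image, rois))
  if (any(!is.finite(pooled))) stop("non-finite intensities in ROIs")
  rng <- range(pooled)
  if (diff(rng) == 0)
    stop("degenerate intensity range: all ROI pixels are equal")
  breaks <- seq(rng[1], rng[2], length.out = nBins + 1L)
  counts <- tabulate(.bincode(pooled, breaks, include.lowest = TRUE),
                     nbins = nBins)
  new("HistogramModel", breaks = breaks, counts = as.numeric(counts),
      n = length(pooled))
}

#' Otsu threshold of a histogram
#'
#' Exhaustively maximizes the between-class variance
#' \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2} over all cut points, using bin
#' midpoints as class values. Returns the upper edge of the last bin of the
#' lower class; ties are broken toward the lowest cut.
#'
#' @param hist a \linkS4class{HistogramModel}.
#' @return Threshold in a.u.
#' @export
otsuThreshold <- function(hist) {
  w <- hist@counts
  if (sum(w > 0) < 2L)
    stop("histogram needs at least two nonempty bins")
  nb <- length(w)
  mids <- (hist@breaks[-1] + hist@breaks[-(nb + 1L)]) / 2
  cw <- cumsum(w)
  cm <- cumsum(w * mids)
  total <- cw[nb]
  totalMean <- cm[nb] / total
  k <- seq_len(nb - 1L)
  w0 <- cw[k] / total
  w1 <- 1 - w0
  mu0 <- ifelse(cw[k] > 0, cm[k] / cw[k], 0)
  mu1 <- ifelse(cw[nb] - cw[k] > 0,
                (cm[nb] - cm[k]) / (cw[nb] - cw[k]), 0)
  bcv <- w0 * w1 * (mu0 - mu1)^2
  bcv[cw[k] == 0 | cw[k] == total] <- -Inf
  # ties (exact or within floating-point noise) resolve to the lowest cut
  m <- max(bcv)
  kstar <- which(bcv >= m - abs(m) * 1e-10)[1]
  hist@breaks[kstar + 1L]
}

#' Repeated ROI placement and Otsu thresholding
#'
#' Repeats place-ROIs / build-histogram / Otsu with fresh random ROI
#' placements and returns the per-trial thresholds and their mean; the mean
#' of (by default) three trials is the subject-level threshold applied to
#' all muscles.
#'
#' @param image matrix or \linkS4class{MRImage2D} (bias-corrected T1W).
#' @param labels a \linkS4class{LabelMask}.
#' @param nTrials number of trials (>= 1).
#' @param nBins histogram bins.
#' @param seed optional RNG seed for reproducible placements.
#' @param ... passed to \code{\link{placeROIs}}.
#' @return A \linkS4class{ThresholdResult}.
#' @export
thresholdTrials <- function(image, labels, nTrials = 3L, nBins = 256L,
                            seed = NULL, ...) {
  if (nTrials < 1L) stop("nTrials must be >= 1")
  withSeed(seed, {
    trials <- vapply(seq_len(nTrials), function(i) {
      rois <- placeROIs(labels, ...)
      otsuThreshold(buildReferenceHistogram(image, rois, nBins))
    }, numeric(1))
    new("ThresholdResult", trials = trials, mean = mean(trials))
  })
}

#' Threshold-based IntraMAT quantification of one muscle
#'
#' Pixels with intensity strictly above the threshold are counted as
#' IntraMAT, pixels at or below it as skeletal muscle, and
#' \deqn{IntraMAT\,(\%) = 100 \cdot n_{fat} / (n_{muscle} + n_{fat}).}
#'
#' @param image matrix or \linkS4class{MRImage2D}.
#' @param mask logical matrix, the muscle compartment (nonempty).
#' @param threshold intensity threshold in a.u.
#' @param spacing pixel spacing in mm (taken from the image if available).
#' @param muscle optional muscle name for the output row.
#' @return One-row data.frame: muscle, nMuscle, nFat, intramatPercent,
#'   csaCm2.
#' @export
quantifyT1W <- function(image, mask, threshold, spacing = NULL,
                        muscle = NA_character_) {
  if (!any(mask)) stop("empty muscle mask")
  m <- .asMatrix(image)
  sp <- .spacingOf(image, spacing)
  vals <- m[mask]
  nFat <- sum(vals > threshold)
  nMuscle <- length(vals) - nFat
  data.frame(muscle = muscle, nMuscle = nMuscle, nFat = nFat,
             intramatPercent = 100 * nFat / (nMuscle + nFat),
             csaCm2 = computeCSA(mask, sp),
             stringsAsFactors = FALSE)
}

#' Cross-sectional area of a mask
#'
#' @param mask logical matrix (nonempty).
#' @param spacing pixel spacing in mm.
#' @return Area in cm^2 (pixel count x spacing^2 / 100).
#' @examples
#' computeCSA(matrix(TRUE, 10, 10), spacing = 1)  # 1 cm^2
#' @export
computeCSA <- function(mask, spacing) {
  if (!any(mask)) stop("empty mask")
  if (spacing <= 0) stop("spacing must be positive")
  sum(mask) * spacing^2 / 100
}
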