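#' N3-style correction of multiplicative intensity inhomogeneity
#'
#' Iterative nonparametric estimation of a smooth multiplicative bias field
#' on a 2-D image, in the spirit of nonuniform intensity normalization
#' (N3): the log-intensity histogram of the foreground is sharpened by
#' Wiener deconvolution of a Gaussian blur kernel, the expected true log
#' intensity of every pixel under the sharpened distribution is computed,
#' and the residual (observed minus expected) is smoothed at the field
#' scale and accumulated into the log-field. Iterations stop when the
#' coefficient of variation of the per-iteration field change drops below
#' the end tolerance.
#'
#' Estimation runs on a subsampled grid (factor
#' \code{subsamplingFactor}); the accumulated log-field is bilinearly
#' upsampled, exponentiated, and normalized to mean 1 over the foreground.
#' Background pixels (intensity <= \code{signalThreshold}) pass through
#' unchanged.
#'
#' With \code{stages > 1}, a coarse-to-fine schedule is used: the field is
#' first estimated at \code{fieldDistance * 2^(stages-1)}, the image
#' corrected, and the residual field re-estimated at successively halved
#' distances down to \code{fieldDistance}; the returned field is the
#' composition. The coarse stages capture the global intensity gradient
#' before class assignment can lock onto a wrong mode, which stabilizes
#' estimation when the bias spread is comparable to the tissue contrast.
#'
#' @param image matrix or \linkS4class{MRImage2D}, nonnegative intensities.
#' @param config an \linkS4class{N3Config}.
#' @param stages number of coarse-to-fine stages (default 1: the single
#'   fixed-distance scheme).
#' @return A \linkS4class{BiasFieldResult}.
#' @examples
#' flat <- MRImage2D(matrix(100, 64, 64), spacing = 1)
#' res <- n3Correct(flat, n3Config())
#' res@converged
#' @export
n3Correct <- function(image, config = n3Config(), stages = 1L) {
  validObject(config)
  if (stages > 1L) return(.n3MultiScale(image, config, as.integer(stages)))
  m <- .asMatrix(image)
  sp <- .spacingOf(image)
  if (any(!is.finite(m))) stop("non-finite input image")
  fg <- m > config@signalThreshold
  if (!any(fg)) stop("empty foreground: no pixel exceeds signalThreshold")

  nr <- nrow(m); nc <- ncol(m)
  sub <- config@subsamplingFactor
  rowsAt <- unique(c(seq(1L, nr, by = sub), nr))
  colsAt <- unique(c(seq(1L, nc, by = sub), nc))
  ms <- m[rowsAt, colsAt, drop = FALSE]
  fgs <- fg[rowsAt, colsAt, drop = FALSE]
  if (!any(fgs)) stop("empty foreground on the subsampled grid")

  v0 <- matrix(0, nrow(ms), ncol(ms))
  v0[fgs] <- log(ms[fgs])
  sigmaPx <- config@fieldDistance / 2.355 / (sp * sub)
  logF <- matrix(0, nrow(ms), ncol(ms))
  cvHist <- numeric(0)
  converged <- FALSE
  iter <- 0L

  repeat {
    iter <- iter + 1L
    v <- v0 - logF
    expd <- .n3SharpenExpectation(v[fgs], config)
    resid <- matrix(0, nrow(ms), ncol(ms))
    resid[fgs] <- v[fgs] - expd
    # normalized convolution over the foreground; the weight floor keeps
    # the estimate bounded (decaying to 0) away from foreground support
    # instead of amplifying numerically empty neighbourhoods
    wts <- gaussSmooth(fgs * 1.0, sigmaPx)
    sm <- gaussSmooth(resid, sigmaPx)
    step <- sm / pmax(wts, 0.05)
    logF <- logF + step
    logF <- logF - mean(logF[fgs])
    e <- exp(step[fgs])
    cv <- stats::sd(e) / mean(e)
    cvHist <- c(cvHist, cv)
    if (is.finite(cv) && cv < config@endTolerance) {
      converged <- TRUE
      break
    }
    if (iter >= config@maxIterations) break
  }

  full <- if (length(rowsAt) > 1 && length(colsAt) > 1)
    bilinearUpsample(logF, rowsAt, colsAt, nr, nc)
  else matrix(logF[1], nr, nc)
  field <- exp(full)
  field <- field / mean(field[fg])
  corrected <- m
  corrected[fg] <- m[fg] / field[fg]
  new("BiasFieldResult",
      corrected = MRImage2D(corrected, sp),
      field = MRImage2D(field, sp),
      iterations = iter, converged = converged, cvHistory = cvHist)
}

# Coarse-to-fine composition of single-scale runs.
.n3MultiScale <- function(image, config, stages) {
  m <- .asMatrix(image)
  sp <- .spacingOf(image)
  fg <- m > config@signalThreshold
  if (!any(fg)) stop("empty foreground: no pixel exceeds signalThreshold")
  work <- m
  fieldTotal <- matrix(1, nrow(m), ncol(m))
  iters <- 0L
  cvh <- numeric(0)
  conv <- FALSE
  for (k in (stages - 1L):0L) {
    cfg <- config
    cfg@fieldDistance <- config@fieldDistance * 2^k
    res <- n3Correct(MRImage2D(work, sp), cfg)
    fieldTotal <- fieldTotal * imageData(biasField(res))
    work <- imageData(correctedImage(res))
    iters <- iters + res@iterations
    cvh <- c(cvh, res@cvHistory)
    conv <- res@converged
  }
  fieldTotal <- fieldTotal / mean(fieldTotal[fg])
  corrected <- m
  corrected[fg] <- m[fg] / fieldTotal[fg]
  new("BiasFieldResult",
      corrected = MRImage2D(corrected, sp),
      field = MRImage2D(fieldTotal, sp),
      iterations = iters, converged = conv, cvHistory = cvh)
}

# Histogram-sharpening expectation step: given foreground log intensities v,
# return E[true log intensity | observed v] under the sharpened density.
.n3SharpenExpectation <- function(v, config) {
  rng <- range(v)
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2])))
    return(v)  # degenerate histogram: nothing to sharpen
  nb <- config@nBins
  # pad the range slightly so edge values fall inside bins
  pad <- diff(rng) * 1e-6
  br <- seq(rng[1] - pad, rng[2] + pad, length.out = nb + 1L)
  mids <- (br[-1] + br[-(nb + 1L)]) / 2
  binw <- br[2] - br[1]
  h <- tabulate(.bincode(v, br, include.lowest = TRUE), nbins = nb)

  # Gaussian blur kernel in log-intensity units, discretized on the bin grid
  sigma <- config@kernelFWHM / 2.355
  L <- 2L * nb  # circular FFT length with padding to avoid wrap-around
  kidx <- c(0:(L %/% 2), -((L - L %/% 2 - 1L):1)) * binw
  g <- stats::dnorm(kidx, sd = sigma)
  g <- g / sum(g)
  G <- stats::fft(g)
  H <- stats::fft(c(h, numeric(L - nb)))
  # Wiener deconvolution of the blur from the histogram
  W <- Conj(G) / (Mod(G)^2 + config@wienerNoise)
  fSharp <- Re(stats::fft(H * W, inverse = TRUE)) / L
  fSharp <- pmax(fSharp[seq_len(nb)], 0)
  if (sum(fSharp) <= 0) return(v)

  # E[t | v]: convolve the sharpened density (and its first moment) with
  # the blur kernel, then evaluate the ratio at each observed v.
  num <- Re(stats::fft(stats::fft(c(fSharp * mids, numeric(L - nb))) * G,
                       inverse = TRUE)) / L
  den <- Re(stats::fft(stats::fft(c(fSharp, numeric(L - nb))) * G,
                       inverse = TRUE)) / L
  num <- num[seq_len(nb)]
  den <- den[seq_len(nb)]
  emap <- ifelse(den > 1e-12 * max(den), num / den, mids)
  idx <- .bincode(v, br, include.lowest = TRUE)
  emap[idx]
}
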