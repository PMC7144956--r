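#' @import methods
NULL

#' Single-channel 2-D MR raster with physical pixel spacing
#'
#' The elementary image container of the package: a numeric matrix of signal
#' intensities (arbitrary units) plus an isotropic pixel spacing in mm.
#' It carries T1-weighted, Dixon water/fat, bias-field and fat-fraction maps
#' alike; fat-fraction maps may hold \code{NA} at pixels below the noise
#' floor.
#'
#' @slot data numeric matrix, row-major anatomical raster.
#' @slot spacing numeric(1), isotropic pixel spacing in mm.
#' @export
setClass("MRImage2D",
  representation(data = "matrix", spacing = "numeric"))

setValidity("MRImage2D", function(object) {
  if (!is.numeric(object@data)) return("data must be a numeric matrix")
  if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
      object@spacing <= 0)
    return("spacing must be a single positive number (mm)")
  TRUE
})

#' Construct an MRImage2D
#'
#' @param data numeric matrix of intensities.
#' @param spacing isotropic pixel spacing in mm.
#' @return An \linkS4class{MRImage2D}.
#' @examples
#' img <- MRImage2D(matrix(rnorm(100, 100, 5), 10, 10), spacing = 1)
#' pixelSpacing(img)
#' @export
MRImage2D <- function(data, spacing = 1) {
  new("MRImage2D", data = as.matrix(data * 1.0), spacing = as.numeric(spacing))
}

#' Integer compartment labels on the imaging grid
#'
#' Assigns every pixel to one anatomical compartment. The default compartment
#' table covers the mid-thigh slice analysed here: vastus lateralis (VL),
#' vastus intermedius (VI), adductor magnus (AM), biceps femoris long head
#' (BFL), subcutaneous fat ring, femur, and background.
#'
#' @slot data integer matrix of compartment ids.
#' @slot spacing numeric(1), pixel spacing in mm.
#' @slot table named integer vector mapping compartment names to ids.
#' @export
setClass("LabelMask",
  representation(data = "matrix", spacing = "numeric", table = "integer"))

setValidity("LabelMask", function(object) {
  if (!is.integer(object@data)) return("label data must be an integer matrix")
  if (is.null(names(object@table))) return("compartment table must be named")
  if (anyDuplicated(object@table)) return("compartment ids must be unique")
  if (!all(object@data %in% object@table))
    return("label image contains ids absent from the compartment table")
  TRUE
})

#' Default mid-thigh compartment table
#' @return Named integer vector of compartment ids.
#' @export
thighCompartments <- function() {
  c(background = 0L, VL = 1L, VI = 2L, AM = 3L, BFL = 4L,
    subcutaneous_fat = 5L, femur = 6L)
}

#' Construct a LabelMask
#' @param data integer matrix of compartment ids.
#' @param spacing pixel spacing in mm.
#' @param table named integer vector mapping names to ids.
#' @return A \linkS4class{LabelMask}.
#' @export
LabelMask <- function(data, spacing = 1, table = thighCompartments()) {
  storage.mode(data) <- "integer"
  new("LabelMask", data = data, spacing = as.numeric(spacing),
      table = table)
}

#' Parameters of the synthetic mid-thigh phantom
#'
#' Defines the geometry, tissue contrast, infiltration pattern and artifact
#' levels of a simulated axial mid-thigh slice with paired T1-weighted and
#' two-point Dixon channels. Defaults emulate a 3 T acquisition at 1 mm
#' in-plane resolution with per-muscle fat fractions in the range reported
#' for healthy adults.
#'
#' @slot imageSize integer(2), raster rows and columns.
#' @slot spacing numeric(1), pixel spacing in mm.
#' @slot geometry named list of compartment ellipses (centers/semi-axes, mm).
#' @slot muscleMeanIntensity T1W signal of pure muscle (a.u.).
#' @slot fatMeanIntensity T1W signal of pure fat (a.u.); must exceed muscle.
#' @slot femurIntensity T1W signal of bone (a.u.).
#' @slot protonSignal Dixon proton signal S over tissue (a.u.); channels are
#'   water = S(1-ff) and fat = S*ff.
#' @slot noiseSD additive noise sd (a.u.) applied to all channels.
#' @slot rician logical; if TRUE T1W noise is Rician (magnitude of a complex
#'   Gaussian), otherwise Gaussian.
#' @slot fatFraction named numeric, target fat fraction per infiltrated
#'   muscle (VL, AM, BFL), each in [0,1]. The vastus intermedius is kept
#'   fat-free by construction as the pure-muscle reference tissue.
#' @slot marblingScale spatial correlation length of infiltration (mm).
#' @slot partialVolumeWidth width of the mixed band around fat clusters (px).
#' @slot partialVolumeExponent concavity of the mixing profile; values < 1
#'   make near-cluster pixels fat-dominant.
#' @slot biasAmplitude peak multiplicative deviation of the bias field from 1.
#' @slot biasScale spatial scale of the bias field (mm).
#' @slot seed integer RNG seed; the phantom is a pure function of the spec.
#' @export
setClass("PhantomSpec",
  representation(
    imageSize = "integer", spacing = "numeric", geometry = "list",
    muscleMeanIntensity = "numeric", fatMeanIntensity = "numeric",
    femurIntensity = "numeric", protonSignal = "numeric",
    noiseSD = "numeric", rician = "logical", fatFraction = "numeric",
    marblingScale = "numeric", partialVolumeWidth = "numeric",
    partialVolumeExponent = "numeric", biasAmplitude = "numeric",
    biasScale = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (length(object@imageSize) != 2L || any(object@imageSize < 32L))
    return("imageSize must be two integers >= 32")
  if (object@fatMeanIntensity <= object@muscleMeanIntensity)
    return("fatMeanIntensity must exceed muscleMeanIntensity")
  if (any(object@fatFraction < 0) || any(object@fatFraction > 1))
    return("fat fractions must lie in [0, 1]")
  if (!all(c("VL", "AM", "BFL") %in% names(object@fatFraction)))
    return("fatFraction must name VL, AM and BFL")
  if (object@noiseSD < 0) return("noiseSD must be >= 0")
  if (object@biasAmplitude < 0 || object@biasAmplitude >= 1)
    return("biasAmplitude must lie in [0, 1)")
  if (object@partialVolumeWidth < 0)
    return("partialVolumeWidth must be >= 0")
  if (object@partialVolumeExponent <= 0)
    return("partialVolumeExponent must be > 0")
  TRUE
})

#' Paired synthetic T1W/Dixon slice with exact ground truth
#'
#' Output of \code{\link{makePhantom}}: the three acquisition channels, the
#' compartment labels, and the latent truths (per-pixel fat fraction, the
#' multiplicative bias field, and the realized per-muscle fat pixel
#' fraction).
#'
#' @slot t1w,water,fat \linkS4class{MRImage2D} channels.
#' @slot labels \linkS4class{LabelMask}.
#' @slot truthFatFraction per-pixel fat fraction in [0,1].
#' @slot truthBias multiplicative bias field applied to the T1W channel.
#' @slot truthP named numeric, exact realized fat pixel fraction per muscle.
#' @slot spec the generating \linkS4class{PhantomSpec}.
#' @export
setClass("ThighPhantom",
  representation(
    t1w = "MRImage2D", water = "MRImage2D", fat = "MRImage2D",
    labels = "LabelMask", truthFatFraction = "MRImage2D",
    truthBias = "MRImage2D", truthP = "numeric", spec = "PhantomSpec"))

setValidity("ThighPhantom", function(object) {
  d <- dim(object@t1w@data)
  same <- identical(dim(object@water@data), d) &&
    identical(dim(object@fat@data), d) &&
    identical(dim(object@labels@data), d) &&
    identical(dim(object@truthFatFraction@data), d) &&
    identical(dim(object@truthBias@data), d)
  if (!same) return("all rasters must share the same shape")
  ff <- object@truthFatFraction@data
  if (any(ff < 0 | ff > 1, na.rm = TRUE))
    return("truth fat fraction must lie in [0, 1]")
  TRUE
})

#' Configuration of the N3-style bias-field correction
#'
#' Parameter block of the nonparametric nonuniform intensity normalization
#' scheme used on T1-weighted images before thresholding.
#'
#' @slot endTolerance convergence tolerance on the coefficient of variation
#'   of the per-iteration field change (default 1e-4).
#' @slot maxIterations iteration cap (default 100).
#' @slot signalThreshold foreground threshold in a.u. (default 1).
#' @slot fieldDistance characteristic smoothness distance of the field in mm
#'   (default 25); the field smoother is Gaussian with
#'   sigma = fieldDistance / 2.355.
#' @slot subsamplingFactor grid subsampling during estimation (default 4).
#' @slot kernelFWHM FWHM of the log-intensity blur kernel deconvolved during
#'   histogram sharpening, in log-intensity units (default 0.15).
#' @slot wienerNoise Wiener deconvolution noise constant (default 0.01).
#' @slot nBins number of log-intensity histogram bins (default 200).
#' @export
setClass("N3Config",
  representation(
    endTolerance = "numeric", maxIterations = "integer",
    signalThreshold = "numeric", fieldDistance = "numeric",
    subsamplingFactor = "integer", kernelFWHM = "numeric",
    wienerNoise = "numeric", nBins = "integer"))

setValidity("N3Config", function(object) {
  vals <- c(object@endTolerance, object@maxIterations,
            object@signalThreshold, object@fieldDistance,
            object@subsamplingFactor, object@kernelFWHM,
            object@wienerNoise, object@nBins)
  if (any(!is.finite(vals)) || any(vals <= 0))
    return("all N3 parameters must be positive")
  if (object@maxIterations < 1L) return("maxIterations must be >= 1")
  TRUE
})

#' @rdname N3Config-class
#' @param endTolerance,maxIterations,signalThreshold,fieldDistance
#'   see slot documentation.
#' @param subsamplingFactor,kernelFWHM,wienerNoise,nBins see slots.
#' @return An \linkS4class{N3Config}.
#' @export
n3Config <- function(endTolerance = 1e-4, maxIterations = 100L,
                     signalThreshold = 1, fieldDistance = 25,
                     subsamplingFactor = 4L, kernelFWHM = 0.15,
                     wienerNoise = 0.01, nBins = 200L) {
  new("N3Config", endTolerance = endTolerance,
      maxIterations = as.integer(maxIterations),
      signalThreshold = signalThreshold, fieldDistance = fieldDistance,
      subsamplingFactor = as.integer(subsamplingFactor),
      kernelFWHM = kernelFWHM, wienerNoise = wienerNoise,
      nBins = as.integer(nBins))
}

#' Result of N3-style bias-field correction
#'
#' @slot corrected corrected image (input / field on foreground, input
#'   elsewhere).
#' @slot field multiplicative field, mean 1 over foreground, positive.
#' @slot iterations number of iterations run.
#' @slot converged whether the end tolerance was reached.
#' @slot cvHistory per-iteration coefficient of variation of the field
#'   change.
#' @export
setClass("BiasFieldResult",
  representation(
    corrected = "MRImage2D", field = "MRImage2D", iterations = "integer",
    converged = "logical", cvHistory = "numeric"))

#' Reference regions of interest for histogram thresholding
#'
#' Square ROIs of fixed physical area (default 25 mm^2): three on the pure
#' muscle reference (vastus intermedius) and three on subcutaneous fat.
#' Stored as 1-based top-left corners plus a common side length in pixels.
#'
#' @slot topLeft integer matrix (n x 2) of 1-based (row, col) corners.
#' @slot side integer side length in pixels.
#' @slot tag character, "muscle_reference" or "fat_reference" per ROI.
#' @slot spacing pixel spacing in mm.
#' @export
setClass("ROISet",
  representation(topLeft = "matrix", side = "integer", tag = "character",
                 spacing = "numeric"))

setValidity("ROISet", function(object) {
  if (nrow(object@topLeft) != length(object@tag))
    return("one tag per ROI required")
  if (!all(object@tag %in% c("muscle_reference", "fat_reference")))
    return("tags must be muscle_reference or fat_reference")
  if (object@side < 1L) return("ROI side must be >= 1 pixel")
  TRUE
})

#' Intensity histogram underlying a threshold
#'
#' @slot breaks bin edges (a.u.), length nbins + 1.
#' @slot counts bin counts.
#' @slot n total source pixel count.
#' @export
setClass("HistogramModel",
  representation(breaks = "numeric", counts = "numeric", n = "integer"))

setValidity("HistogramModel", function(object) {
  if (length(object@breaks) != length(object@counts) + 1L)
    return("breaks must have one more element than counts")
  if (abs(sum(object@counts) - object@n) > 0.5)
    return("counts must sum to the source pixel count")
  TRUE
})

#' Per-trial and mean Otsu thresholds
#'
#' @slot trials per-trial thresholds (a.u.).
#' @slot mean arithmetic mean of the trials (a.u.).
#' @export
setClass("ThresholdResult",
  representation(trials = "numeric", mean = "numeric"))

setValidity("ThresholdResult", function(object) {
  if (length(object@trials) < 1L) return("at least one trial required")
  if (abs(object@mean - mean(object@trials)) > 1e-9)
    return("mean must equal the arithmetic mean of the trials")
  TRUE
})
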