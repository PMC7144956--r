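#' Default mid-thigh geometry
#'
#' Parametric ellipse geometry (mm) of the synthetic axial mid-thigh slice:
#' outer thigh boundary, inner boundary of the subcutaneous fat ring, femur,
#' and four muscle compartments. Centers and semi-axes are in (row, col)
#' physical coordinates.
#'
#' @param fov field of view in mm (isotropic).
#' @return Named list of ellipses (center, radii in mm).
#' @export
thighGeometry <- function(fov = 256) {
  s <- fov / 256
  lapply(list(
    thigh  = list(center = c(128, 128), radii = c(88, 82)),
    ringIn = list(center = c(128, 128), radii = c(80, 74)),
    femur  = list(center = c(120, 125), radii = c(13, 13)),
    VL     = list(center = c(95, 90),  radii = c(26, 22)),
    VI     = list(center = c(100, 160), radii = c(26, 22)),
    AM     = list(center = c(165, 92), radii = c(26, 22)),
    BFL    = list(center = c(170, 160), radii = c(26, 22))
  ), function(e) list(center = e$center * s, radii = e$radii * s))
}

#' Specify a synthetic mid-thigh phantom
#'
#' Defaults define the reference study conditions: a 256 x 256 px slice at
#' 1 mm spacing, muscle/fat T1W intensities 100/200 a.u., additive noise sd
#' 5 a.u. (5\% of muscle signal), per-muscle fat fractions around the values
#' reported for healthy adult thighs (VL 12\%, AM 9\%, BF-L 13\%), 3 mm
#' infiltration marbling, a 2 px fat-dominant partial-volume band, and a
#' smooth multiplicative bias field of amplitude 0.2 at 60 mm scale.
#'
#' @param imageSize raster size (rows, cols).
#' @param spacing pixel spacing in mm.
#' @param geometry compartment geometry, see \code{\link{thighGeometry}}.
#' @param muscleMeanIntensity,fatMeanIntensity T1W tissue intensities
#'   (a.u.); fat must exceed muscle.
#' @param femurIntensity T1W signal of cortical bone (a.u.); near zero, as
#'   cortical bone contributes almost no MR signal. The marrow cavity is
#'   fat-bright.
#' @param protonSignal Dixon proton signal over tissue (a.u.).
#' @param noiseSD additive noise sd (a.u.).
#' @param rician use Rician (magnitude) instead of Gaussian T1W noise.
#' @param fatFraction named target fat fractions for VL, AM, BFL.
#' @param marblingScale correlation length of infiltration (mm).
#' @param partialVolumeWidth mixed band width around fat clusters (px).
#' @param partialVolumeExponent concavity of the band mixing profile.
#' @param biasAmplitude,biasScale bias-field peak deviation and scale (mm).
#' @param seed RNG seed.
#' @return A \linkS4class{PhantomSpec}.
#' @examples
#' spec <- phantomSpec(noiseSD = 0, biasAmplitude = 0)
#' ph <- makePhantom(spec)
#' truthP(ph)
#' @export
phantomSpec <- function(imageSize = c(256L, 256L), spacing = 1,
                        geometry = thighGeometry(max(imageSize) * spacing),
                        muscleMeanIntensity = 100, fatMeanIntensity = 200,
                        femurIntensity = 0, protonSignal = 100,
                        noiseSD = 5, rician = FALSE,
                        fatFraction = c(VL = 0.12, AM = 0.09, BFL = 0.13),
                        marblingScale = 3, partialVolumeWidth = 2,
                        partialVolumeExponent = 0.5,
                        biasAmplitude = 0.2, biasScale = 60,
                        seed = 1L) {
  new("PhantomSpec", imageSize = as.integer(imageSize),
      spacing = spacing, geometry = geometry,
      muscleMeanIntensity = muscleMeanIntensity,
      fatMeanIntensity = fatMeanIntensity,
      femurIntensity = femurIntensity, protonSignal = protonSignal,
      noiseSD = noiseSD, rician = rician,
      fatFraction = fatFraction[c("VL", "AM", "BFL")],
      marblingScale = marblingScale,
      partialVolumeWidth = partialVolumeWidth,
      partialVolumeExponent = partialVolumeExponent,
      biasAmplitude = biasAmplitude, biasScale = biasScale,
      seed = as.integer(seed))
}

#' Build the compartment label mask for a phantom spec
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return A \linkS4class{LabelMask}. Errors if any compartment overflows
#'   the image or the compartments overlap.
#' @export
phantomLabels <- function(spec) {
  dim <- spec@imageSize
  sp <- spec@spacing
  g <- spec@geometry
  msk <- function(nm) ellipseMask(dim, sp, g[[nm]]$center, g[[nm]]$radii)
  thigh <- msk("thigh"); inner <- msk("ringIn")
  muscles <- c("VL", "VI", "AM", "BFL")
  parts <- c(list(femur = msk("femur")), lapply(stats::setNames(muscles, muscles), msk))
  if (!all(inner[Reduce(`|`, parts)]))
    stop("geometry overflow: a compartment extends beyond the inner thigh")
  overlap <- Reduce(`+`, parts)
  if (any(overlap > 1)) stop("geometry overflow: compartments overlap")
  tab <- thighCompartments()
  lab <- matrix(0L, dim[1], dim[2])
  lab[thigh & !inner] <- tab[["subcutaneous_fat"]]
  lab[inner] <- 0L  # inner non-muscle tissue treated as background signal-free gap
  for (nm in muscles) lab[parts[[nm]]] <- tab[[nm]]
  lab[parts$femur] <- tab[["femur"]]
  LabelMask(lab, spacing = sp, table = tab)
}

#' Sample an exact-count binary fat mask inside a region
#'
#' Selects exactly \code{round(p * N)} pixels of the region (N = region
#' size) as fat: the top-ranked pixels of a Gaussian-smoothed noise field
#' with correlation length \code{marblingScale}, so infiltration is
#' spatially clustered ("marbled"); \code{marblingScale = 0} gives i.i.d.
#' selection. Ties in the ranking are broken by pixel index order, so the
#' realized fraction is quantized, never an expected value.
#'
#' @param region logical matrix marking the region (nonempty).
#' @param p target fat fraction in [0, 1].
#' @param marblingScale correlation length in mm.
#' @param spacing pixel spacing in mm.
#' @return Logical matrix with exactly \code{round(p * sum(region))} TRUE
#'   pixels, all inside the region.
#' @export
sampleFatMask <- function(region, p, marblingScale = 0, spacing = 1) {
  if (!any(region)) stop("empty region")
  if (p < 0 || p > 1) stop("fat fraction must lie in [0, 1]")
  N <- sum(region)
  k <- round(p * N)
  out <- matrix(FALSE, nrow(region), ncol(region))
  if (k == 0) return(out)
  noise <- matrix(stats::rnorm(length(region)), nrow(region))
  if (marblingScale > 0)
    noise <- gaussSmooth(noise, marblingScale / spacing)
  vals <- noise[region]
  ord <- order(vals, seq_along(vals), decreasing = c(TRUE, FALSE),
               method = "radix")
  sel <- which(region)[ord[seq_len(k)]]
  out[sel] <- TRUE
  out
}

#' Apply a smooth multiplicative bias field
#'
#' Generates a smooth positive field as the exponential of a
#' Gaussian-smoothed white-noise field, affinely rescaled so that its mean
#' is exactly 1 and its maximum absolute deviation from 1 equals
#' \code{amplitude}, then multiplies the image by it.
#'
#' @param image matrix or \linkS4class{MRImage2D}.
#' @param amplitude peak deviation from 1 (in [0, 1)).
#' @param scale spatial scale of the field in mm.
#' @param spacing pixel spacing in mm (taken from the image if available).
#' @param seed optional RNG seed.
#' @return List with \code{image} (biased) and \code{field}; both matrices,
#'   or \linkS4class{MRImage2D} if the input was one.
#' @export
applyBiasField <- function(image, amplitude, scale, spacing = NULL,
                           seed = NULL) {
  if (amplitude < 0 || amplitude >= 1)
    stop("amplitude must lie in [0, 1)")
  sp <- .spacingOf(image, spacing)
  m <- .asMatrix(image)
  field <- withSeed(seed, {
    if (amplitude == 0) {
      matrix(1, nrow(m), ncol(m))
    } else {
      z <- gaussSmooth(matrix(stats::rnorm(length(m)), nrow(m)), scale / sp)
      f <- exp(z)
      dev <- f - mean(f)
      md <- max(abs(dev))
      if (md == 0) matrix(1, nrow(m), ncol(m))
      else 1 + amplitude * dev / md
    }
  })
  biased <- m * field
  if (is(image, "MRImage2D")) {
    biased <- MRImage2D(biased, sp)
    field <- MRImage2D(field, sp)
  }
  list(image = biased, field = field)
}

#' Generate a paired T1W/Dixon phantom with exact ground truth
#'
#' Deterministic given the spec's seed. The noiseless latent slice is built
#' first: each infiltrated muscle receives an exact-count marbled fat mask
#' (\code{\link{sampleFatMask}}); fat pixels take the fat intensity, muscle
#' pixels the muscle intensity; a band of width \code{partialVolumeWidth}
#' around each fat cluster is linearly mixed in intensity and fat fraction
#' according to a fat-dominant distance profile
#' \code{alpha(d) = (1 - d/(w+1))^q}. The vastus intermedius is kept
#' fat-free as the pure-muscle reference. Dixon channels use a uniform
#' proton signal S over tissue: water = S(1 - ff), fat = S ff, so the two
#' channels sum to S exactly in the noiseless latent. The T1W channel is
#' latent x bias field plus noise; Dixon channels receive independent noise
#' of the same sd.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return A \linkS4class{ThighPhantom}.
#' @export
makePhantom <- function(spec) {
  validObject(spec)
  withSeed(spec@seed, .makePhantom(spec))
}

.makePhantom <- function(spec) {
  labels <- phantomLabels(spec)
  lab <- labels@data
  tab <- labels@table
  dimm <- dim(lab)
  sp <- spec@spacing

  ff <- matrix(0, dimm[1], dimm[2])
  latent <- matrix(0, dimm[1], dimm[2])
  S <- matrix(0, dimm[1], dimm[2])
  tissue <- lab != tab[["background"]]
  S[tissue] <- spec@protonSignal
  latent[lab %in% tab[c("VL", "VI", "AM", "BFL")]] <-
    spec@muscleMeanIntensity
  latent[lab == tab[["subcutaneous_fat"]]] <- spec@fatMeanIntensity
  ff[lab == tab[["subcutaneous_fat"]]] <- 1
  # femur: signal-poor cortical shell around a fat-bright marrow cavity
  femur <- lab == tab[["femur"]]
  g <- spec@geometry$femur
  marrow <- ellipseMask(dimm, sp, g$center, pmax(g$radii - 4, 1)) & femur
  cortex <- femur & !marrow
  latent[cortex] <- spec@femurIntensity
  S[cortex] <- spec@femurIntensity
  latent[marrow] <- spec@fatMeanIntensity
  S[marrow] <- spec@protonSignal
  ff[marrow] <- 1

  p <- c(spec@fatFraction, VI = 0)
  truth <- numeric(0)
  w <- spec@partialVolumeWidth
  q <- spec@partialVolumeExponent
  for (nm in c("VL", "VI", "AM", "BFL")) {
    region <- lab == tab[[nm]]
    fatMask <- sampleFatMask(region, p[[nm]], spec@marblingScale, sp)
    ff[fatMask] <- 1
    latent[fatMask] <- spec@fatMeanIntensity
    truth[nm] <- sum(fatMask) / sum(region)
    if (w > 0 && any(fatMask)) {
      d <- distToMask(fatMask, w)
      band <- region & !fatMask & is.finite(d) & d <= w
      if (any(band)) {
        alpha <- (1 - d[band] / (w + 1))^q
        ff[band] <- alpha
        latent[band] <- spec@muscleMeanIntensity +
          alpha * (spec@fatMeanIntensity - spec@muscleMeanIntensity)
      }
    }
  }

  # bias amplitude is referenced to tissue: the peak deviation the anatomy
  # experiences, not a background corner of the raster
  field <- .tissueBiasField(dimm, spec@biasAmplitude, spec@biasScale, sp,
                            tissue)
  n <- length(latent)
  t1wSignal <- latent * field
  if (spec@noiseSD > 0) {
    if (spec@rician) {
      t1w <- sqrt((t1wSignal + stats::rnorm(n, 0, spec@noiseSD))^2 +
                  stats::rnorm(n, 0, spec@noiseSD)^2)
    } else {
      t1w <- t1wSignal + stats::rnorm(n, 0, spec@noiseSD)
    }
    water <- S * (1 - ff) + stats::rnorm(n, 0, spec@noiseSD)
    fat <- S * ff + stats::rnorm(n, 0, spec@noiseSD)
  } else {
    t1w <- t1wSignal
    water <- S * (1 - ff)
    fat <- S * ff
  }

  new("ThighPhantom",
      t1w = MRImage2D(matrix(t1w, dimm[1]), sp),
      water = MRImage2D(matrix(water, dimm[1]), sp),
      fat = MRImage2D(matrix(fat, dimm[1]), sp),
      labels = labels,
      truthFatFraction = MRImage2D(ff, sp),
      truthBias = MRImage2D(field, sp),
      truthP = truth, spec = spec)
}

# Smooth positive multiplicative field with mean 1 over the tissue mask and
# max|field - 1| = amplitude attained on tissue.
.tissueBiasField <- function(dimm, amplitude, scale, spacing, tissue) {
  if (amplitude == 0) return(matrix(1, dimm[1], dimm[2]))
  z <- gaussSmooth(matrix(stats::rnorm(prod(dimm)), dimm[1]),
                   scale / spacing)
  f <- exp(z)
  dev <- f - mean(f[tissue])
  md <- max(abs(dev[tissue]))
  if (md == 0) return(matrix(1, dimm[1], dimm[2]))
  1 + amplitude * dev / md
}
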