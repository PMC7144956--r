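#' Read a 2-D image with physical spacing
#'
#' NIfTI files carry their pixel spacing in the header; TIFF files do not,
#' so \code{spacing} is then required. 3-D NIfTI volumes with a singleton
#' dimension are squeezed; otherwise a slice index must be given.
#'
#' @param path file path (.nii, .nii.gz, .tif, .tiff).
#' @param spacing pixel spacing in mm; overrides the header, required for
#'   TIFF.
#' @param slice slice index for 3-D NIfTI input.
#' @return An \linkS4class{MRImage2D}.
#' @export
readImage2D <- function(path, spacing = NULL, slice = NULL) {
  ext <- tolower(sub(".*\\.(nii(\\.gz)?|tiff?)$", "\\1", path))
  if (ext %in% c("nii", "nii.gz")) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    pd <- RNifti::pixdim(img)
    if (length(dim(arr)) == 3L) {
      if (any(dim(arr) == 1L)) {
        arr <- array(arr, dim(arr)[dim(arr) > 1L])
      } else if (!is.null(slice)) {
        arr <- arr[, , slice]
      } else {
        stop("3-D input: a slice index is required")
      }
    }
    if (length(dim(arr)) != 2L) stop("input does not reduce to 2-D")
    sp <- if (!is.null(spacing)) spacing else pd[1]
    if (!is.finite(sp) || sp <= 0) stop("missing or invalid pixel spacing")
    MRImage2D(matrix(as.numeric(arr), nrow(arr)), sp)
  } else if (ext %in% c("tif", "tiff")) {
    if (is.null(spacing))
      stop("pixel spacing is required for TIFF input")
    arr <- tiff::readTIFF(path, as.is = FALSE)
    if (length(dim(arr)) == 3L) arr <- arr[, , 1]
    MRImage2D(arr, spacing)
  } else {
    stop("unknown image format: ", path)
  }
}

#' Write a 2-D image
#'
#' NIfTI output stores the spacing in the header (float32 by default;
#' float64 via \code{datatype = "double"}). TIFF output writes 32-bit
#' float samples and requires values in [0, 1] (fat-fraction maps); other
#' images should use NIfTI.
#'
#' @param image an \linkS4class{MRImage2D}.
#' @param path output path (.nii, .nii.gz or .tif).
#' @param datatype NIfTI on-disk datatype, "float" or "double".
#' @return The path, invisibly.
#' @export
writeImage2D <- function(image, path, datatype = "float") {
  ext <- tolower(sub(".*\\.(nii(\\.gz)?|tiff?)$", "\\1", path))
  if (ext %in% c("nii", "nii.gz")) {
    m <- imageData(image)
    attr(m, "pixdim") <- rep(pixelSpacing(image), 2)
    RNifti::writeNifti(RNifti::asNifti(m, datatype = datatype), path)
  } else if (ext %in% c("tif", "tiff")) {
    m <- imageData(image)
    if (any(m < 0 | m > 1, na.rm = TRUE))
      stop("TIFF output supports [0, 1] data only; use NIfTI instead")
    m[is.na(m)] <- 0
    tiff::writeTIFF(m, path, bits.per.sample = 32L)
  } else {
    stop("unknown image format: ", path)
  }
  invisible(path)
}

#' Read and write label masks
#'
#' Labels are stored as integer NIfTI rasters.
#'
#' @param path file path.
#' @param spacing spacing override in mm.
#' @param table compartment table (names to ids).
#' @return A \linkS4class{LabelMask}.
#' @export
readLabelMask <- function(path, spacing = NULL,
                          table = thighCompartments()) {
  img <- readImage2D(path, spacing = spacing)
  LabelMask(round(imageData(img)), pixelSpacing(img), table = table)
}

#' @rdname readLabelMask
#' @param labels a \linkS4class{LabelMask} to write.
#' @export
writeLabelMask <- function(labels, path) {
  m <- labels@data
  attr(m, "pixdim") <- rep(labels@spacing, 2)
  RNifti::writeNifti(RNifti::asNifti(m, datatype = "int16"), path)
  invisible(path)
}

#' Write a phantom set to a directory
#'
#' One NIfTI file per channel plus the labels, the truth rasters, and the
#' realized per-muscle fat fractions as CSV.
#'
#' @param phantom a \linkS4class{ThighPhantom}.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writePhantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeImage2D(phantom@t1w, file.path(dir, "t1w.nii.gz"),
               datatype = "double")
  writeImage2D(phantom@water, file.path(dir, "water.nii.gz"),
               datatype = "double")
  writeImage2D(phantom@fat, file.path(dir, "fat.nii.gz"),
               datatype = "double")
  writeLabelMask(phantom@labels, file.path(dir, "labels.nii.gz"))
  writeImage2D(phantom@truthFatFraction,
               file.path(dir, "truth_fat_fraction.nii.gz"),
               datatype = "double")
  writeImage2D(phantom@truthBias, file.path(dir, "truth_bias.nii.gz"),
               datatype = "double")
  utils::write.csv(
    data.frame(muscle = names(phantom@truthP), p = unname(phantom@truthP)),
    file.path(dir, "truth_p.csv"), row.names = FALSE)
  invisible(dir)
}

# CSV with a provenance comment line (config hash + seed); read back with
# readStageCSV().
writeStageCSV <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# imatQuant config=%s seed=%s", hash,
                     paste(seed, collapse = ",")), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline stage CSV
#'
#' @param path CSV written by the pipeline (leading provenance comment).
#' @return data.frame.
#' @export
readStageCSV <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
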