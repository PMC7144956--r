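#' @rdname accessors
#' @aliases imageData,MRImage2D-method
setMethod("imageData", "MRImage2D", function(object) object@data)

#' @rdname accessors
setMethod("imageData", "LabelMask", function(object) object@data)

#' @rdname accessors
setMethod("pixelSpacing", "MRImage2D", function(object) object@spacing)

#' @rdname accessors
setMethod("pixelSpacing", "LabelMask", function(object) object@spacing)

#' @rdname accessors
setMethod("pixelSpacing", "ThighPhantom",
          function(object) object@t1w@spacing)

#' @rdname accessors
setMethod("compartmentTable", "LabelMask", function(object) object@table)

#' @rdname accessors
setMethod("compartmentTable", "ThighPhantom",
          function(object) object@labels@table)

#' @rdname accessors
#' @param name compartment name, e.g. \code{"VL"}.
setMethod("compartmentMask", "LabelMask", function(object, name) {
  id <- object@table[[name]]
  if (is.null(id)) stop("unknown compartment: ", name)
  object@data == id
})

#' @rdname accessors
setMethod("compartmentMask", "ThighPhantom",
          function(object, name) compartmentMask(object@labels, name))

#' @rdname accessors
setMethod("truthP", "ThighPhantom", function(object) object@truthP)

#' @rdname accessors
setMethod("biasField", "ThighPhantom", function(object) object@truthBias)

#' @rdname accessors
setMethod("biasField", "BiasFieldResult", function(object) object@field)

#' @rdname accessors
setMethod("correctedImage", "BiasFieldResult",
          function(object) object@corrected)

#' @rdname accessors
setMethod("thresholdMean", "ThresholdResult", function(object) object@mean)

#' @rdname accessors
setMethod("trialThresholds", "ThresholdResult",
          function(object) object@trials)

setMethod("show", "MRImage2D", function(object) {
  d <- dim(object@data)
  cat(sprintf("MRImage2D: %d x %d px @ %.3g mm (range %.4g..%.4g a.u.)\n",
              d[1], d[2], object@spacing,
              min(object@data, na.rm = TRUE),
              max(object@data, na.rm = TRUE)))
})

setMethod("show", "LabelMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("LabelMask: %d x %d px @ %.3g mm\n", d[1], d[2],
              object@spacing))
  tab <- table(factor(object@data, levels = object@table,
                      labels = names(object@table)))
  print(tab)
})

setMethod("show", "ThighPhantom", function(object) {
  d <- dim(object@t1w@data)
  cat(sprintf("ThighPhantom: %d x %d px @ %.3g mm, seed %d\n",
              d[1], d[2], pixelSpacing(object), object@spec@seed))
  cat("realized fat pixel fractions:\n")
  print(round(object@truthP, 4))
})

setMethod("show", "BiasFieldResult", function(object) {
  cat(sprintf(
    "BiasFieldResult: %d iteration(s), %s (field range %.4f..%.4f)\n",
    object@iterations,
    if (object@converged) "converged" else "not converged",
    min(object@field@data), max(object@field@data)))
})

setMethod("show", "ThresholdResult", function(object) {
  cat(sprintf("ThresholdResult: mean %.4g a.u. over %d trial(s) [%s]\n",
              object@mean, length(object@trials),
              paste(signif(object@trials, 5), collapse = ", ")))
})

setMethod("show", "ROISet", function(object) {
  cat(sprintf("ROISet: %d ROIs of %d x %d px @ %.3g mm\n",
              nrow(object@topLeft), object@side, object@side,
              object@spacing))
  print(table(object@tag))
})
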