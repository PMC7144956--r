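#' Accessors for imatQuant objects
#'
#' @param object an imatQuant S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imageData", function(object) standardGeneric("imageData"))

#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(object) standardGeneric("pixelSpacing"))

#' @rdname accessors
#' @export
setGeneric("compartmentTable",
           function(object) standardGeneric("compartmentTable"))

#' @rdname accessors
#' @export
setGeneric("compartmentMask",
           function(object, name) standardGeneric("compartmentMask"))

#' @rdname accessors
#' @export
setGeneric("truthP", function(object) standardGeneric("truthP"))

#' @rdname accessors
#' @export
setGeneric("biasField", function(object) standardGeneric("biasField"))

#' @rdname accessors
#' @export
setGeneric("correctedImage",
           function(object) standardGeneric("correctedImage"))

#' @rdname accessors
#' @export
setGeneric("thresholdMean",
           function(object) standardGeneric("thresholdMean"))

#' @rdname accessors
#' @export
setGeneric("trialThresholds",
           function(object) standardGeneric("trialThresholds"))
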