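#' Accessors for SigmaField, EyeshineStack and HexROIGrid
#'
#' Accessor generics for the package's central S4 containers. Slot access is
#' never needed in user code.
#'
#' @param object A [SigmaField-class], [EyeshineStack-class] or
#'   [HexROIGrid-class] object, as appropriate.
#' @param value Replacement value.
#' @param ... Additional arguments passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sigmaValues", function(object) standardGeneric("sigmaValues"))

#' @rdname accessors
#' @export
setGeneric("isMeasured", function(object) standardGeneric("isMeasured"))

#' @rdname accessors
#' @export
setGeneric("isMeasured<-",
  function(object, value) standardGeneric("isMeasured<-"))

#' @rdname accessors
#' @export
setGeneric("latticeCoords", function(object) standardGeneric("latticeCoords"))

#' @rdname accessors
#' @export
setGeneric("patchMetadata", function(object) standardGeneric("patchMetadata"))

#' @rdname accessors
#' @export
setGeneric("rollAngles", function(object) standardGeneric("rollAngles"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("frameData",
  function(object, ...) standardGeneric("frameData"))

#' @rdname accessors
#' @export
setGeneric("spotCenters", function(object) standardGeneric("spotCenters"))

#' @rdname accessors
#' @export
setGeneric("roiCenters", function(object) standardGeneric("roiCenters"))

#' @rdname accessors
#' @export
setGeneric("roiRadius", function(object) standardGeneric("roiRadius"))

#' @rdname accessors
#' @export
setMethod("sigmaValues", "SigmaField", function(object) object@sigma)

#' @rdname accessors
#' @export
setMethod("isMeasured", "SigmaField", function(object) object@measured)

#' Mark ommatidia as unmeasured
#'
#' Replacing \code{isMeasured} demotes cells (e.g. ommatidia whose optical
#' axis falls outside the illumination cone); demoted cells get \code{NA}
#' Sigma.
#'
#' @rdname accessors
#' @export
setMethod("isMeasured<-", "SigmaField", function(object, value) {
  value <- rep_len(as.logical(value), nrow(object@coords))
  object@measured <- value
  object@sigma[!value] <- NA_real_
  validObject(object)
  object
})

#' @rdname accessors
#' @export
setMethod("latticeCoords", "SigmaField", function(object) object@coords)

#' @rdname accessors
#' @export
setMethod("patchMetadata", "SigmaField", function(object) object@metadata)

#' @rdname accessors
#' @export
setMethod("rollAngles", "EyeshineStack", function(object) object@thetas)

#' @rdname accessors
#' @export
setMethod("channelNames", "EyeshineStack", function(object) object@channels)

#' @param channel Channel name for \code{frameData}.
#' @rdname accessors
#' @export
setMethod("frameData", "EyeshineStack", function(object, channel = "R") {
  if (!channel %in% object@channels)
    stop("channel '", channel, "' absent from stack (has: ",
      paste(object@channels, collapse = ", "), ")")
  object@frames[[channel]]
})

#' @rdname accessors
#' @export
setMethod("spotCenters", "EyeshineStack", function(object) object@centers)

#' @rdname accessors
#' @export
setMethod("roiCenters", "HexROIGrid", function(object) object@centers)

#' @rdname accessors
#' @export
setMethod("roiRadius", "HexROIGrid", function(object) object@radius)
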