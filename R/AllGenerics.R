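#' Voxel data of a volume or mask
#' @param x A [CTVolume-class] or [CTMask-class].
#' @return The underlying 3-D array.
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' Voxel spacing in mm
#' @param x A [CTVolume-class], [CTMask-class] or [SubjectPair-class].
#' @return Numeric length-3 spacing in mm.
#' @export
setGeneric("spacingMM", function(x) standardGeneric("spacingMM"))

#' Mask volume in millilitres
#'
#' Voxel count times the physical voxel volume in mm^3, divided by 1000.
#'
#' @param x A [CTMask-class] or [SegmentationResult-class].
#' @return Volume in mL.
#' @examples
#' m <- newMask(array(c(rep(1, 1000), rep(0, 24^3 - 1000)), dim = c(24, 24, 24)),
#'              spacing = c(1, 1, 1))
#' volumeML(m) # 1 mL
#' @export
setGeneric("volumeML", function(x) standardGeneric("volumeML"))

#' @rdname voxelData
#' @export
setMethod("voxelData", "CTVolume", function(x) x@values)
#' @rdname voxelData
#' @export
setMethod("voxelData", "CTMask", function(x) x@values)

#' @rdname spacingMM
#' @export
setMethod("spacingMM", "CTVolume", function(x) x@spacing)
#' @rdname spacingMM
#' @export
setMethod("spacingMM", "CTMask", function(x) x@spacing)
#' @rdname spacingMM
#' @export
setMethod("spacingMM", "SubjectPair", function(x) x@baseline@spacing)

#' @rdname volumeML
#' @export
setMethod("volumeML", "CTMask", function(x) {
    sum(x@values) * prod(x@spacing) / 1000
})
#' @rdname volumeML
#' @export
setMethod("volumeML", "SegmentationResult", function(x) x@volumeML)

#' Construct a CTVolume
#' @param values 3-D numeric array (Hounsfield units or normalized).
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @param origin Numeric length-3 origin in mm.
#' @return A [CTVolume-class].
#' @export
newVolume <- function(values, spacing, origin = c(0, 0, 0)) {
    new("CTVolume", values = values, spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

#' Construct a CTMask
#' @param values 3-D array coercible to 0/1.
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @param origin Numeric length-3 origin in mm.
#' @return A [CTMask-class].
#' @export
newMask <- function(values, spacing, origin = c(0, 0, 0)) {
    storage.mode(values) <- "integer"
    new("CTMask", values = values, spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

#' Accessors for SubjectPair components
#' @param x A [SubjectPair-class].
#' @return The requested component.
#' @export
setGeneric("baselineScan", function(x) standardGeneric("baselineScan"))
#' @rdname baselineScan
#' @export
setGeneric("followupScan", function(x) standardGeneric("followupScan"))
#' @rdname baselineScan
#' @export
setGeneric("truthMasks", function(x) standardGeneric("truthMasks"))
#' @rdname baselineScan
#' @export
setGeneric("trueDeltaML", function(x) standardGeneric("trueDeltaML"))
#' @rdname baselineScan
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname baselineScan
#' @export
setMethod("baselineScan", "SubjectPair", function(x) x@baseline)
#' @rdname baselineScan
#' @export
setMethod("followupScan", "SubjectPair", function(x) x@followup)
#' @rdname baselineScan
#' @export
setMethod("truthMasks", "SubjectPair", function(x)
    list(baseline = x@truthMaskBaseline, followup = x@truthMaskFollowup))
#' @rdname baselineScan
#' @export
setMethod("trueDeltaML", "SubjectPair", function(x) x@trueDeltaML)
#' @rdname baselineScan
#' @export
setMethod("subjectId", "SubjectPair", function(x) x@subjectId)

#' Predicted mask of a segmentation result
#' @param x A [SegmentationResult-class].
#' @return The predicted [CTMask-class].
#' @export
setGeneric("predictedMask", function(x) standardGeneric("predictedMask"))
#' @rdname predictedMask
#' @export
setMethod("predictedMask", "SegmentationResult", function(x) x@predictedMask)

#' Cut value of a calibrated operating point
#' @param x A [ThresholdSpec-class].
#' @return The score cut.
#' @export
setGeneric("cutValue", function(x) standardGeneric("cutValue"))
#' @rdname cutValue
#' @export
setMethod("cutValue", "ThresholdSpec", function(x) x@cutValue)
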