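#' @import methods
NULL

#' 3-D CT volume in Hounsfield units
#'
#' A scalar voxel grid with physical spacing and origin. This is the raw or
#' preprocessed scan: values are Hounsfield units (water 0, air about -1000,
#' bone about +1000) unless the volume has been window-normalized to
#' \eqn{[0,1]}.
#'
#' @slot values 3-D numeric array of voxel intensities.
#' @slot spacing Numeric length-3, voxel edge lengths in mm (strictly positive).
#' @slot origin Numeric length-3, physical position of the first voxel in mm.
#'
#' @seealso [CTMask-class], [makePhantom()]
#' @export
setClass("CTVolume",
    representation(values = "array", spacing = "numeric", origin = "numeric"),
    prototype(origin = c(0, 0, 0))
)

setValidity("CTVolume", function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3L)
        msg <- c(msg, "values must be a 3-D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        msg <- c(msg, "spacing must be 3 strictly positive finite numbers")
    if (length(object@origin) != 3L)
        msg <- c(msg, "origin must have length 3")
    if (anyNA(object@values))
        msg <- c(msg, "values must not contain NA")
    if (length(msg)) msg else TRUE
})

#' Binary mask aligned to a CT volume
#'
#' Hematoma or brain mask on the same grid as its [CTVolume-class]. Voxel
#' values are exactly 0 or 1.
#'
#' @slot values 3-D array with values in \{0, 1\}.
#' @slot spacing Numeric length-3 voxel spacing in mm.
#' @slot origin Numeric length-3 origin in mm.
#' @export
setClass("CTMask",
    representation(values = "array", spacing = "numeric", origin = "numeric"),
    prototype(origin = c(0, 0, 0))
)

setValidity("CTMask", function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3L)
        msg <- c(msg, "values must be a 3-D array")
    if (!all(object@values %in% c(0, 1)))
        msg <- c(msg, "mask values must be 0 or 1")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
        msg <- c(msg, "spacing must be 3 strictly positive numbers")
    if (length(msg)) msg else TRUE
})

#' Paired baseline/follow-up subject
#'
#' The atomic cohort element: baseline and follow-up scans, their ground-truth
#' hematoma masks, and the true absolute expansion in mL.
#'
#' @slot baseline,followup [CTVolume-class] scans sharing anatomy.
#' @slot truthMaskBaseline,truthMaskFollowup Ground-truth [CTMask-class]
#'   hematoma masks aligned to their scans.
#' @slot trueDeltaML True absolute hematoma expansion
#'   (follow-up minus baseline) in mL.
#' @slot subjectId Character identifier.
#' @slot seed Integer seed the pair was generated from.
#' @export
setClass("SubjectPair",
    representation(
        baseline = "CTVolume", followup = "CTVolume",
        truthMaskBaseline = "CTMask", truthMaskFollowup = "CTMask",
        trueDeltaML = "numeric", subjectId = "character", seed = "integer"
    )
)

setValidity("SubjectPair", function(object) {
    msg <- character()
    if (!identical(dim(object@baseline@values), dim(object@truthMaskBaseline@values)))
        msg <- c(msg, "baseline mask must match baseline scan shape")
    if (!identical(dim(object@followup@values), dim(object@truthMaskFollowup@values)))
        msg <- c(msg, "follow-up mask must match follow-up scan shape")
    if (!isTRUE(all.equal(object@baseline@spacing, object@truthMaskBaseline@spacing)))
        msg <- c(msg, "baseline mask spacing must match scan spacing")
    if (length(object@trueDeltaML) != 1L || !is.finite(object@trueDeltaML))
        msg <- c(msg, "trueDeltaML must be a single finite number")
    if (length(msg)) msg else TRUE
})

#' Result of running a segmentation engine on one scan
#'
#' @slot predictedMask Predicted [CTMask-class] in the scan's native space.
#' @slot volumeML Predicted hematoma volume in mL
#'   (voxel count x voxel volume / 1000).
#' @slot diceVsTruth Dice against the ground-truth mask, or `NA` when no
#'   truth is available.
#' @slot engine `"unet"` or `"oracle"`.
#' @export
setClass("SegmentationResult",
    representation(
        predictedMask = "CTMask", volumeML = "numeric",
        diceVsTruth = "numeric", engine = "character"
    )
)

setValidity("SegmentationResult", function(object) {
    v <- volumeML(object@predictedMask)
    if (abs(v - object@volumeML) > 1e-8)
        return("volumeML must equal voxel count x voxel volume / 1000")
    TRUE
})

#' Review-triage accounting at one operating point
#'
#' Confusion counts before expert review, the review burden implied by the
#' review policy, and the error rates that remain after reviewed subjects are
#' corrected. With a positives-review policy and a perfect reviewer, the final
#' errors are exactly the unreviewed false negatives; symmetrically for a
#' negatives-review policy.
#'
#' @slot n Cohort size.
#' @slot counts Named integer vector `c(tp, fp, tn, fn)` before review.
#' @slot reviewCount Number of subjects routed to expert review.
#' @slot reviewFraction,excludedFraction Proportions of the cohort reviewed /
#'   spared; they sum to 1.
#' @slot postReviewCounts Named integer vector `c(tp, fp, tn, fn)` after
#'   review corrections.
#' @slot finalAccuracy,finalFnRate,finalFpRate Post-review rates over all `n`.
#' @slot policy `"positives"` or `"negatives"`.
#' @export
setClass("TriageReport",
    representation(
        n = "integer", counts = "integer", reviewCount = "integer",
        reviewFraction = "numeric", excludedFraction = "numeric",
        postReviewCounts = "integer", finalAccuracy = "numeric",
        finalFnRate = "numeric", finalFpRate = "numeric", policy = "character"
    )
)

setValidity("TriageReport", function(object) {
    msg <- character()
    if (sum(object@counts) != object@n)
        msg <- c(msg, "pre-review counts must sum to n")
    if (sum(object@postReviewCounts) != object@n)
        msg <- c(msg, "post-review counts must sum to n")
    if (abs(object@reviewFraction + object@excludedFraction - 1) > 1e-12)
        msg <- c(msg, "reviewFraction + excludedFraction must equal 1")
    if (length(msg)) msg else TRUE
})

#' Calibrated operating point
#'
#' A score cut chosen on a calibration cohort for a target sensitivity or
#' specificity (or for maximum accuracy / F1). The prediction rule is
#' `score >= cutValue` (ties at the cut are positive).
#'
#' @slot heThresholdML HE definition the scores address (3, 6, 9 or 12.5 mL).
#' @slot mode `"sensitivity"`, `"specificity"`, `"max_accuracy"` or `"max_f1"`.
#' @slot target Target level in (0, 1] for the first two modes, `NA` otherwise.
#' @slot cutValue The chosen cut, in score units.
#' @slot calibrationCohort Name of the cohort the cut was fitted on.
#' @export
setClass("ThresholdSpec",
    representation(
        heThresholdML = "numeric", mode = "character", target = "numeric",
        cutValue = "numeric", calibrationCohort = "character"
    ),
    prototype(heThresholdML = NA_real_, target = NA_real_,
              calibrationCohort = "calibration")
)

setValidity("ThresholdSpec", function(object) {
    msg <- character()
    if (!object@mode %in% c("sensitivity", "specificity", "max_accuracy", "max_f1"))
        msg <- c(msg, "unknown mode")
    needs <- object@mode %in% c("sensitivity", "specificity")
    if (needs && (is.na(object@target) || object@target <= 0 || object@target > 1))
        msg <- c(msg, "target must be in (0, 1] for sensitivity/specificity modes")
    if (!needs && !is.na(object@target))
        msg <- c(msg, "target must be absent for max_accuracy/max_f1 modes")
    if (length(msg)) msg else TRUE
})

setMethod("show", "CTVolume", function(object) {
    d <- dim(object@values)
    cat(sprintf("CTVolume %dx%dx%d, spacing %.3gx%.3gx%.3g mm, HU range [%.4g, %.4g]\n",
        d[1], d[2], d[3], object@spacing[1], object@spacing[2], object@spacing[3],
        min(object@values), max(object@values)))
})

setMethod("show", "CTMask", function(object) {
    d <- dim(object@values)
    cat(sprintf("CTMask %dx%dx%d, spacing %.3gx%.3gx%.3g mm, %d voxels (%.2f mL)\n",
        d[1], d[2], d[3], object@spacing[1], object@spacing[2], object@spacing[3],
        sum(object@values), volumeML(object)))
})

setMethod("show", "SubjectPair", function(object) {
    cat(sprintf("SubjectPair '%s': V_baseline %.2f mL, V_followup %.2f mL, true delta %.2f mL\n",
        object@subjectId, volumeML(object@truthMaskBaseline),
        volumeML(object@truthMaskFollowup), object@trueDeltaML))
})

setMethod("show", "SegmentationResult", function(object) {
    cat(sprintf("SegmentationResult [%s]: %.2f mL%s\n", object@engine, object@volumeML,
        if (is.na(object@diceVsTruth)) "" else sprintf(", Dice vs truth %.3f", object@diceVsTruth)))
})

setMethod("show", "TriageReport", function(object) {
    ct <- object@counts
    cat(sprintf("TriageReport (n = %d, review %s)\n", object@n, object@policy))
    cat(sprintf("  pre-review : TP %d  FP %d  TN %d  FN %d\n",
        ct["tp"], ct["fp"], ct["tn"], ct["fn"]))
    cat(sprintf("  review     : %d subjects (%.1f%%), %.1f%% excluded\n",
        object@reviewCount, 100 * object@reviewFraction, 100 * object@excludedFraction))
    cat(sprintf("  final      : accuracy %.2f%%, FN rate %.2f%%, FP rate %.2f%%\n",
        100 * object@finalAccuracy, 100 * object@finalFnRate, 100 * object@finalFpRate))
})

setMethod("show", "ThresholdSpec", function(object) {
    tgt <- if (is.na(object@target)) "" else sprintf(" target %.2f", object@target)
    cat(sprintf("ThresholdSpec: mode %s%s, cut %.4g (fitted on '%s')\n",
        object@mode, tgt, object@cutValue, object@calibrationCohort))
})
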