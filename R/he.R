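#' The four absolute hematoma-expansion thresholds (mL)
#'
#' Absolute volume increases of >= 3, 6, 9 and 12.5 mL define the binary
#' expansion outcomes used throughout the package. Relative (>= 33%)
#' definitions are deliberately excluded: they are unstable for small
#' baseline hematomas where minor volumetry errors swing the ratio.
#' @export
HE_THRESHOLDS_ML <- c(3, 6, 9, 12.5)

#' Absolute hematoma expansion
#'
#' `V_followup - V_baseline` in mL. Antisymmetric in its arguments.
#'
#' @param v_baseline_ml,v_followup_ml Hematoma volumes in mL (>= 0).
#' @return Signed volume difference in mL.
#' @examples
#' absoluteHE(10, 17.2) # 7.2
#' @export
absoluteHE <- function(v_baseline_ml, v_followup_ml) {
    if (any(v_baseline_ml < 0) || any(v_followup_ml < 0))
        stop("volumes must be >= 0")
    v_followup_ml - v_baseline_ml
}

#' Binarize an absolute expansion at the four HE thresholds
#'
#' Thresholds are inclusive (`delta >= t`), so the labels nest monotonically:
#' a >= 12.5 mL expansion is also a >= 9, >= 6 and >= 3 mL expansion.
#'
#' @param delta_ml Absolute expansion in mL (any sign).
#' @return A list of class `HeLabelSet` with `delta_ml` and integer fields
#'   `label_3`, `label_6`, `label_9`, `label_12_5`.
#' @examples
#' binarizeHE(7.2)  # labels (1, 1, 0, 0)
#' binarizeHE(12.5) # labels (1, 1, 1, 1)
#' @export
binarizeHE <- function(delta_ml) {
    assertScalar(delta_ml, "delta_ml")
    lab <- as.integer(delta_ml >= HE_THRESHOLDS_ML)
    structure(list(delta_ml = delta_ml, label_3 = lab[1], label_6 = lab[2],
                   label_9 = lab[3], label_12_5 = lab[4]),
              class = "HeLabelSet")
}

#' Label a cohort at all four HE thresholds
#'
#' Computes absolute expansion per subject from either the ground-truth masks
#' or the predicted masks of a segmentation engine, and binarizes it at
#' 3/6/9/12.5 mL.
#'
#' @param pairs List of [SubjectPair-class] objects.
#' @param mask_source `"truth"` (generator masks) or `"predicted"`.
#' @param segmented For `mask_source = "predicted"`: a list (one element per
#'   subject) of `list(baseline =, followup =)` [SegmentationResult-class]
#'   objects, e.g. from [oracleSegment()].
#' @return A data.frame with `subject_id`, `delta_ml` and the four binary
#'   label columns.
#' @export
labelCohort <- function(pairs, mask_source = c("truth", "predicted"),
                        segmented = NULL) {
    mask_source <- match.arg(mask_source)
    if (mask_source == "predicted") {
        if (is.null(segmented) || length(segmented) != length(pairs))
            stop("data error: predicted labels require one segmentation result per subject")
    }
    rows <- lapply(seq_along(pairs), function(i) {
        p <- pairs[[i]]
        if (mask_source == "truth") {
            dl <- absoluteHE(volumeML(p@truthMaskBaseline), volumeML(p@truthMaskFollowup))
        } else {
            s <- segmented[[i]]
            if (is.null(s$baseline) || is.null(s$followup))
                stop("data error: missing mask for subject ", p@subjectId)
            dl <- absoluteHE(volumeML(s$baseline), volumeML(s$followup))
        }
        lab <- binarizeHE(dl)
        data.frame(subject_id = p@subjectId, delta_ml = dl,
                   label_3 = lab$label_3, label_6 = lab$label_6,
                   label_9 = lab$label_9, label_12_5 = lab$label_12_5,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
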