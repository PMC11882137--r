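# Candidate operating points: midpoints between adjacent distinct sorted
# scores, plus -Inf/+Inf sentinels. Using midpoints avoids ties between the
# cut and observed score values; the prediction rule everywhere is
# score >= cut (ties at the cut are positive).
candidateCuts <- function(scores) {
    s <- sort(unique(scores))
    if (length(s) == 1L) return(c(-Inf, Inf))
    c(-Inf, (utils::head(s, -1) + utils::tail(s, -1)) / 2, Inf)
}

newThresholdSpec <- function(mode, cut, target = NA_real_, he = NA_real_,
                             cohort = "calibration") {
    new("ThresholdSpec", heThresholdML = he, mode = mode, target = target,
        cutValue = cut, calibrationCohort = cohort)
}

#' Operating point for a target sensitivity
#'
#' Returns the largest score cut whose sensitivity on the calibration data is
#' at least `target` -- i.e. the most specific operating point compatible
#' with the sensitivity constraint. `target = 1` puts the cut just below the
#' minimum positive score, guaranteeing zero calibration false negatives.
#'
#' @param scores Continuous scores (higher = more expansion-like).
#' @param labels Binary truth labels at the HE threshold of interest.
#' @param target Required sensitivity in (0, 1].
#' @param he_threshold_ml Optional HE threshold recorded in the result.
#' @param cohort Calibration cohort name recorded in the result.
#' @return A [ThresholdSpec-class].
#' @export
thresholdForSensitivity <- function(scores, labels, target,
                                    he_threshold_ml = NA_real_,
                                    cohort = "calibration") {
    labels <- as.integer(as.logical(labels))
    if (sum(labels) == 0L)
        stop("calibration error: no positives to calibrate sensitivity on")
    if (target <= 0 || target > 1) stop("target must be in (0, 1]")
    pos <- scores[labels == 1L]
    cuts <- candidateCuts(scores)
    sens <- vapply(cuts, function(ct) mean(pos >= ct), numeric(1))
    ok <- which(sens >= target)
    cut <- max(cuts[ok]) # sensitivity is non-increasing in the cut
    newThresholdSpec("sensitivity", cut, target, he_threshold_ml, cohort)
}

#' Operating point for a target specificity
#'
#' Returns the smallest score cut whose specificity on the calibration data
#' is at least `target` -- the most sensitive operating point compatible
#' with the specificity constraint. `target = 1` guarantees zero calibration
#' false positives.
#'
#' @inheritParams thresholdForSensitivity
#' @param target Required specificity in (0, 1].
#' @return A [ThresholdSpec-class].
#' @export
thresholdForSpecificity <- function(scores, labels, target,
                                    he_threshold_ml = NA_real_,
                                    cohort = "calibration") {
    labels <- as.integer(as.logical(labels))
    if (sum(1L - labels) == 0L)
        stop("calibration error: no negatives to calibrate specificity on")
    if (target <= 0 || target > 1) stop("target must be in (0, 1]")
    neg <- scores[labels == 0L]
    cuts <- candidateCuts(scores)
    spec <- vapply(cuts, function(ct) mean(neg < ct), numeric(1))
    ok <- which(spec >= target)
    cut <- min(cuts[ok]) # specificity is non-decreasing in the cut
    newThresholdSpec("specificity", cut, target, he_threshold_ml, cohort)
}

# Shared exhaustive scan for the max-accuracy / max-F1 operating points.
scanMaxMetric <- function(scores, labels, metric) {
    labels <- as.integer(as.logical(labels))
    if (sum(labels) == 0L || sum(1L - labels) == 0L)
        stop("calibration error: both classes must be present")
    cuts <- candidateCuts(scores)
    vals <- vapply(cuts, function(ct) {
        cm <- confusionCounts(scores >= ct, labels)
        if (metric == "accuracy") (cm[["tp"]] + cm[["tn"]]) / sum(cm)
        else 2 * cm[["tp"]] / (2 * cm[["tp"]] + cm[["fp"]] + cm[["fn"]])
    }, numeric(1))
    best <- max(vals)
    # ties broken toward higher sensitivity, i.e. the smallest cut
    min(cuts[vals >= best - 1e-12])
}

#' Maximum-accuracy operating point
#'
#' Exhaustive scan over all candidate cuts; ties are broken toward higher
#' sensitivity (the smaller cut).
#'
#' @inheritParams thresholdForSensitivity
#' @return A [ThresholdSpec-class].
#' @export
thresholdMaxAccuracy <- function(scores, labels, he_threshold_ml = NA_real_,
                                 cohort = "calibration") {
    cut <- scanMaxMetric(scores, labels, "accuracy")
    newThresholdSpec("max_accuracy", cut, NA_real_, he_threshold_ml, cohort)
}

#' Maximum-F1 operating point
#'
#' @inheritParams thresholdForSensitivity
#' @return A [ThresholdSpec-class].
#' @export
thresholdMaxF1 <- function(scores, labels, he_threshold_ml = NA_real_,
                           cohort = "calibration") {
    cut <- scanMaxMetric(scores, labels, "f1")
    newThresholdSpec("max_f1", cut, NA_real_, he_threshold_ml, cohort)
}

#' Apply a calibrated operating point to scores
#'
#' Pure threshold transfer: `prediction = score >= cutValue`, with no
#' refitting. On an external cohort the realized sensitivity/specificity is
#' measured, not enforced.
#'
#' @param scores Continuous scores on the calibration scale.
#' @param spec A [ThresholdSpec-class].
#' @return Integer 0/1 predictions.
#' @export
applyThreshold <- function(scores, spec) {
    stopifnot(is(spec, "ThresholdSpec"))
    as.integer(scores >= spec@cutValue)
}

#' Expert-review policy
#'
#' Which side of the prediction is routed to expert review of the automated
#' segmentations, and whether the reviewer is modeled as perfect. Reviewing
#' test-positives pairs naturally with sensitivity-mode thresholds (the
#' reviewer corrects false positives, so the only residual errors are the
#' unreviewed false negatives); reviewing test-negatives pairs with
#' specificity-mode thresholds, symmetrically.
#'
#' @param review_side `"positives"` or `"negatives"`.
#' @param review_perfect If `TRUE` (default) reviewed subjects end up with
#'   their true label.
#' @param reviewer_flip_prob With `review_perfect = FALSE`: probability a
#'   reviewed subject still ends up mislabeled (sensitivity analyses).
#' @param seed Seed for the imperfect-reviewer draws.
#' @return A `ReviewPolicy` (validated list).
#' @export
reviewPolicy <- function(review_side = c("positives", "negatives"),
                         review_perfect = TRUE, reviewer_flip_prob = 0,
                         seed = 1L) {
    review_side <- match.arg(review_side)
    if (reviewer_flip_prob < 0 || reviewer_flip_prob >= 1)
        stop("reviewer_flip_prob must be in [0, 1)")
    structure(list(review_side = review_side,
                   review_perfect = isTRUE(review_perfect),
                   reviewer_flip_prob = reviewer_flip_prob,
                   seed = as.integer(seed)),
              class = "ReviewPolicy")
}

#' Review-burden and post-review error accounting
#'
#' Simulates the triage workflow at an operating point: subjects on the
#' review side of the prediction are routed to expert review (and, with a
#' perfect reviewer, corrected to their true label); everyone else keeps the
#' automated call. Final accuracy and error rates are computed over the whole
#' cohort, so with a positives-review policy the residual errors are exactly
#' the unreviewed false negatives.
#'
#' @param predictions,truth Aligned binary vectors.
#' @param policy A [reviewPolicy()].
#' @return A [TriageReport-class].
#' @examples
#' # a 95%-sensitivity-style worked example: 890 subjects, 148 with true
#' # expansion, 141 detected, 175 false positives routed to review
#' truth <- rep(c(1, 1, 0, 0), c(141, 7, 175, 567))
#' pred  <- rep(c(1, 0, 1, 0), c(141, 7, 175, 567))
#' triageReport(pred, truth, reviewPolicy("positives"))
#' @export
triageReport <- function(predictions, truth, policy = reviewPolicy()) {
    if (length(predictions) != length(truth))
        stop("length mismatch between predictions and truth")
    stopifnot(inherits(policy, "ReviewPolicy"))
    pred <- as.integer(as.logical(predictions))
    tr <- as.integer(as.logical(truth))
    n <- length(pred)
    pre <- confusionCounts(pred, tr)
    reviewed <- if (policy$review_side == "positives") pred == 1L else pred == 0L
    final <- pred
    if (policy$review_perfect) {
        final[reviewed] <- tr[reviewed]
    } else {
        flips <- withSeed(policy$seed,
            stats::runif(sum(reviewed)) < policy$reviewer_flip_prob)
        corrected <- tr[reviewed]
        corrected[flips] <- 1L - corrected[flips]
        final[reviewed] <- corrected
    }
    post <- confusionCounts(final, tr)
    preI <- as.integer(pre); names(preI) <- names(pre)
    postI <- as.integer(post); names(postI) <- names(post)
    new("TriageReport",
        n = n, counts = preI, reviewCount = as.integer(sum(reviewed)),
        reviewFraction = sum(reviewed) / n,
        excludedFraction = 1 - sum(reviewed) / n,
        postReviewCounts = postI,
        finalAccuracy = (post[["tp"]] + post[["tn"]]) / n,
        finalFnRate = post[["fn"]] / n,
        finalFpRate = post[["fp"]] / n,
        policy = policy$review_side)
}

#' Calibrate-and-transfer sweep across HE thresholds and operating modes
#'
#' For every combination of HE threshold, mode and target: fit the operating
#' point on the internal score set, apply it unchanged to both cohorts, and
#' tabulate confusion counts, realized sensitivity/specificity, review
#' burden, and post-review error rates under the mode's natural review
#' policy (positives-review for sensitivity and the max-* modes,
#' negatives-review for specificity).
#'
#' @param internal,external `ScoreSet` data.frames (columns `subject_id`,
#'   `threshold`, `score`, `label`).
#' @param targets Sensitivity/specificity targets (default 1.0, 0.95, 0.90).
#' @param modes Subset of `c("sensitivity", "specificity", "max_accuracy",
#'   "max_f1")`.
#' @param he_thresholds HE thresholds (mL) to sweep.
#' @return A data.frame, one row per (he_threshold, mode, target, cohort).
#' @export
sweepReport <- function(internal, external,
                        targets = c(1.0, 0.95, 0.90),
                        modes = c("sensitivity", "specificity"),
                        he_thresholds = HE_THRESHOLDS_ML) {
    stopifnot(all(c("threshold", "score", "label") %in% names(internal)),
              all(c("threshold", "score", "label") %in% names(external)))
    rows <- list()
    for (he in he_thresholds) {
        int <- internal[internal$threshold == he, ]
        ext <- external[external$threshold == he, ]
        for (mode in modes) {
            tgts <- if (mode %in% c("sensitivity", "specificity")) targets else NA_real_
            for (tgt in tgts) {
                spec <- switch(mode,
                    sensitivity = thresholdForSensitivity(int$score, int$label, tgt, he, "internal"),
                    specificity = thresholdForSpecificity(int$score, int$label, tgt, he, "internal"),
                    max_accuracy = thresholdMaxAccuracy(int$score, int$label, he, "internal"),
                    max_f1 = thresholdMaxF1(int$score, int$label, he, "internal"))
                side <- if (mode == "specificity") "negatives" else "positives"
                pol <- reviewPolicy(side)
                for (nm in c("internal", "external")) {
                    dat <- if (nm == "internal") int else ext
                    tri <- triageReport(applyThreshold(dat$score, spec), dat$label, pol)
                    cm <- tri@counts
                    met <- confusionMetrics(cm)
                    rows[[length(rows) + 1L]] <- data.frame(
                        he_threshold_ml = he, mode = mode, target = tgt,
                        cut = spec@cutValue, cohort = nm, n = tri@n,
                        tp = cm[["tp"]], fp = cm[["fp"]],
                        tn = cm[["tn"]], fn = cm[["fn"]],
                        sensitivity = met[["sensitivity"]],
                        specificity = met[["specificity"]],
                        review_fraction = tri@reviewFraction,
                        excluded_fraction = tri@excludedFraction,
                        final_accuracy = tri@finalAccuracy,
                        final_fn_rate = tri@finalFnRate,
                        final_fp_rate = tri@finalFpRate,
                        stringsAsFactors = FALSE)
                }
            }
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' ROC curves with marked operating points
#'
#' Plots the internal (solid) and external (dashed) ROC curves for one HE
#' threshold and marks the calibrated sensitivity-mode operating points.
#'
#' @param internal,external `ScoreSet` data.frames with `label` columns.
#' @param he_threshold_ml Which HE threshold to plot.
#' @param targets Sensitivity targets to mark.
#' @return Invisibly, the list of marked [ThresholdSpec-class] objects.
#' @export
plotRocOperatingPoints <- function(internal, external, he_threshold_ml = 3,
                                   targets = c(1.0, 0.95, 0.90)) {
    int <- internal[internal$threshold == he_threshold_ml, ]
    ext <- external[external$threshold == he_threshold_ml, ]
    ri <- rocAndAuc(int$score, int$label)
    re <- rocAndAuc(ext$score, ext$label)
    graphics::plot(ri$roc$one_minus_specificity, ri$roc$sensitivity, type = "l",
        lty = 1, xlab = "1 - specificity", ylab = "sensitivity",
        main = sprintf(">= %g mL expansion (AUC int %.2f / ext %.2f)",
                       he_threshold_ml, ri$auc, re$auc))
    graphics::lines(re$roc$one_minus_specificity, re$roc$sensitivity, lty = 2)
    graphics::abline(0, 1, col = "grey80")
    cols <- seq_along(targets) + 1
    specs <- list()
    for (i in seq_along(targets)) {
        sp <- thresholdForSensitivity(int$score, int$label, targets[i],
                                      he_threshold_ml, "internal")
        specs[[i]] <- sp
        for (dat in list(int, ext)) {
            cm <- confusionCounts(applyThreshold(dat$score, sp), dat$label)
            met <- confusionMetrics(cm)
            graphics::points(1 - met[["specificity"]], met[["sensitivity"]],
                             pch = 19, col = cols[i])
        }
    }
    graphics::legend("bottomright", lty = c(1, 2, rep(NA, length(targets))),
        pch = c(NA, NA, rep(19, length(targets))),
        col = c(1, 1, cols),
        legend = c("internal", "external",
                   sprintf("%g%% sensitivity", 100 * targets)), bty = "n")
    invisible(specs)
}
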