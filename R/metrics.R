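#' Dice similarity coefficient between two masks
#'
#' `2|A n B| / (|A| + |B|)`, the volumetric overlap of two binary masks on
#' the same grid. Convention: two empty masks have Dice 1 (perfect agreement
#' on "nothing to segment"); empty vs non-empty gives 0.
#'
#' @param a,b [CTMask-class] objects or 0/1 arrays of identical shape.
#' @return Dice in \[0, 1\].
#' @examples
#' m <- array(0L, c(4, 4, 4)); m[1:2, 1, 1] <- 1L
#' diceCoef(m, m) # 1
#' @export
diceCoef <- function(a, b) {
    av <- if (is(a, "CTMask")) a@values else a
    bv <- if (is(b, "CTMask")) b@values else b
    if (!sameShape(av, bv)) stop("shape mismatch between masks")
    na <- sum(av != 0)
    nb <- sum(bv != 0)
    if (na + nb == 0) return(1)
    2 * sum(av != 0 & bv != 0) / (na + nb)
}

#' Hausdorff surface distance in mm
#'
#' Symmetric Hausdorff distance between the surfaces of two non-empty masks:
#' the maximum over both directions of the farthest surface voxel's distance
#' to the nearest surface voxel of the other mask, in mm under anisotropic
#' spacing. Surfaces are the mask voxels with at least one 26-neighbour
#' outside the mask. `percentile < 1` gives the robust percentile variant
#' (e.g. HD95) instead of the true maximum.
#'
#' @param a,b [CTMask-class] objects or 0/1 arrays.
#' @param spacing Spacing triple in mm; taken from `a` when it is a mask.
#' @param percentile Quantile of the directed surface distances (default 1 =
#'   the true maximum).
#' @return Distance in mm.
#' @export
hausdorffMM <- function(a, b, spacing = NULL, percentile = 1) {
    av <- if (is(a, "CTMask")) a@values else a
    bv <- if (is(b, "CTMask")) b@values else b
    if (is.null(spacing))
        spacing <- if (is(a, "CTMask")) a@spacing else c(1, 1, 1)
    if (!sameShape(av, bv)) stop("shape mismatch between masks")
    if (sum(av != 0) == 0 || sum(bv != 0) == 0)
        stop("undefined-distance error: Hausdorff requires two non-empty masks")
    d <- dim(av)
    sa <- which(cpp_boundary(as.integer(av != 0), d, 26L) == 1L)
    sb <- which(cpp_boundary(as.integer(bv != 0), d, 26L) == 1L)
    ca <- arrayInd(sa, d) - 1
    cb <- arrayInd(sb, d) - 1
    storage.mode(ca) <- "double"
    storage.mode(cb) <- "double"
    dab <- cpp_min_dists(ca, cb, as.numeric(spacing))
    dba <- cpp_min_dists(cb, ca, as.numeric(spacing))
    if (percentile >= 1) max(max(dab), max(dba))
    else max(stats::quantile(dab, percentile, names = FALSE),
             stats::quantile(dba, percentile, names = FALSE))
}

#' Confusion counts from binary predictions and truth
#'
#' @param predictions,truth Binary (0/1 or logical) vectors of equal length.
#' @return Named integer vector `c(tp, fp, tn, fn)` summing to the cohort
#'   size.
#' @export
confusionCounts <- function(predictions, truth) {
    if (length(predictions) != length(truth))
        stop("length mismatch between predictions and truth")
    p <- as.logical(predictions)
    t <- as.logical(truth)
    c(tp = sum(p & t), fp = sum(p & !t), tn = sum(!p & !t), fn = sum(!p & t))
}

#' Accuracy, sensitivity, specificity and F1 from confusion counts
#'
#' Standard formulas. A metric whose denominator is zero (e.g. sensitivity
#' with no positives) is returned as `NA` and named in the `undefined`
#' attribute rather than silently fabricated.
#'
#' @param counts Named vector with `tp`, `fp`, `tn`, `fn`.
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`,
#'   `f1`, with an `undefined` character attribute listing degenerate
#'   entries.
#' @examples
#' confusionMetrics(c(tp = 141, fp = 175, tn = 567, fn = 7))["sensitivity"]
#' @export
confusionMetrics <- function(counts) {
    tp <- counts[["tp"]]; fp <- counts[["fp"]]
    tn <- counts[["tn"]]; fn <- counts[["fn"]]
    n <- tp + fp + tn + fn
    safe <- function(num, den) if (den > 0) num / den else NA_real_
    out <- c(
        accuracy = safe(tp + tn, n),
        sensitivity = safe(tp, tp + fn),
        specificity = safe(tn, tn + fp),
        f1 = safe(2 * tp, 2 * tp + fp + fn)
    )
    attr(out, "undefined") <- names(out)[is.na(out)]
    out
}

#' ROC curve and AUC
#'
#' The ROC is traced over the distinct score values in descending order with
#' `(0, 0)` and `(1, 1)` endpoints; the AUC is the trapezoidal area, which
#' equals the probability that a random positive outscores a random negative
#' with half credit for ties.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary truth labels.
#' @return A list with `roc` (data.frame `threshold`,
#'   `sensitivity`, `one_minus_specificity`) and `auc`.
#' @examples
#' rocAndAuc(c(.9, .8, .4, .2), c(1, 0, 1, 0))$auc # 0.75
#' @export
rocAndAuc <- function(scores, labels) {
    labels <- as.integer(as.logical(labels))
    if (length(scores) != length(labels)) stop("length mismatch")
    nPos <- sum(labels == 1L)
    nNeg <- sum(labels == 0L)
    if (nPos == 0L || nNeg == 0L)
        stop("undefined-AUC error: both classes must be present")
    o <- order(scores, decreasing = TRUE)
    s <- scores[o]
    l <- labels[o]
    thr <- unique(s)
    cumPos <- cumsum(l)
    cumNeg <- cumsum(1L - l)
    lastOfThr <- cumsum(rle(s)$lengths) # last index of each distinct score
    sens <- c(0, cumPos[lastOfThr] / nPos, 1)
    fpr <- c(0, cumNeg[lastOfThr] / nNeg, 1)
    thresholds <- c(Inf, thr, -Inf)
    auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
    list(roc = data.frame(threshold = thresholds, sensitivity = sens,
                          one_minus_specificity = fpr),
         auc = auc)
}

#' Percentile bootstrap confidence interval for the AUC
#'
#' Subject-level resampling with replacement; resamples that lose one class
#' are dropped. Deterministic given the seed.
#'
#' @param scores,labels As in [rocAndAuc()].
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param conf Coverage (default 0.95).
#' @return Length-2 numeric `c(lower, upper)`.
#' @export
aucCIBootstrap <- function(scores, labels, n_boot = 2000, seed = 1L, conf = 0.95) {
    labels <- as.integer(as.logical(labels))
    if (sum(labels) == 0L || sum(1L - labels) == 0L)
        stop("undefined-AUC error: both classes must be present")
    n <- length(scores)
    withSeed(seed, {
        vals <- vapply(seq_len(n_boot), function(b) {
            idx <- sample.int(n, n, replace = TRUE)
            lb <- labels[idx]
            if (sum(lb) == 0L || sum(1L - lb) == 0L) return(NA_real_)
            rocAndAuc(scores[idx], lb)$auc
        }, numeric(1))
        vals <- vals[!is.na(vals)]
        alpha <- (1 - conf) / 2
        stats::quantile(vals, c(alpha, 1 - alpha), names = FALSE)
    })
}

#' Paired bootstrap comparison of two AUCs
#'
#' Two score sets on the same subjects are compared by resampling subjects
#' jointly and recomputing the AUC difference; the two-sided p-value is the
#' doubled smaller tail of the bootstrap difference distribution around zero
#' (capped at 1). Identical score sets give p = 1; swapping the score sets
#' leaves p unchanged.
#'
#' @param scores_a,scores_b Score vectors for the same subjects.
#' @param labels Shared binary truth labels.
#' @param n_boot Number of resamples.
#' @param seed Integer seed.
#' @return A list with `p_value`, `auc_a`, `auc_b`, `delta`.
#' @export
compareAucPaired <- function(scores_a, scores_b, labels, n_boot = 2000, seed = 1L) {
    if (length(scores_a) != length(scores_b) || length(scores_a) != length(labels))
        stop("scores_a, scores_b and labels must describe the same subjects")
    labels <- as.integer(as.logical(labels))
    aucA <- rocAndAuc(scores_a, labels)$auc
    aucB <- rocAndAuc(scores_b, labels)$auc
    n <- length(labels)
    deltas <- withSeed(seed, {
        vapply(seq_len(n_boot), function(b) {
            idx <- sample.int(n, n, replace = TRUE)
            lb <- labels[idx]
            if (sum(lb) == 0L || sum(1L - lb) == 0L) return(NA_real_)
            rocAndAuc(scores_a[idx], lb)$auc - rocAndAuc(scores_b[idx], lb)$auc
        }, numeric(1))
    })
    deltas <- deltas[!is.na(deltas)]
    pLo <- mean(deltas <= 0)
    pHi <- mean(deltas >= 0)
    p <- min(1, 2 * min(pLo, pHi))
    list(p_value = p, auc_a = aucA, auc_b = aucB, delta = aucA - aucB)
}
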