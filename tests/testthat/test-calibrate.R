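test_that("threshold finders match exhaustive enumeration on random score sets", {
    set.seed(2024)
    for (rep in 1:60) {
        n <- sample(6:50, 1)
        scores <- round(rnorm(n), sample(0:2, 1)) # coarse rounding forces ties
        labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
        if (sum(labels) == 0 || sum(labels) == n) next
        for (tgt in c(1, 0.95, 0.9, runif(1, 0.5, 1))) {
            expect_equal(cutValue(thresholdForSensitivity(scores, labels, tgt)),
                         bruteSensCut(scores, labels, tgt))
            expect_equal(cutValue(thresholdForSpecificity(scores, labels, tgt)),
                         bruteSpecCut(scores, labels, tgt))
        }
        expect_equal(cutValue(thresholdMaxAccuracy(scores, labels)),
                     bruteMaxCut(scores, labels, "accuracy"))
        expect_equal(cutValue(thresholdMaxF1(scores, labels)),
                     bruteMaxCut(scores, labels, "f1"))
    }
})

test_that("sensitivity-target thresholds meet their constraint and behave monotonically", {
    set.seed(7)
    scores <- rnorm(100)
    labels <- rbinom(100, 1, 0.3)
    cuts <- vapply(c(1, 0.95, 0.9, 0.8), function(t)
        cutValue(thresholdForSensitivity(scores, labels, t)), numeric(1))
    # raising the target never raises the cut
    expect_true(all(diff(cuts) >= 0))
    for (i in seq_along(cuts)) {
        pred <- as.integer(scores >= cuts[i])
        sens <- sum(pred & labels) / sum(labels)
        expect_gte(sens, c(1, 0.95, 0.9, 0.8)[i])
    }
    # target 1: no calibration false negatives, cut below every positive score
    expect_equal(sum(scores[labels == 1] < cuts[1]), 0)

    # mirror symmetry: specificity on negated scores + flipped labels
    spSens <- thresholdForSensitivity(scores, labels, 0.9)
    spSpec <- thresholdForSpecificity(-scores, 1 - labels, 0.9)
    predA <- as.integer(scores >= cutValue(spSens))
    predB <- 1 - as.integer(-scores >= cutValue(spSpec))
    # the two rules give the same sensitivity on the calibration data
    expect_equal(sum(predA & labels) / sum(labels),
                 sum(predB & labels) / sum(labels), tolerance = 0.02)

    # max-accuracy dominates any sensitivity-mode cut on the same data
    accAt <- function(ct) mean(as.integer(scores >= ct) == labels)
    accMax <- accAt(cutValue(thresholdMaxAccuracy(scores, labels)))
    for (ct in cuts) expect_gte(accMax + 1e-12, accAt(ct))

    expect_error(thresholdForSensitivity(scores, rep(0, 100), 0.9), "calibration error")
    expect_error(thresholdForSpecificity(scores, rep(1, 100), 0.9), "calibration error")
})

newThresholdSpecForTest <- function(cut) {
    new("ThresholdSpec", heThresholdML = NA_real_, mode = "max_accuracy",
        target = NA_real_, cutValue = cut, calibrationCohort = "test")
}

test_that("applyThreshold is a pure, idempotent transfer rule", {
    sp <- thresholdForSensitivity(c(1, 2, 3, 4), c(0, 0, 1, 1), 1)
    expect_equal(applyThreshold(c(0, 1, 2.99), sp), c(0, 0, 1))
    pred <- applyThreshold(c(-5, 10, 2), sp)
    expect_equal(applyThreshold(pred * 100, newThresholdSpecForTest(50)), pred)
    # all scores below the cut: all negative
    expect_equal(applyThreshold(c(-3, -2), sp), c(0, 0))
})

test_that("triageReport reproduces a brute-force simulation of the review process", {
    set.seed(91)
    for (rep in 1:10) {
        n <- 40
        truth <- rbinom(n, 1, 0.3)
        pred <- ifelse(runif(n) < 0.8, truth, 1 - truth)
        for (side in c("positives", "negatives")) {
            tri <- triageReport(pred, truth, reviewPolicy(side))
            # brute force: walk the subjects one by one
            reviewed <- if (side == "positives") pred == 1 else pred == 0
            final <- ifelse(reviewed, truth, pred)
            expect_equal(tri@reviewCount, sum(reviewed))
            expect_equal(tri@finalAccuracy, mean(final == truth))
            expect_equal(tri@finalFnRate, mean(final == 0 & truth == 1))
            expect_equal(tri@finalFpRate, mean(final == 1 & truth == 0))
            # conservation and policy identities
            expect_equal(tri@reviewFraction + tri@excludedFraction, 1)
            expect_equal(sum(tri@postReviewCounts), n)
            if (side == "positives") expect_equal(tri@finalFpRate, 0)
            else expect_equal(tri@finalFnRate, 0)
            expect_equal(tri@finalAccuracy, 1 - tri@finalFnRate - tri@finalFpRate)
        }
    }
    # a perfect classifier reviewed on positives: burden equals prevalence
    truth <- rbinom(60, 1, 0.4)
    tri <- triageReport(truth, truth, reviewPolicy("positives"))
    expect_equal(tri@reviewFraction, mean(truth))
    expect_equal(tri@finalAccuracy, 1)

    expect_error(triageReport(c(1, 0), c(1, 0, 1), reviewPolicy()), "length")
})

test_that("an imperfect reviewer leaves residual errors on the reviewed side", {
    truth <- rep(c(1, 0), c(30, 70))
    pred <- rep(c(1, 0, 1, 0), c(28, 2, 20, 50))
    tri <- triageReport(pred, truth,
                        reviewPolicy("positives", review_perfect = FALSE,
                                     reviewer_flip_prob = 0.5, seed = 3))
    expect_gt(tri@finalFpRate + tri@finalFnRate, 2 / 100) # worse than the perfect reviewer
    # deterministic given the policy seed
    tri2 <- triageReport(pred, truth,
                         reviewPolicy("positives", review_perfect = FALSE,
                                      reviewer_flip_prob = 0.5, seed = 3))
    expect_equal(tri@postReviewCounts, tri2@postReviewCounts)
})

test_that("sweepReport calibrates, transfers, and degenerates sensibly", {
    cohort <- fixture("cohort40", buildCohort40)
    man <- cohortManifest(cohort)
    seg <- lapply(cohort, oracleSegment, espec = errorModelSpec(0.86, seed = 9))
    delta <- vapply(seg, function(s) volumeScore(s$baseline, s$followup), numeric(1))
    ss <- scoreSetFromMatrix(man$subject_id, matrix(rep(delta, 4), ncol = 4),
                             labels = as.matrix(man[, 6:9]), source = "volume")
    tab <- sweepReport(ss, ss, targets = c(1, 0.95), he_thresholds = c(3, 6))
    # internal == external data: identical metrics
    for (col in c("tp", "fp", "tn", "fn", "final_accuracy"))
        expect_equal(tab[tab$cohort == "internal", col],
                     tab[tab$cohort == "external", col])
    # the calibrated cut meets its target on the calibration cohort
    sensRows <- tab[tab$mode == "sensitivity" & tab$cohort == "internal", ]
    expect_true(all(sensRows$sensitivity >= sensRows$target - 1e-12))
    specRows <- tab[tab$mode == "specificity" & tab$cohort == "internal", ]
    expect_true(all(specRows$specificity >= specRows$target - 1e-12))
    expect_true(all(abs(tab$review_fraction + tab$excluded_fraction - 1) < 1e-12))

    # degenerate all-negative external cohort: specificity defined,
    # sensitivity absent-flagged
    extNeg <- ss[ss$threshold == 3, ]
    extNeg$label <- 0
    extNeg$threshold <- 3
    tabD <- sweepReport(ss[ss$threshold == 3, ], extNeg, targets = 0.95,
                        modes = "sensitivity", he_thresholds = 3)
    ext <- tabD[tabD$cohort == "external", ]
    expect_true(is.na(ext$sensitivity))
    expect_false(is.na(ext$specificity))
})

test_that("ROC operating-point plot runs and returns the marked thresholds", {
    cohort <- fixture("cohort40", buildCohort40)
    man <- cohortManifest(cohort)
    seg <- lapply(cohort, oracleSegment, espec = errorModelSpec(0.86, seed = 9))
    delta <- vapply(seg, function(s) volumeScore(s$baseline, s$followup), numeric(1))
    ss <- scoreSetFromMatrix(man$subject_id, matrix(rep(delta, 4), ncol = 4),
                             labels = as.matrix(man[, 6:9]), source = "volume")
    pdf(NULL)
    on.exit(dev.off())
    specs <- plotRocOperatingPoints(ss, ss, 3, targets = c(1, 0.95))
    expect_length(specs, 2)
    expect_s4_class(specs[[1]], "ThresholdSpec")
})
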