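test_that("absoluteHE is the signed volume difference and antisymmetric", {
    expect_equal(absoluteHE(10, 17.2), 7.2)
    expect_equal(absoluteHE(12.3, 12.3), 0)
    # cohort-mean-level sanity: baseline 12.9, follow-up 15.6 gives 2.7
    expect_equal(absoluteHE(12.9, 15.6), 2.7)
    for (ab in list(c(1, 5), c(8, 2), c(0, 0))) {
        expect_equal(absoluteHE(ab[1], ab[2]), -absoluteHE(ab[2], ab[1]))
    }
    expect_error(absoluteHE(-1, 5), ">= 0")
})

test_that("binarizeHE uses inclusive thresholds and always nests", {
    expect_equal(unlist(binarizeHE(12.5)[2:5]),
                 c(label_3 = 1, label_6 = 1, label_9 = 1, label_12_5 = 1))
    expect_equal(unlist(binarizeHE(-4)[2:5]),
                 c(label_3 = 0, label_6 = 0, label_9 = 0, label_12_5 = 0))
    for (d in c(-10, 0, 2.9, 3, 5.99, 6, 8.5, 9, 12.49, 12.5, 40)) {
        l <- binarizeHE(d)
        expect_lte(l$label_12_5, l$label_9)
        expect_lte(l$label_9, l$label_6)
        expect_lte(l$label_6, l$label_3)
        expect_equal(l$label_3, as.integer(d >= 3))
    }
})

test_that("labelCohort matches the generator for truth masks and for a perfect oracle", {
    cohort <- fixture("cohort40", buildCohort40)
    man <- cohortManifest(cohort)
    truthTab <- labelCohort(cohort, "truth")
    expect_equal(truthTab[, c("label_3", "label_6", "label_9", "label_12_5")],
                 man[, c("label_3", "label_6", "label_9", "label_12_5")])

    segPerfect <- lapply(cohort, oracleSegment, espec = errorModelSpec(target_dice = 1))
    predTab <- labelCohort(cohort, "predicted", segPerfect)
    expect_equal(predTab[, 3:6], truthTab[, 3:6])

    expect_error(labelCohort(cohort, "predicted"), "data error")
})

test_that("noisy segmentation produces expansion-label discordance that shrinks with Dice", {
    cohort <- fixture("cohort40", buildCohort40)
    man <- cohortManifest(cohort)
    discord <- function(dice, seeds) {
        mean(vapply(seeds, function(s) {
            seg <- lapply(cohort, oracleSegment,
                          espec = errorModelSpec(target_dice = dice, seed = s))
            tab <- labelCohort(cohort, "predicted", seg)
            mean(tab$label_3 != man$label_3)
        }, numeric(1)))
    }
    d086 <- discord(0.86, 1:3)
    expect_gt(d086, 0) # cumulative error flips at least one >= 3 mL label
    d070 <- discord(0.70, 1:3)
    expect_gte(d070, d086)
})
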