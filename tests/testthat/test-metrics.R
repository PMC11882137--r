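test_that("diceCoef follows set arithmetic and its conventions", {
    m <- sphereMask(500, c(16, 16, 16))
    expect_equal(diceCoef(m, m), 1)
    a <- array(0L, dim = c(8, 8, 8)); a[1:2, 1, 1] <- 1L
    b <- array(0L, dim = c(8, 8, 8)); b[5:6, 5, 5] <- 1L
    expect_equal(diceCoef(a, b), 0)
    # |A| = |B| = 8, overlap 4
    a <- array(0L, dim = c(8, 8, 8)); a[1:8, 1, 1] <- 1L
    b <- array(0L, dim = c(8, 8, 8)); b[5:8, 1, 1] <- 1L; b[1:4, 2, 1] <- 1L
    expect_equal(diceCoef(a, b), 0.5)
    empty <- array(0L, dim = c(8, 8, 8))
    expect_equal(diceCoef(empty, empty), 1)
    expect_equal(diceCoef(empty, a), 0)
    expect_error(diceCoef(a, array(0L, dim = c(4, 4, 4))), "shape")
})

test_that("hausdorffMM equals brute-force pairwise surface distances on random masks", {
    # axis-aligned sanity: two single voxels 3 apart at 1 mm
    a <- array(0L, dim = c(12, 12, 12)); a[3, 3, 3] <- 1L
    b <- array(0L, dim = c(12, 12, 12)); b[3, 3, 6] <- 1L
    expect_equal(hausdorffMM(a, b, c(1, 1, 1)), 3)
    expect_equal(hausdorffMM(b, a, c(1, 1, 1)), 3)

    set.seed(404)
    for (rep in 1:20) {
        d3 <- c(10, 11, 12)
        sp <- c(1, 1, 2)
        ma <- newMask(array(as.integer(runif(prod(d3)) < 0.2), dim = d3), sp)
        mb <- newMask(array(as.integer(runif(prod(d3)) < 0.2), dim = d3), sp)
        if (sum(voxelData(ma)) == 0 || sum(voxelData(mb)) == 0) next
        expect_equal(hausdorffMM(ma, mb), bruteHausdorff(ma, mb, sp), tolerance = 1e-10)
    }
    expect_equal(hausdorffMM(a, a, c(1, 1, 1)), 0)
    expect_error(hausdorffMM(a, array(0L, dim = c(12, 12, 12)), c(1, 1, 1)),
                 "undefined-distance")
})

test_that("volumeML is voxel count times voxel volume", {
    empty <- newMask(array(0L, dim = c(8, 8, 8)), c(1, 1, 1))
    expect_equal(volumeML(empty), 0)
    m1 <- sphereMask(1000, c(16, 16, 16), c(1, 1, 1))
    expect_equal(volumeML(m1), 1)
    mAniso <- sphereMask(1000, c(16, 16, 16), c(0.46, 0.46, 5))
    expect_equal(volumeML(mAniso), 1000 * 0.46 * 0.46 * 5 / 1000)
})

test_that("confusionMetrics computes the standard rates and flags degenerate ones", {
    met <- confusionMetrics(c(tp = 141, fp = 175, tn = 567, fn = 7))
    expect_equal(met[["sensitivity"]], 141 / 148)
    expect_equal(met[["accuracy"]], (141 + 567) / 890)
    perfect <- confusionMetrics(c(tp = 10, fp = 0, tn = 30, fn = 0))
    expect_equal(unname(perfect[1:4]), rep(1, 4))
    degen <- confusionMetrics(c(tp = 0, fp = 3, tn = 5, fn = 0))
    expect_true(is.na(degen[["sensitivity"]]))
    expect_true("sensitivity" %in% attr(degen, "undefined"))
})

test_that("rocAndAuc matches pairwise concordance and an independent ROC implementation", {
    expect_equal(rocAndAuc(c(.9, .8, .4, .2), c(1, 0, 1, 0))$auc, 0.75)
    sep <- rocAndAuc(c(5, 6, 7, 1, 2, 3), c(1, 1, 1, 0, 0, 0))
    expect_equal(sep$auc, 1)

    set.seed(77)
    for (rep in 1:25) {
        n <- sample(6:50, 1)
        sc <- round(rnorm(n), 1) # rounding forces ties
        lb <- rbinom(n, 1, 0.4)
        if (sum(lb) == 0 || sum(lb) == n) next
        expect_equal(rocAndAuc(sc, lb)$auc, bruteAuc(sc, lb), tolerance = 1e-12)
    }

    # cross-check against pROC on one fixed set
    if (requireNamespace("pROC", quietly = TRUE)) {
        set.seed(5)
        sc <- rnorm(80); lb <- rbinom(80, 1, 0.3)
        ref <- as.numeric(suppressMessages(pROC::auc(lb, sc)))
        expect_equal(rocAndAuc(sc, lb)$auc, ref, tolerance = 1e-10)
    }

    # random scores on a large cohort sit near 0.5
    set.seed(8)
    sc <- rnorm(2000); lb <- rbinom(2000, 1, 0.5)
    expect_lt(abs(rocAndAuc(sc, lb)$auc - 0.5), 0.05)

    r <- rocAndAuc(c(.9, .8, .4, .2), c(1, 0, 1, 0))$roc
    expect_equal(r$sensitivity[1], 0)
    expect_equal(r$sensitivity[nrow(r)], 1)
    expect_true(all(diff(r$sensitivity) >= 0))
    expect_error(rocAndAuc(1:5, rep(1, 5)), "undefined-AUC")
})

test_that("bootstrap AUC confidence intervals are seeded, contain the point estimate, and are stable", {
    set.seed(12)
    sc <- c(rnorm(60, 1), rnorm(60))
    lb <- rep(c(1, 0), each = 60)
    ci <- aucCIBootstrap(sc, lb, n_boot = 500, seed = 9)
    expect_identical(ci, aucCIBootstrap(sc, lb, n_boot = 500, seed = 9))
    point <- rocAndAuc(sc, lb)$auc
    expect_lte(ci[1], point)
    expect_gte(ci[2], point)
    sepci <- aucCIBootstrap(c(4, 5, 6, 1, 2, 3), c(1, 1, 1, 0, 0, 0),
                            n_boot = 200, seed = 1)
    expect_equal(sepci[2], 1)
    ci2k <- aucCIBootstrap(sc, lb, n_boot = 2000, seed = 2)
    ci4k <- aucCIBootstrap(sc, lb, n_boot = 4000, seed = 3)
    expect_true(all(abs(ci2k - ci4k) < 0.02))
})

test_that("paired AUC comparison is two-sided, symmetric, and seeded", {
    set.seed(30)
    sc <- rnorm(60); lb <- rbinom(60, 1, 0.4)
    same <- compareAucPaired(sc, sc, lb, n_boot = 300, seed = 4)
    expect_equal(same$p_value, 1)
    # perfectly separating vs anti-separating scores
    scA <- lb + rnorm(60, sd = 0.01)
    res <- compareAucPaired(scA, -scA, lb, n_boot = 500, seed = 4)
    expect_lt(res$p_value, 0.01)
    swap <- compareAucPaired(-scA, scA, lb, n_boot = 500, seed = 4)
    expect_equal(res$p_value, swap$p_value)
    expect_identical(compareAucPaired(sc, scA, lb, n_boot = 300, seed = 6)$p_value,
                     compareAucPaired(sc, scA, lb, n_boot = 300, seed = 6)$p_value)
})
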