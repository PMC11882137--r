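test_that("volumeScore ranks exactly like the predicted volume difference", {
    cohort <- fixture("cohort40", buildCohort40)
    man <- cohortManifest(cohort)
    segP <- lapply(cohort, oracleSegment, espec = errorModelSpec(target_dice = 1))
    sc <- vapply(segP, function(s) volumeScore(s$baseline, s$followup), numeric(1))
    expect_equal(sc, man$true_delta_ml, tolerance = prod(deskPhantomSpec()$spacing_mm) / 1000)
    # perfect oracle: AUC 1 against truth labels on a mixed cohort
    expect_equal(rocAndAuc(sc, man$label_3)$auc, 1)
    # brute-force ranking identity
    seg <- lapply(cohort, oracleSegment, espec = errorModelSpec(target_dice = 0.86, seed = 4))
    scN <- vapply(seg, function(s) volumeScore(s$baseline, s$followup), numeric(1))
    brute <- vapply(seg, function(s) s$followup@volumeML - s$baseline@volumeML, numeric(1))
    expect_identical(order(scN), order(brute))
})

test_that("stratifiedKFold balances positives and partitions exactly", {
    f <- stratifiedKFold(rep(c(1, 0), c(25, 75)), k = 5, seed = 1)
    expect_equal(as.numeric(table(f)), rep(20, 5))
    for (k in 1:5) expect_equal(sum(f == k & rep(c(1, 0), c(25, 75)) == 1), 5)

    # 684 subjects at the 25% prevalence of the training registry: a 4-to-1
    # split with 548 training and 136 validation cases exists among the folds
    lab <- rep(c(1, 0), c(171, 513))
    f6 <- stratifiedKFold(lab, k = 5, seed = 2)
    sizes <- as.numeric(table(f6))
    expect_equal(sum(sizes), 684)
    expect_true(136 %in% sizes)
    expect_true(any(684 - sizes == 548))
    # per-fold positive count within one subject of the global ratio
    posPerFold <- vapply(1:5, function(k) sum(lab[f6 == k]), numeric(1))
    expect_lte(max(posPerFold) - min(posPerFold), 1)

    set.seed(11)
    for (rep in 1:10) {
        n <- sample(10:60, 1)
        lb <- rbinom(n, 1, runif(1, 0.2, 0.8))
        k <- sample(2:5, 1)
        fr <- stratifiedKFold(lb, k, seed = rep)
        expect_equal(sort(unique(fr)), seq_len(k))
        pc <- vapply(seq_len(k), function(j) sum(lb[fr == j]), numeric(1))
        expect_lte(max(pc) - min(pc), 1)
    }
    expect_error(stratifiedKFold(c(1, 0), k = 5), "at least")
})

test_that("the four-input CNN learns the expansion labels on a small phantom cohort", {
    dat <- fixture("cnn24", buildCnn24)
    mod <- dat$mod
    # validation loss at the best epoch beats the first epoch
    expect_lt(mod$log$val_loss[mod$best_epoch], mod$log$val_loss[1])

    sc <- predictCnn(mod, dat$inputs, dat$man$subject_id)
    expect_true(all(sc$score > 0 & sc$score < 1))
    # training-set ranking recovers the truth (mask channels carry the signal)
    s3 <- sc$score[sc$threshold == 3]
    expect_gt(rocAndAuc(s3, dat$man$label_3)$auc, 0.9)
    # deterministic inference
    sc2 <- predictCnn(mod, dat$inputs, dat$man$subject_id)
    expect_identical(sc$score, sc2$score)
    # all-zero input still yields finite probabilities
    zero <- array(0, dim = c(48, 48, 48, 4))
    p0 <- predictCnn(mod, list(zero))
    expect_true(all(is.finite(p0$score) & p0$score > 0 & p0$score < 1))
})

test_that("extracted features feed an RBF-SVM that separates what the CNN separates", {
    dat <- fixture("cnn24", buildCnn24)
    feats <- extractFeatures(dat$mod, dat$inputs)
    expect_equal(ncol(feats), 4 * dat$mod$cfg$feature_dim)
    expect_true(all(is.finite(feats)))
    expect_identical(feats, extractFeatures(dat$mod, dat$inputs))
    # different subjects with different lesions embed differently
    expect_gt(max(abs(feats[1, ] - feats[2, ])), 0)

    bank <- suppressWarnings(trainSvm(feats, dat$labels, seed = 3))
    sc <- predictSvm(bank, feats, dat$man$subject_id)
    s3 <- sc$score[sc$threshold == 3]
    expect_true(all(s3 > 0 & s3 < 1))
    expect_gt(rocAndAuc(s3, dat$man$label_3)$auc, 0.9)
    # subject order invariance of decision values
    perm <- rev(seq_len(nrow(feats)))
    scPerm <- predictSvm(bank, feats[perm, ], dat$man$subject_id[perm])
    expect_equal(scPerm$score[scPerm$threshold == 3], s3[perm], tolerance = 1e-10)

    # linearly separable toy features: training accuracy 1
    X <- cbind(c(rnorm(20, -3), rnorm(20, 3)), c(rnorm(20, -3), rnorm(20, 3)))
    y <- cbind(rep(c(0, 1), each = 20), rep(c(0, 1), each = 20),
               rep(c(0, 1), each = 20), rep(c(0, 1), each = 20))
    bankSep <- trainSvm(X, y, seed = 1)
    pr <- predictSvm(bankSep, X)
    expect_true(all((pr$score[pr$threshold == 3] > 0.5) == (y[, 1] == 1)))

    oneClass <- y; oneClass[, 4] <- 0
    expect_warning(trainSvm(X, oneClass, seed = 1), "single-class")
})
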