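# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
    if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
    get(name, envir = .fixtures)
}

# Small fast phantom spec used throughout the unit tests.
deskPhantomSpec <- function() phantomSpec(grid_shape = c(48, 48, 48),
                                          spacing_mm = c(3, 3, 3))

# Coarser grid for the error-model replication studies (cheap perturbations).
coarsePhantomSpec <- function() phantomSpec(grid_shape = c(32, 32, 32),
                                            spacing_mm = c(4.5, 4.5, 4.5))

# Shared fixture builders (used from several test files; the cache in
# `.fixtures` makes the first caller pay the build cost).
buildCohort200 <- function() makeCohort(cohortSpec(200, seed = 31), deskPhantomSpec())
buildCohort40 <- function() makeCohort(cohortSpec(40, seed = 53), deskPhantomSpec())
buildCohort40Coarse <- function() makeCohort(cohortSpec(40, seed = 67), coarsePhantomSpec())
buildCohort8 <- function() makeCohort(cohortSpec(8, seed = 11), deskPhantomSpec())
buildUnet8 <- function() trainUNet(fixture("cohort8_train", buildCohort8),
                                   unetConfig(num_epochs = 5, seed = 1))

buildCnn24 <- function() {
    cohort <- makeCohort(cohortSpec(24, seed = 21), deskPhantomSpec())
    man <- cohortManifest(cohort)
    inputs <- lapply(cohort, function(p)
        preprocessPair(p, cfg = preprocessConfig(target_shape = c(48, 48, 48))))
    labels <- as.matrix(man[, c("label_3", "label_6", "label_9", "label_12_5")])
    mod <- trainCnn(inputs, labels, cnnConfig(epochs = 12, seed = 1))
    list(cohort = cohort, inputs = inputs, labels = labels, man = man, mod = mod)
}

# Volume-difference scores for a cohort under an oracle segmenter.
oracleDeltaScores <- function(cohort, dice, seed) {
    vapply(cohort, function(p) {
        s <- oracleSegment(p, errorModelSpec(target_dice = dice, seed = seed))
        volumeScore(s$baseline, s$followup)
    }, numeric(1))
}

# A compact lesion mask of exactly `n` voxels (ellipsoid-filled cube grid).
sphereMask <- function(n = 2000, dim3 = c(32, 32, 32), spacing = c(1, 1, 1)) {
    ctr <- (dim3 + 1) / 2
    co <- as.matrix(expand.grid(x = seq_len(dim3[1]), y = seq_len(dim3[2]),
                                z = seq_len(dim3[3])))
    d2 <- (co[, 1] - ctr[1])^2 + (co[, 2] - ctr[2])^2 + (co[, 3] - ctr[3])^2
    m <- array(0L, dim = dim3)
    m[order(d2)[seq_len(n)]] <- 1L
    newMask(m, spacing)
}

# Brute-force Dice from first principles (set arithmetic on voxel indices).
bruteDice <- function(a, b) {
    av <- which(voxelData(a) != 0)
    bv <- which(voxelData(b) != 0)
    if (length(av) + length(bv) == 0) return(1)
    2 * length(intersect(av, bv)) / (length(av) + length(bv))
}

# Brute-force symmetric Hausdorff over boundary voxels via full pairwise
# distance matrices in R.
bruteHausdorff <- function(a, b, spacing) {
    surf <- function(m) {
        v <- voxelData(m)
        d <- dim(v)
        idx <- which(v != 0)
        keep <- vapply(idx, function(i) {
            co <- arrayInd(i, d)
            for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
                if (dx == 0 && dy == 0 && dz == 0) next
                nb <- co + c(dx, dy, dz)
                if (any(nb < 1) || any(nb > d)) return(TRUE)
                if (v[nb[1], nb[2], nb[3]] == 0) return(TRUE)
            }
            FALSE
        }, logical(1))
        sweep(arrayInd(idx[keep], d), 2, spacing, `*`)
    }
    sa <- surf(a); sb <- surf(b)
    dm <- as.matrix(stats::dist(rbind(sa, sb)))[seq_len(nrow(sa)),
                                                nrow(sa) + seq_len(nrow(sb)), drop = FALSE]
    max(max(apply(dm, 1, min)), max(apply(dm, 2, min)))
}

# Brute-force AUC as the concordance probability over all positive-negative
# pairs with half credit for ties.
bruteAuc <- function(scores, labels) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (q in neg)
        tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
    tot / (length(pos) * length(neg))
}

# Exhaustive operating-point oracles: evaluate every candidate cut by direct
# counting and pick per the stated rule.
bruteCuts <- function(scores) {
    s <- sort(unique(scores))
    if (length(s) == 1L) return(c(-Inf, Inf))
    c(-Inf, (head(s, -1) + tail(s, -1)) / 2, Inf)
}

bruteSensCut <- function(scores, labels, target) {
    best <- -Inf
    for (ct in bruteCuts(scores)) {
        pred <- as.integer(scores >= ct)
        tp <- sum(pred == 1 & labels == 1)
        fn <- sum(pred == 0 & labels == 1)
        if (tp / (tp + fn) >= target && ct > best) best <- ct
    }
    best
}

bruteSpecCut <- function(scores, labels, target) {
    best <- Inf
    for (ct in bruteCuts(scores)) {
        pred <- as.integer(scores >= ct)
        tn <- sum(pred == 0 & labels == 0)
        fp <- sum(pred == 1 & labels == 0)
        if (tn / (tn + fp) >= target && ct < best) best <- ct
    }
    best
}

bruteMaxCut <- function(scores, labels, metric) {
    cuts <- bruteCuts(scores)
    best <- -Inf; bestCut <- Inf
    for (ct in cuts) {
        pred <- as.integer(scores >= ct)
        tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
        tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
        v <- if (metric == "accuracy") (tp + tn) / length(labels)
             else 2 * tp / (2 * tp + fp + fn)
        # ties toward higher sensitivity = smaller cut
        if (v > best + 1e-12 || (abs(v - best) <= 1e-12 && ct < bestCut)) {
            best <- v; bestCut <- ct
        }
    }
    bestCut
}
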