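test_that("makePhantom carves the requested lesion volume and is deterministic", {
    spec1mm <- phantomSpec(grid_shape = c(64, 64, 64), spacing_mm = c(1, 1, 1))
    p <- makePhantom(spec1mm, 10, seed = 3)
    expect_equal(sum(voxelData(p$mask)), 10000, tolerance = 1e-12)
    expect_lte(abs(volumeML(p$mask) - 10), prod(spacingMM(p$mask)) / 1000)

    # zero lesion: pure brain/CSF/skull phantom
    p0 <- makePhantom(deskPhantomSpec(), 0, seed = 1)
    expect_equal(sum(voxelData(p0$mask)), 0)
    hu <- voxelData(p0$volume)
    expect_true(any(hu > 500))           # skull shell present
    expect_true(mean(hu < -900) > 0.3)   # air outside the head

    # bit-identical reproduction under the same spec + seed
    a <- makePhantom(deskPhantomSpec(), 8, seed = 42)
    b <- makePhantom(deskPhantomSpec(), 8, seed = 42)
    expect_identical(voxelData(a$volume), voxelData(b$volume))
    expect_identical(voxelData(a$mask), voxelData(b$mask))

    # lesion larger than the brain compartment
    expect_error(makePhantom(deskPhantomSpec(), 5000, seed = 1), "capacity")
})

test_that("growLesion hits the requested volume change and stays connected to the lesion", {
    m <- sphereMask(3000, c(32, 32, 32), c(1, 1, 1))
    g <- growLesion(m, 7.2, seed = 5)
    expect_equal(sum(voxelData(g)), 10200, tolerance = 1e-12)
    # superset of the original mask
    expect_true(all(voxelData(g)[voxelData(m) == 1L] == 1L))
    # accretion is face-connected to the lesion: one component total
    lab <- hetriage:::cpp_label_components(as.integer(voxelData(g)),
                                           dim(voxelData(g)), 6L)
    expect_equal(max(lab), 1L)

    expect_identical(voxelData(growLesion(m, 0, seed = 1)), voxelData(m))
    shrunk <- growLesion(m, -volumeML(m), seed = 2)
    expect_equal(sum(voxelData(shrunk)), 0)
    neg <- growLesion(m, -1.5, seed = 3)
    expect_equal(sum(voxelData(neg)), 1500)
    expect_true(all(voxelData(m)[voxelData(neg) == 1L] == 1L))
    expect_error(growLesion(m, -10, seed = 1), "delta_ml")
})

test_that("makePair bookkeeping: true delta, label consistency, independent noise", {
    spec <- deskPhantomSpec()
    vox <- prod(spec$spacing_mm) / 1000
    for (cs in list(c(10, 7.2), c(5, 0), c(20, 13))) {
        pr <- makePair(spec, cs[1], cs[2], seed = 17)
        expect_equal(trueDeltaML(pr), cs[2])
        dv <- volumeML(pr@truthMaskFollowup) - volumeML(pr@truthMaskBaseline)
        expect_lte(abs(dv - cs[2]), vox)
    }
    lab1 <- binarizeHE(7.2)
    expect_equal(unlist(lab1[2:5]), c(label_3 = 1, label_6 = 1, label_9 = 0, label_12_5 = 0))
    expect_equal(unlist(binarizeHE(0)[2:5]), c(label_3 = 0, label_6 = 0, label_9 = 0, label_12_5 = 0))
    expect_equal(unlist(binarizeHE(13)[2:5]), c(label_3 = 1, label_6 = 1, label_9 = 1, label_12_5 = 1))

    pr <- makePair(spec, 10, 7.2, seed = 17)
    # shared anatomy but independent HU noise realizations
    expect_false(identical(voxelData(pr@baseline), voxelData(pr@followup)))
    skullB <- voxelData(pr@baseline) > 500
    skullF <- voxelData(pr@followup) > 500
    expect_gt(mean(skullB == skullF), 0.999)
})

test_that("makeCohort hits the target prevalence and nests labels monotonically", {
    cohort <- fixture("cohort200", buildCohort200)
    man <- cohortManifest(cohort)
    nPos <- sum(man$label_3)
    expect_gte(nPos, 40) # 25% target, +/-5 percentage points
    expect_lte(nPos, 60)
    # monotone nesting for every subject
    expect_true(all(man$label_12_5 <= man$label_9))
    expect_true(all(man$label_9 <= man$label_6))
    expect_true(all(man$label_6 <= man$label_3))
    # volume bookkeeping for every pair
    vox <- prod(deskPhantomSpec()$spacing_mm) / 1000
    expect_true(all(abs(man$V_followup_ml - man$V_baseline_ml - man$true_delta_ml) <= vox))
    # per-subject seeds derive deterministically from the cohort seed
    expect_equal(man$seed, vapply(seq_len(200), function(i) deriveSeed(31L, i), integer(1)))

    one <- makeCohort(cohortSpec(1, seed = 7), deskPhantomSpec())
    one2 <- makeCohort(cohortSpec(1, seed = 7), deskPhantomSpec())
    expect_identical(cohortManifest(one), cohortManifest(one2))

    degen <- cohortSpec(20, delta_distribution = list(zero_weight = 1, tail_scale_ml = 8,
                                                      jitter_ml = 0.4), seed = 5)
    manD <- cohortManifest(makeCohort(degen, deskPhantomSpec()))
    expect_equal(sum(manD$label_3), 0)

    expect_error(cohortSpec(10, delta_distribution = list(zero_weight = NA, tail_scale_ml = 1,
                                                          jitter_ml = 0.5),
                            target_prevalence_3ml = 0.25),
                 "configuration error")
})

test_that("perturbMask identity, calibration and component dropout behave as specified", {
    m <- sphereMask(2000)
    expect_identical(voxelData(perturbMask(m, errorModelSpec(target_dice = 1, seed = 1))),
                     voxelData(m))
    expect_error(errorModelSpec(target_dice = 0), "parameter error")

    # expected Dice close to target on a moderate lesion (fuller 50-seed
    # calibration on a 10 000-voxel lesion lives in the acceptance suite)
    ds <- vapply(1:25, function(s)
        diceCoef(m, perturbMask(m, errorModelSpec(0.86, seed = s))), numeric(1))
    expect_gt(mean(ds), 0.80)
    expect_lt(mean(ds), 0.92)

    # two-component mask with certain dropout: only the largest survives
    two <- array(0L, dim = c(24, 24, 24))
    two[4:12, 4:12, 4:12] <- 1L    # 729 voxels
    two[18:20, 18:20, 18:20] <- 1L # 27 voxels
    two <- newMask(two, c(1, 1, 1))
    pert <- perturbMask(two, errorModelSpec(target_dice = 1, boundary_flip_rate = 0,
                                            component_dropout_prob = 0.999999, seed = 3))
    lab <- hetriage:::cpp_label_components(as.integer(voxelData(pert)),
                                           c(24L, 24L, 24L), 26L)
    expect_lte(max(lab), 1L)
    expect_true(all(voxelData(pert)[18:20, 18:20, 18:20] == 0L))

    # deterministic given the seed
    p1 <- perturbMask(m, errorModelSpec(0.8, seed = 11))
    p2 <- perturbMask(m, errorModelSpec(0.8, seed = 11))
    expect_identical(voxelData(p1), voxelData(p2))

    # empty mask passes through
    empty <- newMask(array(0L, dim = c(8, 8, 8)), c(1, 1, 1))
    expect_identical(voxelData(perturbMask(empty, errorModelSpec(0.8, seed = 1))),
                     voxelData(empty))
})
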