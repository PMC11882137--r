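test_that("stripSkull never keeps bone and recovers the brain compartment", {
    spec <- deskPhantomSpec()
    pr <- fixture("pair_desk", function() makePair(spec, 10, 7.2, seed = 17))
    m <- stripSkull(pr@baseline)
    hu <- voxelData(pr@baseline)
    expect_equal(sum(voxelData(m)[hu > 200]), 0)
    # subset of the HU keep-range thresholded set
    expect_true(all(hu[voxelData(m) == 1L] >= 0 & hu[voxelData(m) == 1L] <= 200))
    # covers >= 95% of the generator's brain compartment
    comp <- hetriage:::phantomCompartments(spec)
    brainAll <- comp$labels %in% c(3L, 4L)
    expect_gte(sum(voxelData(m)[brainAll]) / sum(brainAll), 0.95)

    air <- newVolume(array(-1000, dim = c(32, 32, 32)), c(2, 2, 2))
    expect_error(stripSkull(air), "empty-brain")
})

test_that("windowNormalize maps the brain window onto [0,1] and flags double application", {
    v <- newVolume(array(c(40, 0, -50, 80, 200, 60), dim = c(6, 1, 1)), c(1, 1, 1))
    w <- windowNormalize(v)
    expect_equal(as.numeric(voxelData(w)), c(0.5, 0, 0, 1, 1, 0.75))
    expect_identical(spacingMM(w), spacingMM(v))
    expect_warning(windowNormalize(w), "already")
})

test_that("resampleToGrid: identity, constants, label round trips", {
    spec <- deskPhantomSpec()
    pr <- fixture("pair_desk", function() makePair(spec, 10, 7.2, seed = 17))
    same <- resampleToGrid(pr@baseline, c(48, 48, 48))
    expect_identical(voxelData(same), voxelData(pr@baseline))

    const <- newVolume(array(7, dim = c(16, 16, 16)), c(1, 1, 1))
    up <- resampleToGrid(const, c(24, 24, 24))
    expect_true(all(abs(voxelData(up) - 7) < 1e-12))

    # label mode preserves the value set exactly
    m <- sphereMask(800, c(24, 24, 24))
    lab <- resampleToGrid(m, c(17, 19, 23), "label")
    expect_true(all(voxelData(lab) %in% c(0L, 1L)))

    # round trip at 2x downsample keeps Dice >= 0.9 on a 10 000-voxel lesion
    spec1mm <- phantomSpec(grid_shape = c(64, 64, 64), spacing_mm = c(1.2, 1.2, 1.2))
    big <- makePhantom(spec1mm, 10000 * 1.2^3 / 1000, seed = 2)$mask
    expect_equal(sum(voxelData(big)), 10000)
    down <- resampleToGrid(big, c(32, 32, 32), "label")
    back <- resampleToGrid(down, c(64, 64, 64), "label")
    expect_gte(diceCoef(big, back), 0.9)

    expect_error(resampleToGrid(m, c(0, 10, 10)), "parameter error")
})

test_that("preprocessPair assembles four ordered channels on the target grid", {
    spec <- deskPhantomSpec()
    pr <- fixture("pair_desk", function() makePair(spec, 10, 7.2, seed = 17))
    cfg <- preprocessConfig(target_shape = c(32, 32, 32))
    x <- preprocessPair(pr, cfg = cfg)
    expect_equal(dim(x), c(32, 32, 32, 4))
    expect_true(all(x[, , , 1:2] >= 0 & x[, , , 1:2] <= 1))
    expect_true(all(x[, , , 3:4] %in% c(0, 1)))
    # channel order: swapping scans must show up in channel 1 minus channel 2
    expect_gt(max(abs(x[, , , 1] - x[, , , 2])), 0)
    direct <- resampleToGrid(suppressWarnings(windowNormalize(pr@baseline, cfg)),
                             c(32, 32, 32))
    expect_equal(x[, , , 1], voxelData(direct))
    # mask channels follow their masks; all-zero masks give zero channels
    zeroM <- newMask(array(0L, dim = c(48, 48, 48)), spec$spacing_mm)
    x0 <- preprocessPair(pr, masks = list(zeroM, zeroM), cfg = cfg)
    expect_true(all(x0[, , , 3:4] == 0))

    badM <- newMask(array(0L, dim = c(24, 24, 24)), spec$spacing_mm)
    expect_error(preprocessPair(pr, masks = list(badM, badM), cfg = cfg), "alignment")
})
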