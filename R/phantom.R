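#' Specification of a synthetic head-CT phantom
#'
#' Parametric head anatomy used by the generator: a closed ellipsoidal skull
#' shell of bone-like intensity, a brain compartment separated from the skull
#' by a thin CSF rim, two ellipsoidal ventricles, and (optionally) an
#' ellipsoid-seeded hematoma. Intensities are in Hounsfield units: air
#' -1000, bone-like skull (default 1000), parenchyma around 35 HU, CSF
#' around 8 HU, acute blood uniform in `hematoma_hu_range`.
#'
#' @param grid_shape Integer triple of voxel counts, all >= 16.
#' @param spacing_mm Positive spacing triple in mm.
#' @param skull_hu Skull intensity (HU).
#' @param brain_hu_mean,brain_hu_sd Parenchyma intensity distribution (HU).
#' @param csf_hu_mean,csf_hu_sd CSF intensity distribution (HU).
#' @param hematoma_hu_range Length-2 range for blood intensities; must lie
#'   inside the 40--200 HU band used for hematoma delineation.
#' @param skull_thickness_mm Skull shell thickness in mm.
#' @param noise_sd_hu Additive acquisition noise (HU).
#' @return A `PhantomSpec` (validated list).
#' @examples
#' spec <- phantomSpec(grid_shape = c(48, 48, 48), spacing_mm = c(3, 3, 3))
#' @export
phantomSpec <- function(grid_shape = c(64, 64, 64),
                        spacing_mm = c(2.5, 2.5, 2.5),
                        skull_hu = 1000,
                        brain_hu_mean = 35, brain_hu_sd = 5,
                        csf_hu_mean = 8, csf_hu_sd = 3,
                        hematoma_hu_range = c(50, 80),
                        skull_thickness_mm = 6,
                        noise_sd_hu = 2) {
    grid_shape <- as.integer(grid_shape)
    if (length(grid_shape) != 3L || any(grid_shape < 16L))
        stop("grid_shape must be an integer triple with all entries >= 16")
    if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
        stop("spacing_mm must be strictly positive")
    if (length(hematoma_hu_range) != 2L || hematoma_hu_range[1] >= hematoma_hu_range[2])
        stop("hematoma_hu_range must be an increasing pair")
    if (hematoma_hu_range[1] < 40 || hematoma_hu_range[2] > 200)
        stop("hematoma_hu_range must lie within the 40-200 HU delineation band")
    if (skull_thickness_mm <= 0) stop("skull_thickness_mm must be positive")
    if (noise_sd_hu < 0) stop("noise_sd_hu must be non-negative")
    structure(list(
        grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
        skull_hu = skull_hu, brain_hu_mean = brain_hu_mean,
        brain_hu_sd = brain_hu_sd, csf_hu_mean = csf_hu_mean,
        csf_hu_sd = csf_hu_sd, hematoma_hu_range = as.numeric(hematoma_hu_range),
        skull_thickness_mm = skull_thickness_mm, noise_sd_hu = noise_sd_hu
    ), class = "PhantomSpec")
}

# Deterministic compartment geometry: integer label array
# 0 air, 1 skull, 2 CSF rim, 3 parenchyma, 4 ventricle.
# Returned with helper masks; no RNG involved.
phantomCompartments <- function(spec) {
    d <- spec$grid_shape
    sp <- spec$spacing_mm
    ext <- d * sp
    ctr <- ext / 2
    xs <- (seq_len(d[1]) - 0.5) * sp[1] - ctr[1]
    ys <- (seq_len(d[2]) - 0.5) * sp[2] - ctr[2]
    zs <- (seq_len(d[3]) - 0.5) * sp[3] - ctr[3]
    aOut <- 0.45 * ext
    aIn <- aOut - spec$skull_thickness_mm
    rim <- 2 * sp # CSF rim thickness: two voxels
    aBrain <- aIn - rim

    ellip <- function(cx, cy, cz, ax, ay, az) {
        qx <- ((xs - cx) / ax)^2
        qy <- ((ys - cy) / ay)^2
        qz <- ((zs - cz) / az)^2
        outer(outer(qx, qy, `+`), qz, `+`) <= 1
    }
    inOuter <- ellip(0, 0, 0, aOut[1], aOut[2], aOut[3])
    inInner <- ellip(0, 0, 0, aIn[1], aIn[2], aIn[3])
    inBrain <- ellip(0, 0, 0, aBrain[1], aBrain[2], aBrain[3])
    vSemi <- c(0.06, 0.13, 0.08) * ext
    vOff <- 0.08 * ext[1]
    inVent <- ellip(-vOff, 0, 0, vSemi[1], vSemi[2], vSemi[3]) |
        ellip(vOff, 0, 0, vSemi[1], vSemi[2], vSemi[3])
    inVent <- inVent & inBrain

    lab <- array(0L, dim = d)
    lab[inOuter & !inInner] <- 1L
    lab[inInner & !inBrain] <- 2L
    lab[inBrain] <- 3L
    lab[inVent] <- 4L
    list(labels = lab, brain = inBrain & !inVent, headInterior = inInner)
}

# Render HU volume from compartment labels + lesion mask, under the current RNG.
renderPhantomHU <- function(comp, lesion, spec) {
    d <- spec$grid_shape
    lab <- comp$labels
    hu <- array(-1000, dim = d)
    nS <- sum(lab == 1L)
    nR <- sum(lab == 2L)
    nB <- sum(lab == 3L)
    nV <- sum(lab == 4L)
    hu[lab == 1L] <- spec$skull_hu
    hu[lab == 2L] <- stats::rnorm(nR, spec$csf_hu_mean, spec$csf_hu_sd)
    hu[lab == 3L] <- stats::rnorm(nB, spec$brain_hu_mean, spec$brain_hu_sd)
    hu[lab == 4L] <- stats::rnorm(nV, spec$csf_hu_mean, spec$csf_hu_sd)
    les <- lesion == 1L
    hu[les] <- stats::runif(sum(les), spec$hematoma_hu_range[1], spec$hematoma_hu_range[2])
    if (spec$noise_sd_hu > 0)
        hu <- hu + array(stats::rnorm(prod(d), 0, spec$noise_sd_hu), dim = d)
    hu
}

# Ellipsoid-seeded lesion of an exact voxel count inside `allowed`.
seedLesionMask <- function(spec, nVox, allowed) {
    d <- spec$grid_shape
    if (nVox == 0L) return(array(0L, dim = d))
    idx <- which(allowed)
    if (nVox > length(idx))
        stop("capacity error: requested lesion larger than the brain compartment")
    co <- arrayInd(idx, d)
    sp <- spec$spacing_mm
    # deep-seated centre: restrict candidate centres to the inner half of the
    # brain compartment (by distance to its centroid), lesion still clipped to
    # `allowed` during growth
    cen <- colMeans(co)
    dist2 <- ((co[, 1] - cen[1]) * sp[1])^2 + ((co[, 2] - cen[2]) * sp[2])^2 +
        ((co[, 3] - cen[3]) * sp[3])^2
    deep <- idx[dist2 <= stats::quantile(dist2, 0.35)]
    cIdx <- deep[sample.int(length(deep), 1L)]
    cc <- arrayInd(cIdx, d)[1, ]
    aniso <- stats::runif(3, 0.7, 1.4)
    q <- (((co[, 1] - cc[1]) * sp[1]) / aniso[1])^2 +
        (((co[, 2] - cc[2]) * sp[2]) / aniso[2])^2 +
        (((co[, 3] - cc[3]) * sp[3]) / aniso[3])^2
    take <- idx[order(q)[seq_len(nVox)]]
    m <- array(0L, dim = d)
    m[take] <- 1L
    m
}

#' Generate a single head-CT phantom with a hematoma of known volume
#'
#' Builds the parametric head anatomy and carves a hematoma of
#' `baseline_volume_ml` (to within half a voxel volume) into the brain
#' compartment, then renders Hounsfield intensities with acquisition noise.
#' Identical `spec` and `seed` give bit-identical output.
#'
#' @param spec A [phantomSpec()].
#' @param baseline_volume_ml Target hematoma volume in mL (>= 0; 0 gives a
#'   lesion-free phantom).
#' @param seed Integer seed.
#' @return A list with elements `volume` ([CTVolume-class]) and `mask`
#'   ([CTMask-class]).
#' @examples
#' p <- makePhantom(phantomSpec(c(32, 32, 32), c(4, 4, 4)), 10, seed = 1)
#' volumeML(p$mask)
#' @export
makePhantom <- function(spec, baseline_volume_ml, seed) {
    stopifnot(inherits(spec, "PhantomSpec"))
    assertScalar(baseline_volume_ml, "baseline_volume_ml")
    if (baseline_volume_ml < 0) stop("baseline_volume_ml must be >= 0")
    comp <- phantomCompartments(spec)
    vml <- voxelVolumeML(spec$spacing_mm)
    nVox <- as.integer(round(baseline_volume_ml / vml))
    withSeed(seed, {
        mask <- seedLesionMask(spec, nVox, comp$brain)
        hu <- renderPhantomHU(comp, mask, spec)
        list(volume = newVolume(hu, spec$spacing_mm),
             mask = newMask(mask, spec$spacing_mm))
    })
}

#' Grow (or shrink) a hematoma mask by a controlled volume
#'
#' Positive `delta_ml` adds voxels by face-connected accretion from the
#' existing boundary with a seed-shuffled frontier order, so the result is a
#' superset of the input and the accretion is a single connected layer
#' attached to the lesion. Negative `delta_ml` peels voxels from the surface.
#' The resulting volume differs from `volume + delta_ml` by at most one voxel
#' volume.
#'
#' @param mask A [CTMask-class].
#' @param delta_ml Signed volume change in mL; at least `-volumeML(mask)`.
#' @param seed Integer seed for the frontier shuffle.
#' @param allowed Optional logical/0-1 array restricting growth (e.g. the
#'   brain compartment). Default: the whole grid.
#' @return The grown/shrunken [CTMask-class].
#' @export
growLesion <- function(mask, delta_ml, seed, allowed = NULL) {
    stopifnot(is(mask, "CTMask"))
    assertScalar(delta_ml, "delta_ml")
    vml <- voxelVolumeML(mask@spacing)
    v0 <- volumeML(mask)
    if (delta_ml < -v0 - vml / 2)
        stop("delta_ml must be >= -volumeML(mask)")
    d <- dim(mask@values)
    n0 <- sum(mask@values)
    nTarget <- max(0L, as.integer(round((v0 + delta_ml) / vml)))
    if (nTarget == n0) return(mask)
    withSeed(seed, {
        keys <- stats::runif(prod(d))
        if (nTarget > n0) {
            allow <- if (is.null(allowed)) rep(1L, prod(d)) else as.integer(allowed != 0)
            res <- cpp_grow_mask(as.integer(mask@values), d, nTarget - n0, allow, keys)
            if (res$added < nTarget - n0)
                stop("capacity error: growth exceeds the allowed compartment")
            out <- array(res$mask, dim = d)
        } else {
            res <- cpp_shrink_mask(as.integer(mask@values), d, n0 - nTarget, keys)
            out <- array(res$mask, dim = d)
        }
        newMask(out, mask@spacing, mask@origin)
    })
}

#' Generate a paired baseline/follow-up phantom subject
#'
#' The two scans share anatomy and hematoma location; the follow-up hematoma
#' is the baseline mask grown by `delta_ml`, and the two scans carry
#' independent noise realizations. The true absolute expansion of the pair is
#' `delta_ml` by construction.
#'
#' @param spec A [phantomSpec()].
#' @param baseline_volume_ml Baseline hematoma volume in mL.
#' @param delta_ml True absolute expansion in mL (may be negative).
#' @param seed Integer seed; all internal draws are derived from it.
#' @param subject_id Identifier stored in the pair.
#' @return A [SubjectPair-class].
#' @examples
#' pr <- makePair(phantomSpec(c(32, 32, 32), c(4, 4, 4)), 10, 7.2, seed = 7)
#' trueDeltaML(pr)
#' @export
makePair <- function(spec, baseline_volume_ml, delta_ml, seed,
                     subject_id = sprintf("subj_%06d", seed %% 1000000L)) {
    stopifnot(inherits(spec, "PhantomSpec"))
    comp <- phantomCompartments(spec)
    vml <- voxelVolumeML(spec$spacing_mm)
    nVox <- as.integer(round(baseline_volume_ml / vml))
    maskB <- withSeed(deriveSeed(seed, "lesion"),
        seedLesionMask(spec, nVox, comp$brain))
    maskBObj <- newMask(maskB, spec$spacing_mm)
    maskFObj <- growLesion(maskBObj, delta_ml, deriveSeed(seed, "growth"),
        allowed = comp$brain | (maskB == 1L))
    huB <- withSeed(deriveSeed(seed, "noise_baseline"),
        renderPhantomHU(comp, maskB, spec))
    huF <- withSeed(deriveSeed(seed, "noise_followup"),
        renderPhantomHU(comp, maskFObj@values, spec))
    new("SubjectPair",
        baseline = newVolume(huB, spec$spacing_mm),
        followup = newVolume(huF, spec$spacing_mm),
        truthMaskBaseline = maskBObj, truthMaskFollowup = maskFObj,
        trueDeltaML = delta_ml, subjectId = subject_id, seed = as.integer(seed))
}

#' Specification of a synthetic cohort
#'
#' The expansion law is a zero-inflated mixture: with probability
#' `zero_weight` the true change is a small jitter (uniform on
#' `c(-jitter_ml, jitter_ml)`), otherwise it is drawn from an exponential
#' tail with mean `tail_scale_ml`. When `zero_weight` is `NA` it is solved
#' from `target_prevalence_3ml` so that the expected fraction of subjects
#' with >= 3 mL expansion matches the target.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param delta_distribution List with `zero_weight` (in \[0,1\] or `NA`),
#'   `tail_scale_ml` (> 0) and `jitter_ml` (>= 0).
#' @param baseline_volume_distribution List with `meanlog`, `sdlog`, `min_ml`,
#'   `max_ml` for a truncated log-normal baseline volume law (mL).
#' @param target_prevalence_3ml Desired >= 3 mL expansion prevalence in (0,1).
#' @param seed Integer cohort seed; per-subject seeds are derived from it.
#' @return A `CohortSpec` (validated list).
#' @export
cohortSpec <- function(n_subjects,
                       delta_distribution = list(zero_weight = NA_real_,
                                                 tail_scale_ml = 8,
                                                 jitter_ml = 0.5),
                       baseline_volume_distribution = list(meanlog = log(10),
                                                           sdlog = 0.6,
                                                           min_ml = 2,
                                                           max_ml = 40),
                       target_prevalence_3ml = 0.25,
                       seed = 1L) {
    n_subjects <- as.integer(n_subjects)
    if (n_subjects < 1L) stop("n_subjects must be >= 1")
    dd <- delta_distribution
    if (is.null(dd$jitter_ml)) dd$jitter_ml <- 0.5
    if (dd$tail_scale_ml <= 0) stop("tail_scale_ml must be positive")
    pTail3 <- exp(-3 / dd$tail_scale_ml)
    if (is.na(dd$zero_weight)) {
        if (target_prevalence_3ml <= 0 || target_prevalence_3ml >= 1)
            stop("target_prevalence_3ml must be in (0, 1)")
        if (target_prevalence_3ml > pTail3)
            stop(sprintf(
                "configuration error: prevalence %.3f unattainable with tail scale %.3g (max %.3f)",
                target_prevalence_3ml, dd$tail_scale_ml, pTail3))
        dd$zero_weight <- 1 - target_prevalence_3ml / pTail3
    } else if (dd$zero_weight < 0 || dd$zero_weight > 1) {
        stop("zero_weight must be in [0, 1]")
    }
    structure(list(
        n_subjects = n_subjects, delta_distribution = dd,
        baseline_volume_distribution = baseline_volume_distribution,
        target_prevalence_3ml = target_prevalence_3ml, seed = as.integer(seed)
    ), class = "CohortSpec")
}

#' Generate a synthetic cohort of paired phantoms
#'
#' Tail/no-expansion group sizes are assigned by stratified allocation
#' (exactly `round((1 - zero_weight) * n)` tail draws, shuffled across
#' subjects) so the realized >= 3 mL prevalence concentrates tightly around
#' the target. Per-subject seeds are derived deterministically from the
#' cohort seed.
#'
#' @param cspec A [cohortSpec()].
#' @param pspec A [phantomSpec()].
#' @return A list of [SubjectPair-class] objects.
#' @seealso [cohortManifest()] for the tabular summary.
#' @export
makeCohort <- function(cspec, pspec) {
    stopifnot(inherits(cspec, "CohortSpec"), inherits(pspec, "PhantomSpec"))
    n <- cspec$n_subjects
    dd <- cspec$delta_distribution
    bd <- cspec$baseline_volume_distribution
    params <- withSeed(cspec$seed, {
        nTail <- as.integer(round((1 - dd$zero_weight) * n))
        isTail <- sample(c(rep(TRUE, nTail), rep(FALSE, n - nTail)))
        deltas <- ifelse(isTail,
            stats::rexp(n, rate = 1 / dd$tail_scale_ml),
            stats::runif(n, -dd$jitter_ml, dd$jitter_ml))
        vols <- stats::rlnorm(n, bd$meanlog, bd$sdlog)
        vols <- pmin(pmax(vols, bd$min_ml), bd$max_ml)
        deltas <- pmax(deltas, -0.9 * vols) # cannot shrink below a residual clot
        list(deltas = deltas, vols = vols)
    })
    lapply(seq_len(n), function(i) {
        makePair(pspec, params$vols[i], params$deltas[i],
            seed = deriveSeed(cspec$seed, i),
            subject_id = sprintf("subj_%04d", i))
    })
}

#' Tabular manifest of a generated cohort
#'
#' @param pairs List of [SubjectPair-class] objects.
#' @return A data.frame with one row per subject: identifiers, seeds,
#'   ground-truth volumes, the true expansion, and the four binary HE labels.
#' @export
cohortManifest <- function(pairs) {
    rows <- lapply(pairs, function(p) {
        lab <- binarizeHE(p@trueDeltaML)
        data.frame(
            subject_id = p@subjectId, seed = p@seed,
            V_baseline_ml = volumeML(p@truthMaskBaseline),
            V_followup_ml = volumeML(p@truthMaskFollowup),
            true_delta_ml = p@trueDeltaML,
            label_3 = lab$label_3, label_6 = lab$label_6,
            label_9 = lab$label_9, label_12_5 = lab$label_12_5,
            stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Segmentation error model
#'
#' Corruption model calibrated to a target Dice: independent removal and
#' addition fractions are drawn per scan from a Gamma distribution (shape 2)
#' with mean `1 - target_dice`, voxels are peeled from the inner boundary
#' shells and accreted on the outer shells. Because equal expected removal
#' and addition leave the Dice at `2(1-r)/(2-r+q)`, the expected Dice equals
#' the target while volumes stay unbiased but noisy -- the cumulative-error
#' behaviour that degrades downstream expansion labels.
#'
#' @param target_dice Target expected Dice in (0, 1]; 1 forces the identity
#'   corruption.
#' @param boundary_flip_rate Mean removal/addition fraction; `NA` (default)
#'   auto-derives `1 - target_dice`.
#' @param dilate_erode_bias_voxels Net systematic bias: positive dilates the
#'   corrupted mask by that ball radius, negative erodes.
#' @param component_dropout_prob Probability that each non-largest connected
#'   component is missed entirely (small-satellite misses).
#' @param seed Integer seed.
#' @return An `ErrorModelSpec` (validated list).
#' @export
errorModelSpec <- function(target_dice = 0.86, boundary_flip_rate = NA_real_,
                           dilate_erode_bias_voxels = 0L,
                           component_dropout_prob = 0, seed = 1L) {
    if (target_dice <= 0 || target_dice > 1)
        stop("parameter error: target_dice must be in (0, 1]")
    if (!is.na(boundary_flip_rate) && (boundary_flip_rate < 0 || boundary_flip_rate >= 1))
        stop("boundary_flip_rate must be in [0, 1)")
    if (component_dropout_prob < 0 || component_dropout_prob >= 1 + 1e-12)
        stop("component_dropout_prob must be in [0, 1]")
    structure(list(
        target_dice = target_dice, boundary_flip_rate = boundary_flip_rate,
        dilate_erode_bias_voxels = as.integer(dilate_erode_bias_voxels),
        component_dropout_prob = component_dropout_prob, seed = as.integer(seed)
    ), class = "ErrorModelSpec")
}

#' Corrupt a mask to a target Dice
#'
#' Applies the [errorModelSpec()] corruption: optional dropout of
#' non-largest connected components, seeded boundary peeling and accretion
#' with per-scan error fractions of mean `1 - target_dice`, and an optional
#' systematic dilate/erode bias. Deterministic given the spec's seed.
#'
#' @param mask A [CTMask-class] (the ground truth).
#' @param espec An [errorModelSpec()].
#' @return The corrupted [CTMask-class].
#' @examples
#' p <- makePhantom(phantomSpec(c(32, 32, 32), c(4, 4, 4)), 10, seed = 1)
#' pert <- perturbMask(p$mask, errorModelSpec(target_dice = 0.86, seed = 2))
#' diceCoef(p$mask, pert)
#' @export
perturbMask <- function(mask, espec) {
    stopifnot(is(mask, "CTMask"), inherits(espec, "ErrorModelSpec"))
    if (espec$target_dice <= 0) stop("parameter error: target_dice must be positive")
    d <- dim(mask@values)
    vals <- as.integer(mask@values)
    n0 <- sum(vals)
    identityModel <- espec$target_dice == 1 &&
        (is.na(espec$boundary_flip_rate) || espec$boundary_flip_rate == 0)
    if (n0 == 0L || (identityModel && espec$component_dropout_prob == 0 &&
                     espec$dilate_erode_bias_voxels == 0L))
        return(mask)
    p <- if (is.na(espec$boundary_flip_rate)) 1 - espec$target_dice else espec$boundary_flip_rate
    withSeed(espec$seed, {
        cur <- vals
        if (espec$component_dropout_prob > 0) {
            lab <- cpp_label_components(cur, d, 26L)
            sizes <- tabulate(lab)
            if (length(sizes) > 1L) {
                keepLargest <- which.max(sizes)
                drop <- which(stats::runif(length(sizes)) < espec$component_dropout_prob)
                drop <- setdiff(drop, keepLargest)
                if (length(drop)) cur[lab %in% drop] <- 0L
            }
        }
        nCur <- sum(cur)
        if (p > 0 && nCur > 0L) {
            rates <- pmin(stats::rgamma(2, shape = 2, rate = 2 / p), 0.45)
            nRm <- as.integer(round(rates[1] * nCur))
            nAdd <- as.integer(round(rates[2] * nCur))
            keysRm <- stats::runif(prod(d))
            keysAdd <- stats::runif(prod(d))
            removed <- if (nRm > 0L)
                cpp_shrink_mask(cur, d, nRm, keysRm)$mask else cur
            grown <- if (nAdd > 0L)
                cpp_grow_mask(cur, d, nAdd, rep(1L, prod(d)), keysAdd)$mask else cur
            # (mask minus peeled voxels) union (accreted voxels outside mask)
            cur <- as.integer(removed == 1L | (grown == 1L & cur == 0L))
        }
        if (espec$dilate_erode_bias_voxels > 0L)
            cur <- cpp_dilate(cur, d, espec$dilate_erode_bias_voxels)
        else if (espec$dilate_erode_bias_voxels < 0L)
            cur <- cpp_erode(cur, d, -espec$dilate_erode_bias_voxels)
        newMask(array(as.integer(cur), dim = d), mask@spacing, mask@origin)
    })
}
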