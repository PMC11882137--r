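#' Preprocessing configuration
#'
#' Parameters of the head-CT preprocessing chain: the 0--200 HU soft-tissue
#' keep-range for skull stripping, the brain window/level (center 40 HU,
#' width 80 HU), and the common grid all scans are resampled to. The
#' morphological radii and the small-object cutoff are exposed because the
#' published chain names the operations but not their parameters.
#'
#' @param hu_keep_range HU interval retained before morphology.
#' @param window_center,window_width Brain window/level in HU (width > 0).
#' @param target_shape Common-grid shape; 64^3 is the desk default, 128^3 the
#'   full-scale setting.
#' @param erosion_radius_voxels,dilation_radius_voxels Ball radii (voxels)
#'   of the erosion/dilation pair.
#' @param min_object_voxels Connected components smaller than this are
#'   discarded between erosion and dilation.
#' @return A `PreprocessConfig` (validated list).
#' @export
preprocessConfig <- function(hu_keep_range = c(0, 200),
                             window_center = 40, window_width = 80,
                             target_shape = c(64, 64, 64),
                             erosion_radius_voxels = 2L,
                             min_object_voxels = 1000L,
                             dilation_radius_voxels = 2L) {
    if (window_width <= 0) stop("window_width must be positive")
    if (length(hu_keep_range) != 2L || hu_keep_range[1] >= hu_keep_range[2])
        stop("hu_keep_range must be an increasing pair")
    target_shape <- as.integer(target_shape)
    if (length(target_shape) != 3L || any(target_shape <= 0L))
        stop("parameter error: target_shape must be three positive integers")
    structure(list(
        hu_keep_range = as.numeric(hu_keep_range),
        window_center = window_center, window_width = window_width,
        target_shape = target_shape,
        erosion_radius_voxels = as.integer(erosion_radius_voxels),
        min_object_voxels = as.integer(min_object_voxels),
        dilation_radius_voxels = as.integer(dilation_radius_voxels)
    ), class = "PreprocessConfig")
}

#' Intensity-threshold skull stripping
#'
#' The classic head-CT chain: (1) keep voxels inside `hu_keep_range`
#' (excluding bone and air), (2) binary erosion, (3) removal of connected
#' components below `min_object_voxels` (26-connectivity), (4) binary
#' dilation, (5) removal of the outer boundary layer. The result is finally
#' intersected with the thresholded set, so bone-range voxels (HU > 200) can
#' never appear in the brain mask.
#'
#' @param vol A [CTVolume-class] in Hounsfield units.
#' @param cfg A [preprocessConfig()].
#' @return The brain [CTMask-class].
#' @export
stripSkull <- function(vol, cfg = preprocessConfig()) {
    stopifnot(is(vol, "CTVolume"))
    hu <- vol@values
    d <- dim(hu)
    cand <- as.integer(hu >= cfg$hu_keep_range[1] & hu <= cfg$hu_keep_range[2])
    if (sum(cand) == 0L)
        stop("empty-brain error: no voxels inside the HU keep-range")
    m <- cpp_erode(cand, d, cfg$erosion_radius_voxels)
    if (sum(m) > 0L && cfg$min_object_voxels > 1L) {
        lab <- cpp_label_components(m, d, 26L)
        sizes <- tabulate(lab)
        small <- which(sizes < cfg$min_object_voxels)
        if (length(small)) m[lab %in% small] <- 0L
    }
    if (sum(m) == 0L)
        stop("empty-brain error: nothing survives erosion and small-object removal")
    m <- cpp_dilate(m, d, cfg$dilation_radius_voxels)
    m <- as.integer(m & !cpp_boundary(m, d, 26L)) # strip the outer contour
    m <- as.integer(m & cand)
    newMask(array(m, dim = d), vol@spacing, vol@origin)
}

#' Brain window/level normalization
#'
#' Affine map of `[center - width/2, center + width/2]` HU onto `[0, 1]`,
#' clipping outside; with the defaults, 0 HU maps to 0, 40 HU to 0.5 and
#' 80 HU to 1. Shape and spacing are unchanged. Applying the map to data
#' that already look normalized (all values in `[0, 1]`) is flagged with a
#' warning since double-windowing silently destroys contrast.
#'
#' @param vol A [CTVolume-class].
#' @param cfg A [preprocessConfig()].
#' @return The windowed [CTVolume-class] with values in `[0, 1]`.
#' @export
windowNormalize <- function(vol, cfg = preprocessConfig()) {
    stopifnot(is(vol, "CTVolume"))
    v <- vol@values
    if (min(v) >= 0 && max(v) <= 1)
        warning("input already lies in [0, 1]; applying the HU window again is almost certainly unintended")
    lo <- cfg$window_center - cfg$window_width / 2
    out <- (v - lo) / cfg$window_width
    out[out < 0] <- 0
    out[out > 1] <- 1
    newVolume(out, vol@spacing, vol@origin)
}

#' Resample a volume or mask to a target grid
#'
#' Maps the native field of view onto `target_shape` (centered, half-voxel
#' convention): continuous mode uses trilinear interpolation, label mode
#' nearest-neighbour (preserving the value set \{0, 1\} exactly). The
#' physical extent is unchanged, so resampling back to the native shape is
#' the inverse mapping.
#'
#' @param x A [CTVolume-class] or [CTMask-class].
#' @param target_shape Integer triple of positive dims.
#' @param mode `"continuous"` or `"label"`; defaults to the natural mode for
#'   the class of `x`.
#' @return Same class as `x`, on the target grid (spacing rescaled so that
#'   extent is preserved).
#' @export
resampleToGrid <- function(x, target_shape,
                           mode = if (is(x, "CTMask")) "label" else "continuous") {
    mode <- match.arg(mode, c("continuous", "label"))
    target_shape <- as.integer(target_shape)
    if (length(target_shape) != 3L || any(target_shape <= 0L))
        stop("parameter error: target dims must be positive")
    vals <- if (is(x, "CTMask")) x@values else x@values
    d <- dim(vals)
    if (identical(d, target_shape)) return(x)
    newSpacing <- x@spacing * d / target_shape
    res <- if (mode == "continuous")
        cpp_resample_trilinear(as.numeric(vals), d, target_shape)
    else
        cpp_resample_nearest(as.numeric(vals), d, target_shape)
    arr <- array(res, dim = target_shape)
    if (is(x, "CTMask")) newMask(arr, newSpacing, x@origin)
    else newVolume(arr, newSpacing, x@origin)
}

#' Assemble the four-channel classifier input for a subject pair
#'
#' Channels, in order: baseline CT, follow-up CT, baseline hematoma mask,
#' follow-up hematoma mask -- all on the common target grid, CTs windowed to
#' `[0, 1]`, masks binary. This is the input layout of the four-input
#' expansion classifier.
#'
#' @param pair A [SubjectPair-class].
#' @param masks List of two [CTMask-class] (baseline, follow-up), typically
#'   predicted segmentations; defaults to the pair's truth masks.
#' @param cfg A [preprocessConfig()].
#' @return A numeric array of dim `c(cfg$target_shape, 4)`.
#' @export
preprocessPair <- function(pair, masks = NULL, cfg = preprocessConfig()) {
    stopifnot(is(pair, "SubjectPair"))
    if (is.null(masks))
        masks <- list(pair@truthMaskBaseline, pair@truthMaskFollowup)
    if (!sameShape(masks[[1]]@values, pair@baseline@values) ||
        !sameShape(masks[[2]]@values, pair@followup@values))
        stop("alignment error: masks must match their scans in shape")
    ts <- cfg$target_shape
    chans <- list(
        resampleToGrid(windowNormalize(pair@baseline, cfg), ts, "continuous"),
        resampleToGrid(windowNormalize(pair@followup, cfg), ts, "continuous"),
        resampleToGrid(masks[[1]], ts, "label"),
        resampleToGrid(masks[[2]], ts, "label")
    )
    out <- array(0, dim = c(ts, 4L))
    for (i in 1:4) out[, , , i] <- if (is(chans[[i]], "CTMask"))
        chans[[i]]@values else chans[[i]]@values
    out
}
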