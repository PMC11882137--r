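#' Configuration of the small trainable 3-D U-Net
#'
#' A fixed stride-2-encoder U-Net (depth 3) stands in for a self-configuring
#' segmentation framework: the pipeline around it, not the backbone, is the
#' object of study here, and the desk-scale network trains in minutes on a
#' CPU. Optimizer defaults follow the standard recipe for this family:
#' SGD with momentum 0.9, polynomial learning-rate decay, weight decay 3e-5,
#' initial learning rate 1e-2.
#'
#' @param depth Encoder depth (fixed topology; must be >= 2).
#' @param base_channels Channels of the first encoder level (desk default 8).
#' @param weight_decay L2 penalty on conv weights.
#' @param initial_lr Initial SGD learning rate (> 0).
#' @param num_epochs Training epochs (100 at full scale; desk default 5).
#' @param lr_schedule `"poly"`: lr_t = lr0 * (1 - t/T)^0.9.
#' @param optimizer `"sgd"` (momentum 0.9).
#' @param input_size Common-grid shape volumes are resampled to for the
#'   network (desk default 48^3).
#' @param val_fraction Fraction of training volumes held out to monitor
#'   validation loss.
#' @param augment Axis flips plus about +/-10 HU intensity jitter.
#' @param pos_weight Positive-class weight in the voxelwise cross-entropy.
#'   Hematomas occupy well under 1% of a head volume, so unweighted
#'   cross-entropy collapses to the empty prediction; 30 keeps the desk-scale
#'   network off that trivial optimum.
#' @param seed Integer seed controlling initialization, shuffling and
#'   augmentation.
#' @return A `UNetConfig` (validated list).
#' @export
unetConfig <- function(depth = 3L, base_channels = 8L,
                       weight_decay = 3e-5, initial_lr = 1e-2,
                       num_epochs = 5L, lr_schedule = "poly",
                       optimizer = "sgd",
                       input_size = c(48, 48, 48),
                       val_fraction = 0.2, augment = TRUE,
                       pos_weight = 30, seed = 1L) {
    if (depth < 2L) stop("depth must be >= 2")
    if (initial_lr <= 0) stop("initial_lr must be positive")
    input_size <- as.integer(input_size)
    if (any(input_size %% 4L != 0L))
        stop("input_size must be divisible by 4 for the stride-2 encoder")
    structure(list(
        depth = as.integer(depth), base_channels = as.integer(base_channels),
        weight_decay = weight_decay, initial_lr = initial_lr,
        num_epochs = as.integer(num_epochs), lr_schedule = lr_schedule,
        optimizer = optimizer, input_size = input_size,
        val_fraction = val_fraction, augment = isTRUE(augment),
        pos_weight = pos_weight, seed = as.integer(seed)
    ), class = "UNetConfig")
}

# Skull-stripped, windowed, z-scored, resampled network input for one scan.
# Without the strip, clipped bone (1.0) is indistinguishable from acute
# blood in the windowed image; the within-brain z-scoring puts parenchyma at
# 0 and acute blood several standard deviations up, which conditions the
# desk-scale optimization.
unetPrepInput <- function(vol, input_size) {
    brain <- tryCatch(stripSkull(vol)@values,
                      error = function(e) array(0L, dim = dim(vol@values)))
    v <- suppressWarnings(windowNormalize(vol))
    inb <- brain == 1L
    if (sum(inb) > 1L) {
        mu <- mean(v@values[inb])
        sd <- stats::sd(v@values[inb])
        if (sd > 0) v@values <- (v@values - mu) / sd
    }
    v@values <- v@values * brain
    v <- resampleToGrid(v, input_size, "continuous")
    array(v@values, dim = c(input_size, 1L))
}

unetPrepTarget <- function(mask, input_size) {
    m <- resampleToGrid(mask, input_size, "label")
    array(as.numeric(m@values), dim = c(input_size, 1L))
}

# Random axis flips (same for input and target) and intensity jitter.
unetAugment <- function(x, y) {
    for (ax in 1:3) {
        if (stats::runif(1) < 0.5) {
            idx <- rev(seq_len(dim(x)[ax]))
            if (ax == 1) { x <- x[idx, , , , drop = FALSE]; y <- y[idx, , , , drop = FALSE] }
            if (ax == 2) { x <- x[, idx, , , drop = FALSE]; y <- y[, idx, , , drop = FALSE] }
            if (ax == 3) { x <- x[, , idx, , drop = FALSE]; y <- y[, , idx, , drop = FALSE] }
        }
    }
    x <- x + stats::runif(1, -0.5, 0.5) # intensity jitter, z-score units (~ a few HU)
    list(x = x, y = y)
}

#' Train the small 3-D U-Net on a phantom cohort
#'
#' Both scans of every subject are used as independent training volumes
#' (inputs windowed to `[0, 1]` and resampled to `cfg$input_size`; targets
#' are the ground-truth masks). Training is plain per-volume SGD with
#' momentum under binary cross-entropy with logits, polynomial learning-rate
#' decay and light augmentation. Deterministic given `cfg$seed` on a single
#' thread.
#'
#' @param cohort List of [SubjectPair-class] (>= 4 subjects).
#' @param cfg A [unetConfig()].
#' @return A `UNetModel`: list with `params`, `cfg` and a per-epoch `log`
#'   (training loss, validation loss, training Dice).
#' @export
trainUNet <- function(cohort, cfg = unetConfig()) {
    if (length(cohort) == 0L) stop("data error: empty cohort")
    if (length(cohort) < 4L) stop("data error: need >= 4 subjects to train")
    xs <- list(); ys <- list()
    for (p in cohort) {
        xs[[length(xs) + 1L]] <- unetPrepInput(p@baseline, cfg$input_size)
        ys[[length(ys) + 1L]] <- unetPrepTarget(p@truthMaskBaseline, cfg$input_size)
        xs[[length(xs) + 1L]] <- unetPrepInput(p@followup, cfg$input_size)
        ys[[length(ys) + 1L]] <- unetPrepTarget(p@truthMaskFollowup, cfg$input_size)
    }
    nv <- length(xs)
    withSeed(cfg$seed, {
        nVal <- max(1L, floor(cfg$val_fraction * nv))
        valIdx <- sample.int(nv, nVal)
        trIdx <- setdiff(seq_len(nv), valIdx)
        params <- unetInitParams(cfg$base_channels)
        mom <- nnZeroLike(params)
        log <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric(), train_dice = numeric())
        for (ep in seq_len(cfg$num_epochs)) {
            lr <- cfg$initial_lr * (1 - (ep - 1) / cfg$num_epochs)^0.9
            ord <- sample(trIdx)
            epLoss <- 0; inter <- 0; sizes <- 0
            for (i in ord) {
                xi <- xs[[i]]; yi <- ys[[i]]
                if (cfg$augment) {
                    au <- unetAugment(xi, yi)
                    xi <- au$x; yi <- au$y
                }
                fwd <- unetForward(params, xi)
                bce <- nnBceLogits(as.numeric(fwd$logits), as.numeric(yi), cfg$pos_weight)
                grads <- unetBackward(params, fwd,
                    array(bce$grad, dim = dim(fwd$logits)))
                st <- nnSgdStep(params, grads, mom, lr, 0.9, cfg$weight_decay)
                params <- st$params; mom <- st$state
                epLoss <- epLoss + bce$loss
                pred <- fwd$logits > 0
                inter <- inter + 2 * sum(pred & (yi > 0.5))
                sizes <- sizes + sum(pred) + sum(yi > 0.5)
            }
            valLoss <- mean(vapply(valIdx, function(i) {
                fwd <- unetForward(params, xs[[i]])
                nnBceLogits(as.numeric(fwd$logits), as.numeric(ys[[i]]),
                            cfg$pos_weight)$loss
            }, numeric(1)))
            log <- rbind(log, data.frame(epoch = ep, train_loss = epLoss / length(ord),
                val_loss = valLoss,
                train_dice = if (sizes > 0) inter / sizes else 1))
        }
        structure(list(params = params, cfg = cfg, log = log), class = "UNetModel")
    })
}

#' Segment one scan with a trained U-Net
#'
#' The scan is windowed and resampled to the network grid, the probability
#' map is thresholded at 0.5, and the predicted mask is mapped back to the
#' scan's native space by the inverse (nearest-neighbour) resampling, where
#' the volume is computed.
#'
#' @param model A `UNetModel` from [trainUNet()].
#' @param vol A [CTVolume-class] in Hounsfield units.
#' @param truth Optional truth [CTMask-class] for Dice reporting.
#' @return A [SegmentationResult-class] (engine `"unet"`).
#' @export
segmentScan <- function(model, vol, truth = NULL) {
    stopifnot(inherits(model, "UNetModel"), is(vol, "CTVolume"))
    x <- unetPrepInput(vol, model$cfg$input_size)
    fwd <- unetForward(model$params, x)
    prob <- stats::plogis(as.numeric(fwd$logits))
    common <- newMask(array(as.integer(prob >= 0.5), dim = model$cfg$input_size),
                      vol@spacing * dim(vol@values) / model$cfg$input_size, vol@origin)
    native <- resampleToGrid(common, dim(vol@values), "label")
    native@spacing <- vol@spacing
    dice <- if (is.null(truth)) NA_real_ else diceCoef(truth, native)
    new("SegmentationResult", predictedMask = native,
        volumeML = volumeML(native), diceVsTruth = dice, engine = "unet")
}

#' Oracle-perturbation segmentation of a subject pair
#'
#' A deterministic stand-in for a trained segmenter: the ground-truth masks
#' of the pair are corrupted by [perturbMask()] with seeds derived
#' independently for the baseline and follow-up scans, so segmentation
#' errors on the two scans are independent and accumulate in the volume
#' difference -- the failure mode that motivates probability-scored
#' expansion classification in the first place.
#'
#' @param pair A [SubjectPair-class] with truth masks.
#' @param espec An [errorModelSpec()]; `target_dice = 1` returns the truth
#'   masks unchanged.
#' @return A list of two [SegmentationResult-class] objects
#'   (`baseline`, `followup`), each carrying its Dice against truth.
#' @export
oracleSegment <- function(pair, espec) {
    stopifnot(is(pair, "SubjectPair"), inherits(espec, "ErrorModelSpec"))
    mk <- function(truth, salt) {
        es <- espec
        es$seed <- deriveSeed(espec$seed, paste0(pair@subjectId, "_", salt))
        pred <- perturbMask(truth, es)
        new("SegmentationResult", predictedMask = pred,
            volumeML = volumeML(pred), diceVsTruth = diceCoef(truth, pred),
            engine = "oracle")
    }
    list(baseline = mk(pair@truthMaskBaseline, "baseline"),
         followup = mk(pair@truthMaskFollowup, "followup"))
}
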