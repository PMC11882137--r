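#' Direct volume-difference expansion score
#'
#' The predicted absolute expansion in mL from two segmentation results.
#' One continuous score ranks all four HE thresholds; a perfect segmenter
#' makes this score equal the true expansion and therefore a perfect ranker.
#'
#' @param result_baseline,result_followup [SegmentationResult-class] objects.
#' @return Predicted expansion in mL.
#' @examples
#' # volumes 10 and 17.2 mL give a score of 7.2
#' @export
volumeScore <- function(result_baseline, result_followup) {
    absoluteHE(volumeML(result_baseline), volumeML(result_followup))
}

#' Configuration of the four-input expansion classifier
#'
#' A convolutional classifier over the four-channel subject tensor (baseline
#' CT, follow-up CT, and the two hematoma masks). A shared-weight backbone
#' embeds each input separately; the four pooled embeddings are concatenated
#' and a linear head emits four logits, one per HE threshold, through
#' sigmoids. Training follows the standard recipe: binary cross-entropy with
#' logits, Adam (lr 1e-4, weight decay 1e-5), reduce-on-plateau scheduling,
#' early stopping, dropout 0.1 on the embedding.
#'
#' @param backbone_scale `"desk"` (embedding 64, input 48^3) or `"paper"`
#'   (embedding 1024, input 128^3). Desk scale trains on a CPU in minutes.
#' @param lr Adam learning rate. `NULL` (default) resolves per scale: 1e-4
#'   at paper scale (the published recipe, paired with hundreds of subjects
#'   and 100 epochs) and 1e-2 at desk scale, where only a few hundred
#'   optimizer steps are taken.
#' @param weight_decay Adam weight decay.
#' @param epochs Maximum epochs (desk default 12).
#' @param early_stopping_patience Epochs without validation improvement
#'   before stopping.
#' @param scheduler_patience Epochs without improvement before the learning
#'   rate is halved.
#' @param dropout_p Dropout probability on the concatenated embedding.
#' @param input_size Grid the four channels must be on; `NULL` takes the
#'   scale default.
#' @param feature_dim Per-input embedding size F (features are 4F); `NULL`
#'   takes the scale default.
#' @param val_fraction Held-out fraction for validation monitoring.
#' @param seed Integer seed.
#' @return A `CnnConfig` (validated list).
#' @export
cnnConfig <- function(backbone_scale = c("desk", "paper"),
                      lr = NULL, weight_decay = 1e-5,
                      epochs = 12L, early_stopping_patience = 5L,
                      scheduler_patience = 2L, dropout_p = 0.1,
                      input_size = NULL, feature_dim = NULL,
                      val_fraction = 0.25, seed = 1L) {
    backbone_scale <- match.arg(backbone_scale)
    if (dropout_p < 0 || dropout_p >= 1) stop("dropout_p must be in [0, 1)")
    defaults <- if (backbone_scale == "desk")
        list(input = c(48, 48, 48), fdim = 64L, channels = c(8L, 16L), lr = 1e-2)
    else
        list(input = c(128, 128, 128), fdim = 1024L, channels = c(32L, 64L), lr = 1e-4)
    if (is.null(lr)) lr <- defaults$lr
    structure(list(
        backbone_scale = backbone_scale, loss = "bce_logits",
        lr = lr, weight_decay = weight_decay, optimizer = "adam",
        scheduler = "reduce_on_plateau", epochs = as.integer(epochs),
        early_stopping_patience = as.integer(early_stopping_patience),
        scheduler_patience = as.integer(scheduler_patience),
        dropout_p = dropout_p,
        input_size = as.integer(if (is.null(input_size)) defaults$input else input_size),
        feature_dim = as.integer(if (is.null(feature_dim)) defaults$fdim else feature_dim),
        channels = defaults$channels, n_outputs = 4L,
        val_fraction = val_fraction, seed = as.integer(seed)
    ), class = "CnnConfig")
}

checkCnnInputs <- function(inputs, cfg) {
    for (x in inputs) {
        d <- dim(x)
        if (length(d) != 4L || d[4] != 4L)
            stop("each input must be a 4-channel array from preprocessPair()")
        if (!identical(as.integer(d[1:3]), cfg$input_size))
            stop("configuration error: inputs are not on the configured grid")
    }
    invisible(TRUE)
}

#' Train the four-input CNN expansion classifier
#'
#' Per-subject Adam steps on the multi-label binary cross-entropy over the
#' four HE thresholds, with a random validation split, reduce-on-plateau
#' learning-rate halving, and early stopping on validation loss.
#' Deterministic given `cfg$seed` on a single thread.
#'
#' @param inputs List of four-channel arrays (one per subject), from
#'   [preprocessPair()].
#' @param labels n x 4 binary matrix (columns: >= 3, 6, 9, 12.5 mL).
#' @param cfg A [cnnConfig()].
#' @return A `CnnModel`: list with `params`, `cfg`, per-epoch `log`, and the
#'   `best_epoch` used for the retained weights.
#' @export
trainCnn <- function(inputs, labels, cfg = cnnConfig()) {
    n <- length(inputs)
    if (n < 8L) stop("data error: need >= 8 training subjects")
    labels <- as.matrix(labels)
    if (nrow(labels) != n || ncol(labels) != 4L)
        stop("labels must be an n x 4 binary matrix")
    checkCnnInputs(inputs, cfg)
    withSeed(cfg$seed, {
        nVal <- max(1L, floor(cfg$val_fraction * n))
        # stratified split on the >= 3 mL label so the validation set carries
        # positives at roughly the cohort prevalence
        pos <- sample(which(labels[, 1] == 1))
        neg <- sample(which(labels[, 1] == 0))
        nValPos <- min(length(pos), round(nVal * length(pos) / n))
        valIdx <- c(pos[seq_len(nValPos)],
                    neg[seq_len(min(length(neg), nVal - nValPos))])
        trIdx <- setdiff(seq_len(n), valIdx)
        params <- cnnInitParams(cfg$channels, cfg$feature_dim, cfg$n_outputs)
        adam <- list(t = 0, m = nnZeroLike(params), v = nnZeroLike(params))
        lr <- cfg$lr
        # warm-up pass: embedding batch statistics over the training split
        warm <- vapply(trIdx, function(i)
            cnnForward(params, inputs[[i]])$emb_raw,
            numeric(4L * cfg$feature_dim))
        bn <- list(mean = rowMeans(warm),
                   var = pmax(apply(warm, 1, stats::var), 1e-12), n = length(trIdx))
        bestLoss <- Inf; bestParams <- params; bestBn <- bn; bestEpoch <- 0L
        sinceBest <- 0L; sincePlateau <- 0L
        log <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric(), lr = numeric())
        valLossAt <- function(pr, bns) {
            mean(vapply(valIdx, function(i) {
                fwd <- cnnForward(pr, inputs[[i]], bn = bns)
                nnBceLogits(fwd$logits, labels[i, ])$loss
            }, numeric(1)))
        }
        for (ep in seq_len(cfg$epochs)) {
            ord <- sample(trIdx)
            epLoss <- 0
            for (i in ord) {
                mask <- if (cfg$dropout_p > 0) {
                    keep <- stats::runif(4L * cfg$feature_dim) >= cfg$dropout_p
                    keep / (1 - cfg$dropout_p)
                } else NULL
                fwd <- cnnForward(params, inputs[[i]], mask, bn)
                bce <- nnBceLogits(fwd$logits, labels[i, ])
                grads <- cnnBackward(params, fwd, bce$grad, mask, bn)
                st <- nnAdamStep(params, grads, adam, lr, cfg$weight_decay)
                params <- st$params; adam <- st$state
                bn <- cnnBnUpdate(bn, fwd$emb_raw, momentum = 0.02)
                epLoss <- epLoss + bce$loss
            }
            vl <- valLossAt(params, bn)
            log <- rbind(log, data.frame(epoch = ep, train_loss = epLoss / length(ord),
                                         val_loss = vl, lr = lr))
            if (vl < bestLoss - 1e-9) {
                bestLoss <- vl; bestParams <- params; bestBn <- bn; bestEpoch <- ep
                sinceBest <- 0L; sincePlateau <- 0L
            } else {
                sinceBest <- sinceBest + 1L
                sincePlateau <- sincePlateau + 1L
                if (sincePlateau >= cfg$scheduler_patience) {
                    lr <- lr / 2
                    sincePlateau <- 0L
                }
                if (sinceBest >= cfg$early_stopping_patience) break
            }
        }
        structure(list(params = bestParams, bn = bestBn,
                       final_params = params, final_bn = bn, cfg = cfg,
                       log = log, best_epoch = bestEpoch), class = "CnnModel")
    })
}

#' Predict expansion probabilities with a trained CNN
#'
#' @param model A `CnnModel`.
#' @param inputs List of four-channel arrays.
#' @param subject_ids Optional identifiers for the output table.
#' @param weights `"best"` (the best-validation-loss snapshot, the default)
#'   or `"final"` (the last epoch, e.g. for training-set diagnostics on very
#'   small cohorts where the validation split is too noisy to select on).
#' @return A `ScoreSet` data.frame: one row per subject and HE threshold,
#'   columns `subject_id`, `threshold`, `score`, `source`.
#' @export
predictCnn <- function(model, inputs, subject_ids = NULL,
                       weights = c("best", "final")) {
    stopifnot(inherits(model, "CnnModel"))
    weights <- match.arg(weights)
    pars <- if (weights == "best") model$params else model$final_params
    bn <- if (weights == "best") model$bn else model$final_bn
    checkCnnInputs(inputs, model$cfg)
    if (is.null(subject_ids)) subject_ids <- sprintf("subj_%04d", seq_along(inputs))
    probs <- t(vapply(inputs, function(x)
        stats::plogis(cnnForward(pars, x, bn = bn)$logits), numeric(4)))
    scoreSetFromMatrix(subject_ids, probs, source = "cnn")
}

#' Extract the concatenated embedding features for the SVM
#'
#' The per-input pooled embeddings of the shared backbone, concatenated in
#' channel order (baseline CT, follow-up CT, baseline mask, follow-up mask):
#' a 4F vector per subject, F being `feature_dim`.
#'
#' @param model A `CnnModel`.
#' @param inputs List of four-channel arrays.
#' @return n x 4F numeric matrix.
#' @export
extractFeatures <- function(model, inputs) {
    stopifnot(inherits(model, "CnnModel"))
    checkCnnInputs(inputs, model$cfg)
    t(vapply(inputs, function(x) cnnForward(model$params, x, bn = model$bn)$emb,
             numeric(4L * model$cfg$feature_dim)))
}

#' Train per-threshold RBF-SVM classifiers on CNN features
#'
#' One C-classification support vector machine with a radial basis function
#' kernel per HE threshold, default hyperparameters, with internal
#' cross-validated sigmoid calibration for probability outputs. A threshold
#' whose labels are single-class in the training data is skipped with a
#' warning.
#'
#' @param features n x 4F matrix from [extractFeatures()].
#' @param labels n x 4 binary matrix.
#' @param seed Integer seed (probability calibration resamples internally).
#' @return A `SvmBank`: list of fitted models (or `NULL` where skipped).
#' @export
trainSvm <- function(features, labels, seed = 1L) {
    labels <- as.matrix(labels)
    stopifnot(nrow(features) == nrow(labels), ncol(labels) == 4L)
    # ReLU-dead embedding dimensions are constant; drop them before scaling
    keep <- which(apply(features, 2, stats::sd) > 1e-10)
    if (!length(keep)) stop("all feature columns are constant")
    models <- withSeed(seed, lapply(1:4, function(j) {
        y <- factor(labels[, j], levels = c(0, 1))
        if (length(unique(labels[, j])) < 2L) {
            warning(sprintf("threshold %g mL: single-class labels, SVM skipped",
                            HE_THRESHOLDS_ML[j]))
            return(NULL)
        }
        e1071::svm(x = features[, keep, drop = FALSE], y = y,
                   kernel = "radial", probability = TRUE)
    }))
    structure(list(models = models, keep = keep), class = "SvmBank")
}

#' Predict expansion probabilities with the SVM bank
#'
#' @param bank A `SvmBank` from [trainSvm()].
#' @param features n x 4F matrix.
#' @param subject_ids Optional identifiers.
#' @return A `ScoreSet` data.frame (source `"cnn_svm"`); skipped thresholds
#'   yield `NA` scores.
#' @export
predictSvm <- function(bank, features, subject_ids = NULL) {
    stopifnot(inherits(bank, "SvmBank"))
    if (is.null(subject_ids)) subject_ids <- sprintf("subj_%04d", seq_len(nrow(features)))
    probs <- sapply(1:4, function(j) {
        m <- bank$models[[j]]
        if (is.null(m)) return(rep(NA_real_, nrow(features)))
        pr <- stats::predict(m, features[, bank$keep, drop = FALSE],
                             probability = TRUE)
        attr(pr, "probabilities")[, "1"]
    })
    scoreSetFromMatrix(subject_ids, probs, source = "cnn_svm")
}

#' Build a long-format score table
#'
#' @param subject_ids Character vector, one per subject.
#' @param scores n x 4 matrix of continuous scores (columns = HE thresholds).
#' @param labels Optional n x 4 binary truth matrix.
#' @param source Score provenance: `"volume"`, `"cnn"` or `"cnn_svm"`.
#' @return A `ScoreSet` data.frame with columns `subject_id`, `threshold`,
#'   `score`, (`label`,) `source`.
#' @export
scoreSetFromMatrix <- function(subject_ids, scores, labels = NULL, source = "volume") {
    scores <- as.matrix(scores)
    out <- data.frame(
        subject_id = rep(subject_ids, times = 4L),
        threshold = rep(HE_THRESHOLDS_ML, each = length(subject_ids)),
        score = as.numeric(scores),
        source = source, stringsAsFactors = FALSE)
    if (!is.null(labels)) out$label <- as.integer(as.matrix(labels))
    out
}

#' Stratified k-fold assignment
#'
#' Positives and negatives are shuffled separately and dealt round-robin
#' (negatives in reverse fold order to balance fold sizes), so each fold's
#' positive count is within one subject of the global ratio and the folds
#' partition the cohort exactly.
#'
#' @param labels Binary vector.
#' @param k Number of folds (n >= k).
#' @param seed Integer seed.
#' @return Integer fold assignment (1..k) per subject.
#' @examples
#' f <- stratifiedKFold(rep(c(1, 0), c(25, 75)), k = 5, seed = 1)
#' table(f) # 20 per fold, 5 positives each
#' @export
stratifiedKFold <- function(labels, k = 5L, seed = 1L) {
    labels <- as.integer(as.logical(labels))
    n <- length(labels)
    if (n < k) stop("need at least k subjects")
    withSeed(seed, {
        fold <- integer(n)
        pos <- sample(which(labels == 1L))
        neg <- sample(which(labels == 0L))
        fold[pos] <- rep_len(seq_len(k), length(pos))
        fold[neg] <- rep_len(rev(seq_len(k)), length(neg))
        fold
    })
}
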