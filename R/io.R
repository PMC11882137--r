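#' Read a CT volume from NIfTI-1
#'
#' Spacing is taken from the header `pixdim`. Values and spacing round-trip
#' bit-exactly through [writeVolume()] for volumes written by this package.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [CTVolume-class].
#' @export
readVolume <- function(path) {
    img <- RNifti::readNifti(path)
    arr <- array(as.numeric(img), dim = dim(img))
    sp <- attr(img, "pixdim")[1:3]
    newVolume(arr, sp)
}

#' Read a binary mask from NIfTI-1
#'
#' Values are rounded and must be 0/1 after rounding; anything else raises a
#' validation error reporting the offending values.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [CTMask-class].
#' @export
readMask <- function(path) {
    img <- RNifti::readNifti(path)
    arr <- round(array(as.numeric(img), dim = dim(img)))
    bad <- setdiff(unique(as.numeric(arr)), c(0, 1))
    if (length(bad))
        stop("validation error: mask file contains non-binary voxel values: ",
             paste(utils::head(bad, 5), collapse = ", "))
    sp <- attr(img, "pixdim")[1:3]
    newMask(arr, sp)
}

#' Write a volume or mask as NIfTI-1
#'
#' Volumes are stored as float64 and masks as uint8 so that our own outputs
#' round-trip exactly; spacing goes into the header `pixdim`.
#'
#' @param x A [CTVolume-class] or [CTMask-class].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(x, path) {
    vals <- x@values
    dt <- if (is(x, "CTMask")) "uint8" else "double"
    attr(vals, "pixdim") <- x@spacing
    RNifti::writeNifti(RNifti::asNifti(vals, datatype = dt), path, datatype = dt)
    invisible(path)
}

#' @rdname writeVolume
#' @export
writeMask <- writeVolume

#' Write a cohort to disk
#'
#' One NIfTI per scan and truth mask plus a CSV manifest
#' (`subject_id, seed, V_baseline_ml, V_followup_ml, true_delta_ml,
#' label_3, label_6, label_9, label_12_5`).
#'
#' @param pairs List of [SubjectPair-class].
#' @param dir Output directory (created if missing).
#' @return The manifest data.frame, invisibly.
#' @export
writeCohort <- function(pairs, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (p in pairs) {
        base <- file.path(dir, p@subjectId)
        writeVolume(p@baseline, paste0(base, "_baseline.nii.gz"))
        writeVolume(p@followup, paste0(base, "_followup.nii.gz"))
        writeMask(p@truthMaskBaseline, paste0(base, "_baseline_mask.nii.gz"))
        writeMask(p@truthMaskFollowup, paste0(base, "_followup_mask.nii.gz"))
    }
    manifest <- cohortManifest(pairs)
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    invisible(manifest)
}

#' Assemble a full pipeline run configuration
#'
#' One serializable record holding every stage's parameters plus the global
#' seed. Stage seeds are derived from the global seed, so a config file fully
#' determines a run. Round-trips losslessly through YAML.
#'
#' @param global_seed Integer master seed.
#' @param n_subjects Cohort size per cohort (internal and external).
#' @param out_dir Output directory for [runPipeline()].
#' @param phantom,cohort,error_model,preprocess Stage configs (defaults used
#'   when `NULL`).
#' @param target_dice Oracle segmenter calibration.
#' @param targets Sensitivity/specificity targets for the sweep.
#' @param verbosity 0 silent, 1 progress messages.
#' @return A `RunConfig` (validated list).
#' @export
runConfig <- function(global_seed = 1L, n_subjects = 50L,
                      out_dir = "hetriage_run",
                      phantom = NULL, cohort = NULL, error_model = NULL,
                      preprocess = NULL, target_dice = 0.86,
                      targets = c(1.0, 0.95, 0.90), verbosity = 1L) {
    structure(list(
        global_seed = as.integer(global_seed),
        n_subjects = as.integer(n_subjects),
        out_dir = out_dir,
        phantom = if (is.null(phantom)) phantomSpec() else phantom,
        cohort = cohort, # NULL means: derive from n_subjects + seeds at run time
        error_model = error_model,
        preprocess = if (is.null(preprocess)) preprocessConfig() else preprocess,
        target_dice = target_dice,
        targets = targets, verbosity = as.integer(verbosity)
    ), class = "RunConfig")
}

#' Write / read a run configuration as YAML
#'
#' @param config A [runConfig()].
#' @param path YAML file path.
#' @return `readRunConfig` returns the reconstructed `RunConfig`.
#' @export
writeRunConfig <- function(config, path) {
    stopifnot(inherits(config, "RunConfig"))
    plain <- rapply(unclass(config), function(x) x, how = "replace")
    plain$phantom <- unclass(plain$phantom)
    plain$preprocess <- unclass(plain$preprocess)
    if (!is.null(plain$cohort)) plain$cohort <- unclass(plain$cohort)
    if (!is.null(plain$error_model)) plain$error_model <- unclass(plain$error_model)
    yaml::write_yaml(plain, path)
    invisible(path)
}

#' @rdname writeRunConfig
#' @param path YAML file path.
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    cfg <- runConfig(
        global_seed = y$global_seed, n_subjects = y$n_subjects,
        out_dir = y$out_dir,
        phantom = do.call(phantomSpec, y$phantom),
        preprocess = do.call(preprocessConfig, y$preprocess),
        target_dice = y$target_dice, targets = unlist(y$targets),
        verbosity = y$verbosity)
    if (!is.null(y$cohort)) cfg$cohort <- do.call(cohortSpec, y$cohort)
    if (!is.null(y$error_model)) cfg$error_model <- do.call(errorModelSpec, y$error_model)
    cfg
}

#' Run the end-to-end annotation pipeline on synthetic cohorts
#'
#' Simulate internal and external cohorts, segment every scan with the
#' oracle engine at the configured Dice, compute truth and predicted HE
#' labels, score subjects by predicted volume difference, calibrate
#' sensitivity/specificity operating points on the internal cohort, transfer
#' them to the external cohort, and write all artifacts (manifests, score
#' sets, the threshold sweep, per-subject metrics, a seed log) as CSV under
#' `config$out_dir`. Re-running with the same config reproduces every CSV.
#'
#' @param config A [runConfig()].
#' @return A list with `manifests`, `scores`, `sweep`, and the output paths.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "RunConfig"))
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    say <- function(...) if (config$verbosity > 0) message(sprintf(...))
    stageSeed <- function(stage) deriveSeed(config$global_seed, stage)

    cohorts <- list()
    scores <- list()
    for (nm in c("internal", "external")) {
        cs <- config$cohort
        if (is.null(cs)) cs <- cohortSpec(config$n_subjects)
        cs$seed <- stageSeed(paste0("cohort_", nm))
        cs$n_subjects <- config$n_subjects
        say("simulating %s cohort (n = %d, seed %d)", nm, cs$n_subjects, cs$seed)
        pairs <- makeCohort(cs, config$phantom)
        manifest <- cohortManifest(pairs)
        utils::write.csv(manifest, file.path(config$out_dir,
            paste0("manifest_", nm, ".csv")), row.names = FALSE)

        es <- config$error_model
        if (is.null(es)) es <- errorModelSpec(target_dice = config$target_dice)
        es$seed <- stageSeed(paste0("oracle_", nm))
        say("segmenting %s cohort (oracle, target Dice %.2f)", nm, es$target_dice)
        seg <- lapply(pairs, oracleSegment, espec = es)
        predLab <- labelCohort(pairs, "predicted", seg)
        segTab <- data.frame(
            subject_id = manifest$subject_id,
            dice_baseline = vapply(seg, function(s) s$baseline@diceVsTruth, numeric(1)),
            dice_followup = vapply(seg, function(s) s$followup@diceVsTruth, numeric(1)),
            pred_delta_ml = predLab$delta_ml)
        utils::write.csv(segTab, file.path(config$out_dir,
            paste0("segmentation_", nm, ".csv")), row.names = FALSE)

        sc <- scoreSetFromMatrix(manifest$subject_id,
            matrix(rep(predLab$delta_ml, 4L), ncol = 4L),
            labels = as.matrix(manifest[, c("label_3", "label_6", "label_9", "label_12_5")]),
            source = "volume")
        utils::write.csv(sc, file.path(config$out_dir,
            paste0("scores_", nm, ".csv")), row.names = FALSE)
        cohorts[[nm]] <- pairs
        scores[[nm]] <- sc
    }

    say("calibrating operating points and transferring to the external cohort")
    sweep <- sweepReport(scores$internal, scores$external, targets = config$targets)
    utils::write.csv(sweep, file.path(config$out_dir, "threshold_sweep.csv"),
                     row.names = FALSE)
    seedLog <- data.frame(
        stage = c("global", "cohort_internal", "cohort_external",
                  "oracle_internal", "oracle_external"),
        seed = c(config$global_seed, stageSeed("cohort_internal"),
                 stageSeed("cohort_external"), stageSeed("oracle_internal"),
                 stageSeed("oracle_external")))
    utils::write.csv(seedLog, file.path(config$out_dir, "seed_log.csv"),
                     row.names = FALSE)
    invisible(list(manifests = lapply(cohorts, cohortManifest),
                   scores = scores, sweep = sweep, out_dir = config$out_dir))
}
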