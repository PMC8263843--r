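# Orchestration: presets, cohort evaluation, and the reproducible
# end-to-end run (phantom cohort -> split -> preprocess -> train/oracle ->
# predict -> quantitative + qualitative reports).

#' Desk-scale and acquisition-scale presets
#'
#' \code{deskPreset} is the CPU-trainable configuration used throughout the
#' examples and tests: 32 x 64 x 64 phantoms, a 3-level network with 4 base
#' channels, and a short high-learning-rate schedule.  \code{paperPreset}
#' mirrors a clinical acquisition: 24 x 256 x 256 input resized to
#' 64 x 256 x 256, a 4-level network, Adam at 1e-4, batch 2, 300 epochs;
#' it is constructible and serializable on any machine, but training it is a
#' GPU-scale undertaking.
#'
#' @return A list with elements \code{phantom} (a \code{PhantomConfig}),
#'   \code{unet} (a \code{UNetConfig}) and \code{targetShape}.
#' @export
deskPreset <- function() {
  list(phantom = phantomConfig(preset = "desk"),
       unet = unetConfig(levels = 3L, baseChannels = 8L,
                         learningRate = 1e-2, batchSize = 1L,
                         epochs = 60L, seed = 1L),
       targetShape = c(32L, 64L, 64L))
}

#' @rdname deskPreset
#' @export
paperPreset <- function() {
  list(phantom = phantomConfig(preset = "paper"),
       unet = unetConfig(levels = 4L, baseChannels = 16L,
                         learningRate = 1e-4, batchSize = 2L,
                         epochs = 300L, seed = 1L),
       targetShape = c(64L, 256L, 256L))
}

#' Quantitative + qualitative evaluation of a set of subjects
#'
#' For each (predicted, manual) pair: per-label DSC, overall bone volumes,
#' and the qualitative score report.  Across subjects (n >= 2 per
#' modality): Bland-Altman agreement and a linear fit of predicted on
#' manual volume.
#'
#' @param subjects list of \code{list(id, modality, predicted, manual)}
#'   where predicted/manual are \code{LabelVolume}s.
#' @param rubric scoring rubric, see \code{\link{defaultRubric}}.
#' @return An \code{EvalReport}.
#' @export
evaluateCohort <- function(subjects, rubric = defaultRubric()) {
  if (length(subjects) == 0L) stop("no subjects to evaluate")
  dscRows <- list(); volRows <- list(); scoreRows <- list()
  for (s in subjects) {
    d <- perLabelDSC(s$predicted, s$manual)
    dscRows[[length(dscRows) + 1L]] <- data.frame(
      id = s$id, modality = s$modality,
      label = as.integer(names(d$perLabel)), dsc = unname(d$perLabel),
      stringsAsFactors = FALSE)
    volRows[[length(volRows) + 1L]] <- data.frame(
      id = s$id, modality = s$modality,
      pred_cm3 = labelVolumeCm3(s$predicted),
      manual_cm3 = labelVolumeCm3(s$manual), stringsAsFactors = FALSE)
    sr <- scoreReport(s$predicted, s$manual, s$modality, rubric)
    scoreRows[[length(scoreRows) + 1L]] <- data.frame(
      id = s$id, modality = s$modality, patient_score = sr@patientScore,
      average_dsc = d$average, stringsAsFactors = FALSE)
  }
  dscDf <- do.call(rbind, dscRows)
  volDf <- do.call(rbind, volRows)
  scoreDf <- do.call(rbind, scoreRows)
  sumRows <- list()
  for (m in unique(dscDf$modality)) {
    sub <- dscDf[dscDf$modality == m, ]
    for (l in sort(unique(sub$label))) {
      v <- sub$dsc[sub$label == l]
      sumRows[[length(sumRows) + 1L]] <- data.frame(
        modality = m, label = as.character(l), mean_dsc = mean(v),
        sd_dsc = if (length(v) > 1L) stats::sd(v) else NA_real_,
        stringsAsFactors = FALSE)
    }
    perSubjAvg <- scoreDf$average_dsc[scoreDf$modality == m]
    sumRows[[length(sumRows) + 1L]] <- data.frame(
      modality = m, label = "average", mean_dsc = mean(perSubjAvg),
      sd_dsc = if (length(perSubjAvg) > 1L) stats::sd(perSubjAvg) else NA_real_,
      stringsAsFactors = FALSE)
  }
  agreement <- list()
  for (m in unique(volDf$modality)) {
    sub <- volDf[volDf$modality == m, ]
    if (nrow(sub) >= 2L) {
      agreement[[m]] <- list(
        bland_altman = blandAltman(sub$pred_cm3, sub$manual_cm3),
        fit = if (stats::sd(sub$manual_cm3) > 0)
          linearFitR2(sub$manual_cm3, sub$pred_cm3) else NULL)
    }
  }
  new("EvalReport", dsc = dscDf, dscSummary = do.call(rbind, sumRows),
      volumes = volDf, agreement = agreement, scores = scoreDf)
}

#' Export an evaluation report
#'
#' Per-subject rows as CSV; the cohort summary (per-label mean +/- SD DSC
#' with an average row, agreement statistics, patient scores) as JSON.
#'
#' @param report an \code{EvalReport}.
#' @param csvPath,jsonPath output paths (either may be NULL).
#' @return Invisibly, the written paths.
#' @export
writeEvalReport <- function(report, csvPath = NULL, jsonPath = NULL) {
  if (!is.null(csvPath))
    utils::write.csv(merge(report@dsc, report@scores, by = c("id", "modality")),
                     csvPath, row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(
      list(dsc_summary = report@dscSummary, agreement = report@agreement,
           patient_scores = report@scores),
      jsonPath, auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null")
  invisible(list(csv = csvPath, json = jsonPath))
}

.stage <- function(name, id = NULL, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s'%s failed: %s", name,
                 if (is.null(id)) "" else sprintf(" (subject %s)", id),
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full pipeline end to end
#'
#' Generates a phantom cohort, splits it (train/val/test; small cohorts are
#' guaranteed at least one validation and one test subject), min-max
#' normalizes the intensities, fits the network (or, in oracle mode, takes
#' the ground truth --- optionally perturbed --- as the prediction),
#' predicts the held-out subjects on both modalities, and assembles the
#' quantitative and qualitative reports.  With a fixed seed, all
#' non-training outputs are bit-reproducible.
#'
#' @param n cohort size (>= 3).
#' @param preset \code{\link{deskPreset}()} or a list of the same shape.
#' @param seed global seed for cohort, split and training.
#' @param oracleMode skip training and use the manual segmentation as the
#'   prediction (optionally degraded by \code{oraclePerturb}).
#' @param oraclePerturb optional \code{\link{perturbSpec}} applied to the
#'   oracle predictions.
#' @param epochs training epoch override.
#' @param outDir optional output directory for reports, checkpoints and the
#'   run manifest.
#' @return A list: \code{eval} (an \code{EvalReport}), \code{scores} (per
#'   subject x modality \code{ScoreReport}s), \code{split}, \code{model}
#'   (NULL in oracle mode), \code{log}.
#' @examples
#' \donttest{
#' res <- runEndToEnd(n = 4, oracleMode = TRUE, seed = 1)
#' res$eval@scores$patient_score  # all 10 in oracle mode
#' }
#' @export
runEndToEnd <- function(n = 8, preset = deskPreset(), seed = 1L,
                        oracleMode = FALSE, oraclePerturb = NULL,
                        epochs = NULL, outDir = NULL) {
  if (n < 3L) stop("need n >= 3 for a train/val/test split")
  cohort <- .stage("phantom", NULL, generateCohort(n, preset$phantom, seed))
  ids <- vapply(cohort, `[[`, character(1), "id")
  nVal <- max(1L, n %/% 10L); nTest <- max(1L, n %/% 10L)
  split <- .stage("split", NULL, splitDataset(
    ids, counts = c(train = n - nVal - nTest, val = nVal, test = nTest),
    seed = seed))
  byId <- stats::setNames(cohort, ids)
  prep <- function(id, mod) .stage("prep", id, {
    v <- byId[[id]][[tolower(mod)]]
    if (!identical(dim(v@values), as.integer(preset$targetShape)))
      v <- resizeVolume(v, preset$targetShape)
    normalizeIntensity(v)
  })
  prepLab <- function(id) .stage("prep", id, {
    v <- byId[[id]]$label
    if (!identical(dim(v@values), as.integer(preset$targetShape)))
      v <- resizeVolume(v, preset$targetShape)
    v
  })
  model <- NULL; log <- NULL
  if (!oracleMode) {
    mkPairs <- function(idSet)
      unlist(lapply(idSet, function(id) lapply(.MODALITIES, function(m)
        list(image = prep(id, m), label = prepLab(id)))), recursive = FALSE)
    model <- .stage("build", NULL, buildUNet3D(preset$unet))
    fit <- .stage("train", NULL,
                  trainUNet(model, mkPairs(split$train), mkPairs(split$val),
                            epochs = epochs))
    model <- fit$model; log <- fit$log
  }
  subjects <- list()
  scores <- list()
  for (id in split$test) {
    manual <- prepLab(id)
    for (m in .MODALITIES) {
      pred <- if (oracleMode) {
        p <- manual
        if (!is.null(oraclePerturb))
          p <- .stage("perturb", id, perturbSegmentation(manual, oraclePerturb))
        p
      } else .stage("predict", id, predictLabels(model, prep(id, m)))
      subjects[[length(subjects) + 1L]] <-
        list(id = id, modality = m, predicted = pred, manual = manual)
      scores[[paste(id, m, sep = "_")]] <-
        .stage("score", id, scoreReport(pred, manual, m))
    }
  }
  ev <- .stage("evaluate", NULL, evaluateCohort(subjects))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeSplitJSON(split, file.path(outDir, "split.json"))
    writeEvalReport(ev, file.path(outDir, "eval.csv"),
                    file.path(outDir, "eval.json"))
    for (nm in names(scores))
      writeScoreReport(scores[[nm]],
                       csvPath = file.path(outDir, sprintf("score_%s.csv", nm)))
    if (!is.null(model))
      saveCheckpoint(model, file.path(outDir, "checkpoint.rds"))
    if (!is.null(log))
      writeTrainLog(log, csvPath = file.path(outDir, "trainlog.csv"))
    manifest <- list(
      version = as.character(utils::packageVersion("pelviseg")),
      n = n, seed = seed, oracle_mode = oracleMode,
      target_shape = as.integer(preset$targetShape),
      phantom_grid = as.integer(preset$phantom@dim),
      unet = list(levels = preset$unet@levels,
                  base_channels = preset$unet@baseChannels,
                  learning_rate = preset$unet@learningRate,
                  epochs = epochs %||% preset$unet@epochs),
      split = split[names(split) != "seed"])
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(eval = ev, scores = scores, split = split, model = model, log = log)
}
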