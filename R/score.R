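# The qualitative SCORE rubric: per-CD scores conditioned on overlap class
# and modality, aggregated CD -> label -> patient.
#
# Over-segmentation (A1) is clinically acceptable on DWI, where the images
# serve lesion detection and a slightly larger mask does not hide lesions;
# under-segmentation (A2) is acceptable on ADC maps, where regions of
# interest for ADC measurement must stay inside bone.  The default table
# encodes exactly that asymmetry: A1 scores 10 on DWI and 8 on ADC, A2
# scores 8 on DWI and 10 on ADC, a perfect match scores 10 on both.

#' Configure the scoring rubric
#'
#' @param table numeric 4 x 2 matrix, rows EXACT/A1/A2/A3, columns DWI/ADC,
#'   values in [0, 10].
#' @param unmatchedScore score for NONE matches (missed manual CDs and
#'   spurious predictions); default 0, the floor of the 0-10 range.
#' @param tau containment tolerance for condition classification.
#' @param strict classify with literal set relations instead of tolerances.
#' @param dscFloor optional label-level DSC threshold: when the label's DSC
#'   falls below it, that label's CD scores are capped at \code{cap}.
#'   \code{NA} (default) disables the override.
#' @param cap score cap applied under \code{dscFloor}.
#' @return A \code{RubricConfig}.
#' @examples
#' defaultRubric()
#' @export
defaultRubric <- function(table = NULL, unmatchedScore = 0, tau = 0.95,
                          strict = FALSE, dscFloor = NA_real_, cap = 5) {
  if (is.null(table)) {
    table <- rbind(EXACT = c(10, 10), A1 = c(10, 8), A2 = c(8, 10),
                   A3 = c(6, 6))
    colnames(table) <- c("DWI", "ADC")
  }
  new("RubricConfig", table = table, unmatchedScore = unmatchedScore,
      tau = tau, strict = strict, dscFloor = as.numeric(dscFloor),
      cap = as.numeric(cap))
}

#' Score a single connected domain
#'
#' Table lookup of (condition, modality) in the rubric; NONE matches receive
#' the rubric's unmatched score.
#'
#' @param condition one of "EXACT", "A1", "A2", "A3", "NONE".
#' @param modality "DWI" or "ADC".
#' @param rubric a \code{\link{defaultRubric}}.
#' @return A score in [0, 10].
#' @examples
#' scoreCD("A1", "DWI")  # 10
#' scoreCD("A1", "ADC")  # 8
#' @export
scoreCD <- function(condition, modality = c("DWI", "ADC"),
                    rubric = defaultRubric()) {
  modality <- match.arg(modality)
  if (!condition %in% .CONDITIONS)
    stop(sprintf("unknown condition '%s'", condition))
  if (condition == "NONE") return(rubric@unmatchedScore)
  rubric@table[condition, modality]
}

#' Average the CD scores of one label
#'
#' The label score is the arithmetic mean over all matches carrying the
#' label; every NONE match (a missed manual CD or a spurious predicted CD)
#' contributes the unmatched score, so the denominator counts unmatched
#' components too.
#'
#' @param matches rows of a \code{\link{matchCDs}} table, all with the same
#'   label.
#' @param modality "DWI" or "ADC".
#' @param rubric a \code{\link{defaultRubric}}.
#' @return The mean label score, or \code{NA} for an empty match list
#'   (label not scorable).
#' @export
scoreLabel <- function(matches, modality = c("DWI", "ADC"),
                       rubric = defaultRubric()) {
  modality <- match.arg(modality)
  if (nrow(matches) == 0L) return(NA_real_)
  if (length(unique(matches$label)) != 1L)
    stop("'matches' must all share one label")
  mean(vapply(matches$condition, scoreCD, numeric(1),
              modality = modality, rubric = rubric))
}

#' Aggregate label scores to the patient level
#'
#' The patient score is the unweighted mean over scored labels.
#'
#' @param labelScores numeric vector of label scores (NAs, i.e. unscorable
#'   labels, are dropped).
#' @return The patient score.
#' @export
scorePatient <- function(labelScores) {
  s <- labelScores[!is.na(labelScores)]
  if (length(s) == 0L) stop("no scored labels")
  mean(s)
}

#' Full qualitative score report for one subject
#'
#' Runs the complete pipeline: per-label DSC (recorded in the report),
#' connected-domain extraction on both volumes, prediction-to-manual
#' matching, condition classification, per-CD scoring and CD -> label ->
#' patient aggregation.  Deterministic.
#'
#' @param predicted,manual \code{LabelVolume}s of identical geometry.
#' @param modality "DWI" or "ADC".
#' @param rubric a \code{\link{defaultRubric}}.
#' @param connectivity CD connectivity (default 26).
#' @return A \code{ScoreReport}.
#' @examples
#' lab <- generateLabelPhantom(phantomConfig())
#' rep <- scoreReport(lab, lab, "DWI")
#' rep@patientScore  # 10: a perfect prediction
#' @export
scoreReport <- function(predicted, manual, modality = c("DWI", "ADC"),
                        rubric = defaultRubric(), connectivity = 26L) {
  modality <- match.arg(modality)
  stopifnot(is(predicted, "LabelVolume"), is(manual, "LabelVolume"))
  checkSameGeometry(predicted, manual)
  dscRep <- perLabelDSC(predicted, manual)
  pc <- extractCDs(predicted, connectivity)
  mc <- extractCDs(manual, connectivity)
  matches <- matchCDs(pc, mc, tau = rubric@tau, strict = rubric@strict)
  if (nrow(matches) == 0L) stop("no connected domains in either volume")
  matches$score <- vapply(matches$condition, scoreCD, numeric(1),
                          modality = modality, rubric = rubric)
  if (!is.na(rubric@dscFloor)) {
    for (l in unique(matches$label)) {
      d <- dscRep$perLabel[as.character(l)]
      if (!is.na(d) && d < rubric@dscFloor) {
        sel <- matches$label == l
        matches$score[sel] <- pmin(matches$score[sel], rubric@cap)
      }
    }
  }
  labs <- sort(unique(matches$label))
  labelScores <- vapply(labs, function(l)
    mean(matches$score[matches$label == l]), numeric(1))
  names(labelScores) <- as.character(labs)
  new("ScoreReport", cdTable = matches, labelScores = labelScores,
      patientScore = scorePatient(labelScores), modality = modality,
      dscPerLabel = dscRep$perLabel)
}

#' Serialize a rubric to JSON, or read one back
#'
#' @param rubric a \code{RubricConfig}.
#' @param path JSON path.
#' @return \code{writeRubricJSON}: the path, invisibly;
#'   \code{readRubricJSON}: a \code{RubricConfig}.
#' @export
writeRubricJSON <- function(rubric, path) {
  obj <- list(
    table = as.data.frame(rubric@table),
    conditions = rownames(rubric@table),
    unmatched_score = rubric@unmatchedScore,
    tau = rubric@tau, strict = rubric@strict,
    dsc_floor = rubric@dscFloor, cap = rubric@cap)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname writeRubricJSON
#' @export
readRubricJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tb <- as.matrix(obj$table)
  storage.mode(tb) <- "double"
  rownames(tb) <- obj$conditions
  defaultRubric(table = tb, unmatchedScore = as.numeric(obj$unmatched_score),
                tau = as.numeric(obj$tau), strict = obj$strict,
                dscFloor = obj$dsc_floor %||% NA_real_,
                cap = obj$cap %||% 5)
}

#' Export a score report
#'
#' Writes the per-CD table as CSV and the aggregates (label scores, patient
#' score, per-label DSC) as JSON.
#'
#' @param report a \code{ScoreReport}.
#' @param csvPath,jsonPath output paths (either may be NULL to skip).
#' @return Invisibly, a list of the written paths.
#' @export
writeScoreReport <- function(report, csvPath = NULL, jsonPath = NULL) {
  if (!is.null(csvPath))
    utils::write.csv(report@cdTable, csvPath, row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(
      list(modality = report@modality,
           patient_score = report@patientScore,
           label_scores = as.list(report@labelScores),
           dsc_per_label = as.list(report@dscPerLabel)),
      jsonPath, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(csv = csvPath, json = jsonPath))
}
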