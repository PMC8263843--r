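# Connected-domain extraction, matching, and overlap-condition
# classification.
#
# A connected domain (CD) is one spatially continuous 3D component of a
# single bone label; a label may contain several (e.g. left and right
# ilium).  Predicted CDs are paired with manual CDs by maximal voxel
# intersection and classified into the overlap conditions used by the
# qualitative rubric: EXACT, A1 (prediction larger than the manual CD),
# A2 (smaller), A3 (partial overlap), NONE (no overlap / unmatched).

#' Extract connected domains from a label volume
#'
#' Performs a per-label connected-component decomposition at the requested
#' connectivity.  Components are ordered by (label, descending voxel count).
#'
#' @param labels a \code{LabelVolume}.
#' @param connectivity 6, 18 or 26 (default 26: faces, edges and corners).
#' @return A \code{\link{CDSet-class}}.
#' @examples
#' lab <- generateLabelPhantom(phantomConfig(seed = 3))
#' cds <- extractCDs(lab)
#' nrow(cdTable(cds))  # 14 for the complete phantom
#' @export
extractCDs <- function(labels, connectivity = 26L) {
  stopifnot(is(labels, "LabelVolume"))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("'connectivity' must be 6, 18 or 26")
  dims <- dim(labels@values)
  vol <- labels@values
  rows <- list()
  voxels <- list()
  for (l in sort(unique(as.integer(vol)))) {
    if (l == 0L) next
    mask <- as.logical(vol == l)
    comp <- cpp_cc_label(mask, dims, connectivity)
    k <- max(comp)
    if (k == 0L) next
    sizes <- tabulate(comp, k)
    ord <- order(-sizes)
    for (ci in seq_len(k)) {
      c0 <- ord[ci]
      vx <- which(comp == c0)
      zyx <- linearToZyx(vx, dims)
      ctr <- colMeans(zyx)
      rows[[length(rows) + 1L]] <- data.frame(
        label = l, component_id = ci, voxel_count = length(vx),
        centroid_z = ctr[1], centroid_y = ctr[2], centroid_x = ctr[3],
        bbox_z_min = min(zyx[, 1]), bbox_z_max = max(zyx[, 1]),
        bbox_y_min = min(zyx[, 2]), bbox_y_max = max(zyx[, 2]),
        bbox_x_min = min(zyx[, 3]), bbox_x_max = max(zyx[, 3]))
      voxels[[length(voxels) + 1L]] <- vx
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(), component_id = integer(),
               voxel_count = integer(),
               centroid_z = numeric(), centroid_y = numeric(),
               centroid_x = numeric(),
               bbox_z_min = integer(), bbox_z_max = integer(),
               bbox_y_min = integer(), bbox_y_max = integer(),
               bbox_x_min = integer(), bbox_x_max = integer())
  rownames(tab) <- NULL
  new("CDSet", table = tab, voxels = voxels, dim = as.integer(dims),
      spacing = labels@spacing, connectivity = connectivity)
}

# Classify one pairing from its overlap statistics.  Columns follow the
# CDMatch contract: coverage_of_manual = |P n M| / |M|,
# coverage_of_predicted = |P n M| / |P|.
.classifyRow <- function(interVox, nPred, nMan, covM, covP, tau, strict) {
  if (is.na(nPred) || is.na(nMan) || interVox == 0L) return("NONE")
  if (strict) {
    if (interVox == nPred && interVox == nMan) return("EXACT")
    if (interVox == nMan && nPred > nMan) return("A1")
    if (interVox == nPred && nPred < nMan) return("A2")
    return("A3")
  }
  if (covM >= tau && covP >= tau && nPred == nMan) return("EXACT")
  if (covM >= tau && nPred > nMan) return("A1")
  if (covP >= tau && nPred < nMan) return("A2")
  "A3"
}

#' Classify the overlap condition of a CD match
#'
#' Strict mode uses literal set relations: A1 iff the predicted CD is a
#' strict superset of the manual CD, A2 iff a strict subset, EXACT iff
#' identical, otherwise A3.  Tolerant mode (the default, tolerance
#' \code{tau}) relaxes containment to coverage >= \code{tau}, since
#' voxelized predictions are rarely exact supersets or subsets: A1 iff the
#' prediction covers at least \code{tau} of the manual CD and is larger, A2
#' symmetric, EXACT iff both coverages reach \code{tau} with equal voxel
#' counts.  Matches with no overlap (or one side absent) are NONE.
#'
#' @param match one row of a match table from \code{\link{matchCDs}}, or a
#'   list with entries \code{intersection_voxels}, \code{pred_voxel_count},
#'   \code{manual_voxel_count}, \code{coverage_of_manual},
#'   \code{coverage_of_predicted}.
#' @param tau containment tolerance in (0.5, 1].
#' @param strict use literal set relations instead of tolerances.
#' @return One of "EXACT", "A1", "A2", "A3", "NONE".
#' @export
classifyCondition <- function(match, tau = 0.95, strict = FALSE) {
  if (tau <= 0.5 || tau > 1) stop("'tau' must lie in (0.5, 1]")
  .classifyRow(match$intersection_voxels,
               match$pred_voxel_count, match$manual_voxel_count,
               match$coverage_of_manual, match$coverage_of_predicted,
               tau, strict)
}

#' Match predicted connected domains against manual ones
#'
#' Within each label, every predicted CD is paired with the manual CD of
#' maximal voxel intersection (ties broken towards the larger manual CD,
#' then the lower component id).  Manual CDs left unpaired, and predicted
#' CDs with no overlap to any manual CD, become NONE matches with the other
#' side absent.
#'
#' @param predicted,manual \code{CDSet}s extracted from same-geometry
#'   volumes.
#' @param tau,strict condition classification settings, see
#'   \code{\link{classifyCondition}}.
#' @return A data.frame with one row per match: label, pred/manual component
#'   ids and voxel counts (NA for an absent side), intersection voxels, the
#'   two coverages, and the condition.
#' @export
matchCDs <- function(predicted, manual, tau = 0.95, strict = FALSE) {
  stopifnot(is(predicted, "CDSet"), is(manual, "CDSet"))
  if (!identical(predicted@dim, manual@dim))
    stop("geometry mismatch between predicted and manual CD sets")
  if (tau <= 0.5 || tau > 1) stop("'tau' must lie in (0.5, 1]")
  pt <- predicted@table; mt <- manual@table
  out <- list()
  emit <- function(label, pid, np, mid, nm, inter) {
    covM <- if (is.na(nm) || nm == 0L) 0 else inter / nm
    covP <- if (is.na(np) || np == 0L) 0 else inter / np
    cond <- .classifyRow(inter, np, nm, covM, covP, tau, strict)
    out[[length(out) + 1L]] <<- data.frame(
      label = label, pred_component_id = pid, pred_voxel_count = np,
      manual_component_id = mid, manual_voxel_count = nm,
      intersection_voxels = inter,
      coverage_of_manual = covM, coverage_of_predicted = covP,
      condition = cond, stringsAsFactors = FALSE)
  }
  for (l in sort(unique(c(pt$label, mt$label)))) {
    pi <- which(pt$label == l)
    mi <- which(mt$label == l)
    matchedManual <- rep(FALSE, length(mi))
    for (p in pi) {
      pv <- predicted@voxels[[p]]
      inters <- vapply(mi, function(m)
        length(intersect(pv, manual@voxels[[m]])), integer(1))
      if (length(mi) == 0L || all(inters == 0L)) {
        emit(l, pt$component_id[p], pt$voxel_count[p], NA_integer_,
             NA_integer_, 0L)
        next
      }
      best <- order(-inters, -mt$voxel_count[mi], mt$component_id[mi])[1]
      matchedManual[best] <- TRUE
      m <- mi[best]
      emit(l, pt$component_id[p], pt$voxel_count[p], mt$component_id[m],
           mt$voxel_count[m], inters[best])
    }
    for (k in which(!matchedManual)) {
      m <- mi[k]
      emit(l, NA_integer_, NA_integer_, mt$component_id[m],
           mt$voxel_count[m], 0L)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    label = integer(), pred_component_id = integer(),
    pred_voxel_count = integer(), manual_component_id = integer(),
    manual_voxel_count = integer(), intersection_voxels = integer(),
    coverage_of_manual = numeric(), coverage_of_predicted = numeric(),
    condition = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Export a CD table or match table to CSV
#'
#' @param x a \code{CDSet} or a match table from \code{\link{matchCDs}}.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeCDTable <- function(x, path) {
  tab <- if (is(x, "CDSet")) cdTable(x) else x
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
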