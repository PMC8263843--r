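#' Accessors for volumes and connected-domain sets
#'
#' \code{voxelData} returns the raw 3D array (z, y, x); \code{spacing} the
#' voxel spacing in mm; \code{modality} the MRI sequence tag of an intensity
#' volume; \code{cdTable} the per-CD summary table of a \code{CDSet} or
#' \code{ScoreReport}; \code{cdVoxels} the voxel index list of a \code{CDSet}.
#'
#' @param x a \code{Volume}, \code{CDSet} or \code{ScoreReport}.
#' @return See details per accessor.
#' @name accessors
#' @aliases voxelData spacing modality cdTable cdVoxels
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname accessors
#' @export
setGeneric("cdTable", function(x) standardGeneric("cdTable"))

#' @rdname accessors
#' @export
setGeneric("cdVoxels", function(x) standardGeneric("cdVoxels"))

#' @rdname accessors
#' @export
setMethod("voxelData", "Volume", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("spacing", "Volume", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("modality", "IntensityVolume", function(x) x@modality)

#' @rdname accessors
#' @export
setMethod("cdTable", "CDSet", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("cdTable", "ScoreReport", function(x) x@cdTable)

#' @rdname accessors
#' @export
setMethod("cdVoxels", "CDSet", function(x) x@voxels)

#' @describeIn accessors grid dimensions of a volume, (z, y, x).
#' @export
setMethod("dim", "Volume", function(x) dim(x@values))

setMethod("show", "IntensityVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("IntensityVolume [%s] %d x %d x %d (z,y,x), spacing %s mm\n",
              object@modality, d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x ")))
  cat(sprintf("  range [%.4g, %.4g]%s\n", min(object@values), max(object@values),
              if (is.na(object@bValue)) "" else
                sprintf(", b = %g s/mm^2", object@bValue)))
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@values)
  labs <- sort(unique(as.integer(object@values)))
  labs <- labs[labs > 0L]
  cat(sprintf("LabelVolume %d x %d x %d (z,y,x), spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x ")))
  cat(sprintf("  labels present: %s; foreground voxels: %d\n",
              if (length(labs)) paste(labs, collapse = ", ") else "none",
              sum(object@values > 0L)))
})

setMethod("show", "CDSet", function(object) {
  cat(sprintf("CDSet: %d connected domain(s), %d-connectivity\n",
              nrow(object@table), object@connectivity))
  if (nrow(object@table)) {
    print(utils::head(object@table[, c("label", "component_id", "voxel_count",
                                       "centroid_z", "centroid_y", "centroid_x")],
                      10L), row.names = FALSE)
    if (nrow(object@table) > 10L) cat("  ...\n")
  }
})

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf("PhantomConfig: grid %s, spacing %s mm, %d primitives, seed %d\n",
              paste(object@dim, collapse = "x"),
              paste(format(object@spacing, digits = 3), collapse = "x"),
              nrow(object@bones), object@seed))
})

setMethod("show", "UNetConfig", function(object) {
  cat(sprintf(
    "UNetConfig: %d levels, base %d ch, out %d ch, lr %g, batch %d, %d epochs, %s loss\n",
    object@levels, object@baseChannels, object@outChannels, object@learningRate,
    object@batchSize, object@epochs, object@loss))
})

setMethod("show", "TrainLog", function(object) {
  n <- length(object@trainLoss)
  cat(sprintf("TrainLog: %d epoch(s), %.1f s\n", n, object@elapsedSec))
  if (n) cat(sprintf("  final train loss %.5f%s\n", object@trainLoss[n],
                     if (length(object@valLoss))
                       sprintf(", final val loss %.5f", object@valLoss[n]) else ""))
})

setMethod("show", "RubricConfig", function(object) {
  cat("RubricConfig (condition x modality):\n")
  print(object@table)
  cat(sprintf("  unmatched score %g; tolerance tau %g; strict %s\n",
              object@unmatchedScore, object@tau, object@strict))
})

setMethod("show", "ScoreReport", function(object) {
  cat(sprintf("ScoreReport [%s]: patient score %.2f\n",
              object@modality, object@patientScore))
  cat("  label scores: ",
      paste(sprintf("%s=%.1f", names(object@labelScores), object@labelScores),
            collapse = ", "), "\n", sep = "")
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: %d subject(s)\n", nrow(object@volumes)))
  if (nrow(object@dscSummary)) {
    cat("  DSC summary (per label):\n")
    print(object@dscSummary, row.names = FALSE)
  }
})
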