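#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib pelviseg, .registration = TRUE
NULL

# -- label scheme -------------------------------------------------------------

#' The pelvic bone label scheme
#'
#' Eight bony structures are encoded as integer labels 1-8 on a background of
#' 0.  The lumbar vertebra and the sacrococcyx are midline structures with one
#' connected domain (CD) each; the remaining six bones are bilateral and
#' contribute a left and a right CD, so a complete pelvis carries 14 CDs.
#'
#' @return A data.frame with columns \code{value}, \code{name},
#'   \code{laterality} and \code{expected_cds}.
#' @examples
#' boneLabels()
#' sum(boneLabels()$expected_cds)  # 14
#' @export
boneLabels <- function() {
  data.frame(
    value = 1:8,
    name = c("lumbar_vertebra", "sacrococcyx", "ilium", "acetabulum",
             "femoral_head", "femoral_neck", "ischium", "pubis"),
    laterality = c("midline", "midline", rep("bilateral", 6)),
    expected_cds = c(1L, 1L, rep(2L, 6)),
    stringsAsFactors = FALSE
  )
}

.MODALITIES <- c("DWI", "ADC")
.CONDITIONS <- c("EXACT", "A1", "A2", "A3", "NONE")

# -- volumes ------------------------------------------------------------------

#' @rdname IntensityVolume-class
#' @exportClass Volume
setClass("Volume", representation("VIRTUAL",
  values = "array",
  spacing = "numeric"
))

setValidity("Volume", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L) return("'values' must be a 3D (z, y, x) array")
  if (any(d < 1L)) return("all dimensions must be >= 1")
  if (length(object@spacing) != 3L) return("'spacing' must have length 3 (z, y, x)")
  if (any(!is.finite(object@spacing)) || any(object@spacing <= 0))
    return("'spacing' must be positive and finite")
  TRUE
})

#' Intensity and label volumes
#'
#' The two central data containers.  Both hold a 3D grid in (z, y, x) axis
#' order together with its voxel spacing in millimetres.  An
#' \code{IntensityVolume} carries real-valued image data tagged with its MRI
#' modality (DWI or ADC) and optionally the diffusion b-value; a
#' \code{LabelVolume} holds integer labels 0-8, where 0 is background and 1-8
#' follow \code{\link{boneLabels}}.
#'
#' @slot values 3D array in (z, y, x) order.
#' @slot spacing numeric(3), voxel spacing in mm, (z, y, x).
#' @slot modality "DWI" or "ADC".
#' @slot bValue diffusion b-value in s/mm^2, or NA.
#' @aliases LabelVolume-class Volume-class
#' @seealso \code{\link{intensityVolume}}, \code{\link{labelVolume}}
#' @exportClass IntensityVolume
setClass("IntensityVolume", contains = "Volume", representation(
  modality = "character",
  bValue = "numeric"
))

setValidity("IntensityVolume", function(object) {
  if (length(object@modality) != 1L || !object@modality %in% .MODALITIES)
    return(sprintf("'modality' must be one of %s",
                   paste(.MODALITIES, collapse = ", ")))
  TRUE
})

#' @exportClass LabelVolume
setClass("LabelVolume", contains = "Volume")

setValidity("LabelVolume", function(object) {
  v <- object@values
  if (!is.integer(v)) return("label values must be stored as integers")
  if (anyNA(v)) return("label values must not contain NA")
  bad <- range(v)
  if (bad[1] < 0L || bad[2] > 8L) {
    off <- sort(unique(v[v < 0L | v > 8L]))
    return(sprintf("label values outside 0-8 found: %s",
                   paste(utils::head(off, 5L), collapse = ", ")))
  }
  TRUE
})

#' Construct an IntensityVolume
#'
#' @param values 3D numeric array, (z, y, x) order.
#' @param spacing voxel spacing in mm, (z, y, x).
#' @param modality "DWI" or "ADC".
#' @param bValue optional diffusion b-value (s/mm^2), e.g. 800 or 1000.
#' @return An \code{IntensityVolume}.
#' @examples
#' v <- intensityVolume(array(runif(8 * 16 * 16), c(8, 16, 16)),
#'                      spacing = c(4, 1.4, 1.4), modality = "DWI")
#' @export
intensityVolume <- function(values, spacing, modality = c("DWI", "ADC"),
                            bValue = NA_real_) {
  modality <- match.arg(modality)
  new("IntensityVolume", values = values, spacing = as.numeric(spacing),
      modality = modality, bValue = as.numeric(bValue))
}

#' Construct a LabelVolume
#'
#' @param values 3D array of integers 0-8 (numeric storage is coerced;
#'   non-integral or out-of-range values are rejected).
#' @param spacing voxel spacing in mm, (z, y, x).
#' @return A \code{LabelVolume}.
#' @export
labelVolume <- function(values, spacing) {
  if (!is.integer(values)) {
    if (any(abs(values - round(values)) > 1e-6, na.rm = TRUE))
      stop("label volume contains non-integer values")
    v <- as.integer(round(values))
    dim(v) <- dim(values)
    values <- v
  }
  new("LabelVolume", values = values, spacing = as.numeric(spacing))
}

# -- phantom configuration ----------------------------------------------------

#' @exportClass PhantomConfig
setClass("PhantomConfig", representation(
  dim = "integer",
  spacing = "numeric",
  bones = "data.frame",
  intensity = "list",
  jitter = "list",
  seed = "integer"
))

setValidity("PhantomConfig", function(object) {
  if (length(object@dim) != 3L || any(object@dim < 4L))
    return("'dim' must be three integers >= 4 (z, y, x)")
  b <- object@bones
  need <- c("label", "name", "side", "shape", "cz", "cy", "cx", "rz", "ry", "rx")
  if (!all(need %in% names(b)))
    return(sprintf("bone table must have columns %s", paste(need, collapse = ", ")))
  if (any(!b$label %in% 1:8)) return("bone labels must be in 1-8")
  jc <- object@jitter$centre %||% 0
  jr <- object@jitter$radius %||% 0
  rmax <- 1 + jr
  # every primitive (at maximal jitter) must fit inside the grid
  for (i in seq_len(nrow(b))) {
    lo <- c(b$cz[i], b$cy[i], b$cx[i]) - jc -
      c(b$rz[i], b$ry[i], b$rx[i]) * rmax
    hi <- c(b$cz[i], b$cy[i], b$cx[i]) + jc +
      c(b$rz[i], b$ry[i], b$rx[i]) * rmax
    if (any(lo < 0) || any(hi > 1))
      return(sprintf("bone '%s' (%s) overflows the grid", b$name[i], b$side[i]))
  }
  for (m in .MODALITIES) {
    im <- object@intensity[[m]]
    if (is.null(im) || is.null(im$background) || is.null(im$means) ||
        is.null(im$sd))
      return(sprintf("intensity model for %s must list background, means, sd", m))
  }
  TRUE
})

#' @exportClass PerturbSpec
setClass("PerturbSpec", representation(
  mode = "character",
  magnitude = "numeric",
  target = "list",
  axis = "character",
  seed = "integer"
))

.PERTURB_MODES <- c("dilate", "erode", "shift", "drop_cd", "add_spurious")

setValidity("PerturbSpec", function(object) {
  if (!object@mode %in% .PERTURB_MODES)
    return(sprintf("mode must be one of %s", paste(.PERTURB_MODES, collapse = ", ")))
  if (object@mode %in% c("dilate", "erode", "shift") && object@magnitude < 1)
    return("magnitude must be >= 1 for dilate/erode/shift")
  if (!object@axis %in% c("z", "y", "x"))
    return("axis must be one of z, y, x")
  TRUE
})

#' Describe a controlled segmentation perturbation
#'
#' Perturbations turn a ground-truth label volume into a synthetic
#' "prediction" realizing a known overlap condition: \code{dilate} produces
#' strict supersets (condition A1), \code{erode} strict subsets (A2),
#' \code{shift} partial overlap (A3), \code{drop_cd} a missed connected
#' domain, and \code{add_spurious} a false-positive component.
#'
#' @param mode one of "dilate", "erode", "shift", "drop_cd", "add_spurious".
#' @param magnitude perturbation size in voxels (>= 1 for dilate/erode/shift).
#' @param target optional selector \code{list(label=, component_id=)}; NULL
#'   means all CDs (dilate/erode) or a seeded random CD (shift/drop_cd).
#' @param axis shift axis, one of "z", "y", "x".
#' @param seed integer seed used for any random choice.
#' @return A \code{PerturbSpec}.
#' @export
perturbSpec <- function(mode, magnitude = 1, target = NULL, axis = "x",
                        seed = 1L) {
  new("PerturbSpec", mode = mode, magnitude = as.numeric(magnitude),
      target = if (is.null(target)) list() else target,
      axis = axis, seed = as.integer(seed))
}

# -- connected domains --------------------------------------------------------

#' Connected-domain set
#'
#' The decomposition of a \code{LabelVolume} into connected domains (CDs):
#' spatially continuous components of a single bone label.  \code{table}
#' holds one row per CD (label, component_id, voxel_count, centroid, bounding
#' box); \code{voxels} holds the 1-based linear voxel indices of each CD.
#'
#' @slot table per-CD data.frame.
#' @slot voxels list of integer vectors, parallel to the table rows.
#' @slot dim grid dimensions (z, y, x).
#' @slot spacing voxel spacing (mm).
#' @slot connectivity 6, 18 or 26.
#' @seealso \code{\link{extractCDs}}
#' @exportClass CDSet
setClass("CDSet", representation(
  table = "data.frame",
  voxels = "list",
  dim = "integer",
  spacing = "numeric",
  connectivity = "integer"
))

# -- network configuration ----------------------------------------------------

#' @exportClass UNetConfig
setClass("UNetConfig", representation(
  levels = "integer",
  baseChannels = "integer",
  inChannels = "integer",
  outChannels = "integer",
  learningRate = "numeric",
  batchSize = "integer",
  epochs = "integer",
  loss = "character",
  priorBias = "logical",
  seed = "integer"
))

setValidity("UNetConfig", function(object) {
  if (object@levels < 2L) return("'levels' must be >= 2")
  if (object@baseChannels < 4L) return("'baseChannels' must be >= 4")
  if (object@inChannels != 1L) return("'inChannels' must be 1 (single-sequence input)")
  if (object@outChannels != 9L)
    return("'outChannels' must be 9 (background + 8 bone labels)")
  if (!object@loss %in% c("bce", "softmax"))
    return("'loss' must be \"bce\" or \"softmax\"")
  if (object@learningRate <= 0) return("'learningRate' must be positive")
  if (object@epochs < 0L) return("'epochs' must be >= 0")
  TRUE
})

#' Configure the 3D U-Net
#'
#' Defaults follow the training recipe used throughout: Adam with learning
#' rate 1e-4, batch size 2, 300 epochs and a per-channel binary cross-entropy
#' loss over 9 sigmoid output channels (explicit background + 8 bones).  The
#' desk-scale preset in \code{\link{deskPreset}} overrides size and schedule
#' for CPU use.
#'
#' @param levels number of resolution levels (>= 2); input dimensions must be
#'   divisible by \code{2^(levels-1)}.
#' @param baseChannels channels at the finest level (doubled per level).
#' @param learningRate Adam learning rate.
#' @param batchSize minibatch size.
#' @param epochs training epochs.
#' @param loss "bce" (independent sigmoid channels) or "softmax".
#' @param priorBias initialize the output biases to the per-channel prior
#'   log-odds of the training labels before the first update (applied only
#'   to freshly built models).  Standard warm start for heavily imbalanced
#'   voxel classes: the network starts at the base rates instead of
#'   spending its first updates suppressing all channels.
#' @param seed seed for weight initialization and batch shuffling.
#' @return A \code{UNetConfig}.
#' @export
unetConfig <- function(levels = 4L, baseChannels = 16L, learningRate = 1e-4,
                       batchSize = 2L, epochs = 300L, loss = "bce",
                       priorBias = TRUE, seed = 1L) {
  new("UNetConfig", levels = as.integer(levels),
      baseChannels = as.integer(baseChannels), inChannels = 1L,
      outChannels = 9L, learningRate = learningRate,
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      loss = loss, priorBias = isTRUE(priorBias), seed = as.integer(seed))
}

#' @exportClass TrainLog
setClass("TrainLog", representation(
  trainLoss = "numeric",
  valLoss = "numeric",
  config = "UNetConfig",
  elapsedSec = "numeric"
))

# -- scoring rubric -----------------------------------------------------------

#' @exportClass RubricConfig
setClass("RubricConfig", representation(
  table = "matrix",
  unmatchedScore = "numeric",
  tau = "numeric",
  strict = "logical",
  dscFloor = "numeric",   # c(threshold, cap); NA disables
  cap = "numeric"
))

setValidity("RubricConfig", function(object) {
  tb <- object@table
  if (!identical(rownames(tb), c("EXACT", "A1", "A2", "A3")) ||
      !identical(colnames(tb), .MODALITIES))
    return("rubric table must be conditions (EXACT, A1, A2, A3) x (DWI, ADC)")
  if (any(tb < 0 | tb > 10)) return("rubric scores must lie in [0, 10]")
  if (object@unmatchedScore < 0 || object@unmatchedScore > 10)
    return("unmatchedScore must lie in [0, 10]")
  if (!is.na(object@tau) && (object@tau <= 0.5 || object@tau > 1))
    return("tolerance tau must lie in (0.5, 1]")
  TRUE
})

# -- reports ------------------------------------------------------------------

#' @exportClass ScoreReport
setClass("ScoreReport", representation(
  cdTable = "data.frame",
  labelScores = "numeric",
  patientScore = "numeric",
  modality = "character",
  dscPerLabel = "numeric"
))

#' @exportClass EvalReport
setClass("EvalReport", representation(
  dsc = "data.frame",
  dscSummary = "data.frame",
  volumes = "data.frame",
  agreement = "list",
  scores = "data.frame"
))
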