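# NIfTI input/output and preprocessing.
#
# Volumes are held in memory in (z, y, x) axis order; on disk the slice axis
# is stored as the first NIfTI dimension, and voxel spacing travels in the
# pixdim header field in the same order.  Label maps are written as unsigned
# 8-bit integers, intensities as 32-bit floats.

#' Read a volume from a NIfTI file
#'
#' @param path a NIfTI-1 file (.nii or .nii.gz).
#' @param kind "intensity" or "label"; label files are validated against the
#'   0-8 label scheme and rejected otherwise.
#' @param modality modality tag for intensity volumes ("DWI" or "ADC"); the
#'   tag is a property of the acquisition, not of the file format, so it is
#'   supplied by the caller (conventionally from the file name).
#' @return An \code{IntensityVolume} or \code{LabelVolume} with spacing taken
#'   from the header.
#' @seealso \code{\link{writeVolume}}
#' @export
readVolume <- function(path, kind = c("intensity", "label"),
                       modality = "DWI") {
  kind <- match.arg(kind)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    stop(sprintf("'%s' is not a readable NIfTI file: %s",
                                 path, conditionMessage(e))))
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) d <- d[1:3]
  values <- array(as.vector(img), d)
  stopIfNot3D(values, sprintf("'%s'", path))
  sp <- RNifti::pixdim(img)[1:3]
  if (kind == "label") labelVolume(values, sp)
  else intensityVolume(values, sp, modality)
}

#' Write a volume to a NIfTI file
#'
#' Label volumes are stored as uint8, intensity volumes as float32.  The
#' round trip through \code{\link{readVolume}} preserves label voxels
#' bit-exactly and intensities to float precision.
#'
#' @param volume an \code{IntensityVolume} or \code{LabelVolume}.
#' @param path output path (.nii or .nii.gz); the parent directory must
#'   exist.
#' @return The path, invisibly.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "Volume"))
  if (!dir.exists(dirname(path)))
    stop(sprintf("directory '%s' does not exist", dirname(path)))
  img <- RNifti::asNifti(volume@values)
  RNifti::pixdim(img) <- volume@spacing
  dt <- if (is(volume, "LabelVolume")) "uint8" else "float"
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

# Source coordinates for extent-preserving voxel-centre rescaling.
.resampleCoords <- function(nOut, nIn) (seq_len(nOut) - 0.5) * nIn / nOut + 0.5

#' Resize a volume to a target grid
#'
#' Label volumes are resampled with nearest-neighbour interpolation (no new
#' label values can appear); intensity volumes with trilinear interpolation
#' (every output voxel a convex combination of inputs).  Spacing is rescaled
#' so the physical extent of the volume is preserved.  Resizing to the
#' input's own shape is the identity.
#'
#' @param volume an \code{IntensityVolume} or \code{LabelVolume}.
#' @param targetShape integer (z, y, x), all positive.
#' @return A volume of the same class on the target grid.
#' @examples
#' lab <- generateLabelPhantom(phantomConfig())
#' big <- resizeVolume(lab, c(64, 256, 256))
#' all(unique(as.vector(voxelData(big))) %in%
#'     unique(as.vector(voxelData(lab))))  # TRUE
#' @export
resizeVolume <- function(volume, targetShape) {
  stopifnot(is(volume, "Volume"))
  targetShape <- as.integer(targetShape)
  if (length(targetShape) != 3L || any(is.na(targetShape)) ||
      any(targetShape < 1L))
    stop("'targetShape' must be three positive integers (z, y, x)")
  dIn <- dim(volume@values)
  if (identical(dIn, targetShape)) return(volume)
  newSpacing <- volume@spacing * dIn / targetShape
  if (is(volume, "LabelVolume")) {
    idx <- lapply(1:3, function(a) {
      s <- round(.resampleCoords(targetShape[a], dIn[a]))
      pmin(pmax(as.integer(s), 1L), dIn[a])
    })
    out <- volume@values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    labelVolume(out, newSpacing)
  } else {
    lo <- list(); hi <- list(); w <- list()
    for (a in 1:3) {
      s <- .resampleCoords(targetShape[a], dIn[a])
      f <- floor(s)
      w[[a]] <- s - f
      lo[[a]] <- pmin(pmax(as.integer(f), 1L), dIn[a])
      hi[[a]] <- pmin(pmax(as.integer(f) + 1L, 1L), dIn[a])
    }
    out <- array(0, targetShape)
    v <- volume@values
    for (az in 0:1) for (ay in 0:1) for (ax in 0:1) {
      wz <- if (az == 0) 1 - w[[1]] else w[[1]]
      wy <- if (ay == 0) 1 - w[[2]] else w[[2]]
      wx <- if (ax == 0) 1 - w[[3]] else w[[3]]
      iz <- if (az == 0) lo[[1]] else hi[[1]]
      iy <- if (ay == 0) lo[[2]] else hi[[2]]
      ix <- if (ax == 0) lo[[3]] else hi[[3]]
      wt <- outer(outer(wz, wy), wx)
      out <- out + v[iz, iy, ix, drop = FALSE] * wt
    }
    intensityVolume(out, newSpacing, volume@modality, volume@bValue)
  }
}

#' Min-max normalize an intensity volume to [0, 1]
#'
#' Constant volumes (no intensity range) map to all zeros.  Idempotent on
#' already-normalized non-constant input.
#'
#' @param volume an \code{IntensityVolume}.
#' @return The normalized \code{IntensityVolume}.
#' @export
normalizeIntensity <- function(volume) {
  stopifnot(is(volume, "IntensityVolume"))
  v <- volume@values
  r <- range(v)
  out <- if (r[2] > r[1]) (v - r[1]) / (r[2] - r[1]) else array(0, dim(v))
  intensityVolume(out, volume@spacing, volume@modality, volume@bValue)
}

#' Randomly partition subject identifiers
#'
#' Produces a uniformly random, seed-reproducible disjoint partition of the
#' identifiers.  In counts mode the partition sizes are given explicitly and
#' must sum to the number of identifiers.  In fractions mode every partition
#' after the first is rounded down and the remainder is assigned to the
#' first (so a ratio of 8:1:1 over 10 ids yields sizes 8, 1, 1).
#'
#' @param ids character or integer vector of subject identifiers.
#' @param counts named integer vector of partition sizes, e.g.
#'   \code{c(train = 208, val = 28, test = 28)}.
#' @param fractions named numeric vector summing to 1, e.g.
#'   \code{c(train = 0.8, val = 0.1, test = 0.1)}; ignored when
#'   \code{counts} is given.
#' @param seed integer seed.
#' @return A list with one element per partition (the assigned ids) plus a
#'   \code{seed} element.
#' @examples
#' splitDataset(sprintf("s%03d", 1:10),
#'              fractions = c(train = .8, val = .1, test = .1), seed = 1)
#' @export
splitDataset <- function(ids, counts = NULL,
                         fractions = c(train = 0.8, val = 0.1, test = 0.1),
                         seed = 1L) {
  n <- length(ids)
  if (anyDuplicated(ids)) stop("'ids' must be unique")
  if (!is.null(counts)) {
    if (is.null(names(counts)) || any(names(counts) == ""))
      stop("'counts' must be named")
    nms <- names(counts)
    counts <- as.integer(counts)
    if (sum(counts) != n)
      stop(sprintf("counts sum to %d but there are %d ids", sum(counts), n))
    sizes <- counts
  } else {
    if (is.null(names(fractions)) || any(names(fractions) == ""))
      stop("'fractions' must be named")
    if (abs(sum(fractions) - 1) > 1e-6)
      stop("'fractions' must sum to 1")
    rest <- floor(fractions[-1] * n)
    sizes <- as.integer(c(n - sum(rest), rest))
    nms <- names(fractions)
  }
  names(sizes) <- nms
  if (any(sizes < 0L)) stop("partition sizes must be non-negative")
  perm <- withSeed(seed, sample(ids))
  out <- vector("list", length(sizes))
  names(out) <- names(sizes)
  at <- 0L
  for (k in seq_along(sizes)) {
    out[[k]] <- perm[seq_len(sizes[k]) + at]
    at <- at + sizes[k]
  }
  out$seed <- as.integer(seed)
  out
}

#' Serialize or restore a dataset split as JSON
#'
#' @param split a split from \code{\link{splitDataset}}.
#' @param path JSON path.
#' @return \code{writeSplitJSON}: the path, invisibly; \code{readSplitJSON}:
#'   the split list.
#' @export
writeSplitJSON <- function(split, path) {
  jsonlite::write_json(split, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeSplitJSON
#' @export
readSplitJSON <- function(path) {
  sp <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp$seed <- as.integer(sp$seed)
  sp
}
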