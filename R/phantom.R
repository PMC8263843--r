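# Synthetic pelvic phantom generation.
#
# Bone primitives are analytic solids placed in normalized (z, y, x) index
# fraction coordinates: ellipsoids for the vertebra, sacrococcyx and femoral
# heads, cylinders for the femoral necks, and rounded boxes (superellipsoids,
# exponent 4) for ilium, acetabulum, ischium and pubis.  The layout keeps
# every pair of primitives separated along at least one axis at maximal
# jitter, so a complete phantom always decomposes into exactly 14 connected
# domains: one lumbar vertebra, one sacrococcyx, and left/right components of
# the six bilateral bones.

.defaultBoneTable <- function(labels = 1:8) {
  mid <- function(label, name, shape, cz, cy, cx, rz, ry, rx)
    data.frame(label = label, name = name, side = "midline", shape = shape,
               cz = cz, cy = cy, cx = cx, rz = rz, ry = ry, rx = rx,
               stringsAsFactors = FALSE)
  bil <- function(label, name, shape, cz, cy, rz, ry, rx) {
    rbind(
      data.frame(label = label, name = name, side = "left", shape = shape,
                 cz = cz, cy = cy, cx = 0.23, rz = rz, ry = ry, rx = rx,
                 stringsAsFactors = FALSE),
      data.frame(label = label, name = name, side = "right", shape = shape,
                 cz = cz, cy = cy, cx = 0.77, rz = rz, ry = ry, rx = rx,
                 stringsAsFactors = FALSE))
  }
  tab <- rbind(
    mid(1L, "lumbar_vertebra", "ellipsoid", 0.22, 0.28, 0.50, 0.10, 0.10, 0.09),
    mid(2L, "sacrococcyx",     "ellipsoid", 0.60, 0.28, 0.50, 0.16, 0.10, 0.09),
    bil(3L, "ilium",        "rbox",      0.25, 0.55, 0.11, 0.09, 0.08),
    bil(4L, "acetabulum",   "rbox",      0.55, 0.55, 0.09, 0.07, 0.07),
    bil(5L, "femoral_head", "ellipsoid", 0.30, 0.82, 0.10, 0.09, 0.08),
    bil(6L, "femoral_neck", "cylinder",  0.58, 0.82, 0.10, 0.07, 0.06),
    bil(7L, "ischium",      "rbox",      0.82, 0.55, 0.08, 0.07, 0.07),
    bil(8L, "pubis",        "rbox",      0.84, 0.82, 0.07, 0.07, 0.06)
  )
  tab[tab$label %in% labels, , drop = FALSE]
}

.defaultIntensityModel <- function() {
  list(
    DWI = list(background = 20, means = 120 + 15 * (0:7), sd = 8),
    ADC = list(background = 230, means = 40 + 18 * (0:7), sd = 8)
  )
}

#' Configure a synthetic pelvic phantom
#'
#' The default geometry is a desk-scale 32 x 64 x 64 grid at 4 x 1.4 x 1.4 mm
#' anisotropic spacing (axial stacks with coarse slice spacing, as in
#' clinical pelvic DWI).  \code{preset = "paper"} switches to a 24 x 256 x
#' 256 acquisition-scale grid.  Intensity models give each bone label a
#' distinct mean over a homogeneous background with additive Gaussian noise;
#' DWI renders bone brighter than background, ADC darker.
#'
#' @param dim grid shape (z, y, x).
#' @param spacing voxel spacing in mm (z, y, x).
#' @param labels subset of bone labels 1-8 to include.
#' @param intensity per-modality intensity model: a list with entries
#'   \code{DWI} and \code{ADC}, each \code{list(background=, means=, sd=)}
#'   where \code{means} has one value per label 1-8.
#' @param jitter per-subject geometry jitter: \code{list(centre=, radius=)},
#'   centre offsets (index fractions) and fractional radius scaling.
#' @param seed integer seed controlling jitter and intensity noise.
#' @param preset "desk" (default) or "paper" geometry.
#' @return A \code{PhantomConfig}.
#' @examples
#' cfg <- phantomConfig(seed = 7)
#' lab <- generateLabelPhantom(cfg)
#' nrow(cdTable(extractCDs(lab)))  # 14
#' @seealso \code{\link{generateLabelPhantom}}, \code{\link{generateCohort}}
#' @export
phantomConfig <- function(dim = NULL, spacing = NULL, labels = 1:8,
                          intensity = NULL,
                          jitter = list(centre = 0.01, radius = 0.05),
                          seed = 1L, preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  if (is.null(dim))
    dim <- if (preset == "paper") c(24L, 256L, 256L) else c(32L, 64L, 64L)
  if (is.null(spacing))
    spacing <- if (preset == "paper") c(4, 1.40625, 1.40625) else c(4, 1.4, 1.4)
  if (is.null(intensity)) intensity <- .defaultIntensityModel()
  jitter$centre <- jitter$centre %||% 0
  jitter$radius <- jitter$radius %||% 0
  cfg <- new("PhantomConfig", dim = as.integer(dim),
             spacing = as.numeric(spacing),
             bones = .defaultBoneTable(labels), intensity = intensity,
             jitter = jitter, seed = as.integer(seed))
  .checkBoneSeparation(cfg)
  cfg
}

# Pairwise primitives must be separable along >= 1 axis at maximal jitter;
# this guarantees non-overlap and a stable CD count under jitter.
.checkBoneSeparation <- function(config) {
  b <- config@bones
  jc <- config@jitter$centre
  rs <- 1 + config@jitter$radius
  if (nrow(b) < 2L) return(invisible(TRUE))
  lo <- cbind(b$cz - jc - b$rz * rs, b$cy - jc - b$ry * rs, b$cx - jc - b$rx * rs)
  hi <- cbind(b$cz + jc + b$rz * rs, b$cy + jc + b$ry * rs, b$cx + jc + b$rx * rs)
  for (i in seq_len(nrow(b) - 1L))
    for (j in seq(i + 1L, nrow(b))) {
      sep <- any(hi[i, ] < lo[j, ] | hi[j, ] < lo[i, ])
      if (!sep)
        stop(sprintf("bone primitives '%s' (%s) and '%s' (%s) may overlap under jitter",
                     b$name[i], b$side[i], b$name[j], b$side[j]))
    }
  invisible(TRUE)
}

# Voxel-centre fractional coordinates along one axis of length n.
.fracCoords <- function(n) (seq_len(n) - 0.5) / n

.primitiveMask <- function(shape, dims, centre, radii) {
  z <- .fracCoords(dims[1]); y <- .fracCoords(dims[2]); x <- .fracCoords(dims[3])
  dz <- (z - centre[1]) / radii[1]
  dy <- (y - centre[2]) / radii[2]
  dx <- (x - centre[3]) / radii[3]
  p <- switch(shape, ellipsoid = 2, rbox = 4, cylinder = 2,
              stop(sprintf("unknown primitive shape '%s'", shape)))
  if (shape == "cylinder") {
    # axis along z: elliptical cross-section, flat ends
    inyx <- outer(abs(dy)^p, abs(dx)^p, `+`) <= 1
    inz <- abs(dz) <= 1
    array(outer(inz, inyx, `&`), dims)
  } else {
    q <- outer(abs(dz)^p, abs(dy)^p, `+`)
    array(outer(q, abs(dx)^p, `+`) <= 1, dims)
  }
}

# Apply seeded per-primitive jitter to the bone table.
.jitterBones <- function(config) {
  b <- config@bones
  jc <- config@jitter$centre
  jr <- config@jitter$radius
  withSeed(config@seed, {
    n <- nrow(b)
    off <- matrix(stats::runif(3 * n, -jc, jc), n, 3)
    scl <- matrix(stats::runif(3 * n, 1 - jr, 1 + jr), n, 3)
    b$cz <- b$cz + off[, 1]; b$cy <- b$cy + off[, 2]; b$cx <- b$cx + off[, 3]
    b$rz <- b$rz * scl[, 1]; b$ry <- b$ry * scl[, 2]; b$rx <- b$rx * scl[, 3]
  })
  b
}

#' Generate a synthetic pelvic label phantom
#'
#' Rasterizes the configured bone primitives onto the grid, applying the
#' seeded per-subject geometry jitter.  For the default complete
#' configuration the result decomposes into exactly 14 connected domains.
#' The output is voxel-identical across repeated calls with the same config.
#'
#' @param config a \code{\link{phantomConfig}}.
#' @return A \code{LabelVolume}.
#' @export
generateLabelPhantom <- function(config) {
  stopifnot(is(config, "PhantomConfig"))
  validObject(config)
  b <- .jitterBones(config)
  dims <- config@dim
  vol <- array(0L, dims)
  for (i in seq_len(nrow(b))) {
    ctr <- c(b$cz[i], b$cy[i], b$cx[i])
    rad <- c(b$rz[i], b$ry[i], b$rx[i])
    if (any(ctr - rad < 0) || any(ctr + rad > 1))
      stop(sprintf("bone '%s' (%s) overflows the grid", b$name[i], b$side[i]))
    m <- .primitiveMask(b$shape[i], dims, ctr, rad)
    if (any(vol[m] != 0L))
      stop(sprintf("bone '%s' (%s) overlaps an already placed primitive",
                   b$name[i], b$side[i]))
    vol[m] <- b$label[i]
  }
  labelVolume(vol, config@spacing)
}

#' Render a DWI- or ADC-like intensity volume for a label phantom
#'
#' Each labelled region receives its configured per-label mean plus seeded
#' Gaussian noise; background receives the background level.  With noise
#' standard deviation 0 the result is piecewise constant.
#'
#' @param labels a \code{LabelVolume}.
#' @param modality "DWI" or "ADC".
#' @param config the \code{\link{phantomConfig}} supplying the intensity
#'   model; must share the label volume's geometry.
#' @return An \code{IntensityVolume}.
#' @export
renderIntensities <- function(labels, modality = c("DWI", "ADC"), config) {
  modality <- match.arg(modality)
  stopifnot(is(labels, "LabelVolume"), is(config, "PhantomConfig"))
  if (!identical(dim(labels@values), as.integer(config@dim)))
    stop("label volume and config do not share geometry")
  im <- config@intensity[[modality]]
  lv <- labels@values
  mu <- array(im$background, dim(lv))
  for (l in 1:8) {
    sel <- lv == l
    if (any(sel)) mu[sel] <- im$means[l]
  }
  if (im$sd > 0) {
    noise <- withSeed(config@seed + 1000L * match(modality, .MODALITIES),
                      stats::rnorm(length(mu), 0, im$sd))
    mu <- mu + array(noise, dim(mu))
  }
  bv <- if (modality == "DWI") 800 else NA_real_
  intensityVolume(mu, labels@spacing, modality, bValue = bv)
}

# Select the rows of a CD table addressed by a PerturbSpec target.
.selectTargets <- function(cds, spec, defaultAll) {
  tab <- cds@table
  if (nrow(tab) == 0L) stop("no connected domains to perturb")
  tgt <- spec@target
  if (length(tgt)) {
    sel <- rep(TRUE, nrow(tab))
    if (!is.null(tgt$label)) sel <- sel & tab$label == tgt$label
    if (!is.null(tgt$component_id)) sel <- sel & tab$component_id == tgt$component_id
    if (!any(sel)) stop("perturbation target matches no connected domain")
    which(sel)
  } else if (defaultAll) {
    seq_len(nrow(tab))
  } else {
    withSeed(spec@seed, sample.int(nrow(tab), 1L))
  }
}

#' Apply a controlled perturbation to a segmentation
#'
#' Produces a degraded copy of a label volume realizing a known overlap
#' condition (see \code{\link{perturbSpec}}).  Dilation claims only
#' background voxels, so other labels are never overwritten; erosion that
#' would annihilate a connected domain is clamped to keep at least one voxel
#' and flagged in the returned volume's \code{provenance} attribute.
#'
#' @param labels a \code{LabelVolume}.
#' @param spec a \code{\link{perturbSpec}}.
#' @return A \code{LabelVolume}; perturbation metadata is attached as
#'   \code{attr(result, "provenance")}.
#' @export
perturbSegmentation <- function(labels, spec) {
  stopifnot(is(labels, "LabelVolume"), is(spec, "PerturbSpec"))
  validObject(spec)
  dims <- dim(labels@values)
  vol <- labels@values
  cds <- extractCDs(labels, connectivity = 26L)
  prov <- list(mode = spec@mode, magnitude = spec@magnitude, clamped = list())

  if (spec@mode == "dilate") {
    idx <- .selectTargets(cds, spec, defaultAll = TRUE)
    for (i in idx) {
      vx <- cds@voxels[[i]]
      m <- logical(prod(dims)); m[vx] <- TRUE
      dm <- cpp_binary_dilate(m, dims, 6L, as.integer(spec@magnitude))
      grow <- which(dm & !m)
      grow <- grow[vol[grow] == 0L]
      vol[grow] <- cds@table$label[i]
    }
  } else if (spec@mode == "erode") {
    idx <- .selectTargets(cds, spec, defaultAll = TRUE)
    for (i in idx) {
      vx <- cds@voxels[[i]]
      m <- logical(prod(dims)); m[vx] <- TRUE
      cur <- m
      clamped <- FALSE
      for (k in seq_len(spec@magnitude)) {
        nxt <- cpp_binary_erode(cur, dims, 6L, 1L)
        if (!any(nxt)) { clamped <- TRUE; break }
        cur <- nxt
      }
      if (identical(cur, m)) {
        # even one erosion step would annihilate this CD: keep the voxel
        # nearest the centroid so a non-empty subset remains
        ctr <- colMeans(linearToZyx(vx, dims))
        zyx <- linearToZyx(vx, dims)
        d2 <- rowSums(sweep(zyx, 2, ctr)^2)
        keep <- vx[which.min(d2)]
        cur <- logical(prod(dims)); cur[keep] <- TRUE
        clamped <- TRUE
      }
      if (clamped)
        prov$clamped[[length(prov$clamped) + 1L]] <-
          list(label = cds@table$label[i],
               component_id = cds@table$component_id[i])
      vol[vx] <- 0L
      vol[which(cur)] <- cds@table$label[i]
    }
  } else if (spec@mode == "shift") {
    idx <- .selectTargets(cds, spec, defaultAll = FALSE)
    ax <- match(spec@axis, c("z", "y", "x"))
    for (i in idx) {
      vx <- cds@voxels[[i]]
      zyx <- linearToZyx(vx, dims)
      zyx[, ax] <- zyx[, ax] + as.integer(spec@magnitude)
      inb <- zyx[, ax] >= 1L & zyx[, ax] <= dims[ax]
      if (!any(inb))
        stop(sprintf("shift pushes CD (label %d, component %d) fully outside the grid",
                     cds@table$label[i], cds@table$component_id[i]))
      vol[vx] <- 0L
      dest <- zyxToLinear(zyx[inb, , drop = FALSE], dims)
      dest <- dest[vol[dest] == 0L]
      vol[dest] <- cds@table$label[i]
    }
  } else if (spec@mode == "drop_cd") {
    idx <- .selectTargets(cds, spec, defaultAll = FALSE)
    for (i in idx) vol[cds@voxels[[i]]] <- 0L
  } else if (spec@mode == "add_spurious") {
    lab <- spec@target$label %||%
      withSeed(spec@seed, sample(unique(cds@table$label), 1L))
    r <- max(1, spec@magnitude)
    placed <- FALSE
    sites <- withSeed(spec@seed + 1L, sample.int(prod(dims)))
    for (s in sites) {
      zyx <- linearToZyx(s, dims)[1, ]
      lo <- zyx - r - 1L; hi <- zyx + r + 1L
      if (any(lo < 1L) || any(hi > dims)) next
      zz <- lo[1]:hi[1]; yy <- lo[2]:hi[2]; xx <- lo[3]:hi[3]
      block <- vol[zz, yy, xx]
      if (any(block != 0L)) next
      g <- expand.grid(z = zz, y = yy, x = xx)
      d2 <- (g$z - zyx[1])^2 + (g$y - zyx[2])^2 + (g$x - zyx[3])^2
      sph <- g[d2 <= r^2, , drop = FALSE]
      vol[zyxToLinear(as.matrix(sph), dims)] <- as.integer(lab)
      placed <- TRUE
      break
    }
    if (!placed) stop("no background site large enough for a spurious component")
  }

  out <- labelVolume(vol, labels@spacing)
  attr(out, "provenance") <- prov
  out
}

#' Generate a cohort of phantom subjects
#'
#' Subject \code{i} uses seed \code{seed + i}, so cohorts are reproducible
#' and per-subject geometry is independently jittered within the configured
#' ranges.
#'
#' @param n number of subjects (>= 1).
#' @param config a \code{\link{phantomConfig}} template.
#' @param seed cohort seed.
#' @return A list of \code{n} subjects, each
#'   \code{list(id, dwi, adc, label)}.
#' @export
generateCohort <- function(n, config = phantomConfig(), seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be >= 1")
  lapply(seq_len(n), function(i) {
    cfg <- config
    cfg@seed <- as.integer(seed + i)
    lab <- generateLabelPhantom(cfg)
    list(id = sprintf("sub-%04d", i),
         dwi = renderIntensities(lab, "DWI", cfg),
         adc = renderIntensities(lab, "ADC", cfg),
         label = lab)
  })
}
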