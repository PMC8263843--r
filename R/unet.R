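# A configurable 3D encoder-decoder segmentation network.
#
# The architecture follows the volumetric U-Net pattern: an encoder of
# `levels` resolution levels with two 3x3x3 convolutions + ReLU per level,
# channel count doubling per level, 2x2x2 max pooling between levels; a
# decoder that upsamples (nearest neighbour followed by a 3x3x3
# "up-convolution"), concatenates the encoder skip features, and applies two
# further convolutions; and a final 1x1x1 convolution to 9 output channels
# (explicit background + 8 bone labels).  Decoding applies a per-channel
# sigmoid and a voxelwise argmax.
#
# Convolutions are computed as im2col + GEMM (see src/ops.cpp), which keeps
# a desk-scale configuration trainable on one CPU.  All tensors are
# (voxels x channels) matrices over a (z, y, x) grid.

#' @exportClass UNet3D
setClass("UNet3D", representation(
  config = "UNetConfig",
  params = "list"
))

setMethod("show", "UNet3D", function(object) {
  np <- sum(vapply(object@params, function(p) length(p$W) + length(p$b),
                   numeric(1)))
  cat(sprintf("UNet3D: %d levels, base %d channels, %d parameters\n",
              object@config@levels, object@config@baseChannels, np))
})

.addBias <- function(y, b) {
  for (j in seq_along(b)) y[, j] <- y[, j] + b[j]
  y
}

# One network block: 3x3x3 convolution -> per-volume (instance)
# normalization -> ReLU.  Normalizing each channel over the voxels of the
# volume is the batch-size-robust counterpart of the reference
# architecture's batch normalization; it keeps activations well scaled so
# short schedules converge.  Returns the block output plus the
# normalization cache needed by the backward pass.
.BN_EPS <- 1e-5

.convF <- function(x, dims, layer) {
  pre <- cpp_conv3_fwd(x, dims, layer$W, numeric(ncol(layer$W)), FALSE)
  mu <- colMeans(pre)
  pre <- sweep(pre, 2, mu)
  invstd <- 1 / sqrt(colMeans(pre^2) + .BN_EPS)
  xhat <- sweep(pre, 2, invstd, `*`)
  y <- sweep(sweep(xhat, 2, layer$g, `*`), 2, layer$b, `+`)
  y[y < 0] <- 0
  list(y = y, xhat = xhat, invstd = invstd)
}

# Backward through one block: x is the block input, fw its forward cache,
# dY the gradient at the block output.
.convB <- function(x, dims, layer, fw, dY) {
  dY <- dY * (fw$y > 0)
  dg <- colSums(dY * fw$xhat)
  db <- colSums(dY)
  n <- nrow(dY)
  dxhat <- sweep(dY, 2, layer$g, `*`)
  s2 <- colSums(dxhat * fw$xhat)
  dpre <- dxhat -
    matrix(colSums(dxhat) / n, n, ncol(dY), byrow = TRUE) -
    sweep(fw$xhat, 2, s2 / n, `*`)
  dpre <- sweep(dpre, 2, fw$invstd, `*`)
  bw <- cpp_conv3_bwd(x, dims, layer$W, fw$y, dpre, FALSE)
  list(dW = bw$dW, dg = dg, db = db, dX = bw$dX)
}

.layerNames <- function(L) {
  nms <- character(0)
  for (i in seq_len(L)) nms <- c(nms, sprintf("enc%dA", i), sprintf("enc%dB", i))
  for (i in seq_len(L - 1)) nms <- c(nms, sprintf("dec%dup", i),
                                     sprintf("dec%dA", i), sprintf("dec%dB", i))
  c(nms, "out")
}

# (in, out) channel counts per layer for `levels` L and base channels C.
.layerShapes <- function(L, C, inCh = 1L, outCh = 9L) {
  ch <- C * 2^(seq_len(L) - 1)
  sh <- list()
  for (i in seq_len(L)) {
    sh[[sprintf("enc%dA", i)]] <- c(if (i == 1L) inCh else ch[i - 1], ch[i])
    sh[[sprintf("enc%dB", i)]] <- c(ch[i], ch[i])
  }
  for (i in seq_len(L - 1)) {
    sh[[sprintf("dec%dup", i)]] <- c(ch[i + 1], ch[i])
    sh[[sprintf("dec%dA", i)]] <- c(2 * ch[i], ch[i])
    sh[[sprintf("dec%dB", i)]] <- c(ch[i], ch[i])
  }
  sh[["out"]] <- c(ch[1], outCh)
  sh
}

#' Build a 3D U-Net from a configuration
#'
#' Weights use seeded He-normal initialization, so the same configuration
#' and seed always yield identical initial weights.
#'
#' @param config a \code{\link{unetConfig}}.
#' @return A \code{UNet3D} model.
#' @examples
#' m <- buildUNet3D(unetConfig(levels = 3, baseChannels = 4, seed = 1))
#' @export
buildUNet3D <- function(config) {
  stopifnot(is(config, "UNetConfig"))
  validObject(config)
  sh <- .layerShapes(config@levels, config@baseChannels,
                     config@inChannels, config@outChannels)
  params <- withSeed(config@seed, {
    ps <- lapply(names(sh), function(nm) {
      s <- sh[[nm]]
      k <- if (nm == "out") 1L else 27L
      fanIn <- s[1] * k
      W <- matrix(stats::rnorm(fanIn * s[2], 0, sqrt(2 / fanIn)), fanIn, s[2])
      if (nm == "out") list(W = W, b = numeric(s[2]))
      else list(W = W, g = rep(1, s[2]), b = numeric(s[2]))
    })
    names(ps) <- names(sh)
    ps
  })
  new("UNet3D", config = config, params = params)
}

.checkShape <- function(dims, L) {
  div <- 2L^(L - 1L)
  if (any(dims %% div != 0L))
    stop(sprintf("input shape (%s) must be divisible by %d in every axis for %d levels",
                 paste(dims, collapse = ", "), div, L))
  invisible(div)
}

# Forward pass; with cache = TRUE all activations needed by .unetBackward
# are retained.
.unetForward <- function(pp, x, dims, L, cache = FALSE) {
  ca <- list(enc = vector("list", L), dec = vector("list", L),
             pool = vector("list", L), dims = vector("list", L))
  d <- dims
  skips <- vector("list", L)
  h <- x
  for (i in seq_len(L)) {
    ca$dims[[i]] <- d
    xa <- h
    fa <- .convF(xa, d, pp[[sprintf("enc%dA", i)]])
    fb <- .convF(fa$y, d, pp[[sprintf("enc%dB", i)]])
    if (cache) ca$enc[[i]] <- list(xa = xa, fa = fa, fb = fb)
    skips[[i]] <- fb$y
    if (i < L) {
      pl <- cpp_maxpool3_fwd(fb$y, d)
      if (cache) ca$pool[[i]] <- pl$idx
      h <- pl$y
      d <- d %/% 2L
    } else h <- fb$y
  }
  for (i in rev(seq_len(L - 1))) {
    xu <- cpp_upsample3_fwd(h, d)
    d <- d * 2L
    fu <- .convF(xu, d, pp[[sprintf("dec%dup", i)]])
    xc <- cbind(skips[[i]], fu$y)
    fa <- .convF(xc, d, pp[[sprintf("dec%dA", i)]])
    fb <- .convF(fa$y, d, pp[[sprintf("dec%dB", i)]])
    if (cache) ca$dec[[i]] <- list(xu = xu, fu = fu, xc = xc, fa = fa, fb = fb)
    h <- fb$y
  }
  logits <- .addBias(h %*% pp$out$W, pp$out$b)
  if (cache) ca$final_in <- h
  list(logits = logits, cache = ca)
}

.unetBackward <- function(pp, dlogits, ca, L) {
  g <- list()
  h <- ca$final_in
  g$out <- list(W = crossprod(h, dlogits), b = colSums(dlogits))
  dh <- tcrossprod(dlogits, pp$out$W)
  dskips <- vector("list", L)
  for (i in seq_len(L - 1)) {
    d <- ca$dims[[i]]
    cc <- ca$dec[[i]]
    bB <- .convB(cc$fa$y, d, pp[[sprintf("dec%dB", i)]], cc$fb, dh)
    bA <- .convB(cc$xc, d, pp[[sprintf("dec%dA", i)]], cc$fa, bB$dX)
    chU <- ncol(cc$fu$y)
    nSkip <- ncol(cc$xc) - chU
    dskips[[i]] <- bA$dX[, seq_len(nSkip), drop = FALSE]
    dyu <- bA$dX[, nSkip + seq_len(chU), drop = FALSE]
    bU <- .convB(cc$xu, d, pp[[sprintf("dec%dup", i)]], cc$fu, dyu)
    g[[sprintf("dec%dB", i)]] <- list(W = bB$dW, g = bB$dg, b = bB$db)
    g[[sprintf("dec%dA", i)]] <- list(W = bA$dW, g = bA$dg, b = bA$db)
    g[[sprintf("dec%dup", i)]] <- list(W = bU$dW, g = bU$dg, b = bU$db)
    dh <- cpp_upsample3_bwd(bU$dX, d)
  }
  dxin <- NULL
  for (i in rev(seq_len(L))) {
    cc <- ca$enc[[i]]
    d <- ca$dims[[i]]
    dyb <- if (i == L) dh else
      dskips[[i]] + cpp_maxpool3_bwd(dxin, ca$pool[[i]], nrow(cc$fb$y))
    bB <- .convB(cc$fa$y, d, pp[[sprintf("enc%dB", i)]], cc$fb, dyb)
    bA <- .convB(cc$xa, d, pp[[sprintf("enc%dA", i)]], cc$fa, bB$dX)
    g[[sprintf("enc%dB", i)]] <- list(W = bB$dW, g = bB$dg, b = bB$db)
    g[[sprintf("enc%dA", i)]] <- list(W = bA$dW, g = bA$dg, b = bA$db)
    dxin <- bA$dX
  }
  g
}

# Numerically stable per-channel binary cross-entropy (or softmax
# cross-entropy) with its gradient w.r.t. the logits.
.lossAndGrad <- function(logits, target, loss = "bce") {
  n <- length(logits)
  if (loss == "bce") {
    l <- mean(pmax(logits, 0) - logits * target + log1p(exp(-abs(logits))))
    sig <- 1 / (1 + exp(-logits))
    list(loss = l, dlogits = (sig - target) / n)
  } else {
    mx <- apply(logits, 1, max)
    ex <- exp(logits - mx)
    p <- ex / rowSums(ex)
    nv <- nrow(logits)
    l <- -mean(log(pmax(rowSums(p * target), 1e-12)))
    list(loss = l, dlogits = (p - target) / nv)
  }
}

.oneHot <- function(labels, outCh = 9L) {
  v <- as.integer(labels)
  t <- matrix(0, length(v), outCh)
  t[cbind(seq_along(v), v + 1L)] <- 1
  t
}

.prepPair <- function(pair, L) {
  img <- pair$image; lab <- pair$label
  stopifnot(is(img, "IntensityVolume"), is(lab, "LabelVolume"))
  if (!identical(dim(img@values), dim(lab@values)))
    stop("shape mismatch between image and label")
  dims <- dim(img@values)
  .checkShape(dims, L)
  list(x = matrix(as.numeric(img@values), ncol = 1),
       target = .oneHot(lab@values), dims = dims)
}

#' Train a 3D U-Net
#'
#' Adam optimization of the configured loss (per-channel binary
#' cross-entropy by default, averaged over channels and voxels).  Subjects
#' are shuffled into minibatches each epoch with a seeded permutation.  When
#' validation pairs are given, the weights with the best validation loss are
#' retained; otherwise the final weights are kept.
#'
#' @param model a \code{\link{buildUNet3D}} model.
#' @param trainPairs list of \code{list(image = IntensityVolume,
#'   label = LabelVolume)}; all volumes must share an admissible shape.
#' @param valPairs optional validation pairs in the same format.
#' @param epochs override for the configured epoch count.
#' @return \code{list(model, log)}: the trained \code{UNet3D} and a
#'   \code{TrainLog} with per-epoch training/validation losses.
#' @export
trainUNet <- function(model, trainPairs, valPairs = NULL, epochs = NULL) {
  stopifnot(is(model, "UNet3D"))
  cfg <- model@config
  L <- cfg@levels
  if (length(trainPairs) == 0L) stop("empty training set")
  epochs <- as.integer(epochs %||% cfg@epochs)
  tr <- lapply(trainPairs, .prepPair, L = L)
  va <- lapply(valPairs %||% list(), .prepPair, L = L)
  pp <- model@params
  if (cfg@priorBias && epochs > 0L && all(pp$out$b == 0)) {
    # warm-start the output biases at the per-channel prior log-odds
    p <- rowMeans(vapply(tr, function(s) colMeans(s$target),
                         numeric(cfg@outChannels)))
    p <- pmin(pmax(p, 1e-4), 1 - 1e-4)
    pp$out$b <- log(p / (1 - p))
  }
  state <- lapply(pp, function(p)
    lapply(p, function(w) list(m = w * 0, v = w * 0)))
  t0 <- proc.time()[3]
  trainLoss <- valLoss <- numeric(0)
  best <- pp
  bestVal <- Inf
  step <- 0L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (ep in seq_len(epochs)) {
    ord <- withSeed(cfg@seed + ep, sample(length(tr)))
    batches <- split(ord, ceiling(seq_along(ord) / cfg@batchSize))
    epLoss <- 0
    for (bt in batches) {
      acc <- NULL
      bl <- 0
      for (s in bt) {
        fw <- .unetForward(pp, tr[[s]]$x, tr[[s]]$dims, L, cache = TRUE)
        lg <- .lossAndGrad(fw$logits, tr[[s]]$target, cfg@loss)
        bl <- bl + lg$loss
        g <- .unetBackward(pp, lg$dlogits, fw$cache, L)
        if (is.null(acc)) acc <- g else
          for (nm in names(g))
            for (f in names(g[[nm]]))
              acc[[nm]][[f]] <- acc[[nm]][[f]] + g[[nm]][[f]]
      }
      nb <- length(bt)
      step <- step + 1L
      c1 <- 1 - b1^step; c2 <- 1 - b2^step
      for (nm in names(pp)) {
        for (f in names(pp[[nm]])) {
          gr <- acc[[nm]][[f]] / nb
          st <- state[[nm]][[f]]
          st$m <- b1 * st$m + (1 - b1) * gr
          st$v <- b2 * st$v + (1 - b2) * gr^2
          pp[[nm]][[f]] <- pp[[nm]][[f]] - cfg@learningRate * (st$m / c1) /
            (sqrt(st$v / c2) + eps)
          state[[nm]][[f]] <- st
        }
      }
      epLoss <- epLoss + bl
    }
    trainLoss <- c(trainLoss, epLoss / length(tr))
    if (length(va)) {
      vl <- mean(vapply(va, function(p) {
        fw <- .unetForward(pp, p$x, p$dims, L, cache = FALSE)
        .lossAndGrad(fw$logits, p$target, cfg@loss)$loss
      }, numeric(1)))
      valLoss <- c(valLoss, vl)
      if (vl < bestVal) { bestVal <- vl; best <- pp }
    }
  }
  finalParams <- if (length(va) && epochs > 0L) best else pp
  log <- new("TrainLog", trainLoss = trainLoss, valLoss = valLoss,
             config = cfg, elapsedSec = unname(proc.time()[3] - t0))
  list(model = new("UNet3D", config = cfg, params = finalParams), log = log)
}

#' Predict a label map for an intensity volume
#'
#' Runs the forward pass, applies a per-channel sigmoid and takes the
#' voxelwise argmax over the 9 channels, yielding labels 0-8.  Deterministic
#' for fixed weights.  Input is expected normalized to [0, 1]; values far
#' outside trigger a warning.
#'
#' @param model a trained \code{UNet3D}.
#' @param volume a normalized \code{IntensityVolume} of admissible shape.
#' @return A \code{LabelVolume}.
#' @export
predictLabels <- function(model, volume) {
  stopifnot(is(model, "UNet3D"), is(volume, "IntensityVolume"))
  dims <- dim(volume@values)
  .checkShape(dims, model@config@levels)
  v <- volume@values
  if (min(v) < -0.01 || max(v) > 1.01)
    warning("input does not look normalized to [0, 1]; see normalizeIntensity()")
  fw <- .unetForward(model@params, matrix(as.numeric(v), ncol = 1), dims,
                     model@config@levels, cache = FALSE)
  sig <- 1 / (1 + exp(-fw$logits))
  lab <- max.col(sig, ties.method = "first") - 1L
  labelVolume(array(as.integer(lab), dims), volume@spacing)
}

#' Save or load a model checkpoint
#'
#' Weights and configuration travel together in one file.
#'
#' @param model a \code{UNet3D}.
#' @param path checkpoint path (.rds).
#' @return \code{saveCheckpoint}: the path, invisibly;
#'   \code{loadCheckpoint}: a \code{UNet3D}.
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(is(model, "UNet3D"))
  cfg <- model@config
  saveRDS(list(
    config = list(levels = cfg@levels, baseChannels = cfg@baseChannels,
                  learningRate = cfg@learningRate, batchSize = cfg@batchSize,
                  epochs = cfg@epochs, loss = cfg@loss,
                  priorBias = cfg@priorBias, seed = cfg@seed),
    params = model@params), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(unetConfig, ck$config)
  new("UNet3D", config = cfg, params = ck$params)
}

#' Serialize a network configuration as JSON
#'
#' The acquisition-scale configuration (64 x 256 x 256 input, 300 epochs)
#' is constructible and serializable even where it is not practical to
#' train.
#'
#' @param config a \code{UNetConfig}.
#' @param path JSON path.
#' @return The path, invisibly.
#' @export
writeUNetConfigJSON <- function(config, path) {
  jsonlite::write_json(
    list(levels = config@levels, base_channels = config@baseChannels,
         in_channels = config@inChannels, out_channels = config@outChannels,
         learning_rate = config@learningRate, batch_size = config@batchSize,
         epochs = config@epochs, loss = config@loss, seed = config@seed),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Export a training log
#'
#' @param log a \code{TrainLog}.
#' @param csvPath CSV path (epoch, train_loss, val_loss) or NULL.
#' @param jsonPath JSON path or NULL.
#' @return Invisibly, the written paths.
#' @export
writeTrainLog <- function(log, csvPath = NULL, jsonPath = NULL) {
  n <- length(log@trainLoss)
  df <- data.frame(epoch = seq_len(n), train_loss = log@trainLoss,
                   val_loss = if (length(log@valLoss)) log@valLoss
                              else rep(NA_real_, n))
  if (!is.null(csvPath)) utils::write.csv(df, csvPath, row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(
      list(train_loss = log@trainLoss, val_loss = log@valLoss,
           elapsed_sec = log@elapsedSec),
      jsonPath, pretty = TRUE, digits = NA)
  invisible(list(csv = csvPath, json = jsonPath))
}
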