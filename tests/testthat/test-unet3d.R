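test_that("network configuration enforces the label-scheme contract", {
  cfg <- unetConfig(levels = 3, baseChannels = 4)
  expect_identical(cfg@outChannels, 9L)
  expect_identical(cfg@inChannels, 1L)
  expect_error(unetConfig(levels = 1), "levels")
  expect_error(unetConfig(baseChannels = 2), "baseChannels")
  expect_error(unetConfig(loss = "dice"), "loss")
  # acquisition-scale configuration is constructible and serializable
  paper <- paperPreset()$unet
  expect_identical(paper@epochs, 300L)
  expect_identical(paper@learningRate, 1e-4)
  expect_identical(paper@batchSize, 2L)
  m <- buildUNet3D(paper)
  tf <- withr::local_tempfile(fileext = ".json")
  writeUNetConfigJSON(paper, tf)
  js <- jsonlite::read_json(tf)
  expect_identical(js$epochs, 300L)
  expect_identical(js$out_channels, 9L)
})

test_that("weight initialization is seed-deterministic with channel doubling", {
  cfg <- unetConfig(levels = 3, baseChannels = 4, seed = 5)
  m1 <- buildUNet3D(cfg)
  m2 <- buildUNet3D(cfg)
  expect_identical(m1@params, m2@params)
  m3 <- buildUNet3D(unetConfig(levels = 3, baseChannels = 4, seed = 6))
  expect_false(identical(m1@params, m3@params))
  # channel doubling per level: enc convs output 4, 8, 16 channels
  expect_identical(ncol(m1@params$enc1B$W), 4L)
  expect_identical(ncol(m1@params$enc2B$W), 8L)
  expect_identical(ncol(m1@params$enc3B$W), 16L)
  expect_identical(ncol(m1@params$out$W), 9L)
})

test_that("prediction preserves shape, emits labels 0-8 and is deterministic", {
  m <- buildUNet3D(unetConfig(levels = 3, baseChannels = 4, seed = 1))
  v <- intensityVolume(array(runif(16 * 32 * 32), c(16, 32, 32)),
                       c(4, 1.4, 1.4), "DWI")
  p1 <- predictLabels(m, v)
  expect_identical(dim(p1), dim(v))
  expect_true(all(voxelData(p1) %in% 0:8))
  expect_identical(voxelData(predictLabels(m, v)), voxelData(p1))
  # shape indivisible by 2^(levels-1) is rejected with the divisor named
  bad <- intensityVolume(array(runif(10 * 32 * 32), c(10, 32, 32)),
                         c(4, 1.4, 1.4), "DWI")
  expect_error(predictLabels(m, bad), "divisible by 4")
  # unnormalized input only warns
  big <- intensityVolume(array(runif(16 * 32 * 32) * 100, c(16, 32, 32)),
                         c(4, 1.4, 1.4), "DWI")
  expect_warning(predictLabels(m, big), "normalized")
})

test_that("the loss is zero on perfect predictions and has correct gradients", {
  set.seed(3)
  target <- pelviseg:::.oneHot(sample(0:8, 50, replace = TRUE))
  perfect <- 60 * (2 * target - 1)          # saturated logits
  for (loss in c("bce", "softmax")) {
    lg <- pelviseg:::.lossAndGrad(perfect, target, loss)
    expect_lt(lg$loss, 1e-8)
  }
  # finite-difference check of d(loss)/d(logits)
  z <- matrix(rnorm(9 * 9), 9, 9)
  t9 <- pelviseg:::.oneHot(sample(0:8, 9, replace = TRUE))
  for (loss in c("bce", "softmax")) {
    lg <- pelviseg:::.lossAndGrad(z, t9, loss)
    eps <- 1e-6
    for (idx in sample(length(z), 5)) {
      zp <- z; zp[idx] <- zp[idx] + eps
      zm <- z; zm[idx] <- zm[idx] - eps
      num <- (pelviseg:::.lossAndGrad(zp, t9, loss)$loss -
              pelviseg:::.lossAndGrad(zm, t9, loss)$loss) / (2 * eps)
      expect_equal(lg$dlogits[idx], num, tolerance = 1e-5)
    }
  }
})

test_that("backpropagation matches numerical gradients on a tiny network", {
  cfg <- unetConfig(levels = 2, baseChannels = 4, seed = 2)
  m <- buildUNet3D(cfg)
  dims <- c(4L, 6L, 6L)
  set.seed(4)
  x <- matrix(runif(prod(dims)), ncol = 1)
  target <- pelviseg:::.oneHot(sample(0:8, prod(dims), replace = TRUE))
  lossAt <- function(pp) {
    fw <- pelviseg:::.unetForward(pp, x, dims, cfg@levels, cache = FALSE)
    pelviseg:::.lossAndGrad(fw$logits, target, "bce")$loss
  }
  fw <- pelviseg:::.unetForward(m@params, x, dims, cfg@levels, cache = TRUE)
  lg <- pelviseg:::.lossAndGrad(fw$logits, target, "bce")
  g <- pelviseg:::.unetBackward(m@params, lg$dlogits, fw$cache, cfg@levels)
  eps <- 1e-6
  for (nm in c("enc1A", "enc2B", "dec1up", "dec1A", "dec1B", "out")) {
    for (idx in sample(length(m@params[[nm]]$W), 3)) {
      pp <- m@params
      pp[[nm]]$W[idx] <- pp[[nm]]$W[idx] + eps
      up <- lossAt(pp)
      pp[[nm]]$W[idx] <- pp[[nm]]$W[idx] - 2 * eps
      dn <- lossAt(pp)
      expect_equal(g[[nm]]$W[idx], (up - dn) / (2 * eps), tolerance = 1e-4,
                   info = nm)
    }
  }
})

test_that("the fused convolution kernels match the im2col + GEMM reference", {
  set.seed(6)
  dims <- c(6L, 8L, 10L)
  inC <- 3L; outC <- 5L
  x <- matrix(rnorm(prod(dims) * inC), ncol = inC)
  W <- matrix(rnorm(inC * 27 * outC), inC * 27, outC)
  b <- rnorm(outC)
  ref <- sweep(pelviseg:::cpp_im2col3(x, dims) %*% W, 2, b, "+")
  ref[ref < 0] <- 0
  got <- pelviseg:::cpp_conv3_fwd(x, dims, W, b, TRUE)
  expect_equal(got, ref, tolerance = 1e-12, ignore_attr = TRUE)
  dY <- matrix(rnorm(prod(dims) * outC), ncol = outC)
  dpre <- dY * (ref > 0)
  bw <- pelviseg:::cpp_conv3_bwd(x, dims, W, got, dY, TRUE)
  expect_equal(bw$dW, crossprod(pelviseg:::cpp_im2col3(x, dims), dpre),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(as.numeric(bw$db), colSums(dpre), tolerance = 1e-12)
  expect_equal(bw$dX,
               pelviseg:::cpp_col2im3(tcrossprod(dpre, W), dims, inC),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("training reduces the loss and respects the epoch contract", {
  cfg16 <- phantomConfig(dim = c(16, 32, 32), jitter = list(centre = 0, radius = 0))
  co <- generateCohort(2, cfg16, seed = 31)
  pairs <- lapply(co, function(s)
    list(image = normalizeIntensity(s$dwi), label = s$label))
  m <- buildUNet3D(unetConfig(levels = 3, baseChannels = 4,
                              learningRate = 3e-3, epochs = 6, seed = 1))
  fit <- trainUNet(m, pairs)
  expect_length(fit$log@trainLoss, 6)
  expect_lt(tail(fit$log@trainLoss, 1), fit$log@trainLoss[1])

  # epochs = 0: nothing happens
  fit0 <- trainUNet(m, pairs, epochs = 0)
  expect_length(fit0$log@trainLoss, 0)
  expect_identical(fit0$model@params, m@params)

  # validation losses are tracked per epoch
  fitv <- trainUNet(m, pairs[1], pairs[2], epochs = 3)
  expect_length(fitv$log@valLoss, 3)

  expect_error(trainUNet(m, list()), "empty")
  badPair <- list(list(image = pairs[[1]]$image,
                       label = labelVolume(array(0L, c(8, 32, 32)),
                                           c(4, 1.4, 1.4))))
  expect_error(trainUNet(m, badPair), "mismatch")
})

test_that("checkpoints round-trip weights and configuration", {
  m <- buildUNet3D(unetConfig(levels = 2, baseChannels = 4, seed = 9))
  tf <- withr::local_tempfile(fileext = ".rds")
  saveCheckpoint(m, tf)
  back <- loadCheckpoint(tf)
  expect_identical(back@params, m@params)
  expect_identical(back@config@levels, m@config@levels)
  v <- intensityVolume(array(runif(8 * 16 * 16), c(8, 16, 16)),
                       c(4, 1.4, 1.4), "ADC")
  expect_identical(voxelData(predictLabels(back, v)),
                   voxelData(predictLabels(m, v)))
})
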