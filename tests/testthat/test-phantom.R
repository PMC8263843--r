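test_that("the bone label scheme carries 14 expected connected domains", {
  b <- boneLabels()
  expect_identical(b$value, 1:8)
  expect_identical(b$laterality[1:2], c("midline", "midline"))
  expect_true(all(b$laterality[3:8] == "bilateral"))
  expect_identical(sum(b$expected_cds), 14L)
})

test_that("phantom generation is seed-deterministic with a stable anatomy", {
  cfg <- phantomConfig(seed = 13)
  a <- generateLabelPhantom(cfg)
  b <- generateLabelPhantom(cfg)
  expect_identical(voxelData(a), voxelData(b))
  expect_setequal(unique(as.vector(voxelData(a))), 0:8)
  expect_identical(nrow(cdTable(extractCDs(a))), 14L)
  # different seeds jitter the geometry
  c <- generateLabelPhantom(phantomConfig(seed = 14))
  expect_false(identical(voxelData(a), voxelData(c)))
})

test_that("restricted label sets yield the matching CD counts", {
  two <- generateLabelPhantom(phantomConfig(labels = 1:2))
  expect_identical(nrow(cdTable(extractCDs(two))), 2L)
  one <- generateLabelPhantom(phantomConfig(labels = 5))
  expect_identical(nrow(cdTable(extractCDs(one))), 2L)  # bilateral
})

test_that("overlapping or overflowing geometry is rejected by name", {
  cfg <- phantomConfig()
  bones <- cfg@bones
  bones$cz[bones$name == "ischium"] <- 0.98  # pushed off the grid
  expect_error(new("PhantomConfig", dim = cfg@dim, spacing = cfg@spacing,
                   bones = bones, intensity = cfg@intensity,
                   jitter = cfg@jitter, seed = 1L) |> validObject(),
               "ischium")
  bones2 <- cfg@bones
  bones2[bones2$name == "pubis", c("cz", "cy", "cx")] <-
    bones2[bones2$name == "ischium", c("cz", "cy", "cx")]
  cfg2 <- cfg
  cfg2@bones <- bones2
  expect_error(pelviseg:::.checkBoneSeparation(cfg2), "overlap")
})

test_that("intensity rendering honours the configured means and seed", {
  im <- pelviseg:::.defaultIntensityModel()
  im$DWI$sd <- 0
  cfg <- phantomConfig(intensity = im, seed = 3)
  lab <- generateLabelPhantom(cfg)
  noiseless <- renderIntensities(lab, "DWI", cfg)
  for (l in c(1L, 4L, 8L)) {
    vals <- voxelData(noiseless)[voxelData(lab) == l]
    expect_true(all(vals == im$DWI$means[l]))
  }
  expect_true(all(voxelData(noiseless)[voxelData(lab) == 0L] ==
                  im$DWI$background))

  cfg2 <- phantomConfig(seed = 3)     # sd = 8
  noisy <- renderIntensities(lab, "ADC", cfg2)
  sd0 <- cfg2@intensity$ADC$sd
  for (l in 1:8) {
    vals <- voxelData(noisy)[voxelData(lab) == l]
    se <- sd0 / sqrt(length(vals))
    expect_lt(abs(mean(vals) - cfg2@intensity$ADC$means[l]), 5 * se)
  }
  expect_identical(voxelData(renderIntensities(lab, "ADC", cfg2)),
                   voxelData(noisy))
  expect_error(renderIntensities(lab, "PET", cfg2))
})

test_that("dilation and erosion produce strict supersets and subsets per CD", {
  lab <- deskPhantom(seed = 8)
  cds <- extractCDs(lab)
  dil <- perturbSegmentation(lab, perturbSpec("dilate", 1))
  ero <- perturbSegmentation(lab, perturbSpec("erode", 1))
  for (i in seq_len(nrow(cdTable(cds)))) {
    l <- cdTable(cds)$label[i]
    vx <- cdVoxels(cds)[[i]]
    dilSet <- which(voxelData(dil) == l)
    eroSet <- which(voxelData(ero) == l)
    expect_true(all(vx %in% dilSet))
    expect_gt(length(setdiff(dilSet, vx)), 0)
    eroOwn <- intersect(eroSet, vx)
    expect_gt(length(eroOwn), 0)
  }
  expect_lt(sum(voxelData(ero) > 0), sum(voxelData(lab) > 0))
  expect_identical(attr(dil, "provenance")$mode, "dilate")
})

test_that("erosion that would annihilate a CD is clamped and flagged", {
  tiny <- blobVolume(c(5, 5, 5), list(list(label = 2, z = 2, y = 2:3, x = 2)))
  ero <- perturbSegmentation(tiny, perturbSpec("erode", 1))
  expect_gte(sum(voxelData(ero) == 2L), 1)
  prov <- attr(ero, "provenance")
  expect_identical(length(prov$clamped), 1L)
  expect_identical(prov$clamped[[1]]$label, 2L)
})

test_that("drop, shift and spurious modes change the CD census as intended", {
  lab <- deskPhantom(seed = 10)
  expect_identical(nrow(cdTable(extractCDs(
    perturbSegmentation(lab, perturbSpec("drop_cd", seed = 2))))), 13L)
  sp <- perturbSegmentation(lab, perturbSpec("add_spurious", 2, seed = 2))
  expect_identical(nrow(cdTable(extractCDs(sp))), 15L)
  # the spurious component is disjoint from every original structure
  expect_true(all(voxelData(lab)[voxelData(sp) != voxelData(lab)] == 0L))
  expect_error(perturbSegmentation(lab, perturbSpec("shift", 500, axis = "x",
    target = list(label = 1, component_id = 1))), "outside")
  expect_error(perturbSpec("dilate", 0))
})

test_that("cohorts derive per-subject seeds and keep the 14-CD anatomy", {
  co <- generateCohort(3, phantomConfig(), seed = 21)
  expect_length(co, 3)
  expect_identical(co[[2]]$id, "sub-0002")
  expect_false(identical(voxelData(co[[1]]$label), voxelData(co[[2]]$label)))
  expect_false(identical(voxelData(co[[2]]$label), voxelData(co[[3]]$label)))
  co2 <- generateCohort(3, phantomConfig(), seed = 21)
  for (i in 1:3) {
    expect_identical(voxelData(co[[i]]$label), voxelData(co2[[i]]$label))
    expect_identical(voxelData(co[[i]]$dwi), voxelData(co2[[i]]$dwi))
    expect_identical(nrow(cdTable(extractCDs(co[[i]]$label))), 14L)
  }
  expect_error(generateCohort(0, phantomConfig()), "n")
  # label maps and intensities share geometry
  expect_identical(dim(co[[1]]$dwi), dim(co[[1]]$label))
  expect_identical(spacing(co[[1]]$adc), spacing(co[[1]]$label))
})
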