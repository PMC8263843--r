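test_that("connected-domain extraction matches brute-force flood fill", {
  set.seed(11)
  for (i in 1:30) {
    d <- sample(3:10, 3, replace = TRUE)
    vol <- array(ifelse(runif(prod(d)) < 0.35,
                        sample(1:3, prod(d), replace = TRUE), 0L), d)
    lv <- labelVolume(vol, c(1, 1, 1))
    for (conn in c(6L, 26L)) {
      cds <- extractCDs(lv, conn)
      tab <- cdTable(cds)
      for (l in unique(vol[vol > 0])) {
        ref <- oracleFloodFill(vol == l, conn)
        expect_equal(sum(tab$label == l), max(ref),
                     info = sprintf("label %d conn %d rep %d", l, conn, i))
        # identical component membership (as a set of voxel-index sets)
        refSets <- lapply(seq_len(max(ref)), function(k) which(ref == k))
        gotSets <- cdVoxels(cds)[tab$label == l]
        expect_setequal(lapply(gotSets, sort), lapply(refSets, sort))
      }
      # partition property: per-CD counts sum to the label's voxel count
      for (l in unique(tab$label))
        expect_identical(sum(tab$voxel_count[tab$label == l]),
                         sum(vol == l))
    }
  }
})

test_that("connectivity controls corner-touching components", {
  v <- array(0L, c(4, 4, 4))
  v[1:2, 1:2, 1:2] <- 1L
  v[3:4, 3:4, 3:4] <- 1L  # touches the first cube only at one corner
  lv <- labelVolume(v, c(1, 1, 1))
  expect_identical(nrow(cdTable(extractCDs(lv, 26L))), 1L)
  expect_identical(nrow(cdTable(extractCDs(lv, 6L))), 2L)

  w <- array(0L, c(4, 4, 4))
  w[1, 1, 1] <- 2L; w[4, 4, 4] <- 2L  # disjoint under any connectivity
  expect_identical(nrow(cdTable(extractCDs(labelVolume(w, c(1, 1, 1))))), 2L)

  empty <- labelVolume(array(0L, c(3, 3, 3)), c(1, 1, 1))
  expect_identical(nrow(cdTable(extractCDs(empty))), 0L)
})

test_that("the complete phantom decomposes into 14 connected domains", {
  cds <- extractCDs(deskPhantom(seed = 5))
  tab <- cdTable(cds)
  expect_identical(nrow(tab), 14L)
  expect_equal(as.vector(table(tab$label)), boneLabels()$expected_cds)
  # ordering: by label, then descending voxel count
  expect_true(!is.unsorted(tab$label))
})

test_that("matching pairs each predicted CD with its max-intersection manual CD", {
  lab <- deskPhantom(seed = 2)
  cds <- extractCDs(lab)

  m <- matchCDs(cds, cds)
  expect_identical(nrow(m), 14L)
  expect_true(all(m$condition == "EXACT"))
  expect_true(all(m$coverage_of_manual == 1 & m$coverage_of_predicted == 1))

  # dropping one ilium component leaves that manual CD in a NONE match
  dropped <- perturbSegmentation(lab, perturbSpec("drop_cd",
    target = list(label = 3, component_id = 1)))
  md <- matchCDs(extractCDs(dropped), cds)
  none <- md[md$condition == "NONE", ]
  expect_identical(nrow(none), 1L)
  expect_identical(none$label, 3L)
  expect_true(is.na(none$pred_component_id))

  # a merged prediction spanning two manual CDs pairs with the larger
  # intersection; the other manual CD gets a NONE match
  dims <- c(3, 12, 5)
  manual <- blobVolume(dims, list(
    list(label = 1, z = 1:3, y = 1:5, x = 1:3),    # 45 voxels
    list(label = 1, z = 1:3, y = 8:12, x = 1:3)))  # 45 voxels
  merged <- blobVolume(dims, list(
    list(label = 1, z = 1:3, y = 3:9, x = 1:3)))   # bridges both
  pm <- matchCDs(extractCDs(merged), extractCDs(manual))
  # oracle: enumerate intersections directly
  inter1 <- length(intersect(which(voxelData(merged) == 1),
                             which(voxelData(manual) == 1 &
                                   slice.index(voxelData(manual), 2) <= 5)))
  inter2 <- length(intersect(which(voxelData(merged) == 1),
                             which(voxelData(manual) == 1 &
                                   slice.index(voxelData(manual), 2) >= 8)))
  expect_identical(sort(c(inter1, inter2)), c(18L, 27L))
  paired <- pm[!is.na(pm$pred_component_id), ]
  expect_identical(paired$intersection_voxels, max(inter1, inter2))
  expect_identical(sum(pm$condition == "NONE"), 1L)
  expect_error(matchCDs(extractCDs(manual),
                        extractCDs(blobVolume(c(3, 12, 6), list()))),
               "geometry")
})

test_that("condition classification distinguishes A1, A2, A3 in both modes", {
  lab <- deskPhantom(seed = 4)
  cds <- extractCDs(lab)

  dil <- perturbSegmentation(lab, perturbSpec("dilate", 1))
  for (strict in c(TRUE, FALSE)) {
    m <- matchCDs(extractCDs(dil), cds, strict = strict)
    expect_true(all(m$condition == "A1"),
                info = sprintf("dilate, strict=%s", strict))
  }
  ero <- perturbSegmentation(lab, perturbSpec("erode", 1))
  for (strict in c(TRUE, FALSE)) {
    m <- matchCDs(extractCDs(ero), cds, strict = strict)
    expect_true(all(m$condition == "A2"),
                info = sprintf("erode, strict=%s", strict))
  }

  # a shift with partial overlap is A3 for the shifted component
  sh <- perturbSegmentation(lab, perturbSpec("shift", 3,
    target = list(label = 5, component_id = 1), axis = "x"))
  m <- matchCDs(extractCDs(sh), cds)
  row <- m[m$label == 5 & m$manual_component_id == 1, ]
  expect_identical(row$condition, "A3")
  expect_true(row$coverage_of_manual > 0 && row$coverage_of_manual < 1)

  # a shift beyond the CD diameter leaves zero overlap
  tab <- cdTable(cds)
  diam <- with(tab[tab$label == 8 & tab$component_id == 1, ],
               bbox_x_max - bbox_x_min + 1L)
  far <- perturbSegmentation(lab, perturbSpec("shift", diam + 1,
    target = list(label = 8, component_id = 1), axis = "x"))
  orig <- cdVoxels(cds)[[which(tab$label == 8 & tab$component_id == 1)]]
  moved <- setdiff(which(voxelData(far) == 8L), which(voxelData(lab) == 8L))
  expect_length(intersect(orig, moved), 0)
})

test_that("classification is antisymmetric under swapping roles", {
  lab <- deskPhantom(seed = 9)
  flipMap <- c(EXACT = "EXACT", A1 = "A2", A2 = "A1", A3 = "A3", NONE = "NONE")
  for (mode in c("dilate", "erode")) {
    pred <- perturbSegmentation(lab, perturbSpec(mode, 1))
    fwd <- matchCDs(extractCDs(pred), extractCDs(lab))
    rev <- matchCDs(extractCDs(lab), extractCDs(pred))
    fwd <- fwd[order(fwd$label, fwd$pred_component_id), ]
    rev <- rev[order(rev$label, rev$manual_component_id), ]
    expect_identical(unname(flipMap[fwd$condition]), rev$condition)
  }
})

test_that("tolerant and strict modes agree on exact super/subsets", {
  lab <- deskPhantom(seed = 6)
  cds <- extractCDs(lab)
  for (mode in c("dilate", "erode")) {
    pred <- extractCDs(perturbSegmentation(lab, perturbSpec(mode, 1)))
    for (tau in c(0.8, 0.95, 1)) {
      expect_identical(matchCDs(pred, cds, tau = tau, strict = FALSE)$condition,
                       matchCDs(pred, cds, strict = TRUE)$condition)
    }
  }
  expect_error(classifyCondition(list(intersection_voxels = 1,
    pred_voxel_count = 2, manual_voxel_count = 2, coverage_of_manual = .5,
    coverage_of_predicted = .5), tau = 0.4), "tau")
  expect_error(matchCDs(cds, cds, tau = 1.2), "tau")
})

test_that("equal-size partial overlaps classify as A3", {
  m <- list(intersection_voxels = 8L, pred_voxel_count = 10L,
            manual_voxel_count = 10L, coverage_of_manual = 0.8,
            coverage_of_predicted = 0.8)
  expect_identical(classifyCondition(m), "A3")
  expect_identical(classifyCondition(m, strict = TRUE), "A3")
  # equal counts with coverage above tau is EXACT only in tolerant mode
  m2 <- list(intersection_voxels = 96L, pred_voxel_count = 100L,
             manual_voxel_count = 100L, coverage_of_manual = 0.96,
             coverage_of_predicted = 0.96)
  expect_identical(classifyCondition(m2), "EXACT")
  expect_identical(classifyCondition(m2, strict = TRUE), "A3")
})
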