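test_that("de-noising behaves like its kernel on canonical inputs", {
  const <- VoxelGrid(array(0.4, c(8, 8, 8)))
  expect_equal(voxelData(denoiseVolume(const, "median", 1L)),
               voxelData(const))
  # single impulse in constant background is removed by the median
  v <- array(0.2, c(9, 9, 9)); v[5, 5, 5] <- 5
  out <- denoiseVolume(VoxelGrid(v), "median", 1L)
  expect_equal(max(voxelData(out)), 0.2)
  # gaussian preserves total intensity (reflective boundary)
  set.seed(4)
  g <- VoxelGrid(array(runif(10^3), c(10, 10, 10)))
  sm <- denoiseVolume(g, "gaussian", 2L)
  expect_lt(abs(sum(voxelData(sm)) - sum(voxelData(g))) / sum(voxelData(g)),
            0.001)
  expect_error(denoiseVolume(g, "median", 8L), "extent")
})

test_that("cell segmentation recovers the phantom cell", {
  ph <- sharedPhantom()
  den <- denoiseVolume(ph$grid)
  cm <- segmentCell(den)
  expect_gte(diceCoef(cm, cellMask(ph$truth)), 0.98)
  lab <- nucleomorph3d:::labelComponents(cm, 26L)
  expect_equal(attr(lab, "n_components"), 1L)
  expect_error(segmentCell(VoxelGrid(array(0, c(5, 5, 5)))), "no cell")
})

test_that("comparable twin blobs trigger a multiplicity warning", {
  v <- array(0, c(24, 10, 10))
  v[3:8, 3:8, 3:8] <- 1
  v[15:20, 3:8, 3:8] <- 1
  expect_warning(cm <- segmentCell(VoxelGrid(v)), "multiple comparable")
  expect_equal(sum(cm), 216L)  # exactly one of the two 6^3 blobs
})

test_that("nucleus segmentation stays inside the cell and finds micronuclei", {
  ph <- sharedPhantom()
  den <- denoiseVolume(ph$grid)
  cm <- segmentCell(den)
  nm <- segmentNucleus(den, cm)
  expect_gte(diceCoef(nm, nucleusMask(ph$truth)), 0.95)
  expect_false(any(nm & !cm))
  expect_s3_class(attr(nm, "micronuclei"), "data.frame")

  phm <- makeCellPhantom(phantomSpec(seed = 21L, shapeCategory = 4L,
                                     lobeCount = 2L, nMicronuclei = 2L,
                                     noiseSd = 0))
  cm2 <- segmentCell(phm$grid)
  nm2 <- segmentNucleus(phm$grid, cm2)
  micro <- attr(nm2, "micronuclei")
  expect_equal(nrow(micro), 2L)
  planted <- 4 / 3 * pi * 0.9^3
  expect_true(all(abs(micro$volume - planted) / planted < 0.35))
  expect_error(segmentNucleus(den, array(FALSE, dim(voxelData(den)))),
               "empty")
})

test_that("nucleolus detection recovers planted counts and handles edge cases", {
  ph <- sharedPhantom(noise = FALSE)
  nm <- nucleusMask(ph$truth)
  lab <- detectNucleoli(ph$grid, nm)
  expect_equal(max(lab), 2L)
  sizes <- tabulate(lab[lab > 0L])
  expect_true(all(diff(sizes) <= 0))  # sorted by descending volume
  # uniform nucleus -> none
  v <- array(0.1, c(8, 8, 8)); m <- array(FALSE, dim(v)); m[3:6, 3:6, 3:6] <- TRUE
  expect_equal(max(detectNucleoli(VoxelGrid(v), m)), 0L)
  # two bright bodies closer than a voxel merge into one label
  v2 <- array(0.3, c(16, 9, 9)); m2 <- array(TRUE, dim(v2))
  v2[5:7, 4:6, 4:6] <- 1; v2[8:10, 4:6, 4:6] <- 1
  expect_equal(max(detectNucleoli(VoxelGrid(v2), m2, min_volume = 0.002)), 1L)
})

test_that("condensation partition matches the hand-computed fixture", {
  fx <- odLineFixture()
  part <- partitionCondensation(fx$grid, fx$mask)
  expect_equal(part@mu, 3)
  expect_equal(part@sigma, sqrt(2))
  st <- part@stateLabels[fx$mask]
  expect_equal(st, c(1L, 2L, 2L, 2L, 3L))  # low={1}, medium={2,3,4}, high={5}
  # states partition the nucleus
  expect_equal(sum(part@stateLabels > 0L), sum(fx$mask))
  v <- array(1, c(4, 4, 4)); m <- array(TRUE, dim(v))
  expect_error(partitionCondensation(VoxelGrid(v), m), "degenerate")
})

test_that("thresholds are equivariant under affine OD rescaling", {
  ph <- sharedPhantom()
  v <- voxelData(ph$grid)
  g2 <- VoxelGrid(3.7 * v + 0.9, spacing = spacing(ph$grid))
  expect_identical(segmentCell(ph$grid), segmentCell(g2))
  nmA <- segmentNucleus(ph$grid, segmentCell(ph$grid))
  nmB <- segmentNucleus(g2, segmentCell(g2))
  expect_identical(unname(nmA), unname(nmB))
  pA <- partitionCondensation(ph$grid, nmA)
  pB <- partitionCondensation(g2, nmB)
  expect_identical(pA@stateLabels, pB@stateLabels)
})

test_that("clump labelling recovers planted blobs and honours connectivity", {
  ph <- sharedPhantom(noise = FALSE)
  part <- partitionCondensation(ph$grid, nucleusMask(ph$truth))
  high <- labelClumps(ph$grid, part, 3L)
  truthHigh <- subset(ph$groundTruth@centers, kind %in% c("high_clump",
                                                          "nucleolus"))
  expect_equal(nrow(high$clumps), nrow(truthHigh))
  # each planted centre has a recovered centroid within one voxel
  for (i in seq_len(nrow(truthHigh))) {
    dists <- sqrt((high$clumps$cx - truthHigh$x[i])^2 +
                    (high$clumps$cy - truthHigh$y[i])^2 +
                    (high$clumps$cz - truthHigh$z[i])^2)
    expect_lt(min(dists), spacing(ph$grid))
  }
  # per-state clump volumes sum to the state volume
  s3 <- spacing(ph$grid)^3
  expect_equal(sum(high$clumps$volume), sum(part@stateLabels == 3L) * s3)
  # empty state -> zero clumps
  none <- labelClumps(ph$grid, array(0L, dim(voxelData(ph$grid))), 1L)
  expect_equal(nrow(none$clumps), 0L)
  # diagonal voxel pair: 2 clumps at 6-connectivity, 1 at 26
  st <- array(0L, c(4, 4, 4)); st[2, 2, 2] <- 1L; st[3, 3, 3] <- 1L
  g <- VoxelGrid(array(1, c(4, 4, 4)))
  expect_equal(nrow(labelClumps(g, st, 1L, connectivity = 6L)$clumps), 2L)
  expect_equal(nrow(labelClumps(g, st, 1L, connectivity = 26L)$clumps), 1L)
})
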