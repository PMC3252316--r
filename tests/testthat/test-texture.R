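test_that("descriptive statistics match hand-computed moments", {
  fx <- odLineFixture()
  ds <- descriptiveStats(fx$grid, fx$mask)
  expect_equal(ds$iod, 15)
  expect_equal(ds$mean, 3)
  expect_equal(ds$variance, 2)
  expect_equal(ds$skew, 0)
  expect_equal(ds$kurtosis, -1.3)
  # IOD scales linearly; skew/kurtosis are scale-free
  g2 <- VoxelGrid(2 * voxelData(fx$grid), spacing = 1)
  ds2 <- descriptiveStats(g2, fx$mask)
  expect_equal(ds2$iod, 30)
  expect_equal(ds2$skew, ds$skew)
  expect_equal(ds2$kurtosis, ds$kurtosis)
  # symmetric histogram has zero skew
  v <- array(0, c(7, 3, 3)); v[, 2, 2] <- c(1, 2, 3, 4, 5, 6, 7)
  m <- array(FALSE, dim(v)); m[, 2, 2] <- TRUE
  expect_lt(abs(descriptiveStats(VoxelGrid(v), m)$skew), 1e-12)
})

test_that("discrete features reproduce the line-fixture fractions", {
  fx <- odLineFixture()
  part <- partitionCondensation(fx$grid, fx$mask)
  cen <- nucleusCenter(fx$grid, fx$mask)
  df <- discreteFeatures(fx$grid, part, cen)
  expect_equal(unname(df[paste0(c("low", "medium", "high"),
                                "_density_volume_fraction")]),
               c(0.2, 0.6, 0.2))
  expect_equal(unname(df[paste0(c("low", "medium", "high"),
                                "_density_content_fraction")]),
               c(1 / 15, 9 / 15, 5 / 15))
  expect_equal(unname(df[paste0("number_of_", c("low", "medium", "high"),
                                "_density_clumps")]),
               c(1, 1, 1))
  expect_equal(length(df), 24L)
  expect_equal(sum(df[paste0(c("low", "medium", "high"),
                             "_density_volume_fraction")]), 1)
})

test_that("planted clump counts flow into the discrete block", {
  ph <- sharedPhantom(noise = FALSE)
  nm <- nucleusMask(ph$truth)
  part <- partitionCondensation(ph$grid, nm)
  df <- discreteFeatures(ph$grid, part, nucleusCenter(ph$grid, nm))
  spec <- phantomSpec(seed = 7L, noiseSd = 0)
  expect_equal(unname(df["number_of_low_density_clumps"]),
               as.numeric(spec@nLowClumps))
  expect_equal(unname(df["number_of_high_density_clumps"]),
               as.numeric(spec@nHighClumps + spec@nNucleoli))
  # a single central clump has near-zero centroid distance
  v <- array(0.5, c(11, 11, 11))
  v[5:7, 5:7, 5:7] <- 1; v[2, 2, 2] <- 0.01
  m <- array(TRUE, dim(v))
  g <- VoxelGrid(v, 1)
  p <- partitionCondensation(g, m)
  d2 <- discreteFeatures(g, p, nucleusCenter(g, m))
  expect_lt(unname(
    d2["average_centroidal_distance_from_nucleus_center_to_high_density_regions"]),
    1)
})

test_that("compactness is near 1 for balls and volume-weights clumps", {
  lab <- array(0L, c(24, 12, 12))
  ball <- digitalBall(3L, pad = 2L)  # 11^3
  lab[1:11, 1:11, 1:11][ball] <- 1L
  one <- compactness(lab, 1)
  expect_equal(one, 1, tolerance = 0.1)
  # two equal balls score as one ball (volume weighting)
  lab2 <- lab
  lab2[13:23, 1:11, 1:11][ball] <- 2L
  expect_equal(compactness(lab2, 1), one, tolerance = 0.02)
  # a long thin filament is less compact
  fil <- array(0L, c(30, 8, 8)); fil[2:29, 4:5, 4:5] <- 1L
  expect_lt(compactness(fil, 1), one)
  expect_true(is.na(compactness(array(0L, c(4, 4, 4)), 1)))
})

test_that("extinction ratios compare interface mean densities", {
  # two abutting constant slabs, OD 2 and 4 -> ratio 0.5
  v <- array(0, c(10, 6, 6))
  v[1:5, , ] <- 2; v[6:10, , ] <- 4
  st <- array(0L, dim(v)); st[1:5, , ] <- 1L; st[6:10, , ] <- 2L
  part <- new("CondensationPartition", mu = 3, sigma = 1, tLow = 2.5,
              tHigh = 3.5, stateLabels = st)
  er <- extinctionRatios(VoxelGrid(v), part)
  expect_equal(unname(er["low_medium"]), 0.5)
  expect_true(is.na(er["low_high"]))
  # identical interface densities -> 1
  v2 <- v; v2[1:10, , ] <- 3
  expect_equal(unname(extinctionRatios(VoxelGrid(v2), part)["low_medium"]), 1)
  # a graded interface is smoother (closer to 1) than a step
  vg <- array(0, c(10, 6, 6))
  vg[] <- rep(seq(2, 4, length.out = 10), 36)
  expect_gt(unname(extinctionRatios(VoxelGrid(vg), part)["low_medium"]),
            unname(er["low_medium"]))
})

test_that("offset enumeration covers the 26-neighbourhood at integer multiples", {
  off <- enumerateOffsets(0.35, 0.35)
  expect_equal(nrow(off), 26L)
  expect_true(all(rowSums(abs(off)) > 0))
  expect_true(all(off %in% -1:1))
  off2 <- enumerateOffsets(0.74, 0.35)   # k = round(2.114) = 2
  expect_equal(nrow(off2), 26L)
  expect_true(all(sort(unique(as.vector(off2))) == c(-2L, 0L, 2L)))
  expect_true(any(apply(off2, 1, function(r) all(r == c(0L, 0L, 2L)))))
  expect_error(enumerateOffsets(0.2, 0.35), "scale")
})

test_that("the 3D co-occurrence matrix matches a brute-force pair count", {
  set.seed(9)
  v <- array(runif(10 * 9 * 8), c(10, 9, 8))
  m <- array(runif(10 * 9 * 8) > 0.3, c(10, 9, 8))
  g <- VoxelGrid(v, spacing = 0.35)
  for (scale in c(0.35, 0.74)) {
    off <- enumerateOffsets(scale, 0.35)
    fast <- glcm3d(g, m, levels = 8L, offsets = off)
    slow <- bruteGLCM(v, m, 8L, off)
    expect_equal(fast$p, slow, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(sum(fast$p), 1, tolerance = 1e-9)
    expect_equal(fast$p, t(fast$p))  # symmetric
  }
  # alternating stripes along x with a single x-offset: all mass off-diagonal
  vs <- array(rep(c(0, 1), length.out = 6 * 6 * 6), c(6, 6, 6))
  gs <- VoxelGrid(vs)
  p <- glcm3d(gs, array(TRUE, dim(vs)), 2L, matrix(c(1L, 0L, 0L), 1))$p
  expect_equal(p, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_error(glcm3d(VoxelGrid(array(1, c(4, 4, 4))),
                      array(TRUE, c(4, 4, 4)), 8L, off), "constant")
})

test_that("Haralick features match closed forms and bounds", {
  # degenerate single-cell matrix
  p1 <- matrix(0, 4, 4); p1[2, 2] <- 1
  h1 <- haralickFeatures(p1)
  expect_equal(unname(h1[c("energy", "contrast", "homogeneity")]), c(1, 0, 1))
  expect_true(is.na(h1["correlation"]))
  # two-level checker matrix
  h2 <- haralickFeatures(matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_equal(unname(h2), c(0.5, 1, -1, 0.5), tolerance = 1e-12)
  # bounds on random symmetric matrices
  set.seed(11)
  for (i in 1:20) {
    q <- matrix(runif(36), 6, 6); q <- q + t(q); q <- q / sum(q)
    h <- haralickFeatures(q)
    expect_true(h["energy"] > 0 && h["energy"] <= 1)
    expect_true(h["homogeneity"] > 0 && h["homogeneity"] <= 1)
    expect_true(abs(h["correlation"]) <= 1 + 1e-12)
  }
})

test_that("Haralick features are invariant to affine OD rescaling", {
  ph <- sharedPhantom(noise = FALSE)
  nm <- nucleusMask(ph$truth)
  g2 <- VoxelGrid(2.5 * voxelData(ph$grid) + 0.3, spacing = spacing(ph$grid))
  off <- enumerateOffsets(0.74, spacing(ph$grid))
  hA <- haralickFeatures(glcm3d(ph$grid, nm, 16L, off))
  hB <- haralickFeatures(glcm3d(g2, nm, 16L, off))
  expect_equal(hA, hB, tolerance = 1e-12)
})

test_that("the Markovian block sweeps scales and tracks the canonical one", {
  ph <- sharedPhantom(noise = FALSE)
  nm <- nucleusMask(ph$truth)
  mb <- markovianBlock(ph$grid, nm)
  expect_equal(nrow(mb$perScale), 3L)
  expect_equal(mb$perScale$scale, c(0.44, 0.74, 1.5))
  expect_equal(unname(mb$canonical["contrast"]), mb$perScale$contrast[2])
  mb2 <- markovianBlock(ph$grid, nm)
  expect_identical(mb, mb2)  # deterministic
  # contrast grows with scale on a smooth linear ramp
  d <- c(20, 20, 20)
  ramp <- array(rep(seq(0, 1, length.out = 20), times = 400), d)
  gr <- VoxelGrid(ramp, spacing = 0.35)
  mr <- markovianBlock(gr, array(TRUE, d), scales = c(0.35, 0.7, 1.4))
  expect_true(all(diff(mr$perScale$contrast) > 0))
})
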