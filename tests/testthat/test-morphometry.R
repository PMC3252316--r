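test_that("mask volume is voxel count times spacing cubed", {
  m <- array(FALSE, c(10, 10, 10)); m[1:10, 1:10, 1:10][1:1000] <- TRUE
  expect_equal(maskVolume(m, 0.5), 125)
  expect_equal(maskVolume(array(FALSE, c(3, 3, 3)), 1), 0)
  b <- digitalBall(10L)
  expect_lt(abs(maskVolume(b, 0.35) - 4 / 3 * pi * 3.5^3) / (4 / 3 * pi * 3.5^3),
            0.03)
})

test_that("N/C ratio uses the cytoplasm as denominator", {
  expect_equal(ncRatio(100, 300), 0.5)
  expect_equal(ncRatio(50, 100), 1)
  expect_error(ncRatio(100, 90), "cell_volume")
  expect_error(ncRatio(0, 90), "nucleus_volume")
})

test_that("surface area matches analytic spheres and behaves on edge cases", {
  b <- digitalBall(20L)
  expect_lt(abs(surfaceArea(b, 1) - 4 * pi * 400) / (4 * pi * 400), 0.03)
  # single voxel: positive and finite
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  a1 <- surfaceArea(one, 1)
  expect_true(is.finite(a1) && a1 > 0)
  # mask touching the array border must not fail
  edge <- array(TRUE, c(4, 4, 4))
  expect_gt(surfaceArea(edge, 1), 0)
  # filling a deep concavity reduces area: ball with a spherical pocket
  ball <- digitalBall(10L, pad = 4L)
  d <- dim(ball)
  cx <- (d[1] - 1) / 2
  pock <- array(outer(outer(((seq_len(d[1]) - 1) - cx - 7)^2,
                            ((seq_len(d[2]) - 1) - cx)^2, "+"),
                      ((seq_len(d[3]) - 1) - cx)^2, "+") <= 36, d)
  indented <- ball & !pock
  expect_gt(surfaceArea(indented, 1), surfaceArea(ball, 1))
  expect_error(surfaceArea(array(FALSE, c(3, 3, 3)), 1), "empty")
})

test_that("sphericity hits closed forms and preserves shape ordering", {
  expect_equal(sphericityVA(1, 6), pi^(1 / 3) * 6^(2 / 3) / 6)
  b <- digitalBall(14L)
  expect_equal(sphericity(b, 1), 1, tolerance = 0.05)
  ell <- digitalEllipsoid(c(20, 10, 10))
  indent <- makeNucleusShape(1L, semiAxes = c(4.9, 4.9, 1.9),
                             concavityDepthFraction = 0.5)$mask
  psi <- c(sphericity(b, 1), sphericity(ell, 1), sphericity(indent, 1))
  expect_true(all(diff(psi) < 0))          # ball > 2:1 ellipsoid > indented
  expect_true(all(psi > 0 & psi < 1.05))   # bounded above 1 + discretization
})

test_that("the density-weighted nucleus centre responds to density shifts", {
  b <- digitalBall(8L)
  v <- array(0.5, dim(b))
  g <- VoxelGrid(v, spacing = 1)
  cen <- nucleusCenter(g, b)
  geo <- colMeans(nucleomorph3d:::voxelCoordinates(b, 1))
  expect_lt(sqrt(sum((cen - geo)^2)), 0.5)
  # doubling the density on the x-upper half pulls the centre that way;
  # two-slab closed form: masses m and 2m at +-x0 -> shift x0/3
  d <- dim(b)
  v2 <- v
  upper <- slice.index(b, 1) > (d[1] + 1) / 2
  v2[upper] <- 1
  cen2 <- nucleusCenter(VoxelGrid(v2, 1), b)
  expect_gt(cen2[1], cen[1])
  expect_equal(cen2[2:3], cen[2:3], tolerance = 1e-6)
  # invariant under OD scaling
  cen3 <- nucleusCenter(VoxelGrid(5 * v2, 1), b)
  expect_equal(cen2, cen3, tolerance = 1e-12)
  expect_error(nucleusCenter(VoxelGrid(array(0, c(4, 4, 4)), 1),
                             array(TRUE, c(4, 4, 4))), "zero total")
})

test_that("nucleolar margination summarises distances with population variance", {
  # two nucleoli at distances 2 and 4 um from the centre -> mean 3, var 1
  v <- array(0.1, c(21, 9, 9))
  lab <- array(0L, dim(v))
  lab[11 + 2, 5, 5] <- 1L   # 2 um away at spacing 1
  lab[11 - 4, 5, 5] <- 2L
  g <- VoxelGrid(v, spacing = 1)
  nf <- nucleolarFeatures(lab, g, nucleus_center = c(10, 4, 4))
  expect_equal(nf$count, 2L)
  expect_equal(nf$meanMargination, 3)
  expect_equal(nf$marginationVariance, 1)
  # single nucleolus at the centre
  lab0 <- array(0L, dim(v)); lab0[11, 5, 5] <- 1L
  nf0 <- nucleolarFeatures(lab0, g, c(10, 4, 4))
  expect_equal(nf0$meanMargination, 0)
  # zero nucleoli: count/total zero, margination not applicable
  nfE <- nucleolarFeatures(array(0L, dim(v)), g, c(10, 4, 4))
  expect_equal(nfE$count, 0L)
  expect_equal(nfE$totalVolume, 0)
  expect_true(is.na(nfE$meanMargination))
})

test_that("planted nucleolar margination is recovered within one voxel", {
  ph <- sharedPhantom(noise = FALSE)
  nm <- nucleusMask(ph$truth)
  cen <- nucleusCenter(ph$grid, nm)
  nf <- nucleolarFeatures(detectNucleoli(ph$grid, nm), ph$grid, cen)
  truthN <- subset(ph$groundTruth@centers, kind == "nucleolus")
  truthMarg <- sqrt(rowSums((as.matrix(truthN[, c("x", "y", "z")]) -
                               matrix(cen, nrow(truthN), 3, byrow = TRUE))^2))
  expect_equal(nf$count, nrow(truthN))
  expect_lt(abs(nf$meanMargination - mean(truthMarg)), spacing(ph$grid))
})

test_that("morphological features are invariant to axis rotations and translation", {
  ph <- sharedPhantom(noise = FALSE)
  nm <- nucleusMask(ph$truth)
  cm <- cellMask(ph$truth)
  s <- spacing(ph$grid)
  base <- c(maskVolume(cm, s), maskVolume(nm, s), sphericity(nm, s))
  rot <- function(a) aperm(a, c(3, 1, 2))[, , dim(a)[3]:1]
  nmR <- rot(nm); cmR <- rot(cm)
  rotv <- c(maskVolume(cmR, s), maskVolume(nmR, s), sphericity(nmR, s))
  expect_equal(rotv, base, tolerance = 0.01)
})
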