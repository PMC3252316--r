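test_that("feature registry has the canonical 42-descriptor structure", {
  reg <- featureRegistry()
  expect_equal(nrow(reg), 42L)
  counts <- table(reg$category)
  expect_equal(as.integer(counts[c("morphological", "descriptive",
                                   "discrete", "markovian")]),
               c(9L, 5L, 24L, 4L))
  expect_false(anyDuplicated(reg$name) > 0)
  # spot-check canonical names and ordering blocks
  expect_equal(reg$name[1:2], c("cell_volume", "nuclear_volume"))
  expect_equal(reg$name[7], "variance_in_nucleolar_volume")
  expect_equal(reg$name[39:42],
               paste0("markovian_", c("contrast", "correlation", "energy",
                                      "heterogeneity")))
  expect_true(all(reg$units[reg$name %in% c("cell_volume", "nuclear_volume",
                                            "total_nucleolar_volume")] == "um3"))
})

test_that("VoxelGrid enforces its invariants", {
  expect_s4_class(VoxelGrid(array(0, c(3, 3, 3))), "VoxelGrid")
  expect_error(VoxelGrid(array(0, c(2, 3, 3))), "3 voxels")
  expect_error(VoxelGrid(array(-1, c(3, 3, 3))), "non-negative")
  expect_error(VoxelGrid(array(NA_real_, c(3, 3, 3))))
  expect_error(VoxelGrid(array(0, c(3, 3, 3)), spacing = 0), "spacing")
  expect_error(VoxelGrid(matrix(0, 3, 3)), "3D")
})

test_that("volume round-trips are lossless across containers", {
  set.seed(1)
  v <- array(runif(8^3), c(8, 8, 8))
  g <- VoxelGrid(v, spacing = 0.35, cellId = "rt")
  for (ext in c(".tif", ".nrrd", ".mha")) {
    f <- tempfile(fileext = ext)
    writeVolume(g, f)
    g2 <- if (ext == ".tif") readVolume(f, spacing_override = 0.35)
          else readVolume(f)
    expect_equal(voxelData(g2), v, tolerance = 1e-7, ignore_attr = TRUE)
    expect_equal(spacing(g2), 0.35)
    # overwrite succeeds deterministically
    writeVolume(g, f)
    g3 <- if (ext == ".tif") readVolume(f, spacing_override = 0.35)
          else readVolume(f)
    expect_identical(voxelData(g3), voxelData(g2))
  }
  # NRRD round-trip is bit-identical for doubles
  f <- tempfile(fileext = ".nrrd")
  writeVolume(g, f)
  expect_identical(voxelData(readVolume(f)), v)
})

test_that("label volumes round-trip exactly as 8-bit", {
  m <- array(0, c(6, 6, 6))
  m[2:4, 2:4, 2:4] <- 3
  for (ext in c(".nrrd", ".mha")) {
    f <- tempfile(fileext = ext)
    writeVolume(m, f, type = "uint8", spacing = 0.5)
    expect_identical(voxelData(readVolume(f)), m)
  }
})

test_that("spacing metadata is mandatory and isotropy is enforced", {
  v <- array(runif(4^3), c(4, 4, 4))
  f <- tempfile(fileext = ".tif")
  writeVolume(VoxelGrid(v), f)
  expect_error(readVolume(f), "missing spacing")
  # NRRD with explicit spacing 0.35 passes it through
  f2 <- tempfile(fileext = ".nrrd")
  writeVolume(VoxelGrid(v, spacing = 0.35), f2)
  expect_equal(spacing(readVolume(f2)), 0.35)
  # anisotropic header names the axis
  txt <- readLines(f2, n = 7, warn = FALSE)
  raw <- readBin(f2, "raw", file.size(f2))
  hdrEnd <- which(raw == as.raw(10))[8]
  f3 <- tempfile(fileext = ".nrrd")
  con <- file(f3, "wb")
  writeLines(c(sub("spacings: .*", "spacings: 0.35 0.35 0.5", txt), ""), con)
  writeBin(raw[(hdrEnd + 1):length(raw)], con)
  close(con)
  expect_error(readVolume(f3), "anisotropic.*axis z")
})

test_that("degenerate and unsupported volume inputs are rejected", {
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0.5, 4, 4), matrix(0.5, 4, 4)), f)
  expect_error(readVolume(f, spacing_override = 0.35), "not a 3D volume")
  expect_error(readVolume(tempfile(fileext = ".dcm")), "file not found")
  file.create(f4 <- tempfile(fileext = ".dcm"))
  expect_error(readVolume(f4), "unsupported")
  expect_error(writeVolume(VoxelGrid(array(0, c(3, 3, 3))),
                           tempfile(fileext = ".png")),
               "supported")
})

test_that("feature tables round-trip and enforce the registry schema", {
  reg <- featureRegistry()$name
  set.seed(2)
  tab <- data.frame(cell_id = c("a", "b", "c"),
                    matrix(rnorm(3 * 42), 3, 42), check.names = FALSE)
  names(tab)[-1] <- reg
  f <- tempfile(fileext = ".csv")
  writeFeatures(tab, f)
  back <- readFeatures(f)
  expect_equal(dim(back), c(3L, 43L))
  expect_equal(back[, -1], tab[, -1], tolerance = 1e-11)
  # empty table -> header-only CSV
  writeFeatures(tab[0, ], f)
  expect_equal(nrow(readFeatures(f)), 0L)
  expect_equal(length(readLines(f)), 1L)
  # schema mismatch names the offending columns
  bad <- tab
  names(bad)[2] <- "bogus"
  expect_error(writeFeatures(bad, f), "cell_volume")
  expect_error(writeFeatures(bad, f), "bogus")
})

test_that("study configuration validates, round-trips through YAML", {
  cfg <- studyConfig(glcmLevels = 16L, alpha = 0.01)
  expect_s4_class(cfg, "StudyConfig")
  f <- tempfile(fileext = ".yaml")
  writeStudyConfig(cfg, f)
  cfg2 <- readStudyConfig(f)
  expect_equal(cfg2@glcmLevels, 16L)
  expect_equal(cfg2@alpha, 0.01)
  expect_equal(cfg2@glcmScales, cfg@glcmScales)
  expect_error(studyConfig(alpha = 2), "alpha")
  expect_error(studyConfig(glcmScales = c(0.1)), "spacing")
  expect_error(studyConfig(clumpConnectivity = 10L), "6, 18 or 26")
})
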