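#' Construct a PhantomSpec
#'
#' @param ... named overrides of \linkS4class{PhantomSpec} slots.
#' @return A validated \linkS4class{PhantomSpec}.
#' @examples
#' spec <- phantomSpec(shapeCategory = 1L, concavityDepthFraction = 0.45,
#'                     nucleusSemiAxes = c(4.2, 4.2, 1.9))
#' @export
phantomSpec <- function(...) {
  args <- list(...)
  obj <- new("PhantomSpec")
  for (nm in names(args)) {
    if (!nm %in% slotNames(obj)) stop("unknown PhantomSpec field: ", nm)
    value <- args[[nm]]
    if (is(slot(obj, nm), "integer")) value <- as.integer(value)
    slot(obj, nm) <- value
  }
  validObject(obj)
  obj
}

# --- geometry --------------------------------------------------------------

ellipsoidInside <- function(dims, center, semiAxes, spacing) {
  ax <- lapply(1:3, function(k) {
    (((seq_len(dims[k]) - 1) * spacing - center[k]) / semiAxes[k])^2
  })
  q <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  q <= 1
}

sphereInside <- function(dims, center, radius, spacing) {
  ellipsoidInside(dims, center, rep(radius, 3), spacing)
}

# Shape description for one nucleus; category 4 draws its lobes from the RNG
# (call inside withSeed). Lobe centres are offsets from the nucleus centre in
# micrometres.
nucleusGeometry <- function(category, semiAxes, concavityDepthFraction,
                            lobeCount) {
  if (category %in% c(1L, 2L) && concavityDepthFraction > 0) {
    a <- semiAxes[1]
    cc <- semiAxes[3]
    d <- concavityDepthFraction * cc
    R <- max(a, 1.5 * d)
    z0 <- cc - d + R   # indent sphere centre height above nucleus centre
    list(kind = "indented", a = a, c = cc, depth = d, R = R, z0 = z0)
  } else if (category == 4L) {
    lobes <- list(list(offset = c(0, 0, 0), semiAxes = semiAxes * 0.8))
    for (k in seq_len(lobeCount - 1L)) {
      parent <- lobes[[sample.int(length(lobes), 1L)]]
      axes <- semiAxes * stats::runif(1, 0.62, 0.78)
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      # directional radii keep the overlap (and hence the neck between
      # lobes) shallow whichever way the lobe is displaced
      ru <- function(ax) 1 / sqrt(sum((u / ax)^2))
      dist <- 0.92 * (ru(parent$semiAxes) + ru(axes))
      lobes[[length(lobes) + 1L]] <- list(offset = parent$offset + u * dist,
                                          semiAxes = axes)
    }
    list(kind = "lobed", lobes = lobes)
  } else {
    list(kind = "ellipsoid", semiAxes = semiAxes)
  }
}

rasterizeNucleus <- function(geom, dims, center, spacing) {
  if (geom$kind == "ellipsoid") {
    ellipsoidInside(dims, center, geom$semiAxes, spacing)
  } else if (geom$kind == "indented") {
    ell <- ellipsoidInside(dims, center, c(geom$a, geom$a, geom$c), spacing)
    ind <- sphereInside(dims, center + c(0, 0, geom$z0), geom$R, spacing)
    ell & !ind
  } else {
    mask <- array(FALSE, dims)
    for (lb in geom$lobes)
      mask <- mask | ellipsoidInside(dims, center + lb$offset, lb$semiAxes,
                                     spacing)
    mask
  }
}

# Half-extent (micrometres) of the shape's bounding box about its centre.
geometryExtent <- function(geom) {
  if (geom$kind == "ellipsoid") return(geom$semiAxes)
  if (geom$kind == "indented") return(c(geom$a, geom$a, geom$c))
  ext <- sapply(geom$lobes, function(lb) abs(lb$offset) + lb$semiAxes)
  apply(ext, 1, max)
}

# Analytic volume. Exact closed form for the ellipsoid and for the indented
# spheroid (piecewise polynomial integrals split at the height where the
# indent sphere's cross-section equals the spheroid's); Monte-Carlo for the
# lobed union (draws from the RNG: call inside withSeed).
analyticNucleusVolume <- function(geom, mcSamples = 200000L) {
  if (geom$kind == "ellipsoid")
    return(list(volume = 4 / 3 * pi * prod(geom$semiAxes), se = 0))
  if (geom$kind == "indented") {
    a <- geom$a; cc <- geom$c; R <- geom$R; z0 <- geom$z0; d <- geom$depth
    # crossing height z*: a^2 (1 - z^2/c^2) = R^2 - (z - z0)^2
    A <- 1 - a^2 / cc^2
    B <- -2 * z0
    C <- z0^2 - R^2 + a^2
    if (abs(A) < 1e-12) {
      zs <- -C / B
    } else {
      disc <- B^2 - 4 * A * C
      if (disc < 0) stop("indentation sphere does not intersect the spheroid")
      roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
      zs <- roots[roots > cc - d - 1e-9 & roots < cc + 1e-9]
      if (!length(zs)) stop("indentation sphere does not intersect the spheroid")
      zs <- min(zs)
    }
    # removed = spheroid cross-sections above z*, sphere cross-sections below
    ellInt <- function(z) a^2 * (z - z^3 / (3 * cc^2))         # integral of r_e^2
    sphInt <- function(z) R^2 * z - (z - z0)^3 / 3             # integral of rho^2
    removed <- pi * (ellInt(cc) - ellInt(zs)) +
      pi * (sphInt(zs) - sphInt(cc - d))
    list(volume = 4 / 3 * pi * a^2 * cc - removed, se = 0)
  } else {
    ext <- geometryExtent(geom)
    lo <- -ext
    box <- 2 * ext
    pts <- cbind(stats::runif(mcSamples, lo[1], lo[1] + box[1]),
                 stats::runif(mcSamples, lo[2], lo[2] + box[2]),
                 stats::runif(mcSamples, lo[3], lo[3] + box[3]))
    inside <- rep(FALSE, mcSamples)
    for (lb in geom$lobes) {
      q <- ((pts[, 1] - lb$offset[1]) / lb$semiAxes[1])^2 +
        ((pts[, 2] - lb$offset[2]) / lb$semiAxes[2])^2 +
        ((pts[, 3] - lb$offset[3]) / lb$semiAxes[3])^2
      inside <- inside | q <= 1
    }
    p <- mean(inside)
    vbox <- prod(box)
    list(volume = vbox * p, se = vbox * sqrt(p * (1 - p) / mcSamples))
  }
}

#' Generate a nucleus shape mask of one of the four categories
#'
#' Category 3 is a plain ellipsoid; categories 1 and 2 are a spheroid with a
#' spherical-cap indentation carved along the third axis (deep and slender
#' versus shallow and bulky: the "mushroom cap" morphology); category 4 is a
#' union of 2-4 overlapping displaced ellipsoidal lobes. The analytic volume
#' is exact for categories 1-3 and Monte-Carlo estimated (with standard
#' error) for category 4.
#'
#' @param category integer 1-4.
#' @param semiAxes numeric(3) semi-axes in micrometres (categories 1/2 need
#'   the first two equal).
#' @param concavityDepthFraction cap depth as a fraction of the third
#'   semi-axis (categories 1/2; 0 reduces to the plain ellipsoid).
#' @param lobeCount lobes for category 4.
#' @param spacing voxel spacing in micrometres.
#' @param seed RNG seed (used by category 4 lobe placement and Monte-Carlo).
#' @return list with \code{mask} (logical 3D array), \code{analyticVolume}
#'   (um^3), \code{volumeSE} (um^3, 0 when exact), \code{spacing} and the
#'   internal \code{geometry}.
#' @examples
#' sh <- makeNucleusShape(3L, semiAxes = c(5, 4, 3), spacing = 0.35)
#' sh$analyticVolume            # 4*pi/3 * 60
#' @export
makeNucleusShape <- function(category, semiAxes = c(3.6, 3.6, 2.6),
                             concavityDepthFraction = if (category == 1L) 0.45
                             else if (category == 2L) 0.35 else 0,
                             lobeCount = 2L, spacing = 0.35, seed = 1L) {
  category <- as.integer(category)
  if (!category %in% 1:4) stop("category must be 1, 2, 3 or 4")
  withSeed(seed, {
    geom <- nucleusGeometry(category, semiAxes, concavityDepthFraction,
                            as.integer(lobeCount))
    vol <- analyticNucleusVolume(geom)
    ext <- geometryExtent(geom)
    dims <- as.integer(ceiling(2 * ext / spacing)) + 5L
    center <- (dims - 1) / 2 * spacing
    mask <- rasterizeNucleus(geom, dims, center, spacing)
    list(mask = mask, analyticVolume = vol$volume, volumeSE = vol$se,
         spacing = spacing, geometry = geom)
  })
}

# --- full cell phantom -----------------------------------------------------

# Rejection-sample non-overlapping sphere centres (micrometres) inside
# `mask`: one joint placement for all kinds so the whole configuration can
# be restarted when sequential sampling paints itself into a corner. Pairwise
# surface gaps are kept >= minGap (default 2 voxels, so planted structures
# stay separable under 26-connected component labelling).
placeSphereSets <- function(mask, spacing, kinds, minGap = 2 * spacing,
                            triesPerSphere = 500L, maxRestarts = 50L) {
  d <- dim(mask)
  dt <- sqrt(distanceTransform(mask)) * spacing
  want <- do.call(rbind, lapply(names(kinds), function(nm) {
    r <- kinds[[nm]]
    if (!length(r)) return(NULL)
    data.frame(kind = nm, radius = r)
  }))
  if (is.null(want) || !nrow(want))
    return(data.frame(kind = character(), x = numeric(), y = numeric(),
                      z = numeric(), radius = numeric()))
  want <- want[order(-want$radius), , drop = FALSE]
  eligible <- lapply(seq_len(nrow(want)), function(i)
    which(dt >= want$radius[i] + 1.2 * spacing))
  if (any(!lengths(eligible)))
    stop("cannot place ", want$kind[which.min(lengths(eligible))],
         ": no interior room; use fewer or smaller structures")
  for (restart in seq_len(maxRestarts)) {
    centers <- matrix(numeric(0), ncol = 3)
    radii <- numeric(0)
    failed <- FALSE
    for (i in seq_len(nrow(want))) {
      r <- want$radius[i]
      ok <- eligible[[i]]
      success <- FALSE
      for (t in seq_len(triesPerSphere)) {
        idx <- ok[sample.int(length(ok), 1L)]
        ii <- (idx - 1L) %% d[1]
        jj <- ((idx - 1L) %/% d[1]) %% d[2]
        kk <- (idx - 1L) %/% (d[1] * d[2])
        cand <- c(ii, jj, kk) * spacing
        if (nrow(centers)) {
          gaps <- sqrt(rowSums((centers - matrix(cand, nrow(centers), 3,
                                                 byrow = TRUE))^2)) -
            (radii + r)
          if (any(gaps < minGap)) next
        }
        centers <- rbind(centers, cand)
        radii <- c(radii, r)
        success <- TRUE
        break
      }
      if (!success) { failed <- TRUE; break }
    }
    if (!failed)
      return(data.frame(kind = want$kind, x = centers[, 1], y = centers[, 2],
                        z = centers[, 3], radius = radii))
  }
  stop("placement failed after ", maxRestarts, " restarts; ",
       "use fewer or smaller nucleoli/clumps")
}

#' Generate a complete synthetic cell volume with ground truth
#'
#' Builds the optical-density volume of one H&E-like cell from a
#' \linkS4class{PhantomSpec}: cytoplasm ellipsoid, nucleus of the requested
#' shape category, planted nucleoli (brightest), low- and high-density
#' chromatin clumps (placed without overlap, fully inside the nucleus, by
#' rejection sampling), optional micronuclei in the cytoplasm, and additive
#' Gaussian noise truncated at zero. Deterministic given \code{spec@seed}.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list with \code{grid} (\linkS4class{VoxelGrid}), \code{truth}
#'   (a \linkS4class{SegmentationSet} of the planted masks) and
#'   \code{groundTruth} (a \linkS4class{PhantomGroundTruth}).
#' @examples
#' ph <- makeCellPhantom(phantomSpec(seed = 7L, noiseSd = 0))
#' ph$groundTruth
#' @export
makeCellPhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  s <- spec@spacing
  withSeed(spec@seed, {
    geom <- nucleusGeometry(spec@shapeCategory, spec@nucleusSemiAxes,
                            spec@concavityDepthFraction, spec@lobeCount)
    nVol <- analyticNucleusVolume(geom)
    pad <- 3  # um beyond the cytoplasm bounding box
    ext <- spec@cytoplasmSemiAxes + pad
    dims <- as.integer(ceiling(2 * ext / s))
    center <- (dims - 1) / 2 * s
    cellM <- ellipsoidInside(dims, center, spec@cytoplasmSemiAxes, s)
    nucM <- rasterizeNucleus(geom, dims, center, s) & cellM

    kinds <- list(
      nucleolus = rep(spec@nucleolusRadius, spec@nNucleoli),
      high_clump = if (spec@nHighClumps > 0L)
        stats::runif(spec@nHighClumps, spec@clumpRadiusRange[1],
                     spec@clumpRadiusRange[2]) else numeric(0),
      low_clump = if (spec@nLowClumps > 0L)
        stats::runif(spec@nLowClumps, spec@clumpRadiusRange[1],
                     spec@clumpRadiusRange[2]) else numeric(0)
    )
    centers <- placeSphereSets(nucM, s, kinds)

    micronM <- array(FALSE, dims)
    if (spec@nMicronuclei > 0L) {
      room <- cellM & !nucM
      mn <- placeSphereSets(room, s, list(
        micronucleus = rep(spec@micronucleusRadius, spec@nMicronuclei)))
      centers <- rbind(centers, mn)
      for (i in seq_len(nrow(mn)))
        micronM <- micronM | sphereInside(dims, unlist(mn[i, c("x", "y", "z")]),
                                          mn$radius[i], s)
    }

    paint <- function(kind) {
      lab <- array(0L, dims)
      rows <- centers[centers$kind == kind, , drop = FALSE]
      for (i in seq_len(nrow(rows))) {
        m <- sphereInside(dims, unlist(rows[i, c("x", "y", "z")]),
                          rows$radius[i], s) & nucM
        lab[m] <- i
      }
      lab
    }
    nucleolusLab <- paint("nucleolus")
    highLab <- paint("high_clump")
    lowLab <- paint("low_clump")

    values <- array(0, dims)
    values[cellM] <- spec@odCytoplasm
    values[nucM] <- spec@odNucleus
    values[lowLab > 0L] <- spec@odLow
    values[highLab > 0L] <- spec@odHigh
    values[nucleolusLab > 0L] <- spec@odNucleolus
    values[micronM] <- spec@odNucleus
    if (spec@noiseSd > 0)
      values <- array(pmax(0, values + stats::rnorm(prod(dims), 0,
                                                    spec@noiseSd)), dims)

    stateLab <- array(0L, dims)
    stateLab[nucM] <- 2L
    stateLab[lowLab > 0L] <- 1L
    stateLab[highLab > 0L] <- 3L
    stateLab[nucleolusLab > 0L] <- 3L

    cellId <- paste0("phantom_cat", spec@shapeCategory, "_seed", spec@seed)
    truth <- new("SegmentationSet", cellMask = cellM | micronM,
                 nucleusMask = nucM, nucleolusLabels = nucleolusLab,
                 stateLabels = stateLab,
                 clumpLabels = list(low = lowLab,
                                    medium = labelComponents(stateLab == 2L),
                                    high = highLab))
    gt <- new("PhantomGroundTruth", cellId = cellId,
              category = spec@shapeCategory, nucleusVolume = nVol$volume,
              cellVolume = 4 / 3 * pi * prod(spec@cytoplasmSemiAxes),
              volumeSE = nVol$se, nNucleoli = spec@nNucleoli,
              nLowClumps = spec@nLowClumps, nHighClumps = spec@nHighClumps,
              nMicronuclei = spec@nMicronuclei, centers = centers,
              seed = spec@seed)
    list(grid = VoxelGrid(values, spacing = s, cellId = cellId),
         truth = truth, groundTruth = gt)
  })
}

# --- populations -----------------------------------------------------------

presetParameters <- function(name) {
  switch(name,
    "normal-like" = list(
      radius = c(3.1, 3.5), cytFactor = c(1.75, 1.95),
      nNucleoli = c(1L, 2L), nLow = c(2L, 4L), nHigh = c(2L, 4L),
      categoryProbs = c(0.25, 0.35, 0.30, 0.10), micronucleiProb = 0),
    "fibrocystic-like" = list(
      radius = c(3.5, 3.9), cytFactor = c(1.6, 1.8),
      nNucleoli = c(2L, 4L), nLow = c(4L, 6L), nHigh = c(4L, 6L),
      categoryProbs = c(0.10, 0.35, 0.45, 0.10), micronucleiProb = 0),
    "metastatic-like" = list(
      radius = c(3.9, 4.4), cytFactor = c(1.7, 1.9),
      nNucleoli = c(3L, 5L), nLow = c(5L, 8L), nHigh = c(5L, 8L),
      categoryProbs = c(0.12, 0.40, 0.13, 0.35), micronucleiProb = 0.15),
    stop("unknown preset: ", name, " (available: normal-like, ",
         "fibrocystic-like, metastatic-like)")
  )
}

#' Built-in phantom population presets
#'
#' Three presets emulate the qualitative ordering reported for normal,
#' fibrocystic and metastatic mammary epithelial populations: cell and
#' nuclear volumes increase from normal-like to metastatic-like, planted
#' nucleolus and chromatin-clump counts are higher in the abnormal presets,
#' all four shape categories occur in every preset, and the metastatic-like
#' preset has the largest irregular (category 4) fraction plus occasional
#' micronuclei. The numerical ranges are invented for the generator (the
#' source study reports no category-wise shape parameters) and are frozen
#' here.
#'
#' @return character vector of preset names.
#' @export
phantomPresets <- function() c("normal-like", "fibrocystic-like",
                               "metastatic-like")

# Lobed (category 4) nuclei have less interior room: trim planted counts.
shrink4 <- function(n, category) if (category == 4L) as.integer(ceiling(0.7 * n)) else n

# Draw one PhantomSpec from a preset's parameter ranges (uses the RNG).
drawSpecFromPreset <- function(preset, seed) {
  p <- presetParameters(preset)
  r <- stats::runif(1, p$radius[1], p$radius[2])
  category <- sample.int(4L, 1L, prob = p$categoryProbs)
  if (category == 1L) {
    w <- stats::runif(1, 0.38, 0.5)
    axes <- rep(r / w^(1 / 3), 3)
    axes[3] <- axes[3] * w
    depth <- stats::runif(1, 0.4, 0.5)
    lobes <- 1L
  } else if (category == 2L) {
    w <- stats::runif(1, 0.62, 0.8)
    axes <- rep(r / w^(1 / 3), 3)
    axes[3] <- axes[3] * w
    depth <- stats::runif(1, 0.3, 0.4)
    lobes <- 1L
  } else {
    u <- stats::runif(1, 0.8, 0.95)
    v <- stats::runif(1, 0.62, 0.8)
    sc <- r / (u * v)^(1 / 3)
    axes <- c(sc, sc * u, sc * v)
    depth <- 0
    lobes <- if (category == 4L) sample(2:4, 1L) else 1L
  }
  nMicro <- if (category == 4L && stats::runif(1) < p$micronucleiProb)
    sample(1:2, 1L) else 0L
  phantomSpec(
    shapeCategory = category, nucleusSemiAxes = axes,
    concavityDepthFraction = depth, lobeCount = lobes,
    cytoplasmSemiAxes = max(axes) * stats::runif(1, p$cytFactor[1],
                                                 p$cytFactor[2]) *
      c(1, 1, stats::runif(1, 0.85, 1)),
    nucleolusRadius = stats::runif(1, 0.5, 0.65),
    clumpRadiusRange = if (category == 1L) c(0.4, 0.5) else c(0.4, 0.6),
    nNucleoli = if (category == 4L) min(3L, sample(p$nNucleoli[1]:p$nNucleoli[2], 1L))
      else sample(p$nNucleoli[1]:p$nNucleoli[2], 1L),
    nLowClumps = shrink4(sample(p$nLow[1]:p$nLow[2], 1L), category),
    nHighClumps = shrink4(sample(p$nHigh[1]:p$nHigh[2], 1L), category),
    nMicronuclei = nMicro,
    seed = seed
  )
}

#' Generate a reproducible phantom population
#'
#' Draws \code{n} per-cell \linkS4class{PhantomSpec}s from a preset's
#' parameter ranges and realizes each phantom's ground truth. Volumes are
#' deterministic functions of each spec's seed, so they can be re-realized
#' one at a time with \code{\link{makeCellPhantom}} without storing them.
#'
#' @param name population label (also used in cell ids).
#' @param n number of cells (>= 1).
#' @param preset one of \code{\link{phantomPresets}()}.
#' @param seed population seed; per-cell seeds are derived from it.
#' @param spacing voxel spacing in micrometres.
#' @param realize if TRUE (default) realize each phantom to fill the ground
#'   truth table (volumes, planted counts, category); the grids themselves
#'   are not kept.
#' @return list with \code{specs} (list of \linkS4class{PhantomSpec}) and
#'   \code{truth} (data.frame, one row per cell).
#' @export
makePopulation <- function(name, n, preset = name, seed = 1L,
                           spacing = 0.35, realize = TRUE) {
  if (n < 1L) stop("n must be >= 1")
  p <- presetParameters(preset)  # validates the preset name
  specs <- withSeed(seed, {
    cellSeeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      sp <- drawSpecFromPreset(preset, seed = cellSeeds[i])
      sp@spacing <- spacing
      validObject(sp)
      sp
    })
  })
  truth <- NULL
  if (realize) {
    rows <- lapply(seq_len(n), function(i) {
      ph <- makeCellPhantom(specs[[i]])
      gt <- ph$groundTruth
      data.frame(cell_id = paste0(name, "_", sprintf("%03d", i)),
                 population = name, category = gt@category,
                 nucleus_volume = gt@nucleusVolume,
                 cell_volume = gt@cellVolume,
                 n_nucleoli = gt@nNucleoli, n_low_clumps = gt@nLowClumps,
                 n_high_clumps = gt@nHighClumps,
                 n_micronuclei = gt@nMicronuclei, seed = gt@seed)
    })
    truth <- do.call(rbind, rows)
  }
  list(specs = specs, truth = truth)
}
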