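# Shared fixtures, built in code at test time.

diceCoef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# digital ball of radius r voxels in a padded cube
digitalBall <- function(r, pad = 3L) {
  d <- 2L * r + 2L * pad + 1L
  cx <- (d - 1) / 2
  ax <- ((seq_len(d) - 1) - cx)^2
  array(outer(outer(ax, ax, "+"), ax, "+") <= r^2, c(d, d, d))
}

digitalEllipsoid <- function(semi, pad = 3L) {
  d <- 2L * ceiling(semi) + 2L * pad + 1L
  cx <- (d - 1) / 2
  axs <- lapply(1:3, function(k) (((seq_len(d[k]) - 1) - cx[k]) / semi[k])^2)
  array(outer(outer(axs[[1]], axs[[2]], "+"), axs[[3]], "+") <= 1, d)
}

# the canonical tiny histogram fixture: one line of ODs 1..5 inside a grid
odLineFixture <- function() {
  v <- array(0, c(5, 3, 3))
  v[, 2, 2] <- 1:5
  m <- array(FALSE, dim(v))
  m[, 2, 2] <- TRUE
  list(grid = VoxelGrid(v, spacing = 1), mask = m)
}

# brute-force co-occurrence oracle: double loop over all voxel pairs
bruteGLCM <- function(values, mask, levels, offsets) {
  rng <- range(values[mask])
  bins <- array(NA_integer_, dim(values))
  bins[mask] <- pmin(levels - 1L,
                     as.integer(floor((values[mask] - rng[1]) / diff(rng) *
                                        levels)))
  d <- dim(values)
  counts <- matrix(0, levels, levels)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (!mask[x, y, z]) next
    for (o in seq_len(nrow(offsets))) {
      xx <- x + offsets[o, 1]; yy <- y + offsets[o, 2]; zz <- z + offsets[o, 3]
      if (xx < 1 || yy < 1 || zz < 1 || xx > d[1] || yy > d[2] || zz > d[3])
        next
      if (!mask[xx, yy, zz]) next
      a <- bins[x, y, z] + 1L; b <- bins[xx, yy, zz] + 1L
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  counts / sum(counts)
}

# lazily-built shared phantom (noise-free and noisy variants)
.fixtureCache <- new.env(parent = emptyenv())
sharedPhantom <- function(noise = TRUE) {
  key <- if (noise) "noisy" else "clean"
  if (is.null(.fixtureCache[[key]])) {
    spec <- phantomSpec(seed = 7L, noiseSd = if (noise) 0.02 else 0)
    .fixtureCache[[key]] <- makeCellPhantom(spec)
  }
  .fixtureCache[[key]]
}

sharedFeatures <- function() {
  if (is.null(.fixtureCache$features))
    .fixtureCache$features <- extractFeatures(sharedPhantom()$grid)
  .fixtureCache$features
}

# varied-geometry noise-free phantom for parameter-recovery checks:
# categories 1-3 (exact analytic volume), two well-separated bright
# nucleoli, a handful of chromatin clumps
drawRecoverySpec <- function(seed) {
  set.seed(seed)
  cat <- sample(1:3, 1)
  req <- runif(1, 3.3, 3.7)
  if (cat < 3) {
    w <- if (cat == 1) runif(1, 0.4, 0.5) else runif(1, 0.65, 0.8)
    axes <- rep(req / w^(1 / 3), 3)
    axes[3] <- axes[3] * w
    f <- if (cat == 1) runif(1, 0.4, 0.5) else runif(1, 0.3, 0.4)
  } else {
    u <- runif(1, 0.8, 0.95)
    v <- runif(1, 0.65, 0.8)
    sc <- req / (u * v)^(1 / 3)
    axes <- c(sc, sc * u, sc * v)
    f <- 0
  }
  phantomSpec(shapeCategory = cat, nucleusSemiAxes = axes,
              concavityDepthFraction = f, noiseSd = 0,
              cytoplasmSemiAxes = max(axes) * c(1.85, 1.85, 1.7),
              nNucleoli = 2L, nucleolusRadius = runif(1, 0.72, 0.78),
              nLowClumps = sample(2:4, 1), nHighClumps = sample(2:4, 1),
              clumpRadiusRange = c(0.4, 0.6), seed = seed)
}
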