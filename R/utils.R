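# Internal helpers shared across modules.

# Evaluate expr with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards so phantom generation has no RNG side
# effects.
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

asLogicalArray <- function(x) {
  stopifnot(length(dim(x)) == 3L)
  storage.mode(x) <- "logical"
  x
}

# 3D connected components; returns an integer label array (0 = background).
labelComponents <- function(mask, connectivity = 26L) {
  mask <- asLogicalArray(mask)
  lab <- .cpp_label3d(as.vector(mask), dim(mask), as.integer(connectivity))
  n <- attr(lab, "n_components")
  lab <- array(as.integer(lab), dim(mask))
  attr(lab, "n_components") <- n
  lab
}

componentSizes <- function(labels) {
  n <- attr(labels, "n_components")
  if (is.null(n)) n <- max(labels)
  if (n == 0L) return(integer(0))
  tabulate(labels[labels > 0L], nbins = n)
}

# Relabel components by decreasing voxel count (ties keep scan order).
sortLabelsBySize <- function(labels) {
  sizes <- componentSizes(labels)
  if (length(sizes) == 0L) return(labels)
  ord <- order(sizes, decreasing = TRUE)
  remap <- integer(length(sizes))
  remap[ord] <- seq_along(sizes)
  out <- labels
  sel <- labels > 0L
  out[sel] <- remap[labels[sel]]
  attr(out, "n_components") <- length(sizes)
  out
}

# Fill interior cavities: background components not connected to the array
# border (6-connectivity on the complement) are added to the mask.
fillHoles <- function(mask) {
  mask <- asLogicalArray(mask)
  bg <- labelComponents(!mask, connectivity = 6L)
  d <- dim(mask)
  border <- unique(c(
    bg[c(1, d[1]), , ], bg[, c(1, d[2]), ], bg[, , c(1, d[3])]
  ))
  border <- border[border > 0L]
  mask | (bg > 0L & !(bg %in% border))
}

# Keep the largest connected component; warn when the runner-up is a close
# tie (ambiguous field of view).
largestComponent <- function(mask, connectivity = 26L, warn_tie = TRUE) {
  lab <- labelComponents(mask, connectivity)
  sizes <- componentSizes(lab)
  if (length(sizes) == 0L) stop("mask has no foreground component")
  best <- which.max(sizes)
  if (warn_tie && length(sizes) > 1L) {
    runner <- max(sizes[-best])
    if (runner >= 0.5 * sizes[best])
      warning("multiple comparable foreground components; keeping the first-largest")
  }
  lab == best
}

# Squared Euclidean distance transform (voxel units); the array border counts
# as background.
distanceTransform <- function(mask) {
  mask <- asLogicalArray(mask)
  d <- dim(mask)
  padded <- array(FALSE, d + 2L)
  padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  dt <- array(.cpp_edt3d(as.vector(padded), dim(padded)), dim(padded))
  dt[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
}

# Separable Gaussian smoothing with reflective boundary handling.
gaussianSmooth <- function(values, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  kern <- exp(-0.5 * ((-half:half) / sigma)^2)
  kern <- kern / sum(kern)
  smooth_axis <- function(a, axis) {
    d <- dim(a)
    n <- d[axis]
    idx <- outer(seq_len(n), -half:half, "+")
    # reflect indices at the borders
    idx <- abs(idx - 1L)
    idx <- ifelse(idx >= n, 2L * (n - 1L) - idx, idx) + 1L
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = n)
    out <- matrix(0, nrow = n, ncol = ncol(m))
    for (k in seq_along(kern)) out <- out + kern[k] * m[idx[, k], , drop = FALSE]
    aperm(array(out, dim(ap)), order(perm))
  }
  for (ax in 1:3) values <- smooth_axis(values, ax)
  values
}

# Otsu threshold (256-bin histogram between min and max); returns the OD value
# separating the two classes. Scale-equivariant by construction.
otsuThreshold <- function(values, nbins = 256L) {
  rng <- range(values)
  if (diff(rng) <= 0) stop("degenerate histogram: constant values")
  h <- tabulate(pmin(nbins, 1L + floor((values - rng[1]) / diff(rng) * nbins)),
                nbins = nbins)
  p <- h / sum(h)
  centers <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[nbins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)
  rng[1] + k / nbins * diff(rng)
}

# Voxel-centre coordinates (micrometres) of TRUE voxels / all voxels of idx.
voxelCoordinates <- function(mask, spacing) {
  idx <- which(mask)
  d <- dim(mask)
  i <- (idx - 1L) %% d[1]
  j <- ((idx - 1L) %/% d[1]) %% d[2]
  k <- (idx - 1L) %/% (d[1] * d[2])
  cbind(x = i, y = j, z = k) * spacing
}

popVar <- function(x) mean((x - mean(x))^2)
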