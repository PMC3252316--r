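#' De-noise a volume
#'
#' Median (default) or Gaussian smoothing with the kernel radius in voxels.
#' The median filter is idempotent on piecewise-constant regions larger than
#' its kernel; the Gaussian uses reflective boundaries and so preserves total
#' intensity to numerical accuracy.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param method "median" or "gaussian".
#' @param radius kernel radius in voxels (Gaussian sigma = radius voxels,
#'   kernel truncated at 3 sigma).
#' @return A de-noised \linkS4class{VoxelGrid} of identical shape and spacing.
#' @export
denoiseVolume <- function(grid, method = c("median", "gaussian"), radius = 1L) {
  stopifnot(is(grid, "VoxelGrid"))
  method <- match.arg(method)
  radius <- as.integer(radius)
  if (radius < 1L) stop("radius must be >= 1 voxel")
  v <- voxelData(grid)
  if (any(radius > dim(v) / 2))
    stop("radius exceeds half the volume extent")
  out <- if (method == "median") {
    array(.cpp_median3d(as.vector(v), dim(v), radius), dim(v))
  } else {
    gaussianSmooth(v, sigma = radius)
  }
  VoxelGrid(pmax(out, 0), spacing = spacing(grid), cellId = cellId(grid))
}

#' Segment the cell from the background
#'
#' Otsu threshold over the full volume, followed by extraction of the
#' largest 26-connected foreground component and morphological hole filling.
#' If a second component of comparable size exists, a multiplicity warning
#' is issued and the first-largest is returned.
#'
#' @param grid a \linkS4class{VoxelGrid} containing one dominant cell.
#' @return logical 3D array (the cell mask, one connected component).
#' @export
segmentCell <- function(grid) {
  stopifnot(is(grid, "VoxelGrid"))
  v <- voxelData(grid)
  t <- tryCatch(otsuThreshold(as.vector(v)),
                error = function(e) stop("no cell detected: ",
                                         conditionMessage(e)))
  fg <- v > t
  if (!any(fg)) stop("no cell detected: empty foreground at Otsu threshold")
  fillHoles(largestComponent(fg, 26L))
}

#' Segment the nucleus within the cell
#'
#' Otsu threshold restricted to cell voxels (the nucleus is the upper,
#' hematoxylin-dense class), largest component, hole fill. Secondary nuclear
#' components smaller than 30 percent of the main one are not merged: they
#' are reported as micronucleus candidates in the \code{"micronuclei"}
#' attribute of the returned mask (a data.frame with component volumes in
#' cubic micrometres).
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param cell_mask logical array from \code{\link{segmentCell}}.
#' @return logical 3D array (main nucleus mask, subset of the cell mask),
#'   with attribute \code{micronuclei}.
#' @export
segmentNucleus <- function(grid, cell_mask) {
  stopifnot(is(grid, "VoxelGrid"))
  if (!any(cell_mask)) stop("cell mask is empty")
  v <- voxelData(grid)
  t <- tryCatch(otsuThreshold(v[cell_mask]),
                error = function(e) stop("degenerate cell interior: ",
                                         conditionMessage(e)))
  nuc <- cell_mask & v > t
  if (!any(nuc)) stop("no nucleus detected inside the cell")
  lab <- labelComponents(nuc, 26L)
  sizes <- componentSizes(lab)
  main <- which.max(sizes)
  micro <- which(sizes < 0.3 * sizes[main] & seq_along(sizes) != main)
  keepMain <- fillHoles(lab == main) & cell_mask
  s3 <- spacing(grid)^3
  micronuclei <- data.frame(component = micro,
                            volume = sizes[micro] * s3)
  # components >= 30% of the main one are ambiguous: merge-worthy lobes are
  # connected by definition, so treat them as segmentation multiplicity
  big <- setdiff(which(sizes >= 0.3 * sizes[main]), main)
  if (length(big))
    warning("additional large nuclear components found; keeping the largest")
  structure(keepMain, micronuclei = micronuclei)
}

#' Detect nucleoli
#'
#' Nucleoli are the brightest nuclear bodies: voxels exceeding
#' \code{mu + k_sd * sigma} of the nuclear optical density (population
#' statistics over the nucleus), grouped by 26-connectivity, discarding
#' components smaller than \code{min_volume}. Labels are sorted by
#' decreasing volume. Two nucleoli closer than one voxel merge into one
#' label (a resolution limit of connected-component labelling).
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param nucleus_mask logical array.
#' @param k_sd threshold multiplier (default 2).
#' @param min_volume minimum component volume in cubic micrometres
#'   (default 0.2).
#' @return integer label array; 0 = background. May contain zero labels.
#' @export
detectNucleoli <- function(grid, nucleus_mask, k_sd = 2, min_volume = 0.2) {
  stopifnot(is(grid, "VoxelGrid"))
  if (!any(nucleus_mask)) stop("nucleus mask is empty")
  v <- voxelData(grid)
  dnuc <- v[nucleus_mask]
  mu <- mean(dnuc)
  sigma <- sqrt(popVar(dnuc))
  bright <- nucleus_mask & v > mu + k_sd * sigma
  if (!any(bright)) return(array(0L, dim(v)))
  lab <- labelComponents(bright, 26L)
  sizes <- componentSizes(lab)
  minVox <- min_volume / spacing(grid)^3
  small <- which(sizes < minVox)
  if (length(small)) {
    lab[lab %in% small] <- 0L
    keep <- setdiff(seq_along(sizes), small)
    remap <- integer(length(sizes))
    remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
    attr(lab, "n_components") <- length(keep)
  }
  sortLabelsBySize(lab)
}

#' Partition the nucleus into condensation states
#'
#' Computes the mean \code{mu} and population standard deviation
#' \code{sigma} of the optical density over nucleus voxels and assigns each
#' voxel to the low (\code{d < mu - sigma}), high (\code{d > mu + sigma}) or
#' medium (otherwise) chromatin condensation state. The three states
#' partition the nucleus exactly.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param nucleus_mask logical array with at least 2 distinct OD values.
#' @return A \linkS4class{CondensationPartition}.
#' @examples
#' v <- array(0, c(5, 3, 3)); v[, 2, 2] <- 1:5
#' g <- VoxelGrid(v); m <- array(FALSE, dim(v)); m[, 2, 2] <- TRUE
#' p <- partitionCondensation(g, m)   # low = {1}, high = {5}
#' @export
partitionCondensation <- function(grid, nucleus_mask) {
  stopifnot(is(grid, "VoxelGrid"))
  if (!any(nucleus_mask)) stop("nucleus mask is empty")
  v <- voxelData(grid)
  dnuc <- v[nucleus_mask]
  mu <- mean(dnuc)
  sigma <- sqrt(popVar(dnuc))
  if (sigma == 0) stop("degenerate nucleus histogram: sigma is zero")
  states <- array(0L, dim(v))
  states[nucleus_mask] <- 2L
  states[nucleus_mask & v < mu - sigma] <- 1L
  states[nucleus_mask & v > mu + sigma] <- 3L
  new("CondensationPartition", mu = mu, sigma = sigma, tLow = mu - sigma,
      tHigh = mu + sigma, stateLabels = states)
}

#' Label chromatin clumps of one condensation state
#'
#' A chromatin clump is a connected region of nucleus voxels within one
#' density state. Components are labelled at the configured connectivity
#' (default 26) and summarized with volume, integrated optical density and
#' density-weighted centroid.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param partition a \linkS4class{CondensationPartition}, or any integer
#'   state-label array.
#' @param state 1 (low), 2 (medium), 3 (high), or the vector \code{c(2, 3)}
#'   for the combined medium-high state.
#' @param connectivity 6, 18 or 26.
#' @return list with \code{labels} (integer array) and \code{clumps}
#'   (data.frame: label, n_voxels, volume in um^3, iod, cx, cy, cz in um).
#' @export
labelClumps <- function(grid, partition, state, connectivity = 26L) {
  stopifnot(is(grid, "VoxelGrid"))
  states <- if (is(partition, "CondensationPartition"))
    partition@stateLabels else partition
  sel <- array(states %in% state, dim(states))
  lab <- labelComponents(sel, connectivity)
  n <- attr(lab, "n_components")
  v <- voxelData(grid)
  s <- spacing(grid)
  if (n == 0L) {
    return(list(labels = lab,
                clumps = data.frame(label = integer(), n_voxels = integer(),
                                    volume = numeric(), iod = numeric(),
                                    cx = numeric(), cy = numeric(),
                                    cz = numeric())))
  }
  idx <- which(lab > 0L)
  li <- lab[idx]
  d <- dim(lab)
  ci <- ((idx - 1L) %% d[1]) * s
  cj <- (((idx - 1L) %/% d[1]) %% d[2]) * s
  ck <- ((idx - 1L) %/% (d[1] * d[2])) * s
  w <- v[idx]
  sw <- tapply(w, li, sum)
  nv <- tabulate(li, nbins = n)
  clumps <- data.frame(
    label = seq_len(n), n_voxels = nv, volume = nv * s^3,
    iod = as.numeric(sw),
    cx = as.numeric(tapply(w * ci, li, sum) / sw),
    cy = as.numeric(tapply(w * cj, li, sum) / sw),
    cz = as.numeric(tapply(w * ck, li, sum) / sw))
  list(labels = lab, clumps = clumps)
}
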