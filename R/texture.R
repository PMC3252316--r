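#' Descriptive texture statistics of the nuclear density histogram
#'
#' Integrated optical density (IOD, the total nuclear content), mean OD,
#' population variance, skewness (third standardized moment) and kurtosis
#' (fourth standardized moment, excess convention: 0 for a Gaussian). With
#' zero density spread, skew and kurtosis are NA.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param nucleus_mask logical array, nonempty.
#' @return named list: iod, mean, variance, skew, kurtosis.
#' @examples
#' v <- array(0, c(5, 3, 3)); v[, 2, 2] <- 1:5
#' m <- array(FALSE, dim(v)); m[, 2, 2] <- TRUE
#' descriptiveStats(VoxelGrid(v), m)   # iod 15, mean 3, var 2, kurtosis -1.3
#' @export
descriptiveStats <- function(grid, nucleus_mask) {
  stopifnot(is(grid, "VoxelGrid"))
  if (!any(nucleus_mask)) stop("nucleus mask is empty")
  d <- voxelData(grid)[nucleus_mask]
  mu <- mean(d)
  v <- popVar(d)
  if (v == 0) {
    skew <- kurt <- NA_real_
  } else {
    skew <- mean((d - mu)^3) / v^1.5
    kurt <- mean((d - mu)^4) / v^2 - 3
  }
  list(iod = sum(d), mean = mu, variance = v, skew = skew, kurtosis = kurt)
}

#' Compactness of a condensation state
#'
#' Volume-weighted mean over the state's clumps of the per-clump sphericity
#' (isosurface area vs volume); near 1 for ball-like clumps, lower for
#' filamentous chromatin.
#'
#' @param clump_labels integer label array for one state (or state union).
#' @param spacing voxel spacing in micrometres.
#' @return dimensionless value in (0, 1 + eps], or NA for an empty state.
#' @export
compactness <- function(clump_labels, spacing) {
  n <- max(clump_labels)
  if (n == 0L) return(NA_real_)
  vols <- numeric(n)
  psis <- numeric(n)
  for (k in seq_len(n)) {
    m <- clump_labels == k
    # crop to the clump's bounding box for speed
    w <- which(m, arr.ind = TRUE)
    lo <- pmax(apply(w, 2, min) - 1L, 1L)
    hi <- pmin(apply(w, 2, max) + 1L, dim(m))
    sub <- m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    vols[k] <- maskVolume(sub, spacing)
    psis[k] <- sphericity(sub, spacing)
  }
  sum(vols * psis) / sum(vols)
}

#' Extinction ratios: smoothness of transition between condensation states
#'
#' For a state pair (A, B) with A the lower-density state, the ratio of the
#' mean OD of A-voxels face-adjacent to B over the mean OD of B-voxels
#' face-adjacent to A. A value of 1 means a perfectly smooth transition;
#' small values mean an abrupt density step at the interface. Computed for
#' low-medium, low-high and low-(medium+high). NA when a pair has no
#' face-adjacent interface.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param partition a \linkS4class{CondensationPartition}.
#' @return named numeric(3): low_medium, low_high, low_medium_high.
#' @export
extinctionRatios <- function(grid, partition) {
  stopifnot(is(grid, "VoxelGrid"), is(partition, "CondensationPartition"))
  v <- voxelData(grid)
  st <- partition@stateLabels
  pairRatio <- function(stateA, statesB) {
    A <- array(st %in% stateA, dim(st))
    B <- array(st %in% statesB, dim(st))
    if (!any(A) || !any(B)) return(NA_real_)
    nb <- faceNeighbours(B)
    na <- faceNeighbours(A)
    aTouch <- A & nb   # A voxels with a face neighbour in B
    bTouch <- B & na
    if (!any(aTouch) || !any(bTouch)) return(NA_real_)
    mean(v[aTouch]) / mean(v[bTouch])
  }
  c(low_medium = pairRatio(1L, 2L),
    low_high = pairRatio(1L, 3L),
    low_medium_high = pairRatio(1L, c(2L, 3L)))
}

# TRUE where a voxel has at least one face-adjacent TRUE voxel in `mask`.
faceNeighbours <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  shift <- function(m, axis, by) {
    r <- array(FALSE, d)
    if (axis == 1) {
      if (by > 0) r[(1 + by):d[1], , ] <- m[1:(d[1] - by), , ]
      else r[1:(d[1] + by), , ] <- m[(1 - by):d[1], , ]
    } else if (axis == 2) {
      if (by > 0) r[, (1 + by):d[2], ] <- m[, 1:(d[2] - by), ]
      else r[, 1:(d[2] + by), ] <- m[, (1 - by):d[2], ]
    } else {
      if (by > 0) r[, , (1 + by):d[3]] <- m[, , 1:(d[3] - by)]
      else r[, , 1:(d[3] + by)] <- m[, , (1 - by):d[3]]
    }
    r
  }
  for (ax in 1:3) for (by in c(-1L, 1L)) out <- out | shift(mask, ax, by)
  out
}

#' The 24 discrete texture features
#'
#' Per condensation state (low, medium, high) and the medium-high union:
#' clump counts, state volume fractions, state content (IOD) fractions,
#' extinction ratios, compactness, mean voxel distance to the nucleus
#' centre, and mean (unweighted across clumps) clump-centroid distance to
#' the nucleus centre. Volume fractions and content fractions each sum to 1
#' over the three states. Empty states report count 0, fractions 0 and NA
#' distances.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param partition a \linkS4class{CondensationPartition}.
#' @param nucleus_center numeric(3) micrometre coordinates.
#' @param connectivity clump connectivity (default 26).
#' @return named numeric vector of the 24 discrete registry features, in
#'   registry order, with the per-state clump tables as attribute
#'   \code{"clumps"}.
#' @export
discreteFeatures <- function(grid, partition, nucleus_center,
                             connectivity = 26L) {
  stopifnot(is(grid, "VoxelGrid"), is(partition, "CondensationPartition"))
  v <- voxelData(grid)
  s <- spacing(grid)
  st <- partition@stateLabels
  nucIdx <- which(st > 0L)
  nNuc <- length(nucIdx)
  iodNuc <- sum(v[nucIdx])

  stateSets <- list(low = 1L, medium = 2L, high = 3L, medium_high = c(2L, 3L))
  labs <- lapply(stateSets, function(ss)
    labelClumps(grid, partition, state = ss, connectivity = connectivity))

  d <- dim(v)
  distTo <- function(idx) {
    coords <- cbind(((idx - 1L) %% d[1]),
                    ((idx - 1L) %/% d[1]) %% d[2],
                    (idx - 1L) %/% (d[1] * d[2])) * s
    sqrt(rowSums((coords - matrix(nucleus_center, length(idx), 3,
                                  byrow = TRUE))^2))
  }

  counts <- vapply(labs[1:3], function(l) nrow(l$clumps), numeric(1))
  volFrac <- vapply(stateSets[1:3],
                    function(ss) sum(st %in% ss) / nNuc, numeric(1))
  contFrac <- vapply(stateSets[1:3],
                     function(ss) sum(v[array(st %in% ss, d)]) / iodNuc,
                     numeric(1))
  comp <- vapply(labs, function(l) compactness(l$labels, s), numeric(1))
  ext <- extinctionRatios(grid, partition)
  voxDist <- vapply(stateSets, function(ss) {
    idx <- which(st %in% ss)
    if (!length(idx)) return(NA_real_)
    mean(distTo(idx))
  }, numeric(1))
  cenDist <- vapply(labs, function(l) {
    if (!nrow(l$clumps)) return(NA_real_)
    mean(sqrt((l$clumps$cx - nucleus_center[1])^2 +
                (l$clumps$cy - nucleus_center[2])^2 +
                (l$clumps$cz - nucleus_center[3])^2))
  }, numeric(1))

  out <- c(
    stats::setNames(volFrac, paste0(names(stateSets)[1:3],
                                    "_density_volume_fraction")),
    stats::setNames(contFrac, paste0(names(stateSets)[1:3],
                                     "_density_content_fraction")),
    stats::setNames(counts, paste0("number_of_", names(stateSets)[1:3],
                                   "_density_clumps")),
    stats::setNames(comp, paste0(names(stateSets), "_density_compactness")),
    stats::setNames(ext, paste0("average_extinction_ratio_low_",
                                c("medium", "high", "medium_high"))),
    stats::setNames(voxDist,
                    paste0("average_distance_from_nucleus_center_to_",
                           names(stateSets), "_density_regions")),
    stats::setNames(cenDist,
                    paste0("average_centroidal_distance_from_nucleus_center_to_",
                           names(stateSets), "_density_regions"))
  )
  structure(out, clumps = lapply(labs, `[[`, "clumps"))
}

#' Co-occurrence displacement vectors of the 26-voxel neighbourhood
#'
#' The 26 direction vectors of the 3x3x3 neighbourhood (origin excluded),
#' each scaled per component by \code{k = round(scale / spacing)} (at least
#' 1), so the displacement magnitude approximates the requested physical
#' length scale along axis directions.
#'
#' @param scale length scale in micrometres (>= spacing).
#' @param spacing voxel spacing in micrometres.
#' @return integer matrix, 26 rows x 3 columns.
#' @examples
#' nrow(enumerateOffsets(0.74, 0.35))   # 26, with k = 2
#' @export
enumerateOffsets <- function(scale, spacing) {
  if (scale < spacing) stop("scale must be >= spacing")
  k <- max(1L, as.integer(round(scale / spacing)))
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  storage.mode(g) <- "integer"
  unname(g * k)
}

#' 3D gray-level co-occurrence matrix over the nucleus
#'
#' Nuclear ODs are linearly quantized to \code{levels} bins between the
#' nuclear minimum and maximum (the maximum maps to the top bin); voxel
#' pairs are accumulated over all displacement vectors whose endpoints both
#' lie in the nucleus, symmetrized, and normalized to sum 1.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param nucleus_mask logical array.
#' @param levels number of gray levels G (>= 2).
#' @param offsets integer matrix of displacements from
#'   \code{\link{enumerateOffsets}}.
#' @return list with \code{p} (G x G probability matrix), \code{levels} and
#'   \code{offsets}.
#' @export
glcm3d <- function(grid, nucleus_mask, levels = 32L, offsets) {
  stopifnot(is(grid, "VoxelGrid"), levels >= 2L)
  v <- voxelData(grid)
  dnuc <- v[nucleus_mask]
  rng <- range(dnuc)
  if (diff(rng) <= 0) stop("constant nucleus: no quantization range")
  bins <- array(-1L, dim(v))
  bins[nucleus_mask] <- pmin(levels - 1L,
                             as.integer(floor((dnuc - rng[1]) / diff(rng) *
                                                levels)))
  counts <- .cpp_glcm_accumulate(as.vector(bins), dim(v),
                                 offsets, as.integer(levels))
  total <- sum(counts)
  if (total == 0) stop("no co-occurring voxel pairs inside the nucleus")
  list(p = counts / total, levels = as.integer(levels), offsets = offsets)
}

#' Markovian (Haralick) features of a co-occurrence matrix
#'
#' energy \eqn{\sum p^2}; contrast \eqn{\sum (i-j)^2 p}; correlation
#' \eqn{\sum (i-\mu_x)(j-\mu_y) p / (\sigma_x \sigma_y)} (NA when the
#' marginal SD vanishes); homogeneity (inverse difference moment)
#' \eqn{\sum p / (1 + (i-j)^2)}. The homogeneity value is also reported
#' under the variant name "heterogeneity" used in the canonical registry.
#'
#' @param M a co-occurrence matrix object from \code{\link{glcm3d}}, or a
#'   plain probability matrix.
#' @return named numeric(4): energy, contrast, correlation, homogeneity.
#' @export
haralickFeatures <- function(M) {
  p <- if (is.list(M)) M$p else M
  G <- nrow(p)
  i <- matrix(seq_len(G), G, G)
  j <- t(i)
  px <- rowSums(p)
  mux <- sum(seq_len(G) * px)
  sx <- sqrt(sum((seq_len(G) - mux)^2 * px))
  # symmetric matrix: x and y marginals coincide
  energy <- sum(p^2)
  contrast <- sum((i - j)^2 * p)
  homogeneity <- sum(p / (1 + (i - j)^2))
  correlation <- if (sx == 0) NA_real_ else
    sum((i - mux) * (j - mux) * p) / sx^2
  c(energy = energy, contrast = contrast, correlation = correlation,
    homogeneity = homogeneity)
}

#' Markovian texture at multiple length scales
#'
#' Computes the Haralick quadruple of the nuclear co-occurrence matrix at
#' each requested length scale and singles out the canonical scale whose
#' values enter the 42-feature vector.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param nucleus_mask logical array.
#' @param scales numeric vector of length scales in micrometres.
#' @param levels gray levels G.
#' @param canonical the scale reported as canonical (default the second
#'   entry, conventionally 0.74 um).
#' @return list with \code{perScale} (data.frame: scale, energy, contrast,
#'   correlation, homogeneity) and \code{canonical} (named numeric(4)).
#' @export
markovianBlock <- function(grid, nucleus_mask, scales = c(0.44, 0.74, 1.5),
                           levels = 32L, canonical = scales[min(2L, length(scales))]) {
  rows <- lapply(scales, function(sc) {
    off <- enumerateOffsets(sc, spacing(grid))
    h <- haralickFeatures(glcm3d(grid, nucleus_mask, levels, off))
    data.frame(scale = sc, energy = h["energy"], contrast = h["contrast"],
               correlation = h["correlation"], homogeneity = h["homogeneity"],
               row.names = NULL)
  })
  perScale <- do.call(rbind, rows)
  ci <- which.min(abs(perScale$scale - canonical))
  can <- unlist(perScale[ci, c("energy", "contrast", "correlation",
                               "homogeneity")])
  names(can) <- c("energy", "contrast", "correlation", "homogeneity")
  list(perScale = perScale, canonical = can)
}
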