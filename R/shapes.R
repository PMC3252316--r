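#' Quantitative shape measures of a nucleus mask
#'
#' Computes the measures that drive four-category shape classification:
#' \itemize{
#' \item concavity index \code{c = 1 - V / V_convexhull}, with the convex
#'   hull taken over surface-voxel centres;
#' \item elongation \code{e}, the ratio of shortest to longest principal
#'   axis length from the mask's second-moment (inertia-equivalent)
#'   ellipsoid;
#' \item lobe count: local maxima of the interior Euclidean distance
#'   transform surviving h-maxima suppression at 20 percent of the global
#'   maximum;
#' \item largest-concavity depth in micrometres (maximum distance from a
#'   hull-interior background voxel to the mask).
#' }
#'
#' @param nucleus_mask logical 3D array, one connected component, at least
#'   10 voxels.
#' @param spacing voxel spacing in micrometres.
#' @return list: concavity, elongation, lobes, concavityDepth.
#' @export
shapeMeasures <- function(nucleus_mask, spacing) {
  nv <- sum(nucleus_mask)
  if (nv < 10) stop("mask too small for shape analysis (< 10 voxels)")
  d <- dim(nucleus_mask)

  # surface voxels: mask voxels with a face neighbour outside
  surf <- nucleus_mask & faceNeighbours(!nucleus_mask)
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE; border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  surf <- surf | (nucleus_mask & border)
  pts <- voxelCoordinates(surf, spacing)
  # concavity from voxel counts on both sides: voxels whose centres fall in
  # the hull of the surface-voxel centres vs voxels in the mask (comparing
  # the voxelized volume against the hull's continuous volume would bias
  # flat shapes by half a voxel of rind)
  w <- which(nucleus_mask, arr.ind = TRUE)
  lo <- pmax(apply(w, 2, min) - 1L, 1L)
  hi <- pmin(apply(w, 2, max) + 1L, d)
  qgrid <- as.matrix(expand.grid(x = (lo[1]:hi[1]) - 1L,
                                 y = (lo[2]:hi[2]) - 1L,
                                 z = (lo[3]:hi[3]) - 1L)) * spacing
  inHull <- .cpp_convhull_contains(pts, qgrid)
  sub <- nucleus_mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  inMask <- as.vector(aperm(sub, c(1, 2, 3)))  # expand.grid varies x fastest
  nHull <- sum(inHull | inMask)
  concavity <- max(0, 1 - nv / nHull)

  xyz <- voxelCoordinates(nucleus_mask, spacing)
  cen <- colMeans(xyz)
  cov <- crossprod(sweep(xyz, 2, cen)) / nrow(xyz)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  elong <- sqrt(ev[3] / ev[1])

  # lobes: h-maxima of the interior distance transform (smoothed by one
  # voxel so voxelization ripples along ridge lines do not split maxima)
  dt <- gaussianSmooth(sqrt(distanceTransform(nucleus_mask)), sigma = 1)
  dt[!nucleus_mask] <- 0
  h <- 0.2 * max(dt)
  rec <- array(.cpp_grayreconstruct(as.vector(pmax(dt - h, 0)), as.vector(dt),
                                    d, 26L), d)
  # lobes = regional maxima of the h-maxima transform (plateaus included:
  # a ridge ring around a concavity counts once, not per voxel ripple)
  eps <- max(1e-6, 1e-3 * h)
  rec2 <- array(.cpp_grayreconstruct(as.vector(pmax(rec - eps, 0)),
                                     as.vector(rec), d, 26L), d)
  rmax <- (rec - rec2) >= eps / 2
  lab <- labelComponents(rmax & nucleus_mask, 26L)
  lobes <- max(1L, attr(lab, "n_components"))

  concavityDepth <- if (concavity > 0)
    concavityPocketDepth(nucleus_mask, spacing) else 0
  list(concavity = concavity, elongation = elong, lobes = lobes,
       concavityDepth = concavityDepth)
}

# Depth (um) of the deepest background pocket: background voxels enclosed by
# the morphological closing of the mask, measured by their distance to the
# mask surface.
concavityPocketDepth <- function(mask, spacing) {
  d <- dim(mask)
  # closing via distance transforms: dilate by r then erode by r, r = 1/4 of
  # the max interior radius
  dt <- sqrt(distanceTransform(mask))
  r <- max(1, 0.25 * max(dt))
  dil <- sqrt(distanceTransform(!mask)) ; dil <- dil <= r | mask
  ero <- sqrt(distanceTransform(dil)) > r
  closed <- fillHoles(ero | mask)
  pocket <- closed & !mask
  if (!any(pocket)) return(0)
  max(sqrt(distanceTransform(!mask))[pocket]) * spacing
}

#' Classify a nucleus into one of the four shape categories
#'
#' Deterministic, total rule set on \code{\link{shapeMeasures}}:
#' category 4 (irregular/multilobed) when the lobe count is 2 or more or the
#' concavity index is at least \code{shapeIrregularMin}; otherwise category
#' 3 (convex) when the concavity index is below \code{shapeConvexMax};
#' otherwise category 1 (marked concavity, slender) when elongation is at
#' most \code{shapeSlenderMax}; otherwise category 2 (slight concavity,
#' bulky: the common "fat mushroom cap").
#'
#' @param m list from \code{\link{shapeMeasures}}.
#' @param config a \linkS4class{StudyConfig} providing the thresholds.
#' @return integer category in 1:4.
#' @export
classifyShape <- function(m, config = studyConfig()) {
  stopifnot(is(config, "StudyConfig"))
  if (m$lobes >= 2L || m$concavity >= config@shapeIrregularMin) return(4L)
  if (m$concavity < config@shapeConvexMax) return(3L)
  if (m$elongation <= config@shapeSlenderMax) return(1L)
  2L
}

#' Population shape composition
#'
#' @param masks list of nucleus masks (or a list of lists carrying
#'   \code{mask}).
#' @param spacing voxel spacing in micrometres.
#' @param config a \linkS4class{StudyConfig}.
#' @return data.frame with category, count and fraction (fractions sum to 1).
#' @export
populationShapeReport <- function(masks, spacing, config = studyConfig()) {
  if (!length(masks)) stop("need at least one nucleus")
  cats <- vapply(masks, function(m) {
    if (is.list(m)) m <- m$mask
    classifyShape(shapeMeasures(m, spacing), config)
  }, integer(1))
  counts <- tabulate(cats, nbins = 4L)
  data.frame(category = 1:4, count = counts, fraction = counts / length(cats))
}
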