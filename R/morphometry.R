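#' Volume of a binary mask
#'
#' @param mask logical 3D array.
#' @param spacing voxel edge length in micrometres.
#' @return volume in cubic micrometres (voxel count times spacing cubed).
#' @export
maskVolume <- function(mask, spacing) sum(mask) * spacing^3

#' Nucleus-to-cytoplasm volume ratio
#'
#' The denominator is the cytoplasm proper: cell volume minus nuclear
#' volume.
#'
#' @param nucleus_volume,cell_volume volumes in cubic micrometres,
#'   \code{cell_volume > nucleus_volume > 0}.
#' @return dimensionless ratio.
#' @export
ncRatio <- function(nucleus_volume, cell_volume) {
  if (!(cell_volume > nucleus_volume && nucleus_volume > 0))
    stop("need cell_volume > nucleus_volume > 0")
  nucleus_volume / (cell_volume - nucleus_volume)
}

#' Surface area of a binary mask
#'
#' Triangulated isosurface area: the mask is padded, smoothed with one
#' Gaussian pass (sigma one voxel) and triangulated at the 0.5 level by
#' marching tetrahedra; the triangle areas are summed. Smoothing before
#' triangulation removes the voxelization staircase so digital balls come
#' out within a few percent of \eqn{4\pi r^2}.
#'
#' @param mask logical 3D array (nonempty).
#' @param spacing voxel edge length in micrometres.
#' @return surface area in square micrometres.
#' @export
surfaceArea <- function(mask, spacing) {
  isosurfaceMeasure(mask, spacing)$area
}

# Shared triangulated-isosurface measurement: area and enclosed volume of
# the 0.5 level (adapted downward for objects so small that smoothing pulls
# the whole field below 0.5), with an exposed voxel-face fallback.
isosurfaceMeasure <- function(mask, spacing) {
  if (!any(mask)) stop("mask is empty")
  d <- dim(mask)
  pad <- 4L
  field <- array(0, d + 2L * pad)
  field[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    as.numeric(mask)
  field <- gaussianSmooth(field, sigma = 1)
  level <- min(0.5, 0.5 * max(field))
  av <- .cpp_isosurface_measure(as.vector(field), dim(field), level)
  area <- av[1] * spacing^2
  volume <- av[2] * spacing^3
  if (area <= 0) {
    # last resort for degenerate masks: exposed voxel faces
    nfaces <- 6 * sum(mask) - 2 * countSharedFaces(mask)
    area <- nfaces * spacing^2
    volume <- maskVolume(mask, spacing)
  }
  list(area = area, volume = volume)
}

# number of face-adjacent voxel pairs inside a mask
countSharedFaces <- function(mask) {
  d <- dim(mask)
  sum(mask[-d[1], , ] & mask[-1, , ]) +
    sum(mask[, -d[2], ] & mask[, -1, ]) +
    sum(mask[, , -d[3]] & mask[, , -1])
}

#' Sphericity of a binary mask
#'
#' \deqn{\Psi = \pi^{1/3} (6V)^{2/3} / A} with volume and area both measured
#' on the triangulated 0.5-level isosurface of the smoothed mask (see
#' \code{\link{surfaceArea}}); 1 for a perfect ball, smaller for irregular
#' shapes (values may slightly exceed 1 from discretization).
#'
#' @inheritParams surfaceArea
#' @return dimensionless sphericity.
#' @export
sphericity <- function(mask, spacing) {
  # volume and area are taken from the same triangulated isosurface, so the
  # half-voxel shrinkage that smoothing applies to small objects cancels
  # out of the ratio instead of inflating it
  m <- isosurfaceMeasure(mask, spacing)
  sphericityVA(m$volume, m$area)
}

#' @rdname sphericity
#' @param V volume in cubic micrometres.
#' @param A surface area in square micrometres.
#' @export
sphericityVA <- function(V, A) {
  if (!is.finite(A) || A <= 0) stop("degenerate surface area")
  pi^(1 / 3) * (6 * V)^(2 / 3) / A
}

#' Density-weighted centre of gravity of the nucleus
#'
#' \deqn{\sum_i d_i r_i / \sum_i d_i} over nucleus voxels, in micrometre
#' coordinates (voxel centres at \code{(index-1) * spacing}). Invariant
#' under scaling of the optical density.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param nucleus_mask logical array with positive total OD.
#' @return numeric(3) micrometre coordinates.
#' @export
nucleusCenter <- function(grid, nucleus_mask) {
  stopifnot(is(grid, "VoxelGrid"))
  v <- voxelData(grid)
  w <- v[nucleus_mask]
  if (sum(w) <= 0) stop("zero total optical density in the nucleus")
  xyz <- voxelCoordinates(nucleus_mask, spacing(grid))
  as.numeric(colSums(xyz * w) / sum(w))
}

#' Nucleolar morphology summary
#'
#' Per-nucleolus volumes and marginations. The margination of a nucleolus is
#' the Euclidean distance (micrometres) from its density-weighted centroid
#' to the nucleus density-weighted centre of gravity; means and variances
#' use the population convention. With zero nucleoli the count and total
#' volume are 0 and the remaining fields are NA (not applicable).
#'
#' @param nucleolus_labels integer label array from
#'   \code{\link{detectNucleoli}}.
#' @param grid a \linkS4class{VoxelGrid}.
#' @param nucleus_center numeric(3) from \code{\link{nucleusCenter}}.
#' @return list with count, totalVolume, meanVolume, volumeVariance,
#'   meanMargination, marginationVariance, and the per-nucleolus table.
#' @export
nucleolarFeatures <- function(nucleolus_labels, grid, nucleus_center) {
  stopifnot(is(grid, "VoxelGrid"))
  n <- max(nucleolus_labels)
  if (n == 0L)
    return(list(count = 0L, totalVolume = 0, meanVolume = NA_real_,
                volumeVariance = NA_real_, meanMargination = NA_real_,
                marginationVariance = NA_real_,
                nucleoli = data.frame(label = integer(), volume = numeric(),
                                      margination = numeric())))
  v <- voxelData(grid)
  s <- spacing(grid)
  idx <- which(nucleolus_labels > 0L)
  li <- nucleolus_labels[idx]
  d <- dim(v)
  coords <- cbind(((idx - 1L) %% d[1]),
                  ((idx - 1L) %/% d[1]) %% d[2],
                  (idx - 1L) %/% (d[1] * d[2])) * s
  w <- v[idx]
  sw <- tapply(w, li, sum)
  vols <- tabulate(li, nbins = n) * s^3
  cent <- sapply(1:3, function(k) tapply(w * coords[, k], li, sum) / sw)
  cent <- matrix(cent, ncol = 3)
  marg <- sqrt(rowSums((cent - matrix(nucleus_center, n, 3, byrow = TRUE))^2))
  list(count = n, totalVolume = sum(vols), meanVolume = mean(vols),
       volumeVariance = popVar(vols), meanMargination = mean(marg),
       marginationVariance = popVar(marg),
       nucleoli = data.frame(label = seq_len(n), volume = vols,
                             margination = marg))
}
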