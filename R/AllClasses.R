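#' @useDynLib nucleomorph3d, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' VoxelGrid: an isotropic 3D optical-density volume
#'
#' The unit of analysis: one cell per grid. Values are optical densities
#' (arbitrary units, non-negative); \code{spacing} is the common voxel edge
#' length in micrometres along all three axes (isotropic sampling is a
#' premise of the whole pipeline, so anisotropy is rejected at construction).
#' Voxel centres sit at \code{(index - 1) * spacing} along each axis.
#'
#' @slot values numeric 3D array of optical density.
#' @slot spacing numeric(1), voxel edge length in micrometres (> 0).
#' @slot cellId character(1) opaque identifier.
#' @export
setClass("VoxelGrid",
  representation(values = "array", spacing = "numeric", cellId = "character"),
  prototype(spacing = 0.35, cellId = "cell")
)

setValidity("VoxelGrid", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3L)
    msg <- c(msg, "values must be a 3D array")
  else if (any(d < 3L))
    msg <- c(msg, "minimum extent is 3 voxels per axis")
  if (length(object@spacing) != 1L || !is.finite(object@spacing) || object@spacing <= 0)
    msg <- c(msg, "spacing must be a single positive number (micrometres)")
  if (anyNA(object@values) || any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  else if (any(object@values < 0))
    msg <- c(msg, "optical density values must be non-negative")
  if (length(object@cellId) != 1L) msg <- c(msg, "cellId must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a VoxelGrid
#'
#' @param values numeric 3D array of optical density (finite, >= 0).
#' @param spacing voxel edge length in micrometres, identical for all axes.
#' @param cellId identifier carried through feature tables.
#' @return A \linkS4class{VoxelGrid}.
#' @examples
#' g <- VoxelGrid(array(runif(4^3), c(4, 4, 4)), spacing = 0.35)
#' spacing(g)
#' @export
VoxelGrid <- function(values, spacing = 0.35, cellId = "cell") {
  storage.mode(values) <- "double"
  new("VoxelGrid", values = values, spacing = as.numeric(spacing),
      cellId = as.character(cellId))
}

#' SegmentationSet: the masks recovered (or planted) for one cell
#'
#' Holds the cell and nucleus binary masks, nucleolus labels, the ternary
#' condensation-state volume (0 outside the nucleus, 1 low, 2 medium,
#' 3 high) and per-state chromatin clump label volumes.
#'
#' @slot cellMask logical 3D array.
#' @slot nucleusMask logical 3D array, subset of \code{cellMask}.
#' @slot nucleolusLabels integer 3D array (0 = none), support inside nucleus.
#' @slot stateLabels integer 3D array in 0:3, support == nucleus.
#' @slot clumpLabels list of integer label arrays, one per condensation state.
#' @export
setClass("SegmentationSet",
  representation(cellMask = "array", nucleusMask = "array",
                 nucleolusLabels = "array", stateLabels = "array",
                 clumpLabels = "list")
)

setValidity("SegmentationSet", function(object) {
  msg <- character()
  d <- dim(object@cellMask)
  for (s in c("nucleusMask", "nucleolusLabels", "stateLabels"))
    if (!identical(dim(slot(object, s)), d))
      msg <- c(msg, paste0(s, " dimensions differ from cellMask"))
  if (!length(msg)) {
    if (any(object@nucleusMask & !object@cellMask))
      msg <- c(msg, "nucleus mask must be contained in the cell mask")
    if (any(object@nucleolusLabels > 0 & !object@nucleusMask))
      msg <- c(msg, "nucleolus labels must lie inside the nucleus")
    if (!identical(unname(object@stateLabels > 0), unname(object@nucleusMask == TRUE)))
      msg <- c(msg, "state labels must cover exactly the nucleus")
  }
  if (length(msg)) msg else TRUE
})

#' CondensationPartition: low/medium/high chromatin density states
#'
#' Thresholds are set one standard deviation either side of the mean nuclear
#' optical density: voxels below \code{mu - sigma} are low, above
#' \code{mu + sigma} high, the rest medium. \code{sigma} is the population
#' standard deviation over nucleus voxels.
#'
#' @slot mu mean nuclear optical density.
#' @slot sigma population standard deviation of nuclear optical density.
#' @slot tLow low/medium threshold, \code{mu - sigma}.
#' @slot tHigh medium/high threshold, \code{mu + sigma}.
#' @slot stateLabels integer 3D array in 0:3 (0 outside the nucleus).
#' @export
setClass("CondensationPartition",
  representation(mu = "numeric", sigma = "numeric", tLow = "numeric",
                 tHigh = "numeric", stateLabels = "array")
)

setValidity("CondensationPartition", function(object) {
  msg <- character()
  if (object@sigma <= 0) msg <- c(msg, "sigma must be positive")
  if (!(object@tLow < object@mu && object@mu < object@tHigh))
    msg <- c(msg, "thresholds must straddle the mean")
  if (length(msg)) msg else TRUE
})

#' StudyConfig: tunable parameters of the morphometry pipeline
#'
#' All knobs that downstream stages read, with frozen defaults. Length
#' scales are in micrometres and must not be finer than the voxel spacing.
#'
#' @slot spacing default voxel spacing in micrometres.
#' @slot glcmLevels number of gray levels for co-occurrence quantization.
#' @slot glcmScales co-occurrence displacement length scales (micrometres).
#' @slot markovianScale the single scale whose Markovian quadruple enters the
#'   canonical 42-feature vector.
#' @slot clumpConnectivity 6, 18 or 26.
#' @slot nucleoliKSd nucleolus detection threshold in nuclear SD units.
#' @slot nucleoliMinVolume minimum nucleolus volume in cubic micrometres.
#' @slot shapeConvexMax concavity index below which a nucleus is convex.
#' @slot shapeIrregularMin concavity index at or above which it is irregular.
#' @slot shapeSlenderMax elongation at or below which a concave nucleus is
#'   slender.
#' @slot alpha significance level for the feature screen.
#' @slot denoiseMethod "median" or "gaussian".
#' @slot denoiseRadius kernel radius in voxels.
#' @slot seed integer seed for stochastic stages.
#' @export
setClass("StudyConfig",
  representation(spacing = "numeric", glcmLevels = "integer",
                 glcmScales = "numeric", markovianScale = "numeric",
                 clumpConnectivity = "integer", nucleoliKSd = "numeric",
                 nucleoliMinVolume = "numeric", shapeConvexMax = "numeric",
                 shapeIrregularMin = "numeric", shapeSlenderMax = "numeric",
                 alpha = "numeric", denoiseMethod = "character",
                 denoiseRadius = "integer", seed = "integer"),
  prototype(spacing = 0.35, glcmLevels = 32L, glcmScales = c(0.44, 0.74, 1.5),
            markovianScale = 0.74, clumpConnectivity = 26L, nucleoliKSd = 2,
            nucleoliMinVolume = 0.2, shapeConvexMax = 0.008,
            shapeIrregularMin = 0.25, shapeSlenderMax = 0.55, alpha = 0.0025,
            denoiseMethod = "median", denoiseRadius = 1L, seed = 1L)
)

setValidity("StudyConfig", function(object) {
  msg <- character()
  if (object@spacing <= 0) msg <- c(msg, "spacing must be positive")
  if (object@glcmLevels < 2L) msg <- c(msg, "glcmLevels must be >= 2")
  if (any(object@glcmScales < object@spacing))
    msg <- c(msg, "glcmScales must be >= spacing")
  if (!(object@alpha > 0 && object@alpha < 1)) msg <- c(msg, "alpha must be in (0,1)")
  if (!object@clumpConnectivity %in% c(6L, 18L, 26L))
    msg <- c(msg, "clumpConnectivity must be 6, 18 or 26")
  if (!object@denoiseMethod %in% c("median", "gaussian"))
    msg <- c(msg, "denoiseMethod must be 'median' or 'gaussian'")
  if (any(c(object@nucleoliKSd, object@nucleoliMinVolume, object@shapeConvexMax,
            object@shapeIrregularMin, object@shapeSlenderMax) <= 0))
    msg <- c(msg, "all thresholds must be positive")
  if (length(msg)) msg else TRUE
})

#' PhantomSpec: parameters of one synthetic cell
#'
#' Describes an H&E-like single cell: an ellipsoidal cytoplasm of low optical
#' density containing a nucleus of one of four shape categories, with planted
#' nucleoli (brightest), low- and high-density chromatin clumps, optional
#' micronuclei and additive truncated-Gaussian noise. Optical densities must
#' be ordered background < cytoplasm < low clump < nuclear base < high clump
#' < nucleolus so the planted structures occupy the intended condensation
#' states.
#'
#' @slot shapeCategory integer in 1:4.
#' @slot nucleusSemiAxes numeric(3), micrometres (categories 1/2 require the
#'   first two equal; the indentation is carved along the third axis).
#' @slot concavityDepthFraction cap depth as a fraction of the indented
#'   semi-axis, in [0, 1).
#' @slot lobeCount number of ellipsoidal lobes for category 4 (2-4).
#' @slot cytoplasmSemiAxes numeric(3), micrometres.
#' @slot nNucleoli,nLowClumps,nHighClumps planted counts.
#' @slot nucleolusRadius micrometres.
#' @slot clumpRadiusRange numeric(2), micrometres.
#' @slot odCytoplasm,odLow,odNucleus,odHigh,odNucleolus base optical densities.
#' @slot noiseSd additive Gaussian noise SD (truncated at zero).
#' @slot nMicronuclei micronuclei planted in the cytoplasm.
#' @slot micronucleusRadius micrometres.
#' @slot spacing voxel spacing, micrometres.
#' @slot seed integer seed making the phantom fully reproducible.
#' @export
setClass("PhantomSpec",
  representation(shapeCategory = "integer", nucleusSemiAxes = "numeric",
                 concavityDepthFraction = "numeric", lobeCount = "integer",
                 cytoplasmSemiAxes = "numeric", nNucleoli = "integer",
                 nucleolusRadius = "numeric", nLowClumps = "integer",
                 nHighClumps = "integer", clumpRadiusRange = "numeric",
                 odCytoplasm = "numeric", odLow = "numeric",
                 odNucleus = "numeric", odHigh = "numeric",
                 odNucleolus = "numeric", noiseSd = "numeric",
                 nMicronuclei = "integer", micronucleusRadius = "numeric",
                 spacing = "numeric", seed = "integer"),
  prototype(shapeCategory = 3L, nucleusSemiAxes = c(3.6, 3.6, 2.6),
            concavityDepthFraction = 0, lobeCount = 1L,
            cytoplasmSemiAxes = c(6.5, 6.5, 5.2), nNucleoli = 2L,
            nucleolusRadius = 0.75, nLowClumps = 3L, nHighClumps = 3L,
            clumpRadiusRange = c(0.4, 0.65), odCytoplasm = 0.25, odLow = 0.38,
            odNucleus = 0.5, odHigh = 0.6, odNucleolus = 0.95,
            noiseSd = 0.02, nMicronuclei = 0L, micronucleusRadius = 0.9,
            spacing = 0.35, seed = 1L)
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (!object@shapeCategory %in% 1:4) msg <- c(msg, "shapeCategory must be 1..4")
  if (any(object@nucleusSemiAxes >= object@cytoplasmSemiAxes))
    msg <- c(msg, "nucleus semi-axes must be smaller than cytoplasm semi-axes")
  ods <- c(0, object@odCytoplasm, object@odLow, object@odNucleus,
           object@odHigh, object@odNucleolus)
  if (any(diff(ods) <= 0))
    msg <- c(msg, "optical densities must satisfy background < cytoplasm < low < nucleus < high < nucleolus")
  if (object@concavityDepthFraction < 0 || object@concavityDepthFraction >= 1)
    msg <- c(msg, "concavityDepthFraction must be in [0, 1)")
  if (object@shapeCategory %in% c(1L, 2L) &&
      abs(object@nucleusSemiAxes[1] - object@nucleusSemiAxes[2]) > 1e-9)
    msg <- c(msg, "categories 1 and 2 require a spheroid (first two semi-axes equal)")
  if (object@shapeCategory == 4L && !object@lobeCount %in% 2:4)
    msg <- c(msg, "category 4 requires 2-4 lobes")
  if (min(object@nucleolusRadius, object@clumpRadiusRange) <= object@spacing)
    msg <- c(msg, "all planted radii must exceed the voxel spacing")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' PhantomGroundTruth: generator-side record of one synthetic cell
#'
#' @slot cellId identifier matching the generated \linkS4class{VoxelGrid}.
#' @slot category planted shape category (1-4).
#' @slot nucleusVolume analytic nucleus volume in cubic micrometres (exact
#'   for categories 1-3, Monte-Carlo for category 4; see \code{volumeSE}).
#' @slot cellVolume analytic cell (cytoplasm ellipsoid) volume.
#' @slot volumeSE Monte-Carlo standard error of \code{nucleusVolume}
#'   (0 when the volume is exact).
#' @slot nNucleoli,nLowClumps,nHighClumps,nMicronuclei planted counts.
#' @slot centers data.frame of planted structure centres (micrometres) with
#'   columns kind, x, y, z, radius.
#' @slot seed the seed the phantom was built from.
#' @export
setClass("PhantomGroundTruth",
  representation(cellId = "character", category = "integer",
                 nucleusVolume = "numeric", cellVolume = "numeric",
                 volumeSE = "numeric", nNucleoli = "integer",
                 nLowClumps = "integer", nHighClumps = "integer",
                 nMicronuclei = "integer", centers = "data.frame",
                 seed = "integer")
)
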