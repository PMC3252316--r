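#' Accessors for pipeline objects
#'
#' Small generic accessors used instead of direct slot access.
#'
#' @param object a package object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(object) standardGeneric("voxelData"))

#' @rdname accessors
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))

#' @rdname accessors
#' @export
setGeneric("cellId", function(object) standardGeneric("cellId"))

#' @rdname accessors
#' @export
setGeneric("cellMask", function(object) standardGeneric("cellMask"))

#' @rdname accessors
#' @export
setGeneric("nucleusMask", function(object) standardGeneric("nucleusMask"))

#' @rdname accessors
#' @export
setGeneric("nucleolusLabels", function(object) standardGeneric("nucleolusLabels"))

#' @rdname accessors
#' @export
setGeneric("stateLabels", function(object) standardGeneric("stateLabels"))

#' @rdname accessors
#' @export
setGeneric("clumpLabels", function(object) standardGeneric("clumpLabels"))

#' @rdname accessors
#' @export
setMethod("voxelData", "VoxelGrid", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("spacing", "VoxelGrid", function(object) object@spacing)

#' @rdname accessors
#' @export
setMethod("cellId", "VoxelGrid", function(object) object@cellId)

#' @rdname accessors
#' @export
setMethod("cellMask", "SegmentationSet", function(object) object@cellMask)

#' @rdname accessors
#' @export
setMethod("nucleusMask", "SegmentationSet", function(object) object@nucleusMask)

#' @rdname accessors
#' @export
setMethod("nucleolusLabels", "SegmentationSet", function(object) object@nucleolusLabels)

#' @rdname accessors
#' @export
setMethod("stateLabels", "SegmentationSet", function(object) object@stateLabels)

#' @rdname accessors
#' @export
setMethod("clumpLabels", "SegmentationSet", function(object) object@clumpLabels)

setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@values)
  cat("VoxelGrid '", object@cellId, "': ", d[1], " x ", d[2], " x ", d[3],
      " voxels @ ", object@spacing, " um\n", sep = "")
  cat("  OD range [", signif(min(object@values), 4), ", ",
      signif(max(object@values), 4), "]\n", sep = "")
})

setMethod("show", "SegmentationSet", function(object) {
  cat("SegmentationSet:", sum(object@cellMask), "cell voxels,",
      sum(object@nucleusMask), "nucleus voxels,",
      length(setdiff(unique(as.vector(object@nucleolusLabels)), 0L)),
      "nucleoli\n")
})

setMethod("show", "CondensationPartition", function(object) {
  cat("CondensationPartition: mu =", signif(object@mu, 5),
      "sigma =", signif(object@sigma, 5), "\n")
  cat("  thresholds [", signif(object@tLow, 5), ",", signif(object@tHigh, 5),
      "]; state voxels (low/med/high):",
      paste(tabulate(object@stateLabels[object@stateLabels > 0], 3L),
            collapse = "/"), "\n")
})

setMethod("show", "StudyConfig", function(object) {
  cat("StudyConfig: spacing", object@spacing, "um; GLCM", object@glcmLevels,
      "levels at scales", paste(object@glcmScales, collapse = "/"),
      "um (canonical", object@markovianScale, "um);",
      "connectivity", object@clumpConnectivity, "; alpha", object@alpha, "\n")
})

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec: category", object@shapeCategory, "nucleus",
      paste(object@nucleusSemiAxes, collapse = "x"), "um;",
      object@nNucleoli, "nucleoli,", object@nLowClumps, "low +",
      object@nHighClumps, "high clumps; seed", object@seed, "\n")
})

setMethod("show", "PhantomGroundTruth", function(object) {
  cat("PhantomGroundTruth '", object@cellId, "': category ", object@category,
      ", nucleus ", signif(object@nucleusVolume, 5), " um^3, cell ",
      signif(object@cellVolume, 5), " um^3\n", sep = "")
})
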