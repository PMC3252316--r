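#' Extract the canonical 42-feature vector from one cell volume
#'
#' Runs the full per-cell pipeline: de-noising, cell and nucleus
#' segmentation, nucleolus detection, condensation partitioning, and the
#' morphological, descriptive, discrete and Markovian feature computations.
#' Inapplicable values (e.g. nucleolar margination with zero nucleoli) are
#' reported as NA, never silently zero. Any stage failure is rethrown with
#' the stage name attached.
#'
#' @param grid a \linkS4class{VoxelGrid}.
#' @param config a \linkS4class{StudyConfig}.
#' @return named numeric(42) in registry order, with attributes
#'   \code{cell_id}, \code{extras} (non-canonical extras: mean nucleolar
#'   volume, normalized margination), \code{micronuclei} (candidate table)
#'   and \code{markovian} (the per-scale sweep).
#' @export
extractFeatures <- function(grid, config = studyConfig()) {
  analyzeCell(grid, config)$features
}

# Full per-cell analysis; keeps the segmentation so callers can reuse it
# (e.g. for shape classification) without re-running the pipeline.
analyzeCell <- function(grid, config = studyConfig()) {
  stopifnot(is(grid, "VoxelGrid"), is(config, "StudyConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed for cell '", cellId(grid), "': ",
           conditionMessage(e), call. = FALSE))
  }
  den <- stage("denoise", denoiseVolume(grid, config@denoiseMethod,
                                        config@denoiseRadius))
  cellM <- stage("segment_cell", segmentCell(den))
  nucM <- stage("segment_nucleus", segmentNucleus(den, cellM))
  nucleoli <- stage("detect_nucleoli",
                    detectNucleoli(den, nucM, config@nucleoliKSd,
                                   config@nucleoliMinVolume))
  center <- stage("nucleus_center", nucleusCenter(den, nucM))
  part <- stage("partition_condensation", partitionCondensation(den, nucM))

  s <- spacing(grid)
  vCell <- maskVolume(cellM, s)
  vNuc <- maskVolume(nucM, s)
  nuc <- stage("nucleolar_features", nucleolarFeatures(nucleoli, den, center))
  morph <- c(
    cell_volume = vCell,
    nuclear_volume = vNuc,
    nucleus_to_cytoplasm_ratio = ncRatio(vNuc, vCell),
    nuclear_sphericity = stage("sphericity", sphericity(nucM, s)),
    number_of_nucleoli = as.numeric(nuc$count),
    total_nucleolar_volume = nuc$totalVolume,
    variance_in_nucleolar_volume = nuc$volumeVariance,
    average_nucleolar_margination = nuc$meanMargination,
    variance_in_nucleolar_margination = nuc$marginationVariance
  )
  ds <- stage("descriptive_stats", descriptiveStats(den, nucM))
  descr <- c(total_nuclear_content = ds$iod, mean_nuclear_content = ds$mean,
             variance_in_nuclear_content = ds$variance,
             skew_in_nuclear_content = ds$skew,
             kurtosis_in_nuclear_content = ds$kurtosis)
  disc <- stage("discrete_features",
                discreteFeatures(den, part, center,
                                 connectivity = config@clumpConnectivity))
  mark <- stage("markovian",
                markovianBlock(den, nucM, scales = config@glcmScales,
                               levels = config@glcmLevels,
                               canonical = config@markovianScale))
  markv <- c(markovian_contrast = unname(mark$canonical["contrast"]),
             markovian_correlation = unname(mark$canonical["correlation"]),
             markovian_energy = unname(mark$canonical["energy"]),
             markovian_heterogeneity = unname(mark$canonical["homogeneity"]))
  out <- c(morph, descr, disc[featureRegistry()$name[
    featureRegistry()$category == "discrete"]], markv)
  reg <- featureRegistry()$name
  stopifnot(identical(names(out), reg))
  extras <- c(mean_nucleolar_volume = nuc$meanVolume,
              normalized_nucleolar_margination =
                if (is.na(nuc$meanMargination)) NA_real_ else
                  nuc$meanMargination / ((3 * vNuc / (4 * pi))^(1 / 3)))
  fv <- structure(out, cell_id = cellId(grid), extras = extras,
                  micronuclei = attr(nucM, "micronuclei"),
                  markovian = mark$perScale)
  list(features = fv, cellMask = cellM, nucleusMask = nucM,
       partition = part, nucleolusLabels = nucleoli)
}

#' Angular step of a tomographic acquisition
#'
#' @param n_projections number of projections over a full rotation (>= 1).
#' @return angular interval in degrees, 360 / n.
#' @examples
#' angularStep(500)   # 0.72
#' @export
angularStep <- function(n_projections) {
  if (length(n_projections) != 1L || n_projections < 1)
    stop("n_projections must be a single count >= 1")
  360 / n_projections
}

#' Per-group histogram of one feature
#'
#' Shared bin edges across groups (so group distributions are directly
#' comparable); raw counts, no smoothing.
#'
#' @param feature_table data.frame with \code{cell_id} and feature columns.
#' @param feature feature (column) name.
#' @param group_labels one label per row.
#' @param bins number of bins.
#' @return data.frame: group, bin, left, right, count.
#' @export
histogramReport <- function(feature_table, feature, group_labels, bins = 10L) {
  if (!feature %in% names(feature_table))
    stop("unknown feature: ", feature)
  x <- feature_table[[feature]]
  ok <- !is.na(x)
  if (!any(ok)) stop("feature '", feature, "' has no non-missing values")
  edges <- seq(min(x[ok]), max(x[ok]), length.out = bins + 1L)
  edges[length(edges)] <- edges[length(edges)] + 1e-9 * max(1, abs(edges[length(edges)]))
  groups <- unique(group_labels)
  rows <- lapply(groups, function(g) {
    xv <- x[ok & group_labels == g]
    counts <- tabulate(findInterval(xv, edges, rightmost.closed = TRUE),
                       nbins = bins)
    data.frame(group = g, bin = seq_len(bins), left = edges[-length(edges)],
               right = edges[-1], count = counts)
  })
  do.call(rbind, rows)
}

#' Run the full synthetic three-population study
#'
#' Simulates the three built-in phantom populations, extracts the
#' 42-feature vector and the shape category for every cell, screens all
#' features across the populations, and writes the outputs (feature CSV,
#' shape report, significance table, summary, run manifest with file
#' checksums) into \code{out_dir}. Per-cell failures are quarantined and
#' logged in the manifest; the study aborts only if more than 20 percent of
#' cells fail.
#'
#' @param config a \linkS4class{StudyConfig}; \code{config@seed} drives all
#'   randomness.
#' @param n_per_group cells per population.
#' @param out_dir output directory (created if needed); NULL for no files.
#' @param presets population presets to simulate.
#' @return list: features (data.frame), shapes (per-cell categories),
#'   shapeReport (per-population fractions), significance, summary,
#'   manifest.
#' @export
runStudy <- function(config = studyConfig(), n_per_group = 20L,
                     out_dir = NULL, presets = phantomPresets()) {
  stopifnot(is(config, "StudyConfig"))
  t0 <- Sys.time()
  pops <- lapply(seq_along(presets), function(i)
    makePopulation(presets[i], n_per_group, presets[i],
                   seed = config@seed + i, spacing = config@spacing,
                   realize = FALSE))
  names(pops) <- presets
  featRows <- list()
  shapeRows <- list()
  failures <- list()
  for (p in presets) {
    specs <- pops[[p]]$specs
    for (i in seq_along(specs)) {
      id <- paste0(p, "_", sprintf("%03d", i))
      res <- tryCatch({
        ph <- makeCellPhantom(specs[[i]])
        grid <- ph$grid
        grid@cellId <- id
        an <- analyzeCell(grid, config)
        cat4 <- classifyShape(shapeMeasures(an$nucleusMask, config@spacing),
                              config)
        list(fv = an$features, cat = cat4,
             truthCat = ph$groundTruth@category)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[id]] <- conditionMessage(res)
        next
      }
      featRows[[id]] <- data.frame(cell_id = id, population = p,
                                   t(res$fv), check.names = FALSE)
      shapeRows[[id]] <- data.frame(cell_id = id, population = p,
                                    category = res$cat,
                                    planted_category = res$truthCat)
    }
  }
  total <- length(presets) * n_per_group
  if (length(failures) > 0.2 * total)
    stop("study aborted: ", length(failures), " of ", total, " cells failed")
  features <- do.call(rbind, featRows)
  rownames(features) <- NULL
  shapes <- do.call(rbind, shapeRows)
  rownames(shapes) <- NULL
  shapeReport <- do.call(rbind, lapply(presets, function(p) {
    sel <- shapes$population == p
    counts <- tabulate(shapes$category[sel], nbins = 4L)
    data.frame(population = p, category = 1:4, count = counts,
               fraction = counts / sum(sel))
  }))
  sig <- screenFeatures(features[, c("cell_id", featureRegistry()$name)],
                        features$population, alpha = config@alpha)
  summary <- summarizeDiscriminatory(sig)

  manifest <- list(
    package_version = as.character(utils::packageVersion("nucleomorph3d")),
    seed = config@seed, config = configAsList(config),
    presets = presets, n_per_group = n_per_group,
    n_failed = length(failures), failures = failures,
    started = format(t0, "%Y-%m-%d %H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fFeat <- file.path(out_dir, "features.csv")
    writeFeatures(features[, c("cell_id", featureRegistry()$name)], fFeat)
    fShape <- file.path(out_dir, "shapes.csv")
    utils::write.csv(shapes, fShape, row.names = FALSE)
    fShapeRep <- file.path(out_dir, "shape_report.csv")
    utils::write.csv(shapeReport, fShapeRep, row.names = FALSE)
    fSig <- file.path(out_dir, "significance.csv")
    utils::write.csv(sig, fSig, row.names = FALSE)
    fSum <- file.path(out_dir, "summary.csv")
    utils::write.csv(summary, fSum, row.names = FALSE)
    fCfg <- file.path(out_dir, "config.yaml")
    writeStudyConfig(config, fCfg)
    outs <- c(fFeat, fShape, fShapeRep, fSig, fSum, fCfg)
    manifest$outputs <- lapply(stats::setNames(as.list(outs), basename(outs)),
                               function(f) list(path = f,
                                                md5 = unname(tools::md5sum(f))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  list(features = features, shapes = shapes, shapeReport = shapeReport,
       significance = sig, summary = summary, manifest = manifest)
}
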