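#' Create a study configuration
#'
#' Collects every tunable parameter of the pipeline with its frozen default.
#' Defaults: 0.35 um spacing (the imaging platform's stated isotropic
#' resolution), 32 co-occurrence gray levels at length scales 0.44 / 0.74 /
#' 1.5 um with 0.74 um as the canonical scale, 26-connectivity for chromatin
#' clumps, nucleolus detection at mean + 2 SD with a 0.2 um^3 floor, shape
#' thresholds (convex below 0.05 concavity, irregular at 0.25, slender at
#' 0.55 elongation) and a screening alpha of 0.0025.
#'
#' @param ... named overrides of \linkS4class{StudyConfig} slots.
#' @return A \linkS4class{StudyConfig}.
#' @examples
#' cfg <- studyConfig(glcmLevels = 16L)
#' @export
studyConfig <- function(...) {
  args <- list(...)
  obj <- new("StudyConfig")
  for (nm in names(args)) {
    if (!nm %in% slotNames(obj)) stop("unknown StudyConfig field: ", nm)
    value <- args[[nm]]
    if (is(slot(obj, nm), "integer")) value <- as.integer(value)
    slot(obj, nm) <- value
  }
  validObject(obj)
  obj
}

#' Read / write a study configuration as YAML
#'
#' The configuration file is a flat key/value YAML document whose keys are
#' the \linkS4class{StudyConfig} slot names; absent keys keep their
#' defaults. \code{writeStudyConfig} echoes every effective value, so the
#' written file fully determines a rerun.
#'
#' @param path YAML file path.
#' @param config a \linkS4class{StudyConfig}.
#' @return \code{readStudyConfig} returns a \linkS4class{StudyConfig}.
#' @export
readStudyConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(studyConfig, vals)
}

#' @rdname readStudyConfig
#' @export
writeStudyConfig <- function(config, path) {
  stopifnot(is(config, "StudyConfig"))
  vals <- lapply(slotNames(config), function(nm) slot(config, nm))
  names(vals) <- slotNames(config)
  yaml::write_yaml(vals, path)
  invisible(path)
}

configAsList <- function(config) {
  vals <- lapply(slotNames(config), function(nm) slot(config, nm))
  names(vals) <- slotNames(config)
  vals
}
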