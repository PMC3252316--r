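#' The canonical 42-feature registry
#'
#' Ordered list of the descriptor set computed for every cell: 9
#' morphological, 5 descriptive-texture, 24 discrete-texture and 4 Markovian
#' features. Names are the snake_case forms of the published row labels of
#' the discriminatory-power table and are used as column names in every
#' feature CSV. The Markovian quadruple in this canonical vector is evaluated
#' at the single configured length scale (default 0.74 um); the full
#' multi-scale sweep is available from \code{\link{markovianBlock}}.
#'
#' The registry reports the \emph{variance} in nucleolar volume (the
#' discriminatory-table naming); the mean nucleolar volume is exposed as a
#' non-canonical extra by \code{\link{nucleolarFeatures}}. The quantity named
#' \code{markovian_heterogeneity} is the co-occurrence homogeneity
#' (inverse-difference moment) under its variant published name.
#'
#' @return A data.frame with columns \code{name}, \code{category}
#'   (\code{morphological}, \code{descriptive}, \code{discrete},
#'   \code{markovian}) and \code{units}, in canonical order, 42 rows.
#' @examples
#' reg <- featureRegistry()
#' nrow(reg)            # 42
#' table(reg$category)  # 9 / 5 / 24 / 4
#' @export
featureRegistry <- function() {
  morph <- data.frame(
    name = c("cell_volume", "nuclear_volume", "nucleus_to_cytoplasm_ratio",
             "nuclear_sphericity", "number_of_nucleoli",
             "total_nucleolar_volume", "variance_in_nucleolar_volume",
             "average_nucleolar_margination",
             "variance_in_nucleolar_margination"),
    category = "morphological",
    units = c("um3", "um3", "dimensionless", "dimensionless", "count",
              "um3", "um6", "um", "um2")
  )
  descr <- data.frame(
    name = c("total_nuclear_content", "mean_nuclear_content",
             "variance_in_nuclear_content", "skew_in_nuclear_content",
             "kurtosis_in_nuclear_content"),
    category = "descriptive",
    units = c("au", "au", "au2", "dimensionless", "dimensionless")
  )
  states3 <- c("low", "medium", "high")
  states4 <- c(states3, "medium_high")
  disc <- data.frame(
    name = c(paste0(states3, "_density_volume_fraction"),
             paste0(states3, "_density_content_fraction"),
             paste0("number_of_", states3, "_density_clumps"),
             paste0(states4, "_density_compactness"),
             paste0("average_extinction_ratio_low_",
                    c("medium", "high", "medium_high")),
             paste0("average_distance_from_nucleus_center_to_", states4,
                    "_density_regions"),
             paste0("average_centroidal_distance_from_nucleus_center_to_",
                    states4, "_density_regions")),
    category = "discrete",
    units = c(rep("dimensionless", 6), rep("count", 3), rep("dimensionless", 7),
              rep("um", 8))
  )
  mark <- data.frame(
    name = paste0("markovian_", c("contrast", "correlation", "energy",
                                  "heterogeneity")),
    category = "markovian",
    units = "dimensionless"
  )
  out <- rbind(morph, descr, disc, mark)
  rownames(out) <- NULL
  out
}
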