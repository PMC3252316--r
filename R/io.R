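#' Read a volumetric image into a VoxelGrid
#'
#' Supports multi-page TIFF (\code{.tif}/\code{.tiff}), NRRD (\code{.nrrd},
#' raw encoding) and MetaImage (\code{.mha}, local raw data). NRRD and
#' MetaImage carry voxel spacing in their headers; TIFF does not store 3D
#' spacing, so \code{spacing_override} is required for TIFF input. Spacing is
#' never silently assumed: a file without spacing metadata and without an
#' override is an error, and anisotropic header spacing is rejected naming
#' the offending axis.
#'
#' @param path file to read.
#' @param spacing_override optional isotropic voxel spacing in micrometres,
#'   taking precedence over file metadata.
#' @param cellId identifier for the resulting grid; defaults to the file
#'   base name.
#' @return A \linkS4class{VoxelGrid}.
#' @seealso \code{\link{writeVolume}}
#' @export
readVolume <- function(path, spacing_override = NULL, cellId = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (is.null(cellId)) cellId <- tools::file_path_sans_ext(basename(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
      stop("not a 3D volume: TIFF pages must be single-channel 2D images")
    if (length(pages) < 3L)
      stop("not a 3D volume: need at least 3 TIFF pages (z slices)")
    d <- dim(pages[[1]])
    values <- array(0, c(d[2], d[1], length(pages)))
    for (k in seq_along(pages)) values[, , k] <- t(pages[[k]])
    if (is.null(spacing_override))
      stop("missing spacing: TIFF carries no 3D spacing metadata; ",
           "pass spacing_override (micrometres)")
    sp <- spacing_override
  } else if (ext == "nrrd") {
    vol <- readNrrdRaw(path)
    values <- vol$values
    sp <- resolveSpacing(vol$spacings, spacing_override)
  } else if (ext == "mha") {
    vol <- readMhaRaw(path)
    values <- vol$values
    sp <- resolveSpacing(vol$spacings, spacing_override)
  } else {
    stop("unsupported volume format '.", ext,
         "'; supported: .tif/.tiff, .nrrd, .mha")
  }
  if (length(dim(values)) != 3L) stop("not a 3D volume")
  VoxelGrid(values, spacing = sp, cellId = cellId)
}

resolveSpacing <- function(spacings, spacing_override) {
  if (!is.null(spacing_override)) return(spacing_override)
  if (is.null(spacings) || !length(spacings) || anyNA(spacings))
    stop("missing spacing: file metadata has no voxel spacing and no ",
         "spacing_override was given")
  if (length(spacings) != 3L) stop("expected 3 spacing values")
  rel <- abs(spacings - spacings[1]) / spacings[1]
  if (any(rel > 1e-6)) {
    ax <- c("x", "y", "z")[which(rel > 1e-6)[1]]
    stop("anisotropic voxel spacing in metadata (axis ", ax,
         "); this pipeline requires isotropic volumes")
  }
  spacings[1]
}

#' Write a VoxelGrid or label volume to disk
#'
#' The written file round-trips bit-identically through
#' \code{\link{readVolume}}. TIFF output is 32-bit float multi-page;
#' NRRD/MetaImage output is raw little-endian with the requested element
#' type. Use \code{type = "uint8"} for masks and small label volumes.
#'
#' @param grid a \linkS4class{VoxelGrid}, or a plain 3D array (spacing then
#'   taken from \code{spacing}).
#' @param path output path; the extension picks the container
#'   (\code{.tif}/\code{.tiff}, \code{.nrrd}, \code{.mha}).
#' @param type element type for NRRD/MetaImage: \code{"double"},
#'   \code{"float"} or \code{"uint8"}.
#' @param spacing spacing in micrometres when \code{grid} is a bare array.
#' @return Invisibly, \code{path}.
#' @export
writeVolume <- function(grid, path, type = c("double", "float", "uint8"),
                        spacing = 0.35) {
  type <- match.arg(type)
  if (is(grid, "VoxelGrid")) {
    values <- voxelData(grid)
    sp <- spacing(grid)
  } else {
    values <- grid
    sp <- spacing
  }
  stopifnot(length(dim(values)) == 3L)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (min(values) < 0 || max(values) > 1)
      stop("TIFF output stores 32-bit float samples in [0, 1]; ",
           "rescale the optical densities or write NRRD/MetaImage instead")
    pages <- lapply(seq_len(dim(values)[3]), function(k) t(values[, , k]))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                    reduce = FALSE)
  } else if (ext == "nrrd") {
    writeNrrdRaw(values, path, sp, type)
  } else if (ext == "mha") {
    writeMhaRaw(values, path, sp, type)
  } else {
    stop("unsupported volume format '.", ext,
         "'; supported: .tif/.tiff, .nrrd, .mha")
  }
  invisible(path)
}

# --- minimal raw-encoded NRRD / MetaImage containers -----------------------
# (text header + little-endian raw block; enough to carry volumes, masks and
# spacing metadata between runs and external viewers)

nrrdTypeInfo <- function(type) {
  switch(type,
    "double" = list(nrrd = "double", met = "MET_DOUBLE", size = 8L, what = "double"),
    "float" = list(nrrd = "float", met = "MET_FLOAT", size = 4L, what = "double"),
    "uint8" = , "uchar" = list(nrrd = "uchar", met = "MET_UCHAR", size = 1L,
                               what = "integer"),
    "short" = , "int16" = list(nrrd = "short", met = "MET_SHORT", size = 2L,
                               what = "integer"),
    "ushort" = , "uint16" = list(nrrd = "ushort", met = "MET_USHORT", size = 2L,
                                 what = "integer"),
    "int" = , "int32" = list(nrrd = "int", met = "MET_INT", size = 4L,
                             what = "integer"),
    stop("unsupported element type: ", type)
  )
}

writeNrrdRaw <- function(values, path, spacing, type) {
  info <- nrrdTypeInfo(type)
  d <- dim(values)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- c(
    "NRRD0004",
    paste0("type: ", info$nrrd),
    "dimension: 3",
    paste0("sizes: ", paste(d, collapse = " ")),
    paste0("spacings: ", paste(rep(format(spacing, digits = 15), 3),
                               collapse = " ")),
    "encoding: raw",
    "endian: little",
    ""
  )
  writeLines(header, con, sep = "\n")
  writeRawBlock(con, values, info)
}

writeMhaRaw <- function(values, path, spacing, type) {
  info <- nrrdTypeInfo(type)
  d <- dim(values)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    paste0("DimSize = ", paste(d, collapse = " ")),
    paste0("ElementSpacing = ", paste(rep(format(spacing, digits = 15), 3),
                                      collapse = " ")),
    paste0("ElementType = ", info$met),
    "ElementDataFile = LOCAL"
  )
  writeLines(header, con, sep = "\n")
  writeRawBlock(con, values, info)
}

writeRawBlock <- function(con, values, info) {
  v <- as.vector(values)
  if (info$what == "integer") {
    vi <- as.integer(round(v))
    if (any(vi != v)) stop("non-integer values cannot be written as ", info$nrrd)
    writeBin(vi, con, size = info$size, endian = "little")
  } else {
    writeBin(as.double(v), con, size = info$size, endian = "little")
  }
}

readHeaderLines <- function(con, terminator) {
  lines <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) stop("unexpected end of header")
    if (terminator(ln)) break
    lines <- c(lines, ln)
  }
  lines
}

readNrrdRaw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!startsWith(magic, "NRRD")) stop("not an NRRD file: ", path)
  lines <- readHeaderLines(con, function(ln) !nzchar(trimws(ln)))
  lines <- lines[!startsWith(lines, "#")]
  kv <- strsplit(lines, ":[ =]?")
  fields <- list()
  for (p in kv) fields[[tolower(trimws(p[1]))]] <- trimws(paste(p[-1], collapse = ":"))
  if (!identical(fields[["encoding"]], "raw"))
    stop("only raw NRRD encoding is supported (got '", fields[["encoding"]], "')")
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(sizes) != 3L) stop("not a 3D volume: sizes = ",
                                fields[["sizes"]])
  info <- nrrdTypeInfo(fields[["type"]])
  spac <- if (!is.null(fields[["spacings"]]))
    as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]]) else NULL
  endian <- if (!is.null(fields[["endian"]])) fields[["endian"]] else "little"
  vals <- readBin(con, what = info$what, n = prod(sizes), size = info$size,
                  endian = endian)
  list(values = array(as.double(vals), sizes), spacings = spac)
}

readMhaRaw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) stop("unexpected end of MetaImage header")
    p <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(p[1])
    fields[[key]] <- trimws(paste(p[-1], collapse = "="))
    if (key == "ElementDataFile") break
  }
  if (!identical(fields[["ElementDataFile"]], "LOCAL"))
    stop("only single-file (LOCAL) MetaImage volumes are supported")
  sizes <- as.integer(strsplit(fields[["DimSize"]], "\\s+")[[1]])
  if (length(sizes) != 3L) stop("not a 3D volume: DimSize = ",
                                fields[["DimSize"]])
  type <- switch(fields[["ElementType"]],
    MET_DOUBLE = "double", MET_FLOAT = "float", MET_UCHAR = "uint8",
    MET_SHORT = "short", MET_USHORT = "ushort", MET_INT = "int",
    stop("unsupported ElementType: ", fields[["ElementType"]]))
  info <- nrrdTypeInfo(type)
  spac <- if (!is.null(fields[["ElementSpacing"]]))
    as.numeric(strsplit(fields[["ElementSpacing"]], "\\s+")[[1]]) else NULL
  vals <- readBin(con, what = info$what, n = prod(sizes), size = info$size,
                  endian = "little")
  list(values = array(as.double(vals), sizes), spacings = spac)
}

# --- feature tables --------------------------------------------------------

#' Write / read feature tables
#'
#' Feature tables are plain UTF-8 CSV, one cell per row: a \code{cell_id}
#' column followed by the 42 registry features in canonical order. Values
#' are written with 12 significant digits, so a written table re-reads to
#' within that precision. A table whose columns do not match the registry is
#' rejected naming the missing and extra columns.
#'
#' @param table data.frame with \code{cell_id} plus the registry columns.
#' @param path CSV path.
#' @return \code{readFeatures} returns the checked data.frame.
#' @export
writeFeatures <- function(table, path) {
  checkFeatureSchema(table)
  out <- table
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.12g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname writeFeatures
#' @export
readFeatures <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  checkFeatureSchema(tab)
  tab
}

checkFeatureSchema <- function(table) {
  expected <- c("cell_id", featureRegistry()$name)
  missing <- setdiff(expected, names(table))
  extra <- setdiff(names(table), expected)
  if (length(missing) || length(extra))
    stop("feature table schema mismatch; missing: [",
         paste(missing, collapse = ", "), "]; extra: [",
         paste(extra, collapse = ", "), "]")
  invisible(TRUE)
}
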