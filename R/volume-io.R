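#' Read a segmented label volume from disk
#'
#' Reads a 3D integer label image from a multi-page TIFF stack or an NRRD
#' file. TIFF pages are stacked along the third (naso-temporal) array
#' dimension; pixel values are read as-is (integer labels, 0 = background).
#' For NRRD input, per-axis spacing embedded in the header takes precedence
#' over the `spacing` argument; a warning is emitted if the two disagree.
#'
#' @param path path to a `.tif`/`.tiff` stack or `.nrrd` file.
#' @param spacing per-axis voxel edge length in mm (scalar or length 3).
#'   Required for TIFF (which carries no physical spacing); a fallback for NRRD.
#' @return A [voxel_volume()].
#' @export
load_label_volume <- function(path, spacing = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (is.null(spacing)) stop("spacing (mm) must be given for TIFF input")
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2L) {
      stop("TIFF stack has a single page: 2D data, need a 3D stack")
    }
    if (length(dim(pages[[1]])) != 2L) {
      stop("TIFF pages must be single-channel 2D label images")
    }
    grid <- array(0L, dim = c(dim(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) grid[, , k] <- pages[[k]]
    voxel_volume(grid, spacing)
  } else if (ext == "nrrd") {
    .read_nrrd(path, spacing)
  } else {
    stop("unsupported volume format '.", ext, "' (expected TIFF or NRRD)")
  }
}

#' Write a label volume to disk
#'
#' Writes a [voxel_volume()] as a multi-page TIFF (16-bit, pages along the
#' third axis; spacing is not stored, keep it alongside) or an NRRD file
#' (spacing embedded in the header, gzip-compressed payload).
#'
#' @param volume a [voxel_volume()].
#' @param path output path; format chosen by extension (`.tif`/`.tiff`/`.nrrd`).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (max(volume$grid) > 65535L) stop("labels exceed 16-bit TIFF range")
    pages <- lapply(seq_len(dim(volume$grid)[3]), function(k) {
      volume$grid[, , k] / 65535
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW")
  } else if (ext == "nrrd") {
    .write_nrrd(volume, path)
  } else {
    stop("unsupported volume format '.", ext, "'")
  }
  invisible(path)
}

# --- Minimal NRRD reader/writer -------------------------------------------
# Covers the subset this package emits and typical segmentation exports:
# 3D, integer or float types, raw / gzip encodings, little or big endian,
# "spacings" or diagonal "space directions" headers.

.nrrd_types <- list(
  "signed char" = list(what = "integer", size = 1, signed = TRUE),
  "int8"    = list(what = "integer", size = 1, signed = TRUE),
  "uchar"   = list(what = "integer", size = 1, signed = FALSE),
  "uint8"   = list(what = "integer", size = 1, signed = FALSE),
  "short"   = list(what = "integer", size = 2, signed = TRUE),
  "int16"   = list(what = "integer", size = 2, signed = TRUE),
  "ushort"  = list(what = "integer", size = 2, signed = FALSE),
  "uint16"  = list(what = "integer", size = 2, signed = FALSE),
  "int"     = list(what = "integer", size = 4, signed = TRUE),
  "int32"   = list(what = "integer", size = 4, signed = TRUE),
  "uint"    = list(what = "integer", size = 4, signed = FALSE),
  "uint32"  = list(what = "integer", size = 4, signed = FALSE),
  "float"   = list(what = "numeric", size = 4, signed = TRUE),
  "double"  = list(what = "numeric", size = 8, signed = TRUE)
)

.read_nrrd <- function(path, spacing = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000[0-9]$", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated NRRD header")
    if (line == "") break
    if (startsWith(line, "#")) next
    m <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(m) == 3L) fields[[tolower(trimws(m[2]))]] <- trimws(m[3])
  }
  ndim <- as.integer(fields[["dimension"]])
  if (is.na(ndim) || ndim != 3L) {
    stop("expected 3D NRRD data, got dimension ", fields[["dimension"]])
  }
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  type <- .nrrd_types[[tolower(fields[["type"]])]]
  if (is.null(type)) stop("unsupported NRRD type: ", fields[["type"]])
  endian <- if (identical(fields[["endian"]], "big")) "big" else "little"
  enc <- tolower(fields[["encoding"]] %||% "raw")
  n <- prod(sizes)
  payload <- readBin(con, "raw", n = file.size(path))
  if (enc %in% c("gzip", "gz")) {
    payload <- memDecompress(payload, type = "gzip")
  } else if (enc != "raw") {
    stop("unsupported NRRD encoding: ", enc)
  }
  vals <- readBin(payload, type$what, n = n, size = type$size,
                  signed = if (type$size < 4) type$signed else TRUE,
                  endian = endian)
  if (length(vals) != n) stop("NRRD payload shorter than header sizes imply")
  grid <- array(vals, dim = sizes)

  hdr_spacing <- NULL
  if (!is.null(fields[["spacings"]])) {
    hdr_spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    dirs <- lapply(vecs, function(v) {
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
    })
    if (length(dirs) == 3L) hdr_spacing <- vapply(dirs, function(v) sqrt(sum(v^2)), 0)
  }
  if (!is.null(hdr_spacing) && all(is.finite(hdr_spacing)) && all(hdr_spacing > 0)) {
    if (!is.null(spacing)) {
      arg <- rep(as.numeric(spacing), length.out = 3L)
      if (any(abs(arg - hdr_spacing) > 1e-9 * pmax(arg, hdr_spacing))) {
        warning(sprintf(
          "NRRD header spacing (%s mm) overrides the spacing argument (%s mm)",
          paste(signif(hdr_spacing, 6), collapse = " x "),
          paste(signif(arg, 6), collapse = " x ")))
      }
    }
    spacing <- hdr_spacing
  } else if (is.null(spacing)) {
    stop("NRRD header carries no spacing and none was supplied")
  }
  voxel_volume(grid, spacing)
}

.write_nrrd <- function(volume, path) {
  sizes <- dim(volume$grid)
  header <- c(
    "NRRD0004",
    "# lensmorph label volume",
    "type: int32",
    "dimension: 3",
    sprintf("sizes: %d %d %d", sizes[1], sizes[2], sizes[3]),
    sprintf("spacings: %.10g %.10g %.10g",
            volume$spacing[1], volume$spacing[2], volume$spacing[3]),
    "endian: little",
    "encoding: gzip",
    ""
  )
  payload <- writeBin(as.integer(volume$grid), raw(), size = 4L,
                      endian = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  writeBin(memCompress(payload, type = "gzip"), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
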