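## Readers and writers for the formats the pipeline touches. Axis
## convention on disk and in memory: axis 1 = x (fastest), axis 2 = y,
## axis 3 = z. 2D images read from PNG/TIFF are transposed so that axis 1
## is the image x (width) direction; multi-page TIFF stacks become (x, y,
## page) arrays. Masks are nonzero = inside.

#' Voxel spacing of a volume
#' @param volume An array read by [read_volume()].
#' @return Numeric per-axis spacing (1 if unknown).
#' @export
voxel_spacing <- function(volume) {
  attr(volume, "spacing") %||% rep(1, vol_ndim(volume))
}

guess_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) "nifti"
  else if (grepl("\\.(tif|tiff)$", lp)) "tiff"
  else if (grepl("\\.png$", lp)) "png"
  else if (grepl("\\.(hfa|raw)$", lp)) "raw"
  else stop("cannot infer format of '", path, "'; pass 'format' explicitly",
            call. = FALSE)
}

#' Read a volume
#'
#' Reads a scalar 2D/3D grid as a double array with a `"spacing"` attribute.
#' Integer data (e.g. 12-bit CT stored in 16-bit containers) is
#' range-preserved, never rescaled.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"nifti"`, `"tiff"`, `"png"` or
#'   `"raw"` (the package's named-array container).
#' @return A numeric array.
#' @export
read_volume <- function(path, format = c("auto", "nifti", "tiff", "png", "raw")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    nifti = {
      img <- RNifti::readNifti(path)
      vol <- as.array(img)
      attr(vol, "spacing") <- RNifti::pixdim(img)[seq_len(vol_ndim(vol))]
      storage.mode(vol) <- "double"
      vol
    },
    tiff = {
      pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      ## each page is rows(y) x cols(x); transpose to (x, y)
      slices <- lapply(pages, function(p) {
        if (length(dim(p)) == 3) p <- p[, , 1] # grayscale only
        t(p)
      })
      vol <- if (length(slices) == 1) slices[[1]] else
        array(unlist(slices), c(dim(slices[[1]]), length(slices)))
      storage.mode(vol) <- "double"
      attr(vol, "spacing") <- rep(1, vol_ndim(vol))
      vol
    },
    png = {
      img <- png::readPNG(path)
      if (length(dim(img)) == 3) {
        img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
      }
      vol <- t(img) * 255 # (x, y), 0-255 scale
      attr(vol, "spacing") <- c(1, 1)
      vol
    },
    raw = {
      arrs <- read_arrays(path)
      vol <- arrs$arrays[[1]]
      attr(vol, "spacing") <- arrs$meta$spacing %||% rep(1, vol_ndim(vol))
      vol
    })
}

#' Write a volume
#'
#' @param volume Numeric matrix or array.
#' @param path Output path; the extension selects the format unless given.
#' @param format See [read_volume()]. TIFF output stores integer-valued
#'   data in 16-bit pages losslessly; use NIfTI or the raw container for
#'   floating-point volumes.
#' @param spacing Optional per-axis voxel size to record (NIfTI, raw).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, format = c("auto", "nifti", "tiff", "raw"),
                         spacing = NULL) {
  format <- match.arg(format)
  volume <- as_volume(volume)
  if (format == "auto") format <- guess_format(path)
  spacing <- spacing %||% attr(volume, "spacing") %||% rep(1, vol_ndim(volume))
  switch(format,
    nifti = {
      img <- RNifti::asNifti(volume)
      RNifti::pixdim(img) <- spacing
      RNifti::writeNifti(img, path)
    },
    tiff = {
      if (any(volume < 0) || any(volume > 65535)) {
        stop("TIFF output requires values in [0, 65535]", call. = FALSE)
      }
      nd <- vol_ndim(volume)
      pages <- if (nd == 2) list(t(volume)) else
        lapply(seq_len(dim(volume)[3]), function(k) t(volume[, , k]))
      pages <- lapply(pages, function(p) p / 65535)
      tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    },
    raw = {
      write_arrays(path, list(volume = volume),
                   meta = list(spacing = as.numeric(spacing)))
    })
  invisible(path)
}

## --- named-array container --------------------------------------------------

#' Write a named-array container
#'
#' The package's raw persistence format: a JSON header (array names, dims,
#' metadata) followed by the little-endian float64 payloads. Round-trips
#' losslessly.
#'
#' @param path Output path (conventional extension `.hfa`).
#' @param arrays Named list of numeric arrays.
#' @param meta Optional metadata list (stored in the header).
#' @return `path`, invisibly.
#' @export
write_arrays <- function(path, arrays, meta = list()) {
  stopifnot(is.list(arrays), length(arrays) > 0, !is.null(names(arrays)))
  header <- list(
    magic = "HFARRAYS",
    version = 1L,
    names = names(arrays),
    dims = lapply(arrays, function(a) as.integer(dim(a) %||% length(a))),
    meta = meta
  )
  hjson <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  hraw <- charToRaw(as.character(hjson))
  writeBin(length(hraw), con, size = 4, endian = "little")
  writeBin(hraw, con)
  for (a in arrays) writeBin(as.numeric(a), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a named-array container
#' @param path Path written by [write_arrays()].
#' @return A list with `arrays` (named list) and `meta`.
#' @export
read_arrays <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hlen <- readBin(con, "integer", 1, size = 4, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)),
                               simplifyVector = TRUE)
  if (!identical(header$magic, "HFARRAYS")) {
    stop("not a named-array container: ", path, call. = FALSE)
  }
  arrays <- list()
  for (i in seq_along(header$names)) {
    d <- as.integer(header$dims[[i]])
    vals <- readBin(con, "numeric", prod(d), size = 8, endian = "little")
    arrays[[header$names[i]]] <- array(vals, d)
  }
  list(arrays = arrays, meta = as.list(header$meta))
}

## --- Middlebury .flo --------------------------------------------------------

FLO_MAGIC <- 202021.25
FLO_UNKNOWN <- 1e9

#' Read a Middlebury .flo flow file
#'
#' Parses the 2D optical-flow interchange format (magic 202021.25,
#' little-endian float32, interleaved u then v, row by row). Values with
#' magnitude above 1e9 are "unknown flow" sentinels: they are zeroed and
#' flagged in the returned `valid` attribute.
#'
#' @param path File path.
#' @return A 2D `flow_field` with `u` along axis 1 (image x) and `v` along
#'   axis 2, and a logical attribute `"valid"`.
#' @export
read_flo <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "numeric", 1, size = 4, endian = "little")
  if (!isTRUE(abs(magic - FLO_MAGIC) < 1e-3)) {
    stop("bad .flo magic number in ", path, call. = FALSE)
  }
  wh <- readBin(con, "integer", 2, size = 4, endian = "little")
  w <- wh[1]; h <- wh[2]
  dat <- readBin(con, "numeric", 2 * w * h, size = 4, endian = "little")
  u <- matrix(dat[seq(1, length(dat), by = 2)], nrow = w, ncol = h)
  v <- matrix(dat[seq(2, length(dat), by = 2)], nrow = w, ncol = h)
  valid <- abs(u) < FLO_UNKNOWN & abs(v) < FLO_UNKNOWN
  u[!valid] <- 0; v[!valid] <- 0
  fl <- new_flow_field(u, v)
  attr(fl, "valid") <- valid
  fl
}

#' Write a Middlebury .flo flow file
#' @param flow A 2D `flow_field`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flo <- function(flow, path) {
  if (flow$ndim != 2) stop(".flo files are 2D only", call. = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(FLO_MAGIC, con, size = 4, endian = "little")
  writeBin(as.integer(dim(flow$u)), con, size = 4, endian = "little")
  inter <- as.numeric(rbind(as.numeric(flow$u), as.numeric(flow$v)))
  writeBin(inter, con, size = 4, endian = "little")
  invisible(path)
}

## --- VTK legacy image data --------------------------------------------------

#' Write a 3D flow field as legacy VTK structured points
#'
#' Exports a 3-component vector array (plus an optional scalar intensity
#' array) in the legacy ASCII VTK format, renderable as glyphs in
#' ParaView-like viewers.
#'
#' @param flow A 3D `flow_field`.
#' @param path Output path (conventional extension `.vtk`).
#' @param volume Optional intensity volume of the same shape.
#' @param spacing Per-axis voxel size (default 1).
#' @return `path`, invisibly.
#' @export
write_vtk_flow <- function(flow, path, volume = NULL, spacing = c(1, 1, 1)) {
  if (flow$ndim != 3) {
    stop("VTK export needs a 3D flow (use write_flo for 2D)", call. = FALSE)
  }
  d <- flow$shape
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "hermiteflow vector field",
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               paste("DIMENSIONS", d[1], d[2], d[3]),
               "ORIGIN 0 0 0",
               paste("SPACING", spacing[1], spacing[2], spacing[3]),
               paste("POINT_DATA", prod(d)),
               "VECTORS flow double"), con)
  vec <- rbind(as.numeric(flow$u), as.numeric(flow$v), as.numeric(flow$w))
  writeLines(apply(vec, 2, paste, collapse = " "), con)
  if (!is.null(volume)) {
    writeLines(c("SCALARS intensity double 1", "LOOKUP_TABLE default"), con)
    writeLines(format(as.numeric(volume), trim = TRUE, digits = 10), con)
  }
  invisible(path)
}

#' Read a legacy VTK structured-points flow file
#'
#' Minimal reader for files produced by [write_vtk_flow()] (and compatible
#' legacy ASCII VTK image data with a 3-component `VECTORS` array).
#'
#' @param path File path.
#' @return A 3D `flow_field`; the intensity array, if present, is attached
#'   as attribute `"intensity"`.
#' @export
read_vtk_flow <- function(path) {
  lines <- readLines(path)
  dimln <- grep("^DIMENSIONS", lines, value = TRUE)[1]
  if (is.na(dimln)) stop("no DIMENSIONS line in ", path, call. = FALSE)
  d <- as.integer(strsplit(trimws(dimln), "\\s+")[[1]][2:4])
  vstart <- grep("^VECTORS", lines)[1]
  if (is.na(vstart)) stop("no VECTORS array in ", path, call. = FALSE)
  n <- prod(d)
  vals <- scan(text = lines[(vstart + 1):(vstart + n)], quiet = TRUE)
  m <- matrix(vals, nrow = 3)
  fl <- new_flow_field(array(m[1, ], d), array(m[2, ], d), array(m[3, ], d))
  sstart <- grep("^SCALARS intensity", lines)
  if (length(sstart)) {
    iv <- scan(text = lines[(sstart + 2):(sstart + 1 + n)], quiet = TRUE)
    attr(fl, "intensity") <- array(iv, d)
  }
  fl
}

#' Write a flow field to the named-array container
#' @param flow A `flow_field`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flow_arrays <- function(flow, path) {
  arrs <- list(u = flow$u, v = flow$v)
  if (!is.null(flow$w)) arrs$w <- flow$w
  write_arrays(path, arrs, meta = list(type = "flow_field", ndim = flow$ndim))
  invisible(path)
}

#' Read a flow field from the named-array container
#' @param path Path written by [write_flow_arrays()].
#' @return A `flow_field`.
#' @export
read_flow_arrays <- function(path) {
  x <- read_arrays(path)
  new_flow_field(x$arrays$u, x$arrays$v, x$arrays$w)
}
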