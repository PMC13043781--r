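# Multiband raster I/O for 4-band digital-number scenes, binary ground-truth
# masks and 3-class label maps. Storage is multiband TIFF (16-bit unsigned
# integer samples for scenes, 8-bit for masks/label maps) with an optional
# ESRI world file (.tfw) sidecar carrying the affine georeference.

#' Class codes shared by every classifier
#'
#' Label maps use integer codes 0 (background), 1 (soil), 2 (crops).
#' @export
CLASS_LEVELS <- c(background = 0L, soil = 1L, crops = 2L)

BAND_NAMES <- c("blue", "green", "red", "nir")

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("cultimap_input_error", "error")))
}

stop_compute <- function(...) {
  stop(errorCondition(paste0(...), class = c("cultimap_compute_error", "error")))
}

#' Construct a 4-band multispectral scene
#'
#' A scene holds aligned blue, green, red and near-infrared (NIR) grids of
#' digital numbers (DN): non-negative, finite, dimensionless sensor counts.
#' A pixel is *background* iff every band equals `nodata_value`; this encodes
#' the zero-padded footprint convention where the image border outside the
#' sensed area is 0 in all bands.
#'
#' @param blue,green,red,nir numeric matrices of identical dimension.
#' @param pixel_size_m ground sampling distance in meters (default 0.5).
#' @param geotransform optional numeric vector of length 6, world-file order:
#'   x pixel size, row rotation, column rotation, negative y pixel size,
#'   x and y map coordinates of the upper-left pixel center.
#' @param nodata_value DN that marks background when present in all bands.
#' @return An object of class `mspec_scene`.
#' @export
multispectral_scene <- function(blue, green, red, nir, pixel_size_m = 0.5,
                                geotransform = NULL, nodata_value = 0) {
  bands <- list(blue = blue, green = green, red = red, nir = nir)
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (!is.matrix(b) || !is.numeric(b)) {
      stop_input("band '", nm, "' must be a numeric matrix")
    }
    if (!all(is.finite(b))) stop_input("band '", nm, "' contains non-finite values")
    if (any(b < 0)) stop_input("band '", nm, "' contains negative DN")
    storage.mode(b) <- "double"
    bands[[nm]] <- b
  }
  dims <- unname(vapply(bands, dim, integer(2)))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_input("all four bands must share identical dimensions")
  }
  if (!is.null(geotransform) &&
      (!is.numeric(geotransform) || length(geotransform) != 6)) {
    stop_input("geotransform must be NULL or a numeric vector of length 6")
  }
  structure(
    c(bands, list(
      height = dims[1, 1], width = dims[2, 1],
      pixel_size_m = pixel_size_m,
      geotransform = geotransform,
      nodata_value = nodata_value
    )),
    class = "mspec_scene"
  )
}

#' @export
dim.mspec_scene <- function(x) c(x$height, x$width)

#' @export
print.mspec_scene <- function(x, ...) {
  cat(sprintf("<mspec_scene> %d x %d px, GSD %.3g m, nodata %s%s\n",
              x$height, x$width, x$pixel_size_m, format(x$nodata_value),
              if (is.null(x$geotransform)) "" else ", georeferenced"))
  invisible(x)
}

#' Logical grid of background pixels
#'
#' TRUE where every band equals the scene's `nodata_value`.
#' @param scene an `mspec_scene`.
#' @return logical matrix of the scene's dimensions.
#' @export
background_mask <- function(scene) {
  stopifnot(inherits(scene, "mspec_scene"))
  nd <- scene$nodata_value
  scene$blue == nd & scene$green == nd & scene$red == nd & scene$nir == nd
}

# --- TIFF helpers ------------------------------------------------------------

# readTIFF(all = TRUE) returns one element per directory; an element may be a
# 2D matrix (one band) or a H x W x C array (channels). Flatten to a list of
# 2D double matrices in file order.
read_tiff_bands <- function(path) {
  if (!file.exists(path)) stop_input("cannot read raster: ", path)
  imgs <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                   error = function(e) stop_input("unreadable TIFF '", path, "': ",
                                                  conditionMessage(e)))
  out <- list()
  for (im in imgs) {
    if (is.matrix(im)) {
      out[[length(out) + 1L]] <- im
    } else if (length(dim(im)) == 3) {
      for (ch in seq_len(dim(im)[3])) out[[length(out) + 1L]] <- im[, , ch]
    } else {
      stop_input("unsupported TIFF layout in ", path)
    }
  }
  lapply(out, function(m) { storage.mode(m) <- "double"; m })
}

world_file_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".tfw")
}

read_world_file <- function(path) {
  wf <- world_file_path(path)
  if (!file.exists(wf)) return(NULL)
  v <- as.numeric(readLines(wf, warn = FALSE)[1:6])
  if (length(v) != 6 || any(is.na(v))) stop_input("malformed world file: ", wf)
  v
}

write_world_file <- function(path, geotransform) {
  if (is.null(geotransform)) return(invisible(NULL))
  writeLines(formatC(geotransform, format = "g", digits = 17), world_file_path(path))
  invisible(NULL)
}

# --- scenes ------------------------------------------------------------------

#' Read a multispectral scene from a multiband TIFF
#'
#' Band semantics are never guessed from metadata: `band_order` states, in
#' file order, which band name each TIFF band carries. The near-infrared band
#' is mandatory because every index and classifier in the package uses it.
#' A `.tfw` world file next to the raster, if present, populates the
#' geotransform.
#'
#' @param path raster file path.
#' @param band_order character vector naming each file band; subset of
#'   blue/green/red/nir, must contain "nir".
#' @param nodata_value DN marking background (default 0).
#' @param pixel_size_m ground sampling distance in meters.
#' @return an [multispectral_scene()] object with all bands as doubles.
#' @export
read_scene <- function(path, band_order = c("blue", "green", "red", "nir"),
                       nodata_value = 0, pixel_size_m = 0.5) {
  if (!all(band_order %in% BAND_NAMES) || anyDuplicated(band_order)) {
    stop_input("band_order must be distinct names among ",
               paste(BAND_NAMES, collapse = "/"))
  }
  if (!"nir" %in% band_order) {
    stop_input("band_order must include 'nir': the NIR band is required")
  }
  bands <- read_tiff_bands(path)
  if (length(bands) < length(band_order)) {
    stop_input("raster has ", length(bands), " band(s) but band_order names ",
               length(band_order))
  }
  named <- stats::setNames(bands[seq_along(band_order)], band_order)
  # bands absent from band_order default to a zero grid (only nir is required
  # for thresholding; indices validate their own inputs)
  for (nm in setdiff(BAND_NAMES, band_order)) {
    named[[nm]] <- matrix(0, nrow(named[["nir"]]), ncol(named[["nir"]]))
  }
  multispectral_scene(blue = named$blue, green = named$green,
                      red = named$red, nir = named$nir,
                      pixel_size_m = pixel_size_m,
                      geotransform = read_world_file(path),
                      nodata_value = nodata_value)
}

#' Write a scene as a 4-band 16-bit TIFF
#'
#' DN are stored as unsigned 16-bit integers (0..65535); non-integer DN are
#' rounded. Band order on file is blue, green, red, nir. The geotransform, if
#' any, goes to a `.tfw` sidecar.
#'
#' @param scene an `mspec_scene`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "mspec_scene"))
  bands <- list(scene$blue, scene$green, scene$red, scene$nir)
  for (b in bands) {
    if (any(b > 65535)) stop_input("DN exceed the 16-bit storage range (0..65535)")
  }
  ok <- tryCatch(
    tiff::writeTIFF(lapply(bands, function(b) round(b) / 65535), path,
                    bits.per.sample = 16L, compression = "none"),
    error = function(e) stop_input("cannot write raster '", path, "': ",
                                   conditionMessage(e)))
  write_world_file(path, scene$geotransform)
  invisible(path)
}

# --- ground-truth masks ------------------------------------------------------

#' Construct a binary ground-truth mask
#'
#' @param mask matrix of 0/1 values (1 = cultivated).
#' @return object of class `gt_mask`.
#' @export
ground_truth_mask <- function(mask) {
  if (!is.matrix(mask) || !is.numeric(mask)) stop_input("mask must be a numeric matrix")
  if (!all(mask %in% c(0, 1))) stop_input("mask values must be exactly 0 or 1")
  storage.mode(mask) <- "integer"
  structure(list(mask = mask, height = nrow(mask), width = ncol(mask)),
            class = "gt_mask")
}

#' @export
dim.gt_mask <- function(x) c(x$height, x$width)

#' Read a single-band raster as a binary cultivated-land mask
#'
#' Pixels strictly greater than `threshold` become 1, the rest 0. Rejects
#' multiband input: a mask is one band by definition.
#'
#' @param path raster path.
#' @param threshold binarization threshold (default 0).
#' @return a [ground_truth_mask()].
#' @export
read_mask <- function(path, threshold = 0) {
  bands <- read_tiff_bands(path)
  if (length(bands) != 1) {
    stop_input("mask raster must be single-band, got ", length(bands), " bands")
  }
  ground_truth_mask((bands[[1]] > threshold) + 0)
}

#' Write a binary mask as an 8-bit single-band TIFF
#'
#' @param mask a `gt_mask`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "gt_mask"))
  tiff::writeTIFF(mask$mask / 255, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

# --- class maps --------------------------------------------------------------

#' Construct a 3-class label map
#'
#' @param labels integer matrix over codes 0 (background), 1 (soil), 2 (crops).
#' @param provenance list describing the classifier and parameters that
#'   produced the map.
#' @param cluster_to_class optional named mapping, for clustering provenance.
#' @return object of class `classmap`.
#' @export
classmap <- function(labels, provenance = list(), cluster_to_class = NULL) {
  if (!is.matrix(labels) || !is.numeric(labels)) {
    stop_input("labels must be a numeric matrix")
  }
  if (!all(labels %in% CLASS_LEVELS)) {
    stop_input("labels must be within codes {0,1,2} (background/soil/crops)")
  }
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, provenance = provenance,
                 cluster_to_class = cluster_to_class),
            class = "classmap")
}

#' @export
dim.classmap <- function(x) dim(x$labels)

#' @export
print.classmap <- function(x, ...) {
  n <- length(x$labels)
  counts <- tabulate(x$labels + 1L, nbins = 3L)
  cat(sprintf("<classmap> %d x %d px (%s): background %.2f%%, soil %.2f%%, crops %.2f%%\n",
              nrow(x$labels), ncol(x$labels),
              if (is.null(x$provenance$classifier)) "?" else x$provenance$classifier,
              100 * counts[1] / n, 100 * counts[2] / n, 100 * counts[3] / n))
  invisible(x)
}

# fixed color key for composites: white = background, brown = soil, green = crops
CLASS_PALETTE <- matrix(c(255, 255, 255,
                          139,  69,  19,
                          0,   128,   0) / 255,
                        nrow = 3, byrow = TRUE)

#' Write a class map as an 8-bit label TIFF (codes 0/1/2)
#'
#' Optionally also writes a PNG color composite with the fixed palette
#' white = background, brown = soil, green = crops.
#'
#' @param cm a [classmap()].
#' @param path output TIFF path.
#' @param png_path optional PNG composite path.
#' @return `path`, invisibly.
#' @export
write_classmap <- function(cm, path, png_path = NULL) {
  stopifnot(inherits(cm, "classmap"))
  ok <- tryCatch(
    tiff::writeTIFF(cm$labels / 255, path, bits.per.sample = 8L, compression = "none"),
    error = function(e) stop_input("cannot write class map '", path, "': ",
                                   conditionMessage(e)))
  if (!is.null(png_path)) {
    rgb <- array(0, c(nrow(cm$labels), ncol(cm$labels), 3))
    for (ch in 1:3) {
      rgb[, , ch] <- matrix(CLASS_PALETTE[cm$labels + 1L, ch], nrow(cm$labels))
    }
    png::writePNG(rgb, png_path)
  }
  invisible(path)
}

#' Read a label TIFF back into a class map
#'
#' @param path label raster written by [write_classmap()].
#' @return a [classmap()].
#' @export
read_classmap <- function(path) {
  bands <- read_tiff_bands(path)
  if (length(bands) != 1) stop_input("class map raster must be single-band")
  classmap(bands[[1]], provenance = list(source = path))
}
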