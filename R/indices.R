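# Per-pixel vegetation and water indices. Each is a pure per-pixel map over
# the scene's DN grids; no smoothing, masking or clipping. Ratio indices set
# zero-denominator pixels to 0 and flag them in a degenerate mask so that
# downstream feature stacks stay finite (background zero-padding then carries
# index value 0).

#' Coefficients for the adjusted indices
#'
#' Defaults: soil adjustment `L_savi = 0.5` for SAVI; for EVI, canopy
#' adjustment `L_evi = 1` and aerosol coefficients `C1 = 6`, `C2 = 7.5`.
#'
#' @param L_savi soil adjustment factor.
#' @param L_evi canopy background adjustment.
#' @param C1,C2 aerosol resistance coefficients.
#' @return list of class `index_params`.
#' @export
index_params <- function(L_savi = 0.5, L_evi = 1, C1 = 6, C2 = 7.5) {
  structure(list(L_savi = L_savi, L_evi = L_evi, C1 = C1, C2 = C2),
            class = "index_params")
}

new_index_raster <- function(values, name, degenerate, valid_range = NULL) {
  structure(list(values = values, name = name, degenerate = degenerate,
                 valid_range = valid_range),
            class = "index_raster")
}

#' @export
dim.index_raster <- function(x) dim(x$values)

#' @export
print.index_raster <- function(x, ...) {
  cat(sprintf("<index_raster> %s, %d x %d px, range [%.4g, %.4g], %d degenerate px\n",
              x$name, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values), sum(x$degenerate)))
  invisible(x)
}

# num/den with the zero-denominator convention
safe_ratio <- function(num, den, name, valid_range = NULL) {
  deg <- den == 0
  values <- matrix(0, nrow(num), ncol(num))
  values[!deg] <- num[!deg] / den[!deg]
  new_index_raster(values, name, deg, valid_range)
}

#' Normalized Difference Vegetation Index
#'
#' (NIR - Red) / (NIR + Red), in \[-1, 1\] for non-negative DN. High values
#' indicate photosynthetically active vegetation.
#'
#' @param scene an `mspec_scene`.
#' @return an `index_raster`.
#' @export
ndvi <- function(scene) {
  stopifnot(inherits(scene, "mspec_scene"))
  safe_ratio(scene$nir - scene$red, scene$nir + scene$red, "ndvi", c(-1, 1))
}

#' Modified Normalized Difference Water Index
#'
#' (Green - NIR) / (Green + NIR). Used here as a spectral contrast feature
#' between vegetated and non-vegetated surfaces, not a water-body detector.
#'
#' @param scene an `mspec_scene`.
#' @return an `index_raster`.
#' @export
mndwi <- function(scene) {
  stopifnot(inherits(scene, "mspec_scene"))
  safe_ratio(scene$green - scene$nir, scene$green + scene$nir, "mndwi", c(-1, 1))
}

#' Enhanced Vegetation Index
#'
#' (NIR - Red) / (NIR + C1*Red - C2*Blue + L). This is the two-term form
#' without a leading gain factor; `literature_form = TRUE` applies the common
#' 2.5 gain.
#'
#' @param scene an `mspec_scene`.
#' @param params an [index_params()].
#' @param literature_form multiply by the conventional gain G = 2.5.
#' @return an `index_raster`.
#' @export
evi <- function(scene, params = index_params(), literature_form = FALSE) {
  stopifnot(inherits(scene, "mspec_scene"))
  den <- scene$nir + params$C1 * scene$red - params$C2 * scene$blue + params$L_evi
  r <- safe_ratio(scene$nir - scene$red, den, "evi")
  if (literature_form) r$values <- 2.5 * r$values
  r
}

#' Soil Adjusted Vegetation Index
#'
#' (NIR - Red) / (NIR + Red + L) * (1 + L), L = 0.5 by default.
#'
#' @param scene an `mspec_scene`.
#' @param params an [index_params()].
#' @return an `index_raster`.
#' @export
savi <- function(scene, params = index_params()) {
  stopifnot(inherits(scene, "mspec_scene"))
  L <- params$L_savi
  r <- safe_ratio(scene$nir - scene$red, scene$nir + scene$red + L, "savi")
  r$values <- r$values * (1 + L)
  r
}

#' Green Chlorophyll Index
#'
#' NIR / Green - 1. Zero-Green pixels take value 0 and are flagged degenerate.
#'
#' @param scene an `mspec_scene`.
#' @return an `index_raster`.
#' @export
gci <- function(scene) {
  stopifnot(inherits(scene, "mspec_scene"))
  r <- safe_ratio(scene$nir, scene$green, "gci")
  r$values[!r$degenerate] <- r$values[!r$degenerate] - 1
  r
}

#' Chlorophyll Vegetation Index
#'
#' NIR / (Red - Green), as tabulated here; this differs from the
#' (NIR * Red) / Green^2 form found elsewhere in the literature.
#'
#' @param scene an `mspec_scene`.
#' @param literature_form use (NIR * Red) / Green^2 instead.
#' @return an `index_raster`.
#' @export
cvi <- function(scene, literature_form = FALSE) {
  stopifnot(inherits(scene, "mspec_scene"))
  if (literature_form) {
    return(safe_ratio(scene$nir * scene$red, scene$green^2, "cvi"))
  }
  safe_ratio(scene$nir, scene$red - scene$green, "cvi")
}

#' Difference Vegetation Index
#'
#' NIR - Red. Scales linearly with the DN; never degenerate.
#'
#' @param scene an `mspec_scene`.
#' @return an `index_raster`.
#' @export
dvi <- function(scene) {
  stopifnot(inherits(scene, "mspec_scene"))
  v <- scene$nir - scene$red
  new_index_raster(v, "dvi", matrix(FALSE, nrow(v), ncol(v)))
}

#' Normalized Difference Water Index (SWIR form)
#'
#' (NIR - SWIR) / (NIR + SWIR). The 4-band scenes this package handles carry
#' no shortwave-infrared band, so this always signals an unsupported-band
#' error; MNDWI (Green-NIR) is the available substitute.
#'
#' @param scene an `mspec_scene`.
#' @export
ndwi <- function(scene) {
  stopifnot(inherits(scene, "mspec_scene"))
  stop_input("ndwi requires a SWIR band, which 4-band (B/G/R/NIR) scenes lack; ",
             "use mndwi() instead")
}

#' Export an index raster as a single-band TIFF
#'
#' Values are affinely rescaled to the 16-bit range recorded in a sidecar
#' `.rng` text file (min and max), so `read_index()` can restore them.
#'
#' @param index an `index_raster`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "index_raster"))
  lo <- min(index$values); hi <- max(index$values)
  scaled <- if (hi > lo) (index$values - lo) / (hi - lo) else index$values * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L, compression = "none")
  writeLines(formatC(c(lo, hi), format = "g", digits = 17),
             paste0(tools::file_path_sans_ext(path), ".rng"))
  invisible(path)
}
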