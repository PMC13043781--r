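# Area accounting and error scoring: cultivated-area percentage
# (crops pixels / total pixels x 100), relative error against the reference
# percentage (|detected - actual| / actual x 100), and a 2x2 per-pixel
# agreement table against the ground-truth mask.

#' Percentage of cultivated area in a class map
#'
#' 100 x (crops pixels) / (pixels counted). With
#' `include_background = TRUE` (the default) the denominator is every pixel
#' of the map, zero-padding included; with `FALSE`, background pixels are
#' excluded from the denominator.
#'
#' @param cm a [classmap()].
#' @param include_background count background pixels in the denominator.
#' @return percentage in \[0, 100\].
#' @export
cultivated_percentage <- function(cm, include_background = TRUE) {
  stopifnot(inherits(cm, "classmap"))
  n_total <- length(cm$labels)
  if (n_total == 0) stop_input("empty class map")
  n_crops <- sum(cm$labels == CLASS_LEVELS[["crops"]])
  denom <- if (include_background) n_total
           else n_total - sum(cm$labels == CLASS_LEVELS[["background"]])
  if (denom == 0) stop_input("no countable pixels under this denominator convention")
  100 * n_crops / denom
}

#' Percentage of cultivated area in a ground-truth mask
#'
#' 100 x (mask ones) / (pixels counted), under the same denominator
#' convention as [cultivated_percentage()]: all pixels by default, or all
#' non-background pixels when a `background` grid is supplied with
#' `include_background = FALSE`.
#'
#' @param mask a [ground_truth_mask()].
#' @param background optional logical matrix of the mask's dimensions marking
#'   background pixels (e.g. from [background_mask()]).
#' @param include_background count background pixels in the denominator.
#' @return percentage in \[0, 100\].
#' @export
mask_percentage <- function(mask, background = NULL, include_background = TRUE) {
  stopifnot(inherits(mask, "gt_mask"))
  n_total <- length(mask$mask)
  if (n_total == 0) stop_input("empty mask")
  denom <- n_total
  if (!include_background) {
    if (is.null(background)) {
      stop_input("excluding background requires a background grid")
    }
    if (!identical(dim(background), dim(mask$mask))) {
      stop_input("background grid dimensions do not match the mask")
    }
    denom <- sum(!background)
    if (denom == 0) stop_input("no countable pixels under this denominator convention")
  }
  100 * sum(mask$mask) / denom
}

#' Relative error of a detected area percentage
#'
#' `|detected - actual| / actual x 100`, the study-level accuracy criterion.
#' Scale-free: multiplying both arguments by a positive constant leaves it
#' unchanged.
#'
#' @param detected_percent detected cultivated-area percentage.
#' @param actual_percent reference ("actual") percentage; must be positive.
#' @return non-negative percentage.
#' @export
relative_error <- function(detected_percent, actual_percent) {
  if (!is.numeric(actual_percent) || any(actual_percent <= 0)) {
    stop_input("actual_percent must be positive")
  }
  abs(detected_percent - actual_percent) / actual_percent * 100
}

#' Per-pixel agreement between predicted crops and the mask
#'
#' 2x2 contingency counts of predicted crops vs mask cultivated:
#' rows `crops` / `non_crops` (prediction), columns `cultivated` /
#' `uncultivated` (mask). Counts sum to the pixel total.
#'
#' @param cm a [classmap()].
#' @param mask a [ground_truth_mask()] of the same dimensions.
#' @return 2x2 integer matrix.
#' @export
agreement_table <- function(cm, mask) {
  stopifnot(inherits(cm, "classmap"), inherits(mask, "gt_mask"))
  if (!identical(dim(cm$labels), dim(mask$mask))) {
    stop_input("class map and mask dimensions differ")
  }
  pred <- cm$labels == CLASS_LEVELS[["crops"]]
  truth <- mask$mask == 1L
  matrix(c(sum(pred & truth), sum(pred & !truth),
           sum(!pred & truth), sum(!pred & !truth)),
         nrow = 2, byrow = TRUE,
         dimnames = list(prediction = c("crops", "non_crops"),
                         mask = c("cultivated", "uncultivated")))
}

#' Full area report for a class map
#'
#' Bundles per-class pixel counts, per-pixel ground area, the detected
#' cultivated percentage, and (when a reference is available) the reference
#' percentage and the relative error.
#'
#' @param cm a [classmap()].
#' @param mask optional [ground_truth_mask()]; its percentage (same
#'   denominator convention) becomes the reference.
#' @param reference_percent explicit reference percentage; overrides `mask`.
#' @param pixel_size_m ground sampling distance in meters (default 0.5, i.e.
#'   0.25 m2 per pixel).
#' @param include_background denominator convention, see
#'   [cultivated_percentage()].
#' @return object of class `area_report`.
#' @export
area_report <- function(cm, mask = NULL, reference_percent = NULL,
                        pixel_size_m = 0.5, include_background = TRUE) {
  stopifnot(inherits(cm, "classmap"))
  counts <- tabulate(cm$labels + 1L, nbins = 3L)
  names(counts) <- names(CLASS_LEVELS)
  detected <- cultivated_percentage(cm, include_background = include_background)
  if (is.null(reference_percent) && !is.null(mask)) {
    bg <- if (include_background) NULL else cm$labels == CLASS_LEVELS[["background"]]
    reference_percent <- mask_percentage(mask, background = bg,
                                         include_background = include_background)
  }
  rel_err <- if (!is.null(reference_percent)) {
    relative_error(detected, reference_percent)
  } else {
    NA_real_
  }
  structure(list(
    class_pixel_counts = counts,
    pixel_area_m2 = pixel_size_m^2,
    cultivated_area_m2 = counts[["crops"]] * pixel_size_m^2,
    cultivated_percent = detected,
    reference_percent = if (is.null(reference_percent)) NA_real_ else reference_percent,
    relative_error_percent = rel_err,
    include_background = include_background,
    provenance = cm$provenance
  ), class = "area_report")
}

#' @export
print.area_report <- function(x, ...) {
  cat(sprintf("<area_report>%s\n",
              if (is.null(x$provenance$classifier)) ""
              else paste0(" [", x$provenance$classifier, "]")))
  cat(sprintf("  pixels: background %d, soil %d, crops %d (%.3g m2/px)\n",
              x$class_pixel_counts[["background"]], x$class_pixel_counts[["soil"]],
              x$class_pixel_counts[["crops"]], x$pixel_area_m2))
  cat(sprintf("  cultivated: %.2f%% detected", x$cultivated_percent))
  if (!is.na(x$reference_percent)) {
    cat(sprintf(" vs %.2f%% reference -> relative error %.2f%%",
                x$reference_percent, x$relative_error_percent))
  }
  cat("\n")
  invisible(x)
}
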