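# The four pixel-based classifiers: NIR thresholding, NDVI thresholding,
# K-means on raw normalized bands (NIR, Red, Blue), and spectral K-means on
# normalized NDVI, MNDWI and NIR. All emit a 3-class map over
# background / soil / crops.
#
# Pixel ordering convention: feature-stack rows enumerate the scene grid in
# column-major order (R's native vectorization), so matrix(x, h, w) restores
# the grid.

#' Build the raw-band feature stack (NIR, Red, Blue)
#'
#' Rows are pixels; features are ordered (nir, red, blue), each min-max
#' normalized to \[0, 1\] over all pixels of the scene (background included).
#' A constant feature maps to all zeros. The per-feature (min, max) pairs are
#' kept in `norm_record` so non-constant features can be reconstructed
#' exactly.
#'
#' @param scene an `mspec_scene`.
#' @return object of class `feature_stack`.
#' @export
build_band_stack <- function(scene) {
  stopifnot(inherits(scene, "mspec_scene"))
  raw <- cbind(nir = as.vector(scene$nir),
               red = as.vector(scene$red),
               blue = as.vector(scene$blue))
  new_feature_stack(raw, dim(scene))
}

#' Build the spectral-index feature stack (NDVI, MNDWI, NIR)
#'
#' Computes NDVI and MNDWI per pixel (degenerate denominators give 0), stacks
#' them with the raw NIR band, and min-max normalizes each feature to
#' \[0, 1\].
#'
#' @param scene an `mspec_scene`.
#' @return object of class `feature_stack`.
#' @export
build_spectral_stack <- function(scene) {
  stopifnot(inherits(scene, "mspec_scene"))
  raw <- cbind(ndvi = as.vector(ndvi(scene)$values),
               mndwi = as.vector(mndwi(scene)$values),
               nir = as.vector(scene$nir))
  new_feature_stack(raw, dim(scene))
}

new_feature_stack <- function(raw, dims) {
  mins <- apply(raw, 2, min)
  maxs <- apply(raw, 2, max)
  rng <- maxs - mins
  features <- raw
  for (j in seq_len(ncol(raw))) {
    features[, j] <- if (rng[j] > 0) (raw[, j] - mins[j]) / rng[j] else 0
  }
  structure(list(
    features = features,
    feature_names = colnames(raw),
    norm_record = data.frame(feature = colnames(raw), min = mins, max = maxs,
                             row.names = NULL),
    pixel_index = arrayInd(seq_len(nrow(raw)), dims),
    dims = dims
  ), class = "feature_stack")
}

#' Undo the min-max normalization of one feature
#'
#' @param stack a `feature_stack`.
#' @param feature feature name.
#' @return numeric vector of pre-normalization values (a constant feature
#'   returns its recorded constant).
#' @export
denormalize_feature <- function(stack, feature) {
  stopifnot(inherits(stack, "feature_stack"))
  j <- match(feature, stack$feature_names)
  if (is.na(j)) stop_input("unknown feature: ", feature)
  lo <- stack$norm_record$min[j]
  hi <- stack$norm_record$max[j]
  if (hi > lo) stack$features[, j] * (hi - lo) + lo
  else rep(lo, nrow(stack$features))
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("<feature_stack> %d px x (%s), min-max normalized\n",
              nrow(x$features), paste(x$feature_names, collapse = ", ")))
  invisible(x)
}

#' NIR-threshold pixel classifier
#'
#' Zero NIR intensity is background; NIR in (0, `soil_upper`] is soil; NIR
#' strictly above `soil_upper` is crops. Default `soil_upper = 700` DN.
#'
#' @param scene an `mspec_scene`.
#' @param soil_upper upper DN bound of the soil class (inclusive).
#' @return a [classmap()].
#' @export
classify_nir_threshold <- function(scene, soil_upper = 700) {
  stopifnot(inherits(scene, "mspec_scene"))
  labels <- matrix(CLASS_LEVELS[["soil"]], scene$height, scene$width)
  labels[scene$nir == 0] <- CLASS_LEVELS[["background"]]
  labels[scene$nir > soil_upper] <- CLASS_LEVELS[["crops"]]
  classmap(labels, provenance = list(classifier = "nir-threshold",
                                     soil_upper = soil_upper))
}

#' NDVI-threshold pixel classifier
#'
#' Background pixels (all bands at the nodata value) stay background; among
#' the rest, NDVI at most `crop_lower` is soil and NDVI strictly above it is
#' crops. Default `crop_lower = 0.2`.
#'
#' @param scene an `mspec_scene`.
#' @param crop_lower NDVI above which a pixel is crops.
#' @return a [classmap()].
#' @export
classify_ndvi_threshold <- function(scene, crop_lower = 0.2) {
  stopifnot(inherits(scene, "mspec_scene"))
  v <- ndvi(scene)$values
  labels <- matrix(CLASS_LEVELS[["soil"]], scene$height, scene$width)
  labels[v > crop_lower] <- CLASS_LEVELS[["crops"]]
  labels[background_mask(scene)] <- CLASS_LEVELS[["background"]]
  classmap(labels, provenance = list(classifier = "ndvi-threshold",
                                     crop_lower = crop_lower))
}

#' Map the three K-means clusters to background / soil / crops
#'
#' The cluster holding the majority of the scene's background (all-nodata)
#' pixels becomes background; if the scene has none, the cluster whose
#' centroid has the smallest norm does. Of the remaining two, the cluster
#' with the higher mean pre-normalization NDVI over its member pixels becomes
#' crops (for stacks without an NDVI feature, the higher mean NIR); ties
#' break toward higher mean NIR, then toward the lower cluster index. The
#' mapping is a bijection onto \{background, soil, crops\}.
#'
#' @param model a `cluster_model` with exactly 3 clusters.
#' @param stack the `feature_stack` the model was fitted on.
#' @param scene the source `mspec_scene`.
#' @return integer vector of length 3: `cluster_to_class[j]` is the class
#'   code of cluster `j`, named by class.
#' @export
label_clusters <- function(model, stack, scene) {
  stopifnot(inherits(model, "cluster_model"), inherits(stack, "feature_stack"),
            inherits(scene, "mspec_scene"))
  if (nrow(model$centroids) != 3) {
    stop_input("semantic cluster labeling requires exactly k = 3 clusters")
  }
  if (length(model$assignments) != prod(dim(scene))) {
    stop_input("model was not fitted on this scene's pixels")
  }

  bg <- as.vector(background_mask(scene))
  bg_cluster <- if (any(bg)) {
    which.max(tabulate(model$assignments[bg], nbins = 3))
  } else {
    which.min(rowSums(model$centroids^2))
  }

  rest <- setdiff(1:3, bg_cluster)
  score_feature <- if ("ndvi" %in% stack$feature_names) "ndvi" else "nir"
  score_vals <- denormalize_feature(stack, score_feature)
  nir_vals <- denormalize_feature(stack, "nir")
  cluster_mean <- function(vals, j) {
    m <- model$assignments == j
    if (any(m)) mean(vals[m]) else -Inf
  }
  s <- vapply(rest, function(j) cluster_mean(score_vals, j), numeric(1))
  if (s[1] != s[2]) {
    crops_cluster <- rest[which.max(s)]
  } else {
    nir_means <- vapply(rest, function(j) cluster_mean(nir_vals, j), numeric(1))
    crops_cluster <- if (nir_means[1] != nir_means[2]) {
      rest[which.max(nir_means)]
    } else {
      rest[1]   # lower index
    }
  }
  soil_cluster <- setdiff(rest, crops_cluster)

  mapping <- integer(3)
  mapping[bg_cluster] <- CLASS_LEVELS[["background"]]
  mapping[soil_cluster] <- CLASS_LEVELS[["soil"]]
  mapping[crops_cluster] <- CLASS_LEVELS[["crops"]]
  names(mapping) <- names(CLASS_LEVELS)[match(mapping, CLASS_LEVELS)]
  mapping
}

#' K-means pixel classifier
#'
#' Clusters the feature stack with [kmeans_fit()] at `k = 3` and maps the
#' clusters to semantic classes with [label_clusters()]. Lloyd iterations from
#' a single random initialization can converge to a poor local optimum when
#' one class dominates the scene (all starting centroids land in it), so by
#' default the fit takes the best of `n_start = 10` seeded restarts.
#'
#' @param stack a `feature_stack` built from `scene`.
#' @param scene the source `mspec_scene`.
#' @param k number of clusters; the three-class semantics require 3.
#' @param seed RNG seed for centroid initialization.
#' @param n_start seeded restarts; the lowest-inertia fit wins.
#' @param ... further arguments to [kmeans_fit()].
#' @return a [classmap()] whose provenance records k, seed, iterations and
#'   inertia, and whose `cluster_to_class` holds the mapping used.
#' @export
classify_kmeans <- function(stack, scene, k = 3, seed = 0L, n_start = 10L, ...) {
  stopifnot(inherits(stack, "feature_stack"), inherits(scene, "mspec_scene"))
  if (!identical(as.integer(stack$dims), as.integer(dim(scene)))) {
    stop_input("feature stack dimensions do not match the scene")
  }
  if (k != 3) stop_input("three-class mapping requires k = 3")
  model <- kmeans_fit(stack$features, k = k, seed = seed, n_start = n_start, ...)
  mapping <- label_clusters(model, stack, scene)
  labels <- matrix(mapping[model$assignments], scene$height, scene$width)
  feature_kind <- if ("ndvi" %in% stack$feature_names) "spectral-kmeans" else "kmeans-bands"
  classmap(labels,
           provenance = list(classifier = feature_kind, k = k, seed = model$seed,
                             n_iter = model$n_iter, inertia = model$inertia,
                             converged = model$converged),
           cluster_to_class = mapping)
}
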