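test_that("NIR thresholding follows the 0 / (0,700] / >700 rule", {
  sc <- tiny_scene(blue = 0, green = 0, red = 0,
                   nir = c(0, 1, 700, 700.01, 900, 2047), nrow = 2, ncol = 3)
  cm <- classify_nir_threshold(sc)
  expect_identical(as.vector(cm$labels), c(0L, 1L, 1L, 2L, 2L, 2L))

  # uniform all-crops scene -> 100% crops
  all_crops <- classify_nir_threshold(tiny_scene(blue = 1, green = 1, red = 1,
                                                 nir = 900, nrow = 3, ncol = 3))
  expect_identical(cultivated_percentage(all_crops), 100)
})

test_that("NDVI thresholding uses the nodata test for background and 0.2 for crops", {
  # NDVI 0.6 -> crops, NDVI 0.1 -> soil, all-zero pixel -> background
  sc <- tiny_scene(blue = c(0, 1, 1), green = c(0, 1, 1),
                   red = c(0, 200, 450), nir = c(0, 800, 550), nrow = 1, ncol = 3)
  cm <- classify_ndvi_threshold(sc)
  expect_identical(as.vector(cm$labels), c(0L, 2L, 1L))
  # exactly 0.2 is soil (crops are strictly greater)
  sc2 <- tiny_scene(blue = 1, green = 1, red = 400, nir = 600)
  expect_identical(classify_ndvi_threshold(sc2)$labels[1, 1], 1L)
})

test_that("threshold classifiers agree pixel-for-pixel with a naive rule interpreter", {
  set.seed(51)
  for (rep in 1:3) {
    sc <- random_scene(12, 12, dn_max = 1500)
    # sprinkle exact background pixels and exact-boundary NIR values
    sc$nir[1:3, 1] <- c(0, 700, 701)
    sc$blue[5, 5] <- sc$green[5, 5] <- sc$red[5, 5] <- sc$nir[5, 5] <- 0
    expect_identical(classify_nir_threshold(sc)$labels,
                     naive_threshold_labels(sc, "nir"))
    expect_identical(classify_ndvi_threshold(sc)$labels,
                     naive_threshold_labels(sc, "ndvi"))
  }
})

test_that("feature stacks normalize per feature to [0,1] and keep the record", {
  # 2x1 scene with extremes: rows become (0,0,0) and (1,1,1)
  sc <- tiny_scene(blue = c(0, 250), green = c(0, 0), red = c(0, 500),
                   nir = c(0, 1000), nrow = 2, ncol = 1)
  st <- build_band_stack(sc)
  expect_identical(st$feature_names, c("nir", "red", "blue"))
  expect_equal(unname(st$features[1, ]), c(0, 0, 0))
  expect_equal(unname(st$features[2, ]), c(1, 1, 1))

  # constant feature maps to all zeros
  sc2 <- tiny_scene(blue = c(5, 5), green = c(0, 1), red = c(1, 9),
                    nir = c(2, 8), nrow = 2, ncol = 1)
  st2 <- build_band_stack(sc2)
  expect_true(all(st2$features[, "blue"] == 0))

  set.seed(52)
  sc3 <- random_scene(9, 9)
  for (st in list(build_band_stack(sc3), build_spectral_stack(sc3))) {
    expect_true(all(st$features >= 0 & st$features <= 1))
    # norm_record reconstructs pre-normalization values exactly
    nir_back <- denormalize_feature(st, "nir")
    expect_equal(nir_back, as.vector(sc3$nir))
  }
})

test_that("spectral stack rows hold (ndvi, mndwi, nir) in scene pixel order", {
  # background pixel -> (0, 0, 0) pre-normalization; crop pixel evaluates the
  # two index formulas directly: ndvi 0.8, mndwi (200-900)/1100 = -7/11
  sc <- tiny_scene(blue = c(0, 50), green = c(0, 200), red = c(0, 100),
                   nir = c(0, 900), nrow = 1, ncol = 2)
  st <- build_spectral_stack(sc)
  expect_identical(st$feature_names, c("ndvi", "mndwi", "nir"))
  raw <- vapply(st$feature_names, function(f) denormalize_feature(st, f),
                numeric(2))
  expect_equal(unname(raw[1, ]), c(0, 0, 0))
  expect_equal(unname(raw[2, ]), c(0.8, -700 / 1100, 900))
  # column-major pixel order: row index maps back to (row, col)
  expect_identical(st$pixel_index[2, ], c(1L, 2L))
})

test_that("cluster labeling follows background-majority then NDVI/NIR ordering", {
  gen <- separable_scene()
  sc <- gen$scene
  st <- build_spectral_stack(sc)
  model <- kmeans_fit(st$features, k = 3, seed = 0, n_start = 10)
  mapping <- label_clusters(model, st, sc)

  # bijection onto the three class codes
  expect_identical(sort(unname(mapping)), c(0L, 1L, 2L))
  # the cluster holding the background pixels is labeled background
  bg_cluster <- which.max(tabulate(model$assignments[as.vector(background_mask(sc))], 3))
  expect_identical(unname(mapping[bg_cluster]), 0L)
  # the crops cluster has the higher member-mean NDVI of the remaining two
  ndvi_vals <- denormalize_feature(st, "ndvi")
  rest <- setdiff(1:3, bg_cluster)
  means <- vapply(rest, function(j) mean(ndvi_vals[model$assignments == j]), 0)
  expect_identical(unname(mapping[rest[which.max(means)]]), 2L)

  expect_error(label_clusters(kmeans_fit(st$features, k = 2, seed = 0), st, sc),
               class = "cultimap_input_error")
})

test_that("without background pixels the smallest-norm centroid is background", {
  # three tight blobs, no all-zero pixel anywhere
  set.seed(53)
  h <- 12; w <- 12
  nir <- matrix(1200, h, w); nir[, 1:4] <- 10; nir[, 5:8] <- 500
  red <- matrix(300, h, w); red[, 1:4] <- 12; red[, 5:8] <- 600
  grn <- matrix(350, h, w); grn[, 1:4] <- 11; grn[, 5:8] <- 650
  blu <- matrix(300, h, w); blu[, 1:4] <- 10; blu[, 5:8] <- 450
  sc <- multispectral_scene(blue = blu, green = grn, red = red, nir = nir)
  st <- build_spectral_stack(sc)
  model <- kmeans_fit(st$features, k = 3, seed = 1, n_start = 10)
  mapping <- label_clusters(model, st, sc)
  low_norm <- which.min(rowSums(model$centroids^2))
  expect_identical(unname(mapping[low_norm]), 0L)
  expect_identical(sort(unname(mapping)), c(0L, 1L, 2L))
})

test_that("k-means classifiers recover generating labels on separable scenes", {
  gen <- separable_scene()
  truth <- ifelse(background_mask(gen$scene), 0L,
                  ifelse(gen$mask$mask == 1L, 2L, 1L))
  for (build in list(build_spectral_stack, build_band_stack)) {
    st <- build(gen$scene)
    cm <- classify_kmeans(st, gen$scene, seed = 4)
    expect_identical(unname(cm$labels), unname(truth))
    # determinism: same stack, scene and seed -> identical map
    cm2 <- classify_kmeans(st, gen$scene, seed = 4)
    expect_identical(cm$labels, cm2$labels)
  }
  expect_error(classify_kmeans(build_band_stack(gen$scene), gen$scene, k = 1),
               class = "cultimap_input_error")
})

test_that("class maps partition the pixel grid for every classifier", {
  gen <- separable_scene(h = 24, w = 30, border = 3)
  maps <- list(
    classify_nir_threshold(gen$scene),
    classify_ndvi_threshold(gen$scene),
    classify_kmeans(build_band_stack(gen$scene), gen$scene, seed = 0),
    classify_kmeans(build_spectral_stack(gen$scene), gen$scene, seed = 0)
  )
  for (cm in maps) {
    expect_identical(dim(cm), dim(gen$scene))
    counts <- tabulate(cm$labels + 1L, nbins = 3L)
    expect_identical(sum(counts), length(cm$labels))
    # background pixels of the scene always map to the background class
    expect_true(all(cm$labels[background_mask(gen$scene)] == 0L))
  }
})
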