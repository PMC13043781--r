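# Small in-code fixtures shared across the suite.

# Scene from explicit band matrices, recycling scalars to a common dimension.
tiny_scene <- function(blue, green, red, nir, nrow = NULL, ncol = NULL, ...) {
  to_mat <- function(x) {
    if (is.matrix(x)) return(x)
    matrix(x, nrow %||% 1, ncol %||% 1)
  }
  b <- to_mat(blue); g <- to_mat(green); r <- to_mat(red); n <- to_mat(nir)
  multispectral_scene(blue = b, green = g, red = r, nir = n, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random non-negative integer DN scene.
random_scene <- function(h, w, dn_max = 2047) {
  m <- function() matrix(sample(0:dn_max, h * w, replace = TRUE), h, w)
  multispectral_scene(blue = m(), green = m(), red = m(), nir = m())
}

# Three perfectly separable populations: zero background frame, low-NIR soil,
# high-NDVI crops, with noise small relative to class separation.
separable_scene <- function(h = 40, w = 40, border = 4, noise_sd = 5, seed = 1) {
  parcel <- c(border + 5, border + 5, h - 2 * border - 8, w - 2 * border - 8)
  sp <- list(
    soil = list(blue = c(450, noise_sd), green = c(650, noise_sd),
                red = c(600, noise_sd), nir = c(500, noise_sd)),
    crops = list(blue = c(350, noise_sd), green = c(350, noise_sd),
                 red = c(350, noise_sd), nir = c(1200, noise_sd))
  )
  spec <- synthetic_scene_spec(h, w, background_border = border,
                               parcels = list(parcel), class_spectra = sp,
                               seed = seed)
  generate_scene(spec)
}

# Independent per-pixel rule interpreter for the two threshold classifiers:
# deliberately scalar, loop-based and branch-per-pixel.
naive_threshold_labels <- function(scene, rule) {
  h <- nrow(scene$nir); w <- ncol(scene$nir)
  out <- matrix(NA_integer_, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (rule == "nir") {
        v <- scene$nir[i, j]
        out[i, j] <- if (v == 0) 0L else if (v <= 700) 1L else 2L
      } else {
        zero <- scene$blue[i, j] == 0 && scene$green[i, j] == 0 &&
          scene$red[i, j] == 0 && scene$nir[i, j] == 0
        if (zero) {
          out[i, j] <- 0L
        } else {
          n <- scene$nir[i, j]; r <- scene$red[i, j]
          v <- if (n + r == 0) 0 else (n - r) / (n + r)
          out[i, j] <- if (v > 0.2) 2L else 1L
        }
      }
    }
  }
  out
}

# Global minimum K-means inertia for k = 2 by enumerating every assignment of
# n points to two non-empty groups.
brute_force_min_inertia_k2 <- function(points) {
  n <- nrow(points)
  best <- Inf
  for (code in 1:(2^n - 2)) {
    grp <- as.logical(bitwAnd(code, 2^(seq_len(n) - 1)))
    sse <- 0
    for (g in list(grp, !grp)) {
      sub <- points[g, , drop = FALSE]
      ctr <- colMeans(sub)
      sse <- sse + sum(sweep(sub, 2, ctr)^2)
    }
    if (sse < best) best <- sse
  }
  best
}
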