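# Lloyd's K-means, written out in full: seeded Forgy initialization,
# nearest-centroid assignment under the Euclidean metric with lowest-index
# tie-breaking, per-cluster mean updates, deterministic empty-cluster repair,
# and a per-iteration inertia log. Squared distances are used internally
# (monotone equivalent); the exported distance returns the rooted value.

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Euclidean distance between two feature vectors
#'
#' `sqrt(sum((x - c)^2))` over the shared dimensions.
#'
#' @param x,c numeric vectors of equal length.
#' @return non-negative scalar.
#' @export
euclidean_distance <- function(x, c) {
  if (!is.numeric(x) || !is.numeric(c) || length(x) != length(c)) {
    stop_input("euclidean_distance requires numeric vectors of equal length")
  }
  sqrt(sum((x - c)^2))
}

# n x k matrix of squared Euclidean distances, computed per centroid without
# algebraic expansion so that exact ties stay exact.
squared_distances <- function(points, centroids) {
  n <- nrow(points)
  k <- nrow(centroids)
  d2 <- matrix(0, n, k)
  for (j in seq_len(k)) {
    diff <- points - matrix(centroids[j, ], n, ncol(points), byrow = TRUE)
    d2[, j] <- rowSums(diff * diff)
  }
  d2
}

#' Assign points to nearest centroids
#'
#' Each point maps to the centroid at minimal Euclidean distance; exact ties
#' break toward the lowest centroid index.
#'
#' @param points n x d numeric matrix.
#' @param centroids k x d numeric matrix.
#' @return integer vector of 1-based cluster indices, length n.
#' @export
assign_clusters <- function(points, centroids) {
  points <- as.matrix(points); centroids <- as.matrix(centroids)
  if (ncol(points) != ncol(centroids)) {
    stop_input("points and centroids must have the same number of columns")
  }
  max.col(-squared_distances(points, centroids), ties.method = "first")
}

#' Fit K-means by Lloyd iterations
#'
#' Alternates nearest-centroid assignment and per-cluster mean updates until
#' the maximum per-coordinate centroid displacement is at most `tol` or
#' `max_iter` is reached. Initialization samples `k` distinct input rows
#' (Forgy) from a dedicated RNG stream per start seed, so identical inputs and
#' seed give bit-identical models. A cluster emptied by an assignment step is
#' repaired by moving its centroid to the point currently farthest from its
#' assigned centroid. With `n_start > 1`, starts use seeds
#' `seed, seed + 1, ...`, an initialization that duplicates an earlier
#' start's point subset is redrawn so restarts explore distinct starting
#' subsets, and the lowest-inertia model wins (ties toward the earlier seed).
#'
#' @param points n x d numeric matrix, finite.
#' @param k number of clusters, `1 <= k <= n`.
#' @param seed integer seed for centroid initialization.
#' @param max_iter iteration cap (default 300).
#' @param tol convergence tolerance on centroid displacement (default 1e-4).
#' @param n_start number of seeded restarts.
#' @param init_centroids optional k x d matrix of explicit starting centroids
#'   (order-independent initialization); forces a single start.
#' @return object of class `cluster_model`: `centroids` (k x d),
#'   `assignments` (1-based), `inertia` (sum of squared point-to-centroid
#'   distances), `n_iter`, `seed`, `converged`, and `trajectory` (inertia
#'   logged after every assignment step).
#' @export
kmeans_fit <- function(points, k, seed = 0L, max_iter = 300L, tol = 1e-4,
                       n_start = 1L, init_centroids = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (!all(is.finite(points))) stop_input("kmeans_fit requires finite inputs")
  n <- nrow(points)
  if (k < 1 || k > n) stop_input("k must satisfy 1 <= k <= n (n = ", n, ")")
  if (!is.null(init_centroids)) {
    init_centroids <- as.matrix(init_centroids)
    if (nrow(init_centroids) != k || ncol(init_centroids) != ncol(points)) {
      stop_input("init_centroids must be a k x d matrix")
    }
    n_start <- 1L
  }

  best <- NULL
  seen <- character(0)
  for (s in seq_len(n_start) - 1L) {
    start_seed <- as.integer(seed) + s
    centroids <- if (is.null(init_centroids)) {
      idx <- with_seed(start_seed, {
        draw <- sample.int(n, k)
        # restarts should explore distinct starting subsets: redraw on
        # collision with an earlier start (bounded, deterministic)
        tries <- 0L
        while (paste(sort(draw), collapse = ",") %in% seen && tries < 50L) {
          draw <- sample.int(n, k)
          tries <- tries + 1L
        }
        draw
      })
      seen <- c(seen, paste(sort(idx), collapse = ","))
      points[idx, , drop = FALSE]
    } else {
      init_centroids
    }
    fit <- lloyd_iterate(points, centroids, max_iter, tol)
    fit$seed <- start_seed
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  best
}

lloyd_iterate <- function(points, centroids, max_iter, tol) {
  n <- nrow(points)
  k <- nrow(centroids)
  trajectory <- numeric(0)
  converged <- FALSE
  iter <- 0L
  assignments <- integer(n)

  while (iter < max_iter) {
    iter <- iter + 1L
    d2 <- squared_distances(points, centroids)
    assignments <- max.col(-d2, ties.method = "first")

    # deterministic repair: an empty cluster takes the point farthest from its
    # assigned centroid (strictly lowers inertia)
    repeat {
      sizes <- tabulate(assignments, nbins = k)
      empties <- which(sizes == 0L)
      if (length(empties) == 0L) break
      mind2 <- d2[cbind(seq_len(n), assignments)]
      far <- which.max(mind2)
      j <- empties[1L]
      centroids[j, ] <- points[far, ]
      d2[, j] <- rowSums((points - matrix(centroids[j, ], n, ncol(points),
                                          byrow = TRUE))^2)
      assignments <- max.col(-d2, ties.method = "first")
      assignments[far] <- j   # guard against a zero-distance tie with a lower index
    }

    trajectory <- c(trajectory, sum(d2[cbind(seq_len(n), assignments)]))

    new_centroids <- centroids
    for (j in seq_len(k)) {
      new_centroids[j, ] <- colMeans(points[assignments == j, , drop = FALSE])
    }
    shift <- max(abs(new_centroids - centroids))
    centroids <- new_centroids
    if (shift <= tol) { converged <- TRUE; break }
  }

  # final assignment so labels are consistent with the returned centroids
  d2 <- squared_distances(points, centroids)
  assignments <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(n), assignments)])

  structure(list(centroids = centroids, assignments = assignments,
                 inertia = inertia, n_iter = iter, seed = NA_integer_,
                 converged = converged, trajectory = trajectory),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d, d = %d, inertia %.6g, %d iteration(s)%s, seed %s\n",
              nrow(x$centroids), ncol(x$centroids), x$inertia, x$n_iter,
              if (x$converged) " (converged)" else "", format(x$seed)))
  invisible(x)
}
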