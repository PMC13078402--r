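# Interpretability geometry: k-means partition of the labeled audiograms
# into 23 groups and a deterministic 3D embedding of the 11-dimensional
# feature space, with out-of-sample placement of a new patient.

standardize_fit <- function(x) {
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ < 1e-12] <- 1
  list(center = center, scale = scale_)
}

standardize_apply <- function(x, std) {
  sweep(sweep(x, 2, std$center), 2, std$scale, "/")
}

# k-means++ seeding: first center uniform, subsequent centers drawn with
# probability proportional to squared distance from the nearest chosen
# center.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums(sweep(x, 2, centers[1L, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    prob <- d2 / sum(d2)
    idx <- sample.int(n, 1L, prob = prob)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

nearest_centroid <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers^2)) - 2 * x %*% t(centers)
  # lower cluster index wins ties
  apply(d2, 1, which.min)
}

#' Cluster audiograms into gene-sized groups
#'
#' Partitions feature vectors into `k` groups (default 23, matching the
#' gene panel size) with k-means: k-means++ seeding followed by Lloyd
#' iterations, repeated over `nstart` seeded restarts keeping the solution
#' with the lowest within-cluster sum of squares. Features are z-scored
#' per dimension by default (age in years and thresholds in dB are on
#' different scales). Final assignments are recomputed as each point's
#' nearest centroid, with the lower cluster index winning exact ties.
#'
#' @param x Numeric feature matrix (rows = audiograms; row names are
#'   audiogram ids).
#' @param k Number of clusters (default 23).
#' @param seed Integer seed (restart r uses `seed + r`).
#' @param nstart Number of seeded restarts (default 10).
#' @param standardize Z-score columns before clustering (default `TRUE`).
#' @return Object of class `"cluster_model"`: `centers` (k x p, in the
#'   standardized space), `assignments` (named integer vector), `inertia`,
#'   `std`, `k`, `seed`.
#' @export
fit_clusters <- function(x, k = 23L, seed = 1L, nstart = 10L,
                         standardize = TRUE) {
  x <- as.matrix(x)
  if (nrow(unique(x)) < k) {
    stop(sprintf("need at least k = %d distinct points, have %d",
                 k, nrow(unique(x))))
  }
  std <- if (standardize) standardize_fit(x) else
    list(center = rep(0, ncol(x)), scale = rep(1, ncol(x)))
  xs <- standardize_apply(x, std)
  best <- NULL
  for (r in seq_len(nstart)) {
    set.seed(seed + r)
    init <- kmeanspp_init(xs, k)
    km <- suppressWarnings(
      stats::kmeans(xs, centers = init, iter.max = 100L,
                    algorithm = "Lloyd")
    )
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  assign <- nearest_centroid(xs, best$centers)
  names(assign) <- rownames(x)
  inertia <- sum((xs - best$centers[assign, , drop = FALSE])^2)
  structure(
    list(centers = best$centers, assignments = assign, inertia = inertia,
         std = std, k = as.integer(k), seed = as.integer(seed)),
    class = "cluster_model"
  )
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d, %d points, inertia %.3f\n",
              x$k, length(x$assignments), x$inertia))
  invisible(x)
}

#' Embed audiograms into three dimensions
#'
#' Produces a deterministic neighbour-preserving 3D map of the
#' 11-dimensional feature space: classical metric scaling of the
#' standardized Euclidean distances initializes the configuration, which is
#' then refined by Sammon's nonlinear stress mapping (errors on small
#' distances are weighted up, preserving local neighbourhoods). Duplicate
#' feature rows are collapsed before stress refinement and share a
#' coordinate. The same seed (and input) always reproduces identical
#' coordinates.
#'
#' @param x Numeric feature matrix (row names are audiogram ids; at least
#'   10 rows).
#' @param n_neighbors Neighbourhood size used for out-of-sample placement
#'   (default 15; see [place_patient()]).
#' @param seed Integer seed, stored with the embedding.
#' @param niter Maximum Sammon iterations (default 100).
#' @param standardize Z-score columns first (default `TRUE`).
#' @return Object of class `"embedding3d"`: `coords` (n x 3), `train_x`
#'   (standardized features), `std`, `n_neighbors`, `seed`.
#' @export
embed3d <- function(x, n_neighbors = 15L, seed = 42L, niter = 100L,
                    standardize = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 10L) stop("embedding requires at least 10 points")
  std <- if (standardize) standardize_fit(x) else
    list(center = rep(0, ncol(x)), scale = rep(1, ncol(x)))
  xs <- standardize_apply(x, std)
  uniq <- !duplicated(xs)
  xu <- xs[uniq, , drop = FALSE]
  d <- stats::dist(xu)
  init <- stats::cmdscale(d, k = 3)
  if (ncol(init) < 3) {   # degenerate geometry: pad with zeros
    init <- cbind(init, matrix(0, nrow(init), 3 - ncol(init)))
  }
  coords_u <- if (nrow(xu) > 3L) {
    MASS::sammon(d, y = init, k = 3, niter = niter, trace = FALSE)$points
  } else init
  # map every row (incl. duplicates) to its unique representative's coords
  key <- apply(xs, 1, paste, collapse = "\r")
  coords <- coords_u[match(key, key[uniq]), , drop = FALSE]
  dimnames(coords) <- list(rownames(x), c("d1", "d2", "d3"))
  structure(
    list(coords = coords, train_x = xs, std = std,
         n_neighbors = as.integer(n_neighbors), seed = as.integer(seed)),
    class = "embedding3d"
  )
}

#' @export
print.embedding3d <- function(x, ...) {
  cat(sprintf("<embedding3d> %d points in 3 dimensions\n",
              nrow(x$coords)))
  invisible(x)
}

#' Cluster composition table
#'
#' Gene counts per cluster. Row marginals equal cluster sizes and the grand
#' total equals the number of labeled audiograms.
#'
#' @param model A [fit_clusters()] result.
#' @param labels Character vector of gene labels, named by audiogram id (or
#'   aligned with the model's assignments).
#' @return Integer matrix, clusters x genes.
#' @export
cluster_composition <- function(model, labels) {
  if (!is.null(names(labels))) labels <- labels[names(model$assignments)]
  stopifnot(length(labels) == length(model$assignments))
  t(table(
    gene = factor(labels),
    cluster = factor(model$assignments, levels = seq_len(model$k))
  ))
}

#' Place a new audiogram in the cluster/embedding geometry
#'
#' Assigns the audiogram to its nearest k-means centroid (lower index wins
#' ties) and computes its 3D coordinate by the embedding's out-of-sample
#' transform: the inverse-squared-distance weighted average of the
#' embedding coordinates of the `n_neighbors` nearest training audiograms
#' in the standardized feature space. An audiogram identical to a training
#' point receives that point's coordinate exactly.
#'
#' @param model A [fit_clusters()] result.
#' @param embedding An [embed3d()] result.
#' @param aud An audiogram (imputed internally if incomplete).
#' @return List with `cluster` (integer index) and `coords` (length-3
#'   numeric).
#' @export
place_patient <- function(model, embedding, aud) {
  aud <- impute_thresholds(aud)
  fv <- feature_vector(aud)
  xc <- matrix((fv - model$std$center) / model$std$scale, nrow = 1)
  cl <- nearest_centroid(xc, model$centers)
  xe <- (fv - embedding$std$center) / embedding$std$scale
  d2 <- rowSums(sweep(embedding$train_x, 2, xe)^2)
  if (min(d2) < 1e-16) {
    coords <- embedding$coords[which.min(d2), ]
  } else {
    k <- min(embedding$n_neighbors, length(d2))
    nb <- order(d2)[seq_len(k)]
    w <- 1 / d2[nb]
    coords <- colSums(embedding$coords[nb, , drop = FALSE] * w) / sum(w)
  }
  list(cluster = as.integer(cl), coords = as.numeric(coords))
}
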