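#' Standardize fraction profiles protein-wise
#'
#' Each protein's vector of fraction means is z-scored: the mean across
#' fractions is subtracted and the result divided by the sample (n-1)
#' standard deviation.  Constant profiles cannot be standardized and are
#' excluded (reported in the `"excluded"` attribute).
#'
#' @param means protein x fraction matrix of mean log2 intensities.
#' @return matrix of standardized profiles (rows: retained proteins) with
#'   attribute `"excluded"`: data.frame of dropped proteins and reasons.
#' @export
standardize_profiles <- function(means) {
  stopifnot(is.matrix(means), ncol(means) >= 2L)
  mu <- rowMeans(means)
  s <- apply(means, 1L, sd)
  keep <- s > 0 & is.finite(s)
  z <- (means[keep, , drop = FALSE] - mu[keep]) / s[keep]
  attr(z, "excluded") <- data.frame(
    protein_id = rownames(means)[!keep],
    reason = rep("zero_variance", sum(!keep)),
    stringsAsFactors = FALSE
  )
  z
}

# squared Euclidean distances between rows of a and rows of b
.cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0  # numerical guard
  d2
}

#' Train a batch self-organizing map on standardized profiles
#'
#' A rectangular SOM grid trained with the deterministic batch rule: each
#' epoch assigns every profile to its nearest codebook (Euclidean distance)
#' and recomputes each codebook as the Gaussian-neighborhood-weighted mean of
#' all profiles.  The neighborhood width decays linearly from `sigma0`
#' (default half the larger grid dimension) to `sigma_final` over the
#' epochs.  Codebooks are initialized from a seeded sample of the data, so
#' the same seed reproduces the model exactly.
#'
#' @param z matrix of standardized profiles (proteins x fractions).
#' @param grid integer vector `c(rows, cols)`; default `c(4, 3)` gives the
#'   12 basic units.
#' @param seed integer RNG seed for the initialization.
#' @param epochs number of batch epochs.
#' @param sigma0,sigma_final initial and final neighborhood standard
#'   deviations, in grid units.
#' @return a `som_model`: list with `grid`, `codebooks` (units x fractions),
#'   `assignment` (named unit index per protein), `distance` (Euclidean
#'   distance to the assigned codebook), `unit_coords`, and the training
#'   hyperparameters.
#' @export
train_som <- function(z, grid = c(4L, 3L), seed = 1L, epochs = 500L,
                      sigma0 = NULL, sigma_final = 0.3) {
  stopifnot(is.matrix(z), length(grid) == 2L, all(grid >= 1L), epochs >= 1L)
  n_units <- prod(grid)
  if (is.null(sigma0)) sigma0 <- max(grid) / 2
  coords <- as.matrix(expand.grid(row = seq_len(grid[1L]),
                                  col = seq_len(grid[2L])))
  grid_d2 <- .cross_dist2(coords, coords)

  init_idx <- with_seed_if(seed,
    sample.int(nrow(z), n_units, replace = nrow(z) < n_units))
  w <- z[init_idx, , drop = FALSE]
  rownames(w) <- paste0("unit", seq_len(n_units))

  for (e in seq_len(epochs)) {
    sigma <- if (epochs == 1L) sigma_final else
      sigma0 + (sigma_final - sigma0) * (e - 1) / (epochs - 1)
    bmu <- max.col(-.cross_dist2(z, w), ties.method = "first")
    h <- exp(-grid_d2 / (2 * sigma^2))          # units x units
    a <- h[bmu, , drop = FALSE]                  # proteins x units
    den <- colSums(a)
    num <- crossprod(a, z)                       # units x fractions
    upd <- den > 1e-12
    w[upd, ] <- num[upd, , drop = FALSE] / den[upd]
  }

  d2 <- .cross_dist2(z, w)
  bmu <- max.col(-d2, ties.method = "first")
  dist <- sqrt(d2[cbind(seq_len(nrow(z)), bmu)])
  structure(list(
    grid = as.integer(grid), codebooks = w,
    assignment = setNames(bmu, rownames(z)),
    distance = setNames(dist, rownames(z)),
    unit_coords = coords, seed = seed, epochs = as.integer(epochs),
    sigma0 = sigma0, sigma_final = sigma_final
  ), class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("som_model: %dx%d grid, %d proteins, %d epochs (seed %s)\n",
              x$grid[1L], x$grid[2L], length(x$assignment), x$epochs,
              format(x$seed)))
  invisible(x)
}

#' Merge low-quality SOM units into an uncategorized pool
#'
#' The merge threshold is the given percentile of *all* protein-to-assigned-
#' codebook distances.  Every non-empty unit whose members' mean distance
#' exceeds the threshold is dissolved: its members move to the
#' `uncategorized` pool.  The remaining non-empty units become the profile
#' clusters, renumbered in unit order.
#'
#' @param som a trained `som_model`.
#' @param percentile merge percentile (default 75).
#' @return a `cluster_set`: list with `clusters` (named list, cluster id ->
#'   member protein ids), `cluster_units` (originating unit per cluster),
#'   `uncategorized` (protein ids), `threshold`, `percentile`.
#' @export
merge_low_quality <- function(som, percentile = 75) {
  stopifnot(inherits(som, "som_model"), percentile >= 0, percentile <= 100)
  thr <- quantile(som$distance, percentile / 100, names = FALSE, type = 7)
  units <- sort(unique(som$assignment))
  members <- split(names(som$assignment), som$assignment)
  mean_d <- vapply(members, function(ids) mean(som$distance[ids]), 0)
  dissolve <- mean_d > thr
  uncategorized <- unlist(members[dissolve], use.names = FALSE)
  kept <- members[!dissolve]
  clusters <- setNames(kept, paste0("cluster", seq_along(kept)))
  structure(list(
    clusters = clusters,
    cluster_units = setNames(as.integer(names(kept)), names(clusters)),
    uncategorized = if (is.null(uncategorized)) character(0) else uncategorized,
    threshold = thr, percentile = percentile,
    unit_mean_distance = mean_d
  ), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters (sizes %s), %d uncategorized\n",
              length(x$clusters),
              paste(lengths(x$clusters), collapse = ", "),
              length(x$uncategorized)))
  invisible(x)
}

#' Two-component principal component scores
#'
#' Centered (not scaled) PCA; components are ordered by explained variance
#' and the sign of each component is fixed so that its largest-magnitude
#' loading is positive.
#'
#' @param x numeric matrix (observations x variables), >= 2 rows.
#' @return list with `scores` (n x 2), `loadings` (p x 2),
#'   `explained_variance` (all components).
#' @export
pca_2d <- function(x) {
  stopifnot(is.matrix(x), nrow(x) >= 2L)
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(p$rotation))
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  sco <- p$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  if (k < 2L) {  # degenerate single-variable input
    sco <- cbind(sco, 0)
    colnames(sco) <- c("PC1", "PC2")
  }
  list(scores = sco, loadings = rot, explained_variance = p$sdev^2)
}

# exact shortest open Hamiltonian path by Held-Karp dynamic programming
.shortest_open_path <- function(d) {
  n <- nrow(d)
  if (n == 1L) return(1L)
  full <- bitwShiftL(1L, n) - 1L
  cost <- matrix(Inf, full, n)
  parent <- matrix(NA_integer_, full, n)
  for (j in seq_len(n)) cost[bitwShiftL(1L, j - 1L), j] <- 0
  for (s in seq_len(full)) {
    in_s <- which(bitwAnd(s, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    if (length(in_s) < 2L) next
    for (j in in_s) {
      s_prev <- bitwAnd(s, bitwNot(bitwShiftL(1L, j - 1L)))
      prev <- setdiff(in_s, j)
      c_new <- cost[s_prev, prev] + d[prev, j]
      best <- which.min(c_new)
      if (c_new[best] < cost[s, j]) {
        cost[s, j] <- c_new[best]
        parent[s, j] <- prev[best]
      }
    }
  }
  end <- which.min(cost[full, ])
  path <- integer(n)
  s <- full
  for (i in n:1) {
    path[i] <- end
    nxt <- parent[s, end]
    s <- bitwAnd(s, bitwNot(bitwShiftL(1L, end - 1L)))
    end <- nxt
  }
  path
}

#' Order clusters along the shortest path in PCA space
#'
#' Finds the exact shortest open Hamiltonian path (traveling-salesman path)
#' through the clusters' 2-D PCA coordinates, giving a linear display order
#' in which adjacent clusters have similar profiles.  Orientation is fixed:
#' of the path's two endpoints, the one with the smaller first-component
#' coordinate comes first.
#'
#' @param points cluster x 2 matrix of PCA coordinates, rownames = cluster
#'   ids; at most 12 clusters.
#' @return character vector of cluster ids in display order, with attribute
#'   `"path_length"`.
#' @export
order_clusters_tsp <- function(points) {
  stopifnot(is.matrix(points), ncol(points) >= 2L)
  n <- nrow(points)
  if (n > 12L) stop("exact path ordering supports at most 12 clusters",
                    call. = FALSE)
  ids <- rownames(points)
  if (n == 1L) {
    out <- ids
    attr(out, "path_length") <- 0
    return(out)
  }
  d <- as.matrix(dist(points[, 1:2, drop = FALSE]))
  path <- .shortest_open_path(d)
  if (points[path[n], 1L] < points[path[1L], 1L]) path <- rev(path)
  out <- ids[path]
  attr(out, "path_length") <- sum(d[cbind(path[-n], path[-1L])])
  out
}

#' Median standardized profile of each cluster
#'
#' @param clusterset a `cluster_set`.
#' @param z matrix of standardized profiles covering all cluster members.
#' @return cluster x fraction matrix of per-fraction member medians.
#' @export
median_profiles <- function(clusterset, z) {
  stopifnot(inherits(clusterset, "cluster_set"), is.matrix(z))
  t(vapply(clusterset$clusters, function(ids) {
    apply(z[ids, , drop = FALSE], 2L, median)
  }, numeric(ncol(z))))
}
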