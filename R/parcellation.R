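# K-means parcellation of the group connectivity-profile matrix with
# correlation distance, restart selection, small-component cleanup, and
# parcellation comparison metrics.

# rows centered to zero mean and scaled to unit L2 norm; the correlation
# distance between two such rows is 1 - their dot product.
standardize_rows <- function(X) {
  X <- X - rowMeans(X)
  n <- sqrt(rowSums(X^2))
  if (any(n < .Machine$double.eps))
    stop("constant profile row: correlation distance undefined")
  X / n
}

#' K-means clustering with correlation distance
#'
#' Clusters the rows of a connectivity-profile matrix with Lloyd's
#' algorithm under correlation distance d(x, c) = 1 - cor(x, c): rows are
#' centered and unit-normalized once, centroids are means of their
#' members' standardized rows, re-standardized after every update. The
#' solution with the lowest total within-cluster point-to-centroid
#' distance (inertia) over \code{n_restarts} random initializations is
#' returned. Ties in the nearest-centroid assignment go to the lowest
#' cluster index; a restart that empties a cluster re-seeds that centroid
#' at the row farthest from its centroid. Deterministic given
#' \code{rng_seed}.
#'
#' @param profiles a \code{\link{connectivity_profiles}} or a plain
#'   numeric matrix (rows = seed voxels, columns = targets).
#' @param K number of clusters (<= number of rows).
#' @param n_restarts number of random initializations.
#' @param rng_seed integer seed; restart r uses a sub-seed derived from
#'   (rng_seed, K, r).
#' @param max_iter Lloyd iteration cap per restart.
#' @return Object of class \code{parcellation}: \code{labels} (1..K),
#'   \code{K}, \code{inertia}, \code{centroids}, \code{restart_inertias},
#'   \code{n_reseeded}, \code{n_restarts}, \code{rng_seed}.
#' @export
kmeans_correlation <- function(profiles, K, n_restarts = 100,
                               rng_seed = 1L, max_iter = 100) {
  X <- if (inherits(profiles, "connectivity_profiles"))
    profiles$z_matrix else as.matrix(profiles)
  V <- nrow(X)
  if (K > V) stop("K exceeds the number of seed voxels")
  if (ncol(X) < 2) stop("need at least 2 target columns")
  Xs <- standardize_rows(X)
  best <- NULL
  restart_inertias <- numeric(n_restarts)
  n_reseeded <- 0L
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(derive_seed(rng_seed, "kmeans", K, r),
                     lloyd_correlation(Xs, K, max_iter))
    restart_inertias[r] <- fit$inertia
    n_reseeded <- n_reseeded + fit$n_reseeded
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  structure(list(labels = best$labels, K = as.integer(K),
                 inertia = best$inertia, centroids = best$centroids,
                 restart_inertias = restart_inertias,
                 n_reseeded = n_reseeded,
                 n_restarts = as.integer(n_restarts),
                 rng_seed = as.integer(rng_seed)),
            class = "parcellation")
}

# one Lloyd run on pre-standardized rows
lloyd_correlation <- function(Xs, K, max_iter) {
  V <- nrow(Xs)
  C <- Xs[sample.int(V, K), , drop = FALSE]
  labels <- integer(V)
  n_reseeded <- 0L
  for (it in seq_len(max_iter)) {
    sim <- Xs %*% t(C)                      # cor(x, c); distance = 1 - sim
    new_labels <- max.col(sim, ties.method = "first")
    for (k in seq_len(K)) {                 # re-seed empty clusters
      if (!any(new_labels == k)) {
        # move the point farthest from its centroid, never emptying
        # another cluster in the process
        d_own <- 1 - sim[cbind(seq_len(V), new_labels)]
        sizes <- tabulate(new_labels, K)
        d_own[sizes[new_labels] <= 1L] <- -Inf
        far <- which.max(d_own)
        new_labels[far] <- k
        n_reseeded <- n_reseeded + 1L
      }
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    C <- t(sapply(seq_len(K), function(k)
      colMeans(Xs[labels == k, , drop = FALSE])))
    C <- standardize_rows(C)
  }
  sim <- Xs %*% t(C)
  inertia <- sum(1 - sim[cbind(seq_len(V), labels)])
  list(labels = labels, centroids = C, inertia = inertia,
       n_reseeded = n_reseeded)
}

# connected components of a voxel set under face (6), edge (18) or corner
# (26) connectivity; coords are integer (n x 3). Returns component ids.
connected_components <- function(coords, connectivity = 6) {
  n <- nrow(coords)
  if (n == 0L) return(integer(0))
  offs <- neighbor_offsets(connectivity)
  key <- function(xyz) paste(xyz[, 1], xyz[, 2], xyz[, 3])
  lookup <- new.env(hash = TRUE, size = n)
  ks <- key(coords)
  for (i in seq_len(n)) assign(ks[i], i, envir = lookup)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- sweep(offs, 2, as.numeric(coords[v, ]), `+`)
      for (k in key(nb)) {
        j <- lookup[[k]]
        if (!is.null(j) && comp[j] == 0L) {
          comp[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  comp
}

neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  d <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = d == 1, "18" = d >= 1 & d <= 2, "26" = d >= 1,
                 stop("connectivity must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

#' Flag isolated voxels within each cluster
#'
#' Within each cluster's voxel set, connected components (under the given
#' connectivity) smaller than \code{min_component} voxels are flagged as
#' isolated. Flagged voxels keep their label but are excluded from
#' cluster-mean time series and exported seed masks; they are not
#' reassigned to another cluster.
#'
#' @param parcellation a \code{\link{kmeans_correlation}} result or an
#'   integer label vector.
#' @param coords integer matrix (voxels x 3) of grid coordinates aligned
#'   with the labels.
#' @param connectivity 6, 18 or 26.
#' @param min_component smallest component size kept.
#' @return list with \code{labels}, \code{flagged} (logical), and
#'   \code{component_sizes} (per-voxel size of its component).
#' @export
remove_isolated_voxels <- function(parcellation, coords, connectivity = 6,
                                   min_component = 3) {
  labels <- if (inherits(parcellation, "parcellation"))
    parcellation$labels else as.integer(parcellation)
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(labels))
  flagged <- logical(length(labels))
  sizes <- integer(length(labels))
  for (k in sort(unique(labels))) {
    idx <- which(labels == k)
    comp <- connected_components(coords[idx, , drop = FALSE], connectivity)
    cs <- table(comp)
    sizes[idx] <- as.integer(cs[as.character(comp)])
    flagged[idx] <- sizes[idx] < min_component
  }
  list(labels = labels, flagged = flagged, component_sizes = sizes)
}

# maximum-trace assignment on a (padded square) contingency table by
# bitmask dynamic programming over columns; exact for K up to ~20.
max_assignment_total <- function(tab) {
  k <- max(dim(tab))
  M <- matrix(0, k, k)
  M[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  best <- rep(-Inf, 2^k)
  best[1] <- 0
  for (mask in 0:(2^k - 1)) {
    if (!is.finite(best[mask + 1])) next
    row <- sum(bitwAnd(mask, 2^(0:(k - 1))) > 0) + 1L
    if (row > k) next
    for (col in seq_len(k)) {
      bit <- 2^(col - 1)
      if (bitwAnd(mask, bit) == 0) {
        nm <- mask + bit
        cand <- best[mask + 1] + M[row, col]
        if (cand > best[nm + 1]) best[nm + 1] <- cand
      }
    }
  }
  best[2^k]
}

#' Percent agreement between two parcellations under optimal label matching
#'
#' Builds the K_a x K_b contingency table and finds the label matching
#' (optimal one-to-one assignment) that maximizes the number of voxels on
#' which the two parcellations agree; returns that number as a percentage
#' of all voxels. Invariant to label permutations.
#'
#' @param parcellation_a,parcellation_b \code{\link{kmeans_correlation}}
#'   results or label vectors over the same voxel set.
#' @return percent agreement in [0, 100].
#' @export
label_agreement <- function(parcellation_a, parcellation_b) {
  a <- if (inherits(parcellation_a, "parcellation"))
    parcellation_a$labels else as.integer(parcellation_a)
  b <- if (inherits(parcellation_b, "parcellation"))
    parcellation_b$labels else as.integer(parcellation_b)
  if (length(a) != length(b))
    stop("parcellations cover different voxel sets")
  tab <- table(a, b)
  100 * max_assignment_total(tab) / length(a)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two labelings, computed from the
#' contingency table; 1 for identical partitions (up to relabeling),
#' approximately 0 for independent ones.
#'
#' @param labels_a,labels_b label vectors of equal length.
#' @return numeric scalar in (-1, 1].
#' @export
adjusted_rand <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors differ in length")
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (abs(max_index - expected) < .Machine$double.eps) return(1)
  (sum_ij - expected) / (max_index - expected)
}
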