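# Seed-to-voxel connectivity maps of the parcels: per-subject simultaneous
# multiple regression on the cluster-mean time series, group-level
# random-effect one-sample t tests, and permutation (sign-flip)
# cluster-extent correction.

#' Cluster-mean time series of a parcellated seed region
#'
#' Row k is the mean series over the (non-flagged) voxels of cluster k.
#' Voxels flagged as isolated by \code{\link{remove_isolated_voxels}} are
#' excluded from the mean.
#'
#' @param subject a \code{\link{subject_timeseries}}.
#' @param parcellation a \code{\link{kmeans_correlation}} result, label
#'   vector, or \code{\link{remove_isolated_voxels}} output on the
#'   subject's seed-voxel ordering.
#' @return K x T matrix (row k = cluster k).
#' @export
cluster_mean_timeseries <- function(subject, parcellation) {
  stopifnot(inherits(subject, "subject_timeseries"))
  if (is.list(parcellation) && !is.null(parcellation$flagged)) {
    labels <- parcellation$labels
    flagged <- parcellation$flagged
  } else {
    labels <- if (inherits(parcellation, "parcellation"))
      parcellation$labels else as.integer(parcellation)
    flagged <- logical(length(labels))
  }
  stopifnot(length(labels) == nrow(subject$roi_series))
  ks <- sort(unique(labels))
  out <- matrix(NA_real_, length(ks), ncol(subject$roi_series))
  for (i in seq_along(ks)) {
    idx <- which(labels == ks[i] & !flagged)
    if (!length(idx))
      stop(sprintf("cluster %d has no voxels left after cleanup", ks[i]))
    out[i, ] <- colMeans(subject$roi_series[idx, , drop = FALSE])
  }
  rownames(out) <- paste0("cluster", ks)
  out
}

#' Simultaneous seed regression of target voxels on cluster series
#'
#' Ordinary least squares of every target voxel's series on all K
#' cluster-mean series entered together (plus an intercept), so each beta
#' reflects the variance a cluster explains uniquely, after fitting the
#' other clusters.
#'
#' @param target_series V x T matrix.
#' @param cluster_series K x T matrix of regressors (K < T).
#' @return V x K matrix of partial slopes (intercept not returned).
#' @export
seed_glm <- function(target_series, cluster_series) {
  Y <- t(as.matrix(target_series))              # T x V
  Xr <- t(as.matrix(cluster_series))            # T x K
  if (ncol(Xr) >= nrow(Xr)) stop("need K < T")
  X <- cbind(intercept = 1, Xr)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient design; collinear regressors: %s",
                 paste(dropped, collapse = ", ")))
  }
  B <- qr.coef(qrX, Y)                          # (K+1) x V
  t(B[-1, , drop = FALSE])
}

#' Group-level one-sample t test across subjects
#'
#' Per voxel, t = mean / (sd / sqrt(N)) over subjects with df = N - 1 and
#' a two-sided p. Voxels with zero variance across subjects get
#' non-finite t and are excluded from any downstream thresholding.
#'
#' @param subject_betas N x V matrix (one row per subject).
#' @return list with \code{mean}, \code{t}, \code{p} (length-V vectors),
#'   \code{df}, \code{n}.
#' @export
group_onesample_t <- function(subject_betas) {
  B <- as.matrix(subject_betas)
  N <- nrow(B)
  if (N < 3) stop("need at least 3 subjects")
  mu <- colMeans(B)
  sdv <- apply(B, 2, stats::sd)
  tval <- ifelse(sdv > 0, mu / (sdv / sqrt(N)), NaN)
  p <- 2 * stats::pt(-abs(tval), df = N - 1)
  list(mean = mu, t = tval, p = p, df = N - 1, n = N)
}

# suprathreshold clusters of one sign: list of (voxel indices, size, peak)
suprathreshold_clusters <- function(tval, coords, t_crit, connectivity) {
  idx <- which(is.finite(tval) & tval > t_crit)
  if (!length(idx)) return(list())
  comp <- connected_components(coords[idx, , drop = FALSE], connectivity)
  lapply(split(idx, comp), function(members) {
    peak <- members[which.max(tval[members])]
    list(members = members, size = length(members), peak = peak)
  })
}

# max suprathreshold cluster size over both signs for one t map
max_cluster_size <- function(tval, coords, t_crit, connectivity) {
  sizes <- c(vapply(suprathreshold_clusters(tval, coords, t_crit,
                                            connectivity),
                    `[[`, 0L, "size"),
             vapply(suprathreshold_clusters(-tval, coords, t_crit,
                                            connectivity),
                    `[[`, 0L, "size"))
  if (length(sizes)) max(sizes) else 0L
}

#' Permutation cluster-extent correction by subject sign flipping
#'
#' Thresholds the group t map voxelwise (one-sided \code{voxel_p} per
#' sign), forms connected suprathreshold clusters, and compares each
#' observed cluster's size with the null distribution of the maximum
#' cluster size obtained by randomly sign-flipping whole subject maps and
#' recomputing the t map. Corrected p = (1 + #\{null >= size\}) /
#' (1 + n_perm); clusters with corrected p <= \code{fwe_alpha} are marked
#' significant. Positive and negative clusters are reported separately;
#' the null maximum is taken over both signs, so the correction is
#' familywise over both maps.
#'
#' @param subject_betas N x V matrix of per-subject voxel maps.
#' @param coords integer V x 3 voxel coordinates.
#' @param voxel_p one-sided voxel-level threshold per sign.
#' @param fwe_alpha familywise significance level on cluster size.
#' @param n_perm number of sign-flip permutations (>= 100 recommended).
#' @param connectivity 6, 18 or 26.
#' @param rng_seed integer seed for the sign flips.
#' @return list with \code{clusters} (data.frame: sign, size, peak
#'   coordinate, corrected_p, significant), \code{members} (list of voxel
#'   index vectors), \code{t} (observed t map), \code{t_crit},
#'   \code{null_max_sizes}.
#' @export
cluster_extent_correct <- function(subject_betas, coords,
                                   voxel_p = 0.001, fwe_alpha = 0.05,
                                   n_perm = 1000, connectivity = 6,
                                   rng_seed = 1L) {
  B <- as.matrix(subject_betas)
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == ncol(B))
  if (n_perm < 100)
    warning("n_perm < 100: null tail estimate will be unstable")
  N <- nrow(B)
  obs <- group_onesample_t(B)
  t_crit <- stats::qt(1 - voxel_p, df = N - 1)

  null_max <- with_seed(derive_seed(rng_seed, "signflip"), {
    vapply(seq_len(n_perm), function(i) {
      flips <- sample(c(-1, 1), N, replace = TRUE)
      Bp <- B * flips
      tp <- group_onesample_t(Bp)$t
      max_cluster_size(tp, coords, t_crit, connectivity)
    }, 0L)
  })

  rows <- list(); members <- list()
  for (sgn in c(1, -1)) {
    cl <- suprathreshold_clusters(sgn * obs$t, coords, t_crit, connectivity)
    for (c_i in cl) {
      p_corr <- (1 + sum(null_max >= c_i$size)) / (1 + n_perm)
      rows[[length(rows) + 1]] <- data.frame(
        sign = if (sgn > 0) "positive" else "negative",
        size = c_i$size,
        peak_x = coords[c_i$peak, 1], peak_y = coords[c_i$peak, 2],
        peak_z = coords[c_i$peak, 3],
        corrected_p = p_corr, significant = p_corr <= fwe_alpha)
      members[[length(members) + 1]] <- c_i$members
    }
  }
  clusters <- if (length(rows)) do.call(rbind, rows)
  else data.frame(sign = character(0), size = integer(0),
                  peak_x = integer(0), peak_y = integer(0),
                  peak_z = integer(0), corrected_p = numeric(0),
                  significant = logical(0))
  list(clusters = clusters, members = members, t = obs$t,
       t_crit = t_crit, null_max_sizes = null_max)
}

#' Seed-to-voxel connectivity maps for every cluster of a parcellation
#'
#' Runs \code{\link{seed_glm}} per subject on the cluster-mean series,
#' then \code{\link{group_onesample_t}} and
#' \code{\link{cluster_extent_correct}} per cluster.
#'
#' @param subjects list of \code{\link{subject_timeseries}}.
#' @param parcellation labels / parcellation / cleanup result shared by
#'   all subjects.
#' @param coords target-voxel coordinates (defaults to the first
#'   subject's \code{target_coords}).
#' @param ... passed to \code{\link{cluster_extent_correct}}.
#' @return named list (one entry per cluster) of
#'   \code{\link{cluster_extent_correct}} results, each with the group
#'   stats under \code{group}.
#' @export
fc_map_pipeline <- function(subjects, parcellation, coords = NULL, ...) {
  betas <- lapply(subjects, function(s)
    seed_glm(s$target_series, cluster_mean_timeseries(s, parcellation)))
  K <- ncol(betas[[1]])
  if (is.null(coords)) coords <- subjects[[1]]$target_coords
  out <- vector("list", K)
  for (k in seq_len(K)) {
    Bk <- t(vapply(betas, function(b) b[, k], numeric(nrow(betas[[1]]))))
    res <- cluster_extent_correct(Bk, coords, ...)
    res$group <- group_onesample_t(Bk)
    out[[k]] <- res
  }
  names(out) <- paste0("cluster", seq_len(K))
  out
}
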