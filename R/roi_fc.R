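# ROI-to-ROI functional connectivity between parcel time series and
# atlas-region time series, with Benjamini-Hochberg FDR control over the
# full table of (cluster, region) pairs.

#' Region-mean time series from target voxels
#'
#' Row r is the mean series over the target voxels carrying region label
#' r. Regions with no voxels in the target set are dropped with a
#' warning.
#'
#' @param target_series V x T matrix.
#' @param region_labels length-V integer vector assigning each target
#'   voxel to a region (0 = unassigned).
#' @param region_ids regions to extract (default: all nonzero labels
#'   present).
#' @return R x T matrix with rownames \code{region_<id>}.
#' @export
roi_timeseries <- function(target_series, region_labels,
                           region_ids = NULL) {
  X <- as.matrix(target_series)
  region_labels <- as.integer(region_labels)
  stopifnot(length(region_labels) == nrow(X))
  if (is.null(region_ids))
    region_ids <- sort(unique(region_labels[region_labels > 0]))
  present <- region_ids[region_ids %in% region_labels]
  absent <- setdiff(region_ids, present)
  if (length(absent))
    warning(sprintf("region(s) with no voxels in the target set: %s",
                    paste(absent, collapse = ", ")))
  if (!length(present)) stop("no region has voxels in the target set")
  out <- t(vapply(present, function(r)
    colMeans(X[region_labels == r, , drop = FALSE]), numeric(ncol(X))))
  rownames(out) <- paste0("region_", present)
  out
}

#' Atlas labels at voxel coordinates
#'
#' @param atlas an \code{\link{atlas_volume}}.
#' @param coords integer n x 3 matrix of 0-based voxel coordinates on the
#'   atlas grid.
#' @return integer vector of labels (0 outside the grid).
#' @export
atlas_labels_at <- function(atlas, coords) {
  stopifnot(inherits(atlas, "atlas_volume"))
  coords <- as.matrix(coords)
  d <- dim(atlas$labels)
  inside <- coords[, 1] >= 0 & coords[, 1] < d[1] &
    coords[, 2] >= 0 & coords[, 2] < d[2] &
    coords[, 3] >= 0 & coords[, 3] < d[3]
  out <- integer(nrow(coords))
  lin <- 1L + coords[inside, 1] + d[1] * (coords[inside, 2] +
                                            d[2] * coords[inside, 3])
  out[inside] <- as.integer(atlas$labels[lin])
  out
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up rule: with p-values sorted ascending, reject hypotheses 1..i*
#' where i* is the largest i with p_(i) <= i q / m. Returned q values are
#' the monotone BH-adjusted p-values; the reject flags equal
#' \code{q <= q_threshold}.
#'
#' @param p_values numeric vector in [0, 1].
#' @param q_threshold FDR level.
#' @return list with \code{q_values} and \code{reject} (logical).
#' @export
bh_fdr <- function(p_values, q_threshold = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  q <- stats::p.adjust(p_values, method = "BH")
  list(q_values = q, reject = !is.na(q) & q <= q_threshold)
}

#' ROI-to-ROI functional connectivity table
#'
#' For every (cluster, region) pair: per-subject Pearson correlation
#' between the cluster-mean and region-mean series, Fisher z, a one-sample
#' t test of the z values across subjects (two-sided), and BH-FDR over all
#' pairs in the table. Pairs in which any subject has a constant series
#' are excluded with a warning.
#'
#' @param cluster_series_list per-subject K x T matrices (cluster-mean
#'   series, identical row order across subjects).
#' @param region_series_list per-subject R x T matrices (region-mean
#'   series).
#' @param q_threshold FDR level for the significant flag.
#' @return data.frame of class \code{roi_fc_table} with columns
#'   \code{cluster}, \code{region}, \code{mean_z}, \code{t}, \code{p},
#'   \code{q}, \code{significant}.
#' @export
roi_roi_fc <- function(cluster_series_list, region_series_list,
                       q_threshold = 0.05) {
  n <- length(cluster_series_list)
  stopifnot(n == length(region_series_list), n >= 3)
  K <- nrow(cluster_series_list[[1]])
  R <- nrow(region_series_list[[1]])
  cl_names <- rownames(cluster_series_list[[1]]) %||%
    paste0("cluster", seq_len(K))
  rg_names <- rownames(region_series_list[[1]]) %||%
    paste0("region", seq_len(R))
  rows <- list()
  for (k in seq_len(K)) {
    for (r in seq_len(R)) {
      z <- rep(NA_real_, n)
      ok <- TRUE
      for (s in seq_len(n)) {
        x <- cluster_series_list[[s]][k, ]
        y <- region_series_list[[s]][r, ]
        if (stats::sd(x) < .Machine$double.eps ||
            stats::sd(y) < .Machine$double.eps) { ok <- FALSE; break }
        z[s] <- fisher_z(stats::cor(x, y))
      }
      if (!ok) {
        warning(sprintf("pair (%s, %s) excluded: constant series",
                        cl_names[k], rg_names[r]))
        next
      }
      sdz <- stats::sd(z)
      tval <- if (sdz > 0) mean(z) / (sdz / sqrt(n)) else
        sign(mean(z)) * Inf
      p <- 2 * stats::pt(-abs(tval), df = n - 1)
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cl_names[k], region = rg_names[r],
        mean_z = mean(z), t = tval, p = p)
    }
  }
  tab <- do.call(rbind, rows)
  fdr <- bh_fdr(tab$p, q_threshold)
  tab$q <- fdr$q_values
  tab$significant <- fdr$reject
  class(tab) <- c("roi_fc_table", "data.frame")
  tab
}
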