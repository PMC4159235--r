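# Connectivity profiles: seed-voxel x target-voxel Pearson correlation,
# Fisher z transform, and group averaging.

#' Seed-voxel by target-voxel correlation matrix
#'
#' Entry (i, j) is the Pearson correlation between seed voxel i's series
#' and target voxel j's series. Zero-variance voxels yield a zero row or
#' column (with a warning) rather than being dropped, so voxel indexing
#' stays stable across subjects.
#'
#' @param roi_series seed voxels x frames matrix.
#' @param target_series target voxels x frames matrix (same frame count).
#' @return V_roi x V_target matrix of correlations in [-1, 1].
#' @export
voxel_profile_matrix <- function(roi_series, target_series) {
  A <- as.matrix(roi_series)
  B <- as.matrix(target_series)
  if (ncol(A) != ncol(B)) stop("series must share the number of frames")
  sa <- apply(A, 1, stats::sd)
  sb <- apply(B, 1, stats::sd)
  bad_a <- sa < .Machine$double.eps
  bad_b <- sb < .Machine$double.eps
  if (any(bad_a) || any(bad_b)) {
    warning(sprintf("%d zero-variance voxel(s); rows/columns set to 0",
                    sum(bad_a) + sum(bad_b)))
    # non-constant placeholder keeps cor() quiet; rows are zeroed below
    A[bad_a, ] <- rep(seq_len(ncol(A)), each = sum(bad_a))
    B[bad_b, ] <- rep(seq_len(ncol(B)), each = sum(bad_b))
  }
  R <- stats::cor(t(A), t(B))
  R[bad_a, ] <- 0
  R[, bad_b] <- 0
  pmin(pmax(R, -1), 1)
}

#' Fisher z transform
#'
#' \code{z = atanh(r)}, with |r| clamped to 1 - 1e-7 before the transform
#' so perfectly correlated pairs stay finite. Strictly increasing and odd.
#'
#' @param r correlations, any shape; |r| must not exceed 1 (beyond 1e-9
#'   rounding slack).
#' @return object of the same shape.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-9, na.rm = TRUE))
    stop("correlations outside [-1, 1]")
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' Connectivity-profile container
#'
#' @param z_matrix seed voxels x target voxels matrix of Fisher z values.
#' @param level \code{"subject"} or \code{"group"}.
#' @param subjects character vector of the subject ids the matrix
#'   represents (one id at subject level; all averaged ids at group level).
#' @return Object of class \code{connectivity_profiles}.
#' @export
connectivity_profiles <- function(z_matrix, level = c("subject", "group"),
                                  subjects = character(0)) {
  z_matrix <- as.matrix(z_matrix)
  if (!all(is.finite(z_matrix))) stop("z matrix must be finite")
  structure(list(z_matrix = z_matrix, level = match.arg(level),
                 subjects = subjects),
            class = "connectivity_profiles")
}

#' Subject-level connectivity profiles from time series
#'
#' Convenience wrapper: Pearson profile matrix then Fisher z.
#'
#' @param subject a \code{\link{subject_timeseries}}.
#' @return a subject-level \code{\link{connectivity_profiles}}.
#' @export
subject_profiles <- function(subject) {
  stopifnot(inherits(subject, "subject_timeseries"))
  connectivity_profiles(
    fisher_z(voxel_profile_matrix(subject$roi_series,
                                  subject$target_series)),
    level = "subject", subjects = subject$subject_id)
}

#' Group-average connectivity profiles
#'
#' Elementwise arithmetic mean of the subjects' Fisher z matrices;
#' provenance records the averaged subject ids. Order of subjects does not
#' affect the result.
#'
#' @param profiles list of subject-level
#'   \code{\link{connectivity_profiles}} with identical dimensions and
#'   voxel ordering.
#' @return a group-level \code{\link{connectivity_profiles}}.
#' @export
group_average <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  d1 <- dim(profiles[[1]]$z_matrix)
  for (i in seq_along(profiles)) {
    di <- dim(profiles[[i]]$z_matrix)
    if (!identical(di, d1))
      stop(sprintf("subject %s has dimensions %dx%d, expected %dx%d",
                   profiles[[i]]$subjects[1] %||% as.character(i),
                   di[1], di[2], d1[1], d1[2]))
  }
  Z <- Reduce(`+`, lapply(profiles, `[[`, "z_matrix")) / length(profiles)
  connectivity_profiles(
    Z, level = "group",
    subjects = unlist(lapply(profiles, `[[`, "subjects")))
}
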