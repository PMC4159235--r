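# Temporal preprocessing: framewise displacement and motion exclusion,
# despiking, CompCor nuisance components, the 23-column nuisance design,
# and simultaneous band-pass filtering + nuisance regression.

#' Framewise displacement of a motion trace
#'
#' Per-frame sum of absolute backward differences of the six realignment
#' parameters, with rotation differences converted to arc length on a
#' sphere of radius \code{head_radius_mm} (Power-style FD). The first frame
#' has FD 0. Adding a constant to any parameter leaves FD unchanged.
#'
#' @param motion a \code{\link{motion_trace}} (translations mm, rotations
#'   radians).
#' @param head_radius_mm sphere radius for the rotation conversion.
#' @return numeric vector of length \code{nrow(motion)}.
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  m <- unclass(as.matrix(motion))
  if (ncol(m) != 6L) stop("motion trace must have 6 columns")
  if (!all(is.finite(m))) stop("motion trace contains non-finite values")
  d <- abs(apply(m, 2, function(x) c(0, diff(x))))
  d <- matrix(d, nrow = nrow(m))
  d[, 4:6] <- d[, 4:6] * head_radius_mm
  rowSums(d)
}

#' Motion-based subject exclusion report
#'
#' A subject is included iff max |translation| < \code{max_trans_mm}, max
#' |rotation| < \code{max_rot_deg} degrees, and mean FD <
#' \code{max_mean_fd}, all strict. Rotations are stored in radians and
#' converted to degrees for the comparison.
#'
#' @param traces list of \code{\link{motion_trace}} objects (one per
#'   subject), optionally named.
#' @param max_trans_mm,max_rot_deg,max_mean_fd thresholds.
#' @param head_radius_mm passed to \code{\link{framewise_displacement}}.
#' @return data.frame with columns \code{subject}, \code{max_translation_mm},
#'   \code{max_rotation_deg}, \code{mean_fd_mm}, \code{included}.
#' @export
apply_exclusion <- function(traces, max_trans_mm = 1.5, max_rot_deg = 1.5,
                            max_mean_fd = 0.30, head_radius_mm = 50) {
  if (inherits(traces, "motion_trace")) traces <- list(traces)
  ids <- names(traces) %||% sprintf("sub-%02d", seq_along(traces))
  rows <- lapply(seq_along(traces), function(i) {
    m <- unclass(as.matrix(traces[[i]]))
    mt <- max(abs(m[, 1:3]))
    mr <- max(abs(m[, 4:6])) * 180 / pi
    fd <- mean(framewise_displacement(traces[[i]], head_radius_mm))
    data.frame(subject = ids[i], max_translation_mm = mt,
               max_rotation_deg = mr, mean_fd_mm = fd,
               included = mt < max_trans_mm & mr < max_rot_deg &
                 fd < max_mean_fd)
  })
  do.call(rbind, rows)
}

#' Despike a time series by robust winsorization
#'
#' Samples whose robust z score |x - median| / (1.4826 MAD) exceeds
#' \code{mad_threshold} are shrunk to the threshold boundary, preserving
#' sign; all other samples pass unchanged. A zero-MAD (near-constant)
#' series is returned unchanged with a warning.
#'
#' @param series numeric vector (length >= 5) or voxels x frames matrix
#'   (despiked row-wise).
#' @param mad_threshold robust z cutoff.
#' @return object of the same shape as \code{series}.
#' @export
despike <- function(series, mad_threshold = 3) {
  if (is.matrix(series))
    return(t(apply(series, 1, despike, mad_threshold = mad_threshold)))
  if (length(series) < 5) stop("despike needs at least 5 samples")
  med <- stats::median(series)
  s <- stats::mad(series)  # 1.4826 * MAD
  if (s < .Machine$double.eps) {
    warning("zero MAD; series returned unchanged")
    return(series)
  }
  z <- (series - med) / s
  out <- series
  hi <- z > mad_threshold
  lo <- z < -mad_threshold
  out[hi] <- med + mad_threshold * s
  out[lo] <- med - mad_threshold * s
  out
}

#' CompCor nuisance components from a noise-voxel pool
#'
#' Each voxel series is linearly detrended and scaled to unit variance;
#' the top principal-component time courses of the resulting matrix are
#' returned as orthonormal columns ordered by explained variance.
#'
#' @param noise_voxel_series voxels x frames matrix (white-matter or CSF
#'   pool).
#' @param n_components number of components requested.
#' @return frames x \code{n_components} matrix (fewer columns, with a
#'   warning, if the pool has lower rank).
#' @export
compcor_components <- function(noise_voxel_series, n_components = 5) {
  X <- as.matrix(noise_voxel_series)
  if (nrow(X) < n_components)
    warning(sprintf("only %d voxels for %d requested components",
                    nrow(X), n_components))
  tt <- seq_len(ncol(X))
  X <- t(apply(X, 1, function(x) stats::resid(stats::lm.fit(
    cbind(1, tt), x))))
  sds <- apply(X, 1, stats::sd)
  keep <- sds > .Machine$double.eps
  X <- X[keep, , drop = FALSE] / sds[keep]
  sv <- svd(X, nu = 0)
  tol <- max(dim(X)) * sv$d[1] * .Machine$double.eps
  rank <- sum(sv$d > tol)
  k <- min(n_components, rank)
  if (k < n_components)
    warning(sprintf("rank %d < %d requested components; returning %d",
                    rank, n_components, k))
  comp <- sv$v[, seq_len(k), drop = FALSE]
  colnames(comp) <- paste0("pc", seq_len(k))
  comp
}

#' Assemble the 23-column nuisance design
#'
#' Columns: 6 motion parameters, their 6 backward-difference first
#' derivatives (first row 0), 5 white-matter and 5 CSF CompCor components,
#' and a linear trend — 23 regressors in total.
#'
#' @param motion a \code{\link{motion_trace}} with T rows.
#' @param wm_components,csf_components T x 5 component matrices (from
#'   \code{\link{compcor_components}}).
#' @return T x 23 matrix with named columns.
#' @export
nuisance_design <- function(motion, wm_components, csf_components) {
  m <- unclass(as.matrix(motion))
  T_frames <- nrow(m)
  dm <- apply(m, 2, function(x) c(0, diff(x)))
  wm <- as.matrix(wm_components)
  csf <- as.matrix(csf_components)
  stopifnot(nrow(wm) == T_frames, nrow(csf) == T_frames,
            ncol(wm) == 5L, ncol(csf) == 5L)
  X <- cbind(m, dm, wm, csf, seq_len(T_frames))
  colnames(X) <- c(colnames(motion_trace(m)),
                   paste0("d_", colnames(motion_trace(m))),
                   paste0("wm_pc", 1:5), paste0("csf_pc", 1:5), "trend")
  stopifnot(ncol(X) == 23L)
  X
}

# Zero-phase frequency-domain band-pass of the rows of a matrix.
# Hard mask: Fourier bins with |f| inside [band[1], band[2]] pass, all
# others (including DC) are zeroed; exactly symmetric, so output is real.
fft_bandpass <- function(X, band, tr_seconds) {
  X <- as.matrix(X)
  T_frames <- ncol(X)
  f <- (seq_len(T_frames) - 1) / (T_frames * tr_seconds)
  f <- pmin(f, 1 / tr_seconds - f)  # fold to [0, Nyquist]
  keep <- f >= band[1] & f <= band[2]
  Y <- t(apply(X, 1, function(x) {
    z <- stats::fft(x)
    z[!keep] <- 0
    Re(stats::fft(z, inverse = TRUE)) / T_frames
  }))
  matrix(Y, nrow = nrow(X))
}

#' Simultaneous band-pass filtering and nuisance regression
#'
#' Both the data and the nuisance design are band-limited with a zero-phase
#' frequency-domain filter, then the filtered data are residualized on the
#' filtered design by least squares. Filtering both sides keeps the
#' regression from reintroducing out-of-band nuisance variance. Design
#' columns that the filter annihilates (e.g. a pure constant) are dropped.
#'
#' @param series_matrix voxels x frames matrix.
#' @param design frames x P nuisance design (see
#'   \code{\link{nuisance_design}}); NULL regresses nothing.
#' @param band \code{c(low, high)} in Hz; \code{high} must be below the
#'   Nyquist frequency 1/(2 TR).
#' @param tr_seconds repetition time.
#' @return voxels x frames matrix of cleaned series, orthogonal to every
#'   retained filtered design column.
#' @export
bandpass_regress <- function(series_matrix, design = NULL,
                             band = c(0.009, 0.1), tr_seconds) {
  X <- as.matrix(series_matrix)
  nyq <- 1 / (2 * tr_seconds)
  if (band[2] >= nyq)
    stop(sprintf("band high %.4f Hz >= Nyquist %.4f Hz", band[2], nyq))
  if (!is.null(design) && nrow(as.matrix(design)) != ncol(X))
    stop("design row count must equal the number of frames")
  Xf <- fft_bandpass(X, band, tr_seconds)
  if (is.null(design)) return(Xf)
  Df <- t(fft_bandpass(t(as.matrix(design)), band, tr_seconds))
  norms <- sqrt(colSums(Df^2))
  Df <- Df[, norms > 1e-10 * max(norms, 1), drop = FALSE]
  if (ncol(Df) == 0L) return(Xf)
  qrD <- qr(Df)
  t(qr.resid(qrD, t(Xf)))
}

#' Discard initial frames
#'
#' Drops the first \code{n} frames of a time-series matrix (columns) or
#' motion trace (rows) so all later stages operate on the remaining T - n
#' frames.
#'
#' @param x voxels x frames matrix, \code{\link{motion_trace}}, or
#'   \code{\link{subject_timeseries}}.
#' @param n number of frames to discard (default 4).
#' @return object of the same class with \code{n} frames removed.
#' @export
drop_initial_frames <- function(x, n = 4) {
  if (inherits(x, "subject_timeseries")) {
    x$roi_series <- x$roi_series[, -seq_len(n), drop = FALSE]
    x$target_series <- x$target_series[, -seq_len(n), drop = FALSE]
    return(x)
  }
  if (inherits(x, "motion_trace"))
    return(motion_trace(unclass(x)[-seq_len(n), , drop = FALSE]))
  as.matrix(x)[, -seq_len(n), drop = FALSE]
}
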