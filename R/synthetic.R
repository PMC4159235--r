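# Synthetic multi-subject resting-state data with planted cluster structure.
# Seed voxels belong to K_true latent clusters; each cluster mixes M latent
# band-limited "network" signals through a row of the weight matrix W, and
# target voxels follow one network each. Everything downstream of the scanner
# (despiking, nuisance regression, profiles, clustering, stability, FC maps)
# can be exercised on these datasets.

#' Configuration for the synthetic dataset generator
#'
#' Defaults emulate the acquisition this pipeline is designed for: 59
#' subjects, 116 frames at TR = 3.5 s, mean framewise displacement around
#' 0.12 mm, and fluctuations confined to the 0.009-0.1 Hz band.
#'
#' @param n_subjects number of subjects.
#' @param T_frames frames per subject (before discarding initial frames).
#' @param tr_seconds repetition time in seconds.
#' @param K_true number of planted seed-voxel clusters.
#' @param voxels_per_cluster seed voxels per cluster.
#' @param M_networks number of latent network signals (default K_true).
#' @param n_target_voxels_per_network target voxels driven by each network.
#' @param weight_matrix K_true x M_networks mixing weights; rows must be
#'   pairwise distinct. Default: 1 on the cluster's own network, 0.25
#'   elsewhere.
#' @param noise_sd voxel noise standard deviation (signal units; network
#'   signals have unit variance).
#' @param subject_sd between-subject jitter added to each subject's copy of
#'   the weight matrix.
#' @param mean_fd_target target mean framewise displacement (mm) of the
#'   generated motion traces.
#' @param n_wm_voxels,n_csf_voxels sizes of the white-matter / CSF noise
#'   pools used for CompCor.
#' @param band frequency band (Hz) of the latent signals.
#' @param rng_seed master seed; all randomness derives from it.
#' @return Object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_subjects = 59, T_frames = 116,
                             tr_seconds = 3.5, K_true = 3,
                             voxels_per_cluster = 10,
                             M_networks = K_true,
                             n_target_voxels_per_network = 20,
                             weight_matrix = NULL,
                             noise_sd = 1.0, subject_sd = 0.1,
                             mean_fd_target = 0.12,
                             n_wm_voxels = 30, n_csf_voxels = 30,
                             band = c(0.009, 0.1),
                             rng_seed = 1L) {
  if (K_true < 1) stop("K_true must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (T_frames < 8) stop("need at least 8 frames")
  if (is.null(weight_matrix)) {
    # hierarchical similarity structure: clusters and networks sit at
    # unevenly spaced positions on a 1D gradient and couple by
    # exponential decay of distance. Coarser solutions then merge the
    # closest clusters consistently, as near-hierarchical splits do in
    # real parcellations.
    pos_k <- cumsum(c(0, rep_len(c(0.8, 1.2), max(K_true - 1, 0))))
    pos_m <- if (M_networks == K_true) pos_k
    else seq(min(pos_k), max(pos_k) + 1e-9, length.out = M_networks)
    weight_matrix <- exp(-abs(outer(pos_k, pos_m, `-`)))
  }
  weight_matrix <- as.matrix(weight_matrix)
  stopifnot(nrow(weight_matrix) == K_true,
            ncol(weight_matrix) == M_networks)
  if (K_true > 1 && any(duplicated(round(weight_matrix, 12))))
    stop("rows of weight_matrix must be pairwise distinct")
  structure(list(n_subjects = n_subjects, T_frames = T_frames,
                 tr_seconds = tr_seconds, K_true = K_true,
                 voxels_per_cluster = voxels_per_cluster,
                 M_networks = M_networks,
                 n_target_voxels_per_network = n_target_voxels_per_network,
                 weight_matrix = weight_matrix, noise_sd = noise_sd,
                 subject_sd = subject_sd, mean_fd_target = mean_fd_target,
                 n_wm_voxels = n_wm_voxels, n_csf_voxels = n_csf_voxels,
                 band = band, rng_seed = as.integer(rng_seed)),
            class = "synthetic_config")
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv, inherits = FALSE))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

# Derive a child seed from a master seed and a stage / index pair;
# keeps every source of randomness reproducible from one integer.
derive_seed <- function(master, ...) {
  parts <- c(master, unlist(lapply(list(...), function(x) {
    if (is.character(x)) utils::head(utf8ToInt(x), 8) else as.integer(x)
  })))
  s <- 0
  for (p in parts) s <- (s * 69069 + as.double(p) + 1) %% 2147483647
  as.integer(s)
}

#' Zero-mean band-limited Gaussian signal
#'
#' White Gaussian noise restricted to a frequency band with a hard
#' frequency-domain mask, rescaled to unit standard deviation.
#'
#' @param T_frames length of the series.
#' @param tr_seconds sampling interval (seconds).
#' @param band \code{c(low, high)} in Hz.
#' @return numeric vector of length \code{T_frames}, zero mean, unit sd.
#' @export
bandlimited_signal <- function(T_frames, tr_seconds, band = c(0.009, 0.1)) {
  x <- stats::rnorm(T_frames)
  y <- fft_bandpass(matrix(x, 1), band, tr_seconds)[1, ]
  s <- stats::sd(y)
  if (s < .Machine$double.eps) stop("band contains no resolvable frequency")
  (y - mean(y)) / s
}

#' Generate a smooth motion trace with a prescribed mean FD
#'
#' Six autocorrelated parameter traces (random-walk with low-pass smoothed
#' increments) are scaled so that the mean framewise displacement equals
#' \code{mean_fd_target} exactly (FD is linear in a common scaling of all
#' parameters). \code{mean_fd_target = 0} gives an all-zero trace.
#'
#' @param T_frames number of frames.
#' @param mean_fd_target desired mean FD in mm (>= 0).
#' @param rng_seed integer seed.
#' @param head_radius_mm rotation-to-arc-length radius used in FD.
#' @return A \code{\link{motion_trace}}.
#' @export
generate_motion <- function(T_frames, mean_fd_target, rng_seed = 1L,
                            head_radius_mm = 50) {
  if (T_frames < 2) stop("T_frames must be >= 2")
  if (mean_fd_target < 0) stop("mean_fd_target must be >= 0")
  if (mean_fd_target == 0)
    return(motion_trace(matrix(0, T_frames, 6)))
  # stationary AR(1) traces: smooth frame-to-frame drift without the
  # unbounded excursions of a random walk, so a subject scaled to a
  # realistic mean FD also stays within realistic absolute-motion limits
  phi <- 0.95
  params <- with_seed(rng_seed, {
    sapply(1:6, function(j) {
      e <- stats::rnorm(T_frames)
      x <- numeric(T_frames)
      x[1] <- e[1] / sqrt(1 - phi^2)
      for (t in 2:T_frames) x[t] <- phi * x[t - 1] + e[t]
      x
    })
  })
  # rotations live on a smaller scale so both kinds contribute to FD
  params[, 4:6] <- params[, 4:6] / head_radius_mm
  fd <- framewise_displacement(motion_trace(params),
                               head_radius_mm = head_radius_mm)
  params <- params * (mean_fd_target / mean(fd))
  motion_trace(params)
}

#' Generate a full synthetic multi-subject dataset
#'
#' For subject s, seed voxel v in cluster c follows
#' \code{x_v = sum_m W_s[c, m] * s_m + sigma * eps_v}, where the network
#' signals \code{s_m} are per-subject band-limited unit-variance processes
#' and \code{W_s} is the group weight matrix plus subject jitter. Target
#' voxel t assigned to network m follows \code{s_m + sigma * eps_t}.
#' White-matter and CSF pools mix two slow nuisance signals each. Identical
#' configs (same \code{rng_seed}) give bit-identical output.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return list with elements \code{subjects} (list of
#'   \code{\link{subject_timeseries}}), \code{motion} (list of
#'   \code{\link{motion_trace}}), \code{wm_series} / \code{csf_series}
#'   (lists of voxels x frames matrices), and \code{ground_truth}
#'   (\code{true_labels}, \code{target_network}, \code{network_signals} per
#'   subject, \code{subject_weights}, \code{config}).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- config
  V_roi <- cf$K_true * cf$voxels_per_cluster
  if (cf$K_true > V_roi) stop("K_true exceeds seed voxel count")
  true_labels <- rep(seq_len(cf$K_true), each = cf$voxels_per_cluster)
  target_network <- rep(seq_len(cf$M_networks),
                        each = cf$n_target_voxels_per_network)
  V_tgt <- length(target_network)
  # seed voxels laid out as one compact block per cluster on a 3D grid,
  # targets on a separate coarse grid
  roi_coords <- cluster_block_coords(cf$K_true, cf$voxels_per_cluster)
  target_coords <- as.matrix(expand.grid(
    x = 0:(ceiling(sqrt(V_tgt)) - 1), y = 0:(ceiling(sqrt(V_tgt)) - 1),
    z = 0L))[seq_len(V_tgt), , drop = FALSE]
  storage.mode(target_coords) <- "integer"

  subjects <- vector("list", cf$n_subjects)
  motion <- vector("list", cf$n_subjects)
  wm_series <- vector("list", cf$n_subjects)
  csf_series <- vector("list", cf$n_subjects)
  signals <- vector("list", cf$n_subjects)
  weights <- vector("list", cf$n_subjects)

  for (s in seq_len(cf$n_subjects)) {
    sub <- with_seed(derive_seed(cf$rng_seed, "subject", s), {
      S <- t(sapply(seq_len(cf$M_networks), function(m)
        bandlimited_signal(cf$T_frames, cf$tr_seconds, cf$band)))
      W_s <- cf$weight_matrix
      if (cf$subject_sd > 0)
        W_s <- W_s + matrix(stats::rnorm(length(W_s), sd = cf$subject_sd),
                            nrow(W_s))
      roi <- W_s[true_labels, , drop = FALSE] %*% S +
        cf$noise_sd * matrix(stats::rnorm(V_roi * cf$T_frames), V_roi)
      tgt <- S[target_network, , drop = FALSE] +
        cf$noise_sd * matrix(stats::rnorm(V_tgt * cf$T_frames), V_tgt)
      nuis <- t(sapply(1:2, function(i)
        bandlimited_signal(cf$T_frames, cf$tr_seconds,
                           c(0.005, 0.05))))
      wm <- matrix(stats::rnorm(2 * cf$n_wm_voxels, sd = 0.5),
                   cf$n_wm_voxels) %*% nuis +
        0.3 * matrix(stats::rnorm(cf$n_wm_voxels * cf$T_frames),
                     cf$n_wm_voxels)
      csf <- matrix(stats::rnorm(2 * cf$n_csf_voxels, sd = 0.5),
                    cf$n_csf_voxels) %*% nuis +
        0.3 * matrix(stats::rnorm(cf$n_csf_voxels * cf$T_frames),
                     cf$n_csf_voxels)
      list(S = S, W_s = W_s, roi = roi, tgt = tgt, wm = wm, csf = csf)
    })
    subjects[[s]] <- subject_timeseries(
      sub$roi, sub$tgt, roi_coords = roi_coords,
      target_coords = target_coords, tr_seconds = cf$tr_seconds,
      subject_id = sprintf("sub-%02d", s))
    motion[[s]] <- generate_motion(cf$T_frames, cf$mean_fd_target,
                                   derive_seed(cf$rng_seed, "motion", s))
    wm_series[[s]] <- sub$wm
    csf_series[[s]] <- sub$csf
    signals[[s]] <- sub$S
    weights[[s]] <- sub$W_s
  }
  list(subjects = subjects, motion = motion,
       wm_series = wm_series, csf_series = csf_series,
       ground_truth = list(true_labels = true_labels,
                           target_network = target_network,
                           network_signals = signals,
                           subject_weights = weights,
                           config = cf))
}

# one compact 2x... block of voxel coords per cluster, blocks spatially
# separated along x so per-cluster components are connected
cluster_block_coords <- function(K, per_cluster) {
  out <- NULL
  for (k in seq_len(K)) {
    nz <- ceiling(per_cluster / 4)
    g <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:(nz - 1)))
    g <- g[seq_len(per_cluster), , drop = FALSE]
    g[, 1] <- g[, 1] + (k - 1) * 4L
    out <- rbind(out, g)
  }
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  out
}
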