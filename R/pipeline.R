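# End-to-end orchestration: simulate -> preprocess -> connectivity ->
# parcellate -> stability -> seed-to-voxel maps -> ROI-to-ROI, from one
# config, with a resolved-config snapshot and a hashed manifest.

#' Assemble a pipeline configuration
#'
#' Defaults follow the analysis this package implements: K = 2-10, 100
#' clustering restarts, 100 split-half permutations, 0.009-0.1 Hz band,
#' voxel p < 0.001 with familywise cluster correction at 0.05, and
#' ROI-to-ROI FDR q < 0.05.
#'
#' @param synthetic list of \code{\link{synthetic_config}} arguments (the
#'   master seed is injected automatically).
#' @param k_range integer vector of K values.
#' @param n_restarts K-means restarts.
#' @param n_perm split-half permutations.
#' @param alpha significance level of the optimal-K rule.
#' @param band band-pass limits (Hz).
#' @param drop_frames initial frames discarded before any computation.
#' @param voxel_p,fwe_alpha,n_perm_fwe seed-to-voxel map thresholds and
#'   sign-flip permutation count.
#' @param q_threshold ROI-to-ROI FDR level.
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(synthetic = list(), k_range = 2:10,
                            n_restarts = 100, n_perm = 100, alpha = 0.05,
                            band = c(0.009, 0.1), drop_frames = 4,
                            voxel_p = 0.001, fwe_alpha = 0.05,
                            n_perm_fwe = 1000, q_threshold = 0.05,
                            seed = 1L) {
  structure(list(synthetic = synthetic, k_range = sort(as.integer(k_range)),
                 n_restarts = n_restarts, n_perm = n_perm, alpha = alpha,
                 band = band, drop_frames = drop_frames, voxel_p = voxel_p,
                 fwe_alpha = fwe_alpha, n_perm_fwe = n_perm_fwe,
                 q_threshold = q_threshold, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are
#'   \code{\link{pipeline_config}} arguments.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full parcellation pipeline on synthetic data
#'
#' Stages, in dependency order: (1) simulate the multi-subject dataset;
#' (2) motion exclusion, initial-frame removal, despiking, CompCor,
#' simultaneous band-pass + nuisance regression; (3) subject connectivity
#' profiles and group average; (4) K-means parcellation for every K; (5)
#' split-half stability and optimal-K selection; (6) seed-to-voxel maps
#' for the selected parcellation; (7) ROI-to-ROI table against the latent
#' network target groups. All artifacts are plain text (TSV/JSON); the
#' manifest lists every file with its MD5 hash. Re-running the same
#' config reproduces all artifacts bit-exactly.
#'
#' @param config a \code{\link{pipeline_config}} or YAML path.
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the in-memory stage results
#'   (\code{exclusion}, \code{profiles}, \code{parcellations},
#'   \code{stability}, \code{fc_maps}, \code{roi_fc}, \code{manifest}).
#' @export
run_pipeline <- function(config, out_dir = tempfile("striaparc_run_")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cf <- config
  paths <- character(0)
  emit <- function(name, writer) {
    p <- file.path(out_dir, name)
    writer(p)
    paths <<- c(paths, p)
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  emit("config.json", function(p)
    jsonlite::write_json(unclass(cf), p, auto_unbox = TRUE, digits = NA,
                         null = "null"))

  ## 1. simulate
  syn_args <- cf$synthetic
  syn_args$rng_seed <- derive_seed(cf$seed, "simulate")
  data <- stage("simulate", generate_dataset(
    do.call(synthetic_config, syn_args)))

  ## 2. preprocess
  pp <- stage("preprocess", {
    excl <- apply_exclusion(data$motion)
    keep <- which(excl$included)
    if (length(keep) < 4) stop("fewer than 4 subjects pass exclusion")
    cleaned <- lapply(keep, function(s) {
      sub <- drop_initial_frames(data$subjects[[s]], cf$drop_frames)
      mot <- drop_initial_frames(data$motion[[s]], cf$drop_frames)
      wm <- drop_initial_frames(data$wm_series[[s]], cf$drop_frames)
      csf <- drop_initial_frames(data$csf_series[[s]], cf$drop_frames)
      sub$roi_series <- despike(sub$roi_series)
      sub$target_series <- despike(sub$target_series)
      design <- nuisance_design(mot, compcor_components(wm),
                                compcor_components(csf))
      sub$roi_series <- bandpass_regress(sub$roi_series, design,
                                         cf$band, sub$tr_seconds)
      sub$target_series <- bandpass_regress(sub$target_series, design,
                                            cf$band, sub$tr_seconds)
      sub
    })
    list(exclusion = excl, cleaned = cleaned, kept = keep)
  })
  emit("exclusion.tsv", function(p)
    utils::write.table(pp$exclusion, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))

  ## 3. connectivity
  profiles <- stage("connectivity", lapply(pp$cleaned, subject_profiles))
  group <- stage("connectivity", group_average(profiles))

  ## 4. parcellation per K
  parcs <- stage("parcellation", {
    out <- lapply(cf$k_range, function(K)
      kmeans_correlation(group, K, cf$n_restarts,
                         derive_seed(cf$seed, "parcellate", K)))
    names(out) <- paste0("K", cf$k_range)
    out
  })
  coords <- pp$cleaned[[1]]$roi_coords
  emit("parcellation.tsv", function(p) {
    tab <- data.frame(voxel = seq_len(nrow(coords)),
                      x = coords[, 1], y = coords[, 2], z = coords[, 3])
    for (nm in names(parcs)) tab[[nm]] <- parcs[[nm]]$labels
    utils::write.table(tab, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })

  ## 5. stability
  stab <- stage("stability", split_half_stability(
    profiles, k_values = cf$k_range, n_perm = cf$n_perm,
    rng_seed = derive_seed(cf$seed, "stability"),
    n_restarts = cf$n_restarts, alpha = cf$alpha))
  emit("stability_vi.tsv", function(p) {
    long <- data.frame(
      K = rep(stab$k_values, each = stab$n_perm),
      permutation = rep(seq_len(stab$n_perm), length(stab$k_values)),
      vi = as.vector(stab$vi_samples))
    utils::write.table(long, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  emit("stability_summary.json", function(p)
    jsonlite::write_json(list(
      k_values = stab$k_values, mean_vi = unname(colMeans(stab$vi_samples)),
      transitions = stab$transition_tests,
      optimal_k = if (is.na(stab$optimal_k)) NULL else stab$optimal_k,
      optimal_k_found = !is.na(stab$optimal_k),
      split_sizes = stab$split_sizes, n_perm = stab$n_perm,
      rng_seed = stab$rng_seed), p, auto_unbox = TRUE, digits = NA,
      null = "null"))

  ## 6. seed-to-voxel maps for the selected (or smallest) K
  k_use <- if (!is.na(stab$optimal_k)) stab$optimal_k else min(cf$k_range)
  parc_use <- parcs[[paste0("K", k_use)]]
  cleaned_parc <- remove_isolated_voxels(parc_use, coords)
  fc <- stage("fc_maps", fc_map_pipeline(
    pp$cleaned, cleaned_parc, voxel_p = cf$voxel_p,
    fwe_alpha = cf$fwe_alpha, n_perm = cf$n_perm_fwe,
    rng_seed = derive_seed(cf$seed, "fcmap")))
  emit("fc_clusters.tsv", function(p) {
    tabs <- lapply(names(fc), function(nm) {
      tab <- fc[[nm]]$clusters
      if (nrow(tab)) cbind(seed_cluster = nm, tab) else NULL
    })
    tabs <- tabs[!vapply(tabs, is.null, TRUE)]
    tab <- if (length(tabs)) do.call(rbind, tabs)
    else data.frame(seed_cluster = character(0))
    utils::write.table(tab, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })

  ## 7. ROI-to-ROI against the latent network groups
  roifc <- stage("roi_fc", {
    cl_series <- lapply(pp$cleaned, cluster_mean_timeseries,
                        parcellation = cleaned_parc)
    rg_series <- lapply(pp$cleaned, function(s)
      roi_timeseries(s$target_series, data$ground_truth$target_network))
    roi_roi_fc(cl_series, rg_series, q_threshold = cf$q_threshold)
  })
  emit("roi_fc.tsv", function(p)
    utils::write.table(roifc, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))

  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA)
  result <- list(out_dir = out_dir, exclusion = pp$exclusion,
                 profiles = profiles, group = group,
                 parcellations = parcs, stability = stab,
                 selected_k = k_use, fc_maps = fc, roi_fc = roifc,
                 manifest = manifest, ground_truth = data$ground_truth)
  invisible(result)
}
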