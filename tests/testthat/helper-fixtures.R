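# Shared fixtures, built in code at test time.

# tiny toy atlas: 6x6x6 grid, 3 mm isotropic, origin at -7.5 mm so voxel
# centers span -7.5 .. 7.5; labels 1 and 2 fill two slabs.
toy_atlas <- function() {
  labels <- array(0L, c(6, 6, 6))
  labels[1:2, , ] <- 1L
  labels[5:6, , ] <- 2L
  aff <- diag(c(3, 3, 3, 1))
  aff[1:3, 4] <- -7.5
  atlas_volume(labels, aff,
               data.frame(id = c(1L, 2L), name = c("left", "right")))
}

# small synthetic dataset used across modules
small_dataset <- function(n_subjects = 8, K_true = 3, noise_sd = 1,
                          rng_seed = 1, ...) {
  generate_dataset(synthetic_config(
    n_subjects = n_subjects, K_true = K_true, noise_sd = noise_sd,
    rng_seed = rng_seed, ...))
}

# independent brute-force VI oracle: builds the contingency counts with
# explicit loops and evaluates H + H - 2I directly from the definition.
oracle_vi <- function(a, b) {
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  H <- function(labels, levels) {
    h <- 0
    for (l in levels) {
      p <- sum(labels == l) / n
      if (p > 0) h <- h - p * log(p)
    }
    h
  }
  I <- 0
  for (k in ua) for (kk in ub) {
    pkk <- sum(a == k & b == kk) / n
    if (pkk > 0)
      I <- I + pkk * log(pkk / ((sum(a == k) / n) * (sum(b == kk) / n)))
  }
  H(a, ua) + H(b, ub) - 2 * I
}

# brute-force BH step-up: tests every cutoff index explicitly
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  k_star <- 0
  for (i in seq_len(m)) if (p[ord[i]] <= i * q / m) k_star <- i
  reject <- logical(m)
  if (k_star > 0) reject[ord[seq_len(k_star)]] <- TRUE
  reject
}

random_labels <- function(n, k) sample.int(k, n, replace = TRUE)
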