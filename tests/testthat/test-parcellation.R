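test_that("correlation K-means separates two planted profile groups", {
  set.seed(20)
  base1 <- c(1, 1, 0, 0); base2 <- c(0, 0, 1, 1)
  X <- rbind(base1, base1, base1, base2, base2, base2) +
    matrix(rnorm(24, sd = 0.05), 6)
  pc <- kmeans_correlation(X, 2, n_restarts = 10, rng_seed = 1)
  expect_equal(adjusted_rand(pc$labels, c(1, 1, 1, 2, 2, 2)), 1)
  # K = 1: single label, inertia = sum of 1 - cor(row, standardized mean)
  p1 <- kmeans_correlation(X, 1, n_restarts = 2, rng_seed = 1)
  expect_equal(unique(p1$labels), 1L)
  Xs <- striaparc:::standardize_rows(X)
  cen <- striaparc:::standardize_rows(matrix(colMeans(Xs), 1))
  expect_equal(p1$inertia, sum(1 - Xs %*% t(cen)), tolerance = 1e-10)
  # duplicated rows always share a label
  Xdup <- rbind(X, X[1, ])
  pd <- kmeans_correlation(Xdup, 2, n_restarts = 10, rng_seed = 2)
  expect_equal(pd$labels[7], pd$labels[1])
  expect_error(kmeans_correlation(X, 7, rng_seed = 1), "K exceeds")
})

test_that("returned solution minimizes inertia over restarts, deterministically", {
  set.seed(21)
  X <- matrix(rnorm(40 * 8), 40)
  pc <- kmeans_correlation(X, 4, n_restarts = 25, rng_seed = 5)
  expect_equal(pc$inertia, min(pc$restart_inertias), tolerance = 1e-12)
  expect_true(all(pc$restart_inertias >= pc$inertia - 1e-12))
  pc2 <- kmeans_correlation(X, 4, n_restarts = 25, rng_seed = 5)
  expect_identical(pc$labels, pc2$labels)
  expect_setequal(unique(pc$labels), 1:4)
})

test_that("clustering is invariant to positive row scaling", {
  set.seed(22)
  X <- matrix(rnorm(30 * 6), 30)
  s <- runif(30, 0.2, 5)
  p1 <- kmeans_correlation(X, 3, n_restarts = 10, rng_seed = 3)
  p2 <- kmeans_correlation(X * s, 3, n_restarts = 10, rng_seed = 3)
  expect_equal(adjusted_rand(p1$labels, p2$labels), 1)
})

test_that("planted clusters are recovered exactly at the fixture noise level", {
  for (seed in 1:10) {
    d <- generate_dataset(synthetic_config(
      n_subjects = 6, K_true = 3, rng_seed = seed))
    g <- group_average(lapply(d$subjects, subject_profiles))
    pc <- kmeans_correlation(g, 3, n_restarts = 20, rng_seed = seed)
    expect_equal(adjusted_rand(pc$labels, d$ground_truth$true_labels), 1)
  }
})

test_that("isolated voxels are flagged by connected-component size", {
  # cluster 1: a 20-voxel slab plus one detached voxel; cluster 2: a bar
  slab <- as.matrix(expand.grid(0:4, 0:1, 0:1))
  lone <- matrix(c(9, 9, 9), 1)
  bar <- cbind(0:5, 9, 9)
  coords <- rbind(slab, lone, bar)
  labels <- c(rep(1, 21), rep(2, 6))
  out <- remove_isolated_voxels(labels, coords, min_component = 3)
  expect_identical(which(out$flagged), 21L)
  expect_equal(out$component_sizes[21], 1L)
  expect_equal(out$component_sizes[1], 20L)
  # min_component = 1 is the identity
  expect_false(any(remove_isolated_voxels(labels, coords,
                                          min_component = 1)$flagged))
  # a single connected cluster is untouched
  expect_false(any(remove_isolated_voxels(rep(1, 6), bar)$flagged))
  # flood-fill oracle: diagonal neighbors are separate under 6- but one
  # component under 26-connectivity
  diag2 <- rbind(c(0, 0, 0), c(1, 1, 1))
  expect_true(all(remove_isolated_voxels(c(1, 1), diag2, 6, 2)$flagged))
  expect_false(any(remove_isolated_voxels(c(1, 1), diag2, 26, 2)$flagged))
})

test_that("label agreement maximizes over label matchings", {
  expect_equal(label_agreement(c(1, 1, 2, 2), c(1, 1, 2, 2)), 100)
  expect_equal(label_agreement(c(1, 1, 2, 2), c(2, 2, 1, 1)), 100)
  expect_equal(label_agreement(c(1, 1, 2, 2), c(1, 1, 1, 2)), 75)
  # unequal K: best matching of 3 test labels onto 2 reference labels
  expect_equal(label_agreement(c(1, 1, 2, 2), c(1, 3, 2, 2)), 75)
  expect_error(label_agreement(1:3, 1:4), "voxel set")
  # exhaustive-permutation oracle on random pairs
  set.seed(23)
  for (i in 1:20) {
    a <- random_labels(12, 3); b <- random_labels(12, 3)
    tab <- table(factor(a, 1:3), factor(b, 1:3))
    best <- 0
    perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
    for (p in perms) best <- max(best, sum(tab[cbind(1:3, p)]))
    expect_equal(label_agreement(a, b), 100 * best / 12)
  }
})

test_that("adjusted Rand matches brute force and is calibrated at chance", {
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  # brute-force pair-counting oracle
  set.seed(24)
  for (i in 1:10) {
    a <- random_labels(15, 3); b <- random_labels(15, 4)
    n <- length(a)
    s11 <- s00 <- s10 <- s01 <- 0
    for (u in 1:(n - 1)) for (v in (u + 1):n) {
      sa <- a[u] == a[v]; sb <- b[u] == b[v]
      if (sa && sb) s11 <- s11 + 1
      else if (!sa && !sb) s00 <- s00 + 1
      else if (sa) s10 <- s10 + 1 else s01 <- s01 + 1
    }
    np <- choose(n, 2)
    exp_idx <- (s11 + s10) * (s11 + s01) / np
    max_idx <- ((s11 + s10) + (s11 + s01)) / 2
    expect_equal(adjusted_rand(a, b),
                 (s11 - exp_idx) / (max_idx - exp_idx), tolerance = 1e-12)
  }
  # independent labelings: mean ARI near 0
  set.seed(25)
  aris <- replicate(100, adjusted_rand(random_labels(1000, 3),
                                       random_labels(1000, 3)))
  expect_lt(abs(mean(aris)), 0.02)
  expect_error(adjusted_rand(1:3, 1:4), "length")
})

test_that("adjusted Rand agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  set.seed(26)
  for (i in 1:20) {
    a <- random_labels(30, 4); b <- random_labels(30, 3)
    expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})
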