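test_that("clustering entropy matches hand-evaluated values", {
  expect_equal(cluster_entropy(c(1, 1, 1, 1)), 0)
  expect_equal(cluster_entropy(c(1, 1, 2, 2)), log(2), tolerance = 1e-12)
  expect_equal(cluster_entropy(c(1, 1, 1, 2)),
               -0.75 * log(0.75) - 0.25 * log(0.25), tolerance = 1e-12)
  expect_equal(cluster_entropy(c(1, 1, 1, 2)), 0.562335, tolerance = 1e-6)
  expect_error(cluster_entropy(integer(0)), "empty")
})

test_that("mutual information matches the joint-table definition", {
  expect_equal(mutual_information(c(1, 1, 2, 2), c(1, 1, 2, 2)), log(2),
               tolerance = 1e-12)
  # independent clusterings: all joint cells 1/4 = product of marginals
  expect_equal(mutual_information(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0,
               tolerance = 1e-12)
  expect_equal(mutual_information(c(1, 2, 1, 2), rep(1, 4)), 0)
  a <- random_labels(40, 3); b <- random_labels(40, 4)
  expect_lte(mutual_information(a, b),
             min(cluster_entropy(a), cluster_entropy(b)) + 1e-12)
  expect_error(mutual_information(1:3, 1:4), "length")
})

test_that("variation of information reproduces worked fixtures", {
  expect_equal(variation_of_information(c(1, 1, 2, 2), c(1, 1, 2, 2)), 0)
  expect_equal(variation_of_information(c(1, 1, 2, 2), c(2, 2, 1, 1)), 0)
  expect_equal(variation_of_information(c(1, 1, 2, 2), c(1, 2, 1, 2)),
               2 * log(2), tolerance = 1e-12)
  expect_equal(variation_of_information(c(1, 1, 2, 2), c(1, 2, 3, 3)),
               0.5 * log(2), tolerance = 1e-12)
})

test_that("VI is a metric: brute-force agreement, symmetry, triangle, log-n bound", {
  set.seed(30)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    a <- random_labels(n, sample(2:5, 1))
    b <- random_labels(n, sample(2:5, 1))
    c_ <- random_labels(n, sample(2:5, 1))
    vab <- variation_of_information(a, b)
    expect_equal(vab, oracle_vi(a, b), tolerance = 1e-12)
    expect_equal(vab, variation_of_information(b, a), tolerance = 1e-12)
    expect_lte(vab, log(n) + 1e-12)
    expect_gte(vab, 0)
    expect_lte(vab, variation_of_information(a, c_) +
                 variation_of_information(c_, b) + 1e-12)
  }
})

test_that("split-half halves have sizes floor(n/2) and ceiling(n/2)", {
  set.seed(31)
  profs <- lapply(1:59, function(i)
    connectivity_profiles(matrix(rnorm(8 * 12), 8), "subject",
                          sprintf("s%02d", i)))
  st <- split_half_stability(profs, k_values = 2:3, n_perm = 5,
                             rng_seed = 1, n_restarts = 2)
  expect_equal(st$split_sizes, c(29, 30))
  expect_equal(dim(st$vi_samples), c(5, 2))
  expect_true(all(st$vi_samples >= 0 & st$vi_samples <= log(8)))
  expect_error(split_half_stability(profs[1:3], 2:3, 5, 1), "4 subjects")
  expect_error(split_half_stability(profs, 2:3, n_perm = 1), "n_perm")
})

test_that("noiseless planted data give VI = 0 at K_true in every split", {
  d <- generate_dataset(synthetic_config(
    n_subjects = 8, K_true = 3, noise_sd = 0, subject_sd = 0,
    rng_seed = 32))
  profs <- lapply(d$subjects, subject_profiles)
  st <- split_half_stability(profs, k_values = 2:3, n_perm = 5,
                             rng_seed = 3, n_restarts = 5)
  expect_true(all(st$vi_samples[, "K3"] == 0))
})

test_that("stability is deterministic in the seed and VI rises past K_true", {
  d <- generate_dataset(synthetic_config(
    n_subjects = 12, K_true = 3, rng_seed = 33))
  profs <- lapply(d$subjects, subject_profiles)
  st1 <- split_half_stability(profs, 2:6, n_perm = 10, rng_seed = 9,
                              n_restarts = 5)
  st2 <- split_half_stability(profs, 2:6, n_perm = 10, rng_seed = 9,
                              n_restarts = 5)
  expect_identical(st1$vi_samples, st2$vi_samples)
  expect_lt(mean(st1$vi_samples[, "K3"]), mean(st1$vi_samples[, "K6"]))
})

test_that("optimal-K rule returns the first non-significant transition", {
  # construct VI samples with prescribed transition outcomes
  mk_result <- function(vi) {
    structure(list(k_values = 2:6, vi_samples = vi,
                   split_sizes = c(10, 10),
                   transition_tests = NULL, optimal_k = NA,
                   n_perm = nrow(vi), rng_seed = 1L, test = "paired"),
              class = "stability_result")
  }
  set.seed(34)
  n <- 40
  base <- rnorm(n, sd = 0.01)
  # VI means 0.1, 0.3, 0.5, 0.7, 0.703: transitions 3,4,5 significant,
  # transition 6 not
  vi <- cbind(K2 = base + 0.1, K3 = base + 0.3, K4 = base + 0.5,
              K5 = base + 0.7, K6 = base + 0.7 + rnorm(n, sd = 0.05))
  res <- mk_result(vi)
  tt <- striaparc:::transition_tests(res)
  expect_true(all(tt$p[tt$K %in% 3:5] < 0.05))
  expect_gte(tt$p[tt$K == 6], 0.05)
  res$transition_tests <- tt
  expect_equal(select_optimal_k(res), 6L)
  # all transitions significant: no K qualifies
  vi2 <- cbind(K2 = base, K3 = base + 0.2, K4 = base + 0.4,
               K5 = base + 0.6, K6 = base + 0.8)
  res2 <- mk_result(vi2)
  res2$transition_tests <- striaparc:::transition_tests(res2)
  expect_true(is.na(select_optimal_k(res2)))
  # identical VI vectors: p = 1 by convention, K selected
  vi3 <- cbind(K2 = base, K3 = base, K4 = base + 1, K5 = base + 2,
               K6 = base + 3)
  res3 <- mk_result(vi3)
  res3$transition_tests <- striaparc:::transition_tests(res3)
  expect_equal(res3$transition_tests$p[res3$transition_tests$K == 3], 1)
  expect_equal(select_optimal_k(res3), 3L)
})

test_that("paired transition t matches the closed-form paired formula", {
  set.seed(35)
  x <- rnorm(30, 1); y <- rnorm(30, 0.8)
  vi <- cbind(K2 = y, K3 = x)
  res <- structure(list(k_values = 2:3, vi_samples = vi,
                        split_sizes = c(5, 5), transition_tests = NULL,
                        optimal_k = NA, n_perm = 30, rng_seed = 1L,
                        test = "paired"),
                   class = "stability_result")
  tt <- striaparc:::transition_tests(res)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(tt$t, t_hand, tolerance = 1e-12)
  expect_equal(tt$p, 2 * pt(-abs(t_hand), df = 29), tolerance = 1e-12)
})
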