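# Split-half stability of cluster solutions: variation of information
# between the parcellations of two random half-samples of subjects,
# repeated over permutations, and the optimal-K selection rule.

# contingency table as joint probabilities
joint_prob <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors differ in length")
  table(labels_a, labels_b) / length(labels_a)
}

#' Entropy of a clustering (nats)
#'
#' H(C) = -sum_k P(k) log P(k) with P(k) = n_k / n and 0 log 0 = 0.
#' Natural logarithm throughout; H = 0 iff all voxels share one cluster.
#'
#' @param labels non-empty label vector.
#' @return entropy in nats.
#' @export
cluster_entropy <- function(labels) {
  if (length(labels) == 0) stop("empty labeling")
  p <- as.numeric(table(labels)) / length(labels)
  -sum(ifelse(p > 0, p * log(p), 0))
}

#' Mutual information between two clusterings (nats)
#'
#' I(C, C') = sum_{k,k'} P(k, k') log( P(k, k') / (P(k) P(k')) ) with
#' joint probabilities from the contingency table. Bounded by
#' min(H(C), H(C')).
#'
#' @param labels_a,labels_b label vectors of equal length.
#' @return mutual information in nats (>= 0).
#' @export
mutual_information <- function(labels_a, labels_b) {
  P <- joint_prob(labels_a, labels_b)
  pa <- rowSums(P)
  pb <- colSums(P)
  num <- P / outer(pa, pb)
  max(0, sum(ifelse(P > 0, P * log(num), 0)))
}

#' Variation of information between two clusterings (nats)
#'
#' VI(C, C') = H(C) + H(C') - 2 I(C, C'). A true metric on partitions:
#' zero iff the clusterings are identical up to relabeling, symmetric,
#' triangle inequality, and bounded by log n. High VI means low similarity
#' between the two clusterings.
#'
#' @param labels_a,labels_b label vectors of equal length.
#' @return VI in nats (>= 0).
#' @export
variation_of_information <- function(labels_a, labels_b) {
  vi <- cluster_entropy(labels_a) + cluster_entropy(labels_b) -
    2 * mutual_information(labels_a, labels_b)
  max(0, vi)
}

#' Split-half permutation stability of cluster solutions
#'
#' In each permutation, subjects are randomly split into halves of size
#' floor(n/2) and ceiling(n/2); each half's subject z matrices are
#' averaged and clustered at every K in \code{k_values} (the same split is
#' reused across K), and the VI between the two halves' parcellations is
#' recorded. Per transition K-1 -> K (K >= 3), a paired t test (pairing by
#' permutation) compares the VI distributions; K = 2 has no meaningful
#' K-1 = 1 comparison because two one-cluster solutions always have VI 0.
#'
#' @param subject_profiles list of subject-level
#'   \code{\link{connectivity_profiles}} (>= 4 subjects).
#' @param k_values increasing integer vector of K values (e.g. 2:10).
#' @param n_perm number of random splits (>= 2).
#' @param rng_seed master seed for splits and clustering restarts.
#' @param n_restarts K-means restarts per clustering.
#' @param test \code{"paired"} (default) or \code{"two-sample"} transition
#'   test.
#' @param alpha significance level for the optimal-K rule.
#' @return Object of class \code{stability_result}: \code{k_values},
#'   \code{vi_samples} (n_perm x length(k_values) matrix),
#'   \code{split_sizes}, \code{transition_tests} (data.frame with K, t,
#'   p), \code{optimal_k} (NA if no K qualifies), \code{n_perm},
#'   \code{rng_seed}.
#' @export
split_half_stability <- function(subject_profiles, k_values = 2:10,
                                 n_perm = 100, rng_seed = 1L,
                                 n_restarts = 100,
                                 test = c("paired", "two-sample"),
                                 alpha = 0.05) {
  test <- match.arg(test)
  n <- length(subject_profiles)
  if (n < 4) stop("need at least 4 subjects for split-half stability")
  if (n_perm < 2) stop("n_perm must be >= 2")
  k_values <- sort(as.integer(k_values))
  n_lo <- n %/% 2L
  vi <- matrix(NA_real_, n_perm, length(k_values),
               dimnames = list(NULL, paste0("K", k_values)))
  for (p in seq_len(n_perm)) {
    ord <- with_seed(derive_seed(rng_seed, "split", p), sample.int(n))
    half1 <- group_average(subject_profiles[ord[seq_len(n_lo)]])
    half2 <- group_average(subject_profiles[ord[(n_lo + 1):n]])
    for (j in seq_along(k_values)) {
      K <- k_values[j]
      lab1 <- kmeans_correlation(half1, K, n_restarts,
                                 derive_seed(rng_seed, "perm", p, K, 1))
      lab2 <- kmeans_correlation(half2, K, n_restarts,
                                 derive_seed(rng_seed, "perm", p, K, 2))
      vi[p, j] <- variation_of_information(lab1$labels, lab2$labels)
    }
  }
  res <- structure(list(k_values = k_values, vi_samples = vi,
                        split_sizes = c(n_lo, n - n_lo),
                        transition_tests = NULL, optimal_k = NA_integer_,
                        n_perm = as.integer(n_perm),
                        rng_seed = as.integer(rng_seed), test = test),
                   class = "stability_result")
  res$transition_tests <- transition_tests(res)
  res$optimal_k <- select_optimal_k(res, alpha = alpha)
  res
}

# per-transition t statistics: VI(K) vs VI(K-1) for consecutive K >= 3
transition_tests <- function(result) {
  kv <- result$k_values
  rows <- list()
  for (j in seq_along(kv)) {
    K <- kv[j]
    if (K < 3 || !((K - 1) %in% kv)) next
    x <- result$vi_samples[, paste0("K", K)]
    y <- result$vi_samples[, paste0("K", K - 1)]
    if (result$test == "paired") {
      d <- x - y
      if (stats::sd(d) < .Machine$double.eps) {
        # degenerate: identical differences in every permutation
        tt <- if (abs(mean(d)) < .Machine$double.eps)
          list(statistic = 0, p.value = 1)
        else list(statistic = sign(mean(d)) * Inf, p.value = 0)
      } else tt <- stats::t.test(x, y, paired = TRUE)
    } else if (stats::sd(x) + stats::sd(y) < .Machine$double.eps) {
      tt <- if (abs(mean(x) - mean(y)) < .Machine$double.eps)
        list(statistic = 0, p.value = 1)
      else list(statistic = sign(mean(x) - mean(y)) * Inf, p.value = 0)
    } else tt <- stats::t.test(x, y)
    rows[[length(rows) + 1]] <-
      data.frame(K = K, t = unname(tt$statistic), p = tt$p.value)
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(K = integer(0), t = numeric(0), p = numeric(0))
}

#' Select the optimal number of clusters from a stability result
#'
#' The smallest K (>= 3, since K = 2 has no informative K-1 comparison)
#' whose VI distribution is statistically indistinguishable from that of
#' the K-1 solution (transition p >= alpha). NA if every transition is
#' significant.
#'
#' @param result a \code{\link{split_half_stability}} result.
#' @param alpha significance level.
#' @return integer K, or NA.
#' @export
select_optimal_k <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "stability_result"))
  tt <- result$transition_tests
  if (is.null(tt)) tt <- transition_tests(result)
  kv <- result$k_values
  need <- kv[kv >= 3]
  if (length(need) && !all(need %in% (tt$K)))
    stop("missing consecutive K values for transition tests")
  ok <- tt$K[tt$p >= alpha]
  if (length(ok)) as.integer(min(ok)) else NA_integer_
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("Split-half stability: %d permutations, splits %d/%d\n",
              x$n_perm, x$split_sizes[1], x$split_sizes[2]))
  means <- colMeans(x$vi_samples)
  for (j in seq_along(x$k_values))
    cat(sprintf("  K = %d: mean VI = %.4f\n", x$k_values[j], means[j]))
  if (nrow(x$transition_tests)) {
    cat("Transitions (VI at K vs K-1):\n")
    for (i in seq_len(nrow(x$transition_tests)))
      cat(sprintf("  K = %d: t = %.3f, p = %.4f\n",
                  x$transition_tests$K[i], x$transition_tests$t[i],
                  x$transition_tests$p[i]))
  }
  cat(sprintf("Optimal K: %s\n",
              if (is.na(x$optimal_k)) "none" else x$optimal_k))
  invisible(x)
}
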