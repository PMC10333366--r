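tp <- c(0, 2, 4, 6)

test_that("standardization z-scores rows and drops constants", {
  m <- matrix(c(2, 4, 6, 8), 1, 4, dimnames = list("pk1", NULL))
  z <- standardize_trajectories(m)
  expect_equal(as.numeric(z),
               c(-1.161895003862, -0.387298334621,
                 0.387298334621, 1.161895003862),
               tolerance = 1e-10)

  m2 <- rbind(pk1 = c(2, 4, 6, 8), flat = c(3, 3, 3, 3))
  expect_message(z2 <- standardize_trajectories(m2), "1 constant")
  expect_equal(rownames(z2), "pk1")
  expect_equal(attr(z2, "excluded"), "flat")

  # idempotence on an already-standardized row
  z3 <- standardize_trajectories(z)
  expect_equal(as.numeric(z3), as.numeric(z), tolerance = 1e-12)
})

test_that("k = 1 clustering is the mean trajectory with full membership", {
  set.seed(30)
  x <- matrix(rnorm(40), 10, 4)
  cl <- fuzzy_cmeans(x, k = 1L)
  expect_equal(as.numeric(cl$centroids), colMeans(x))
  expect_true(all(cl$membership == 1))
})

test_that("well-separated bundles are recovered and match e1071", {
  set.seed(31)
  proto1 <- c(2, 1, 0, -1)   # argmax at t = 0
  proto2 <- c(-1, 0, 1, 2)   # argmax at t = 6
  x <- rbind(
    matrix(rep(proto1, each = 20), 20) + rnorm(80, sd = 0.1),
    matrix(rep(proto2, each = 20), 20) + rnorm(80, sd = 0.1))
  rownames(x) <- paste0("t", 1:40)
  cl <- fuzzy_cmeans(x, k = 2L, seed = 5L)
  own <- cl$membership[cbind(1:40, cl$labels)]
  expect_true(all(own > 0.9))
  expect_true(all(cl$labels[1:20] == cl$labels[1]))
  expect_true(all(cl$labels[21:40] == cl$labels[21]))
  expect_true(cl$labels[1] != cl$labels[21])

  skip_if_not_installed("e1071")
  ref <- e1071::cmeans(x, centers = cl$centroids, m = 2,
                       iter.max = 200, method = "cmeans")
  d <- as.matrix(stats::dist(rbind(cl$centroids, ref$centers)))[1:2, 3:4]
  expect_lt(max(apply(d, 1, min)), 1e-3)
})

test_that("objective is non-increasing and memberships sum to one", {
  set.seed(32)
  x <- matrix(rnorm(200), 50, 4)
  cl <- fuzzy_cmeans(x, k = 3L, seed = 9L)
  expect_true(all(diff(cl$objective) <= 1e-9))
  expect_true(cl$converged)
  expect_equal(unname(rowSums(cl$membership)), rep(1, 50),
               tolerance = 1e-9)
  expect_error(fuzzy_cmeans(x, k = 0L), "1 <= k")
  expect_error(fuzzy_cmeans(x, k = 51L), "1 <= k")
})

test_that("duplicating every trajectory leaves centroids unchanged", {
  set.seed(33)
  x <- matrix(rnorm(80), 20, 4)
  init <- x[c(3, 11), ]
  # fixed iteration count: the doubled objective would otherwise stop
  # the two runs at different iterations
  cl1 <- fuzzy_cmeans(x, k = 2L, centers = init, max_iter = 50L, tol = 0)
  cl2 <- fuzzy_cmeans(rbind(x, x), k = 2L, centers = init,
                      max_iter = 50L, tol = 0)
  expect_equal(cl1$centroids, cl2$centroids, tolerance = 1e-9)
})

test_that("semantic names follow centroid argmax timing", {
  cl <- structure(list(k = 3L, centroids = rbind(c(0, 0, 0, 1),
                                                 c(1, 0, 0, 0),
                                                 c(0, 1, 0, 0))),
                  class = "fuzzy_clustering")
  expect_equal(name_clusters(cl, tp), c("late", "early", "intermediate"))

  # argmax tie between two centroids: larger value at the first
  # timepoint is the earlier restorer
  cl2 <- structure(list(k = 3L, centroids = rbind(c(0.9, 1, -1, -0.9),
                                                  c(-1, 1, 0.5, -0.5),
                                                  c(-1, -0.5, 0.5, 1))),
                   class = "fuzzy_clustering")
  expect_message(nm <- name_clusters(cl2, tp), "tie")
  expect_equal(nm, c("early", "intermediate", "late"))

  cl3 <- structure(list(k = 2L, centroids = diag(2)),
                   class = "fuzzy_clustering")
  expect_warning(nm3 <- name_clusters(cl3, c(0, 2)), "k = 3")
  expect_equal(nm3, c("cluster_1", "cluster_2"))
})

test_that("semantic assignment is invariant to cluster relabeling", {
  set.seed(34)
  cfg <- chor_config(seed = 34L, n_peaks = 300L, noise = "none")
  ds <- suppressMessages(simulate_chor_dataset(cfg))
  norm <- normalize_timecourse(ds$tc$raw, ds$tc$spike_stats,
                               ds$tc$peak_lengths)
  z <- standardize_trajectories(norm)
  for (s in c(2L, 17L)) {   # different seeds -> different cluster order
    cl <- fuzzy_cmeans(z, 3L, seed = s)
    nm <- name_clusters(cl, tp)[cl$labels]
    if (s == 2L) first <- nm else expect_gt(mean(first == nm), 0.98)
  }
})

test_that("cluster proportions are fractions summing to one", {
  p <- cluster_proportions(c("A", "A", "B", "C"))
  expect_equal(unname(p), c(0.5, 0.25, 0.25))
  expect_equal(unname(cluster_proportions(rep("A", 5))), 1)
  expect_error(cluster_proportions(character(0)), "no labels")
})

test_that("known argmax-time classes are recovered with high ARI", {
  skip_if_not_installed("mclust")
  cfg <- chor_config(seed = 35L, n_peaks = 600L)
  ds <- suppressMessages(simulate_chor_dataset(cfg))
  norm <- normalize_timecourse(ds$tc$raw, ds$tc$spike_stats,
                               ds$tc$peak_lengths)
  z <- standardize_trajectories(norm)
  cl <- fuzzy_cmeans(z, 3L, seed = 35L)
  est <- name_clusters(cl, tp)[cl$labels]
  truth <- ds$truth$class[match(rownames(z), ds$truth$peak_id)]
  expect_gte(mclust::adjustedRandIndex(truth, est), 0.8)
})
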