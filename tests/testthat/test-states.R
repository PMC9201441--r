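# Manhattan k-means, validity index, elbow selection, window vectorization.

test_that("window vectorization is a bijection on symmetric matrices", {
  set.seed(4)
  m <- matrix(0, 13, 13)
  m[upper.tri(m, diag = TRUE)] <- runif(91)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  arr <- array(m, dim = c(13, 13, 1))
  v <- vectorize_windows(arr)
  expect_equal(dim(v), c(1, 91))
  expect_equal(unvectorize_window(v[1, ], 13), m)

  m2 <- matrix(c(1, 2, 2, 3), 2, 2)
  expect_equal(ncol(vectorize_windows(array(m2, c(2, 2, 1)))), 3)

  bad <- array(matrix(c(0, 1, 2, 0), 2, 2), c(2, 2, 1))
  expect_error(vectorize_windows(bad), "symmetric")
})

test_that("k-means recovers degenerate and planted clusters exactly", {
  # two collapsed point clouds: centroids equal the locations, cost 0
  X <- rbind(matrix(rep(c(0, 0, 0), 5), 5, 3, byrow = TRUE),
             matrix(rep(c(5, 5, 5), 4), 4, 3, byrow = TRUE))
  fit <- kmeans_manhattan(X, 2, n_replicates = 10, seed = 1)
  expect_equal(fit$cost, 0)
  expect_setequal(split(seq_len(9), fit$labels), list(1:5, 6:9))

  # well-separated planted clusters: perfect recovery across seeds
  for (s in 1:10) {
    pl <- planted_clusters(30, rbind(c(0, 0, 0, 0), c(4, 4, 0, 0),
                                     c(0, 4, 4, 4)), spread = 0.2, seed = s)
    fit <- kmeans_manhattan(pl$X, 3, n_replicates = 30, seed = s)
    expect_equal(align_states(fit$labels, pl$labels, 3)$accuracy, 1.0)
  }

  # determinism under a fixed seed
  pl <- planted_clusters(20, rbind(c(0, 0), c(3, 3)), seed = 7)
  f1 <- kmeans_manhattan(pl$X, 2, n_replicates = 25, seed = 11)
  f2 <- kmeans_manhattan(pl$X, 2, n_replicates = 25, seed = 11)
  expect_identical(f1$centroids, f2$centroids)
  expect_identical(f1$labels, f2$labels)
})

test_that("replicate-best solution attains the exhaustive-partition minimum (n <= 8, k = 2)", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(5:8, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    # exhaustive search over all 2-partitions with median centroids
    best_cost <- Inf
    for (mask in 1:(2^(n - 1) - 1)) {
      g <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
      if (!any(g) || all(g)) next
      c1 <- apply(X[g, , drop = FALSE], 2, median)
      c2 <- apply(X[!g, , drop = FALSE], 2, median)
      cost <- sum(abs(sweep(X[g, , drop = FALSE], 2, c1))) +
        sum(abs(sweep(X[!g, , drop = FALSE], 2, c2)))
      best_cost <- min(best_cost, cost)
    }
    fit <- kmeans_manhattan(X, 2, n_replicates = 200, seed = rep)
    expect_equal(fit$cost, best_cost, tolerance = 1e-10)
  }
})

test_that("shuffling window order permutes labels identically", {
  pl <- planted_clusters(15, rbind(c(0, 0), c(5, 5), c(0, 5)), seed = 3)
  fit <- kmeans_manhattan(pl$X, 3, n_replicates = 50, seed = 2)
  perm <- sample(nrow(pl$X))
  fitp <- kmeans_manhattan(pl$X[perm, ], 3, n_replicates = 50, seed = 2)
  # align centroid indices, then labels must match the permutation
  map <- apply(dibs:::l1_dist_to_centroids(fit$centroids, fitp$centroids),
               1, which.min)
  expect_equal(unname(map[fit$labels[perm]]), fitp$labels)
})

test_that("validity index matches a hand-computed 4-point instance", {
  X <- rbind(c(0, 0), c(0, 2), c(10, 0), c(10, 2))
  labels <- c(1, 1, 2, 2)
  centroids <- rbind(c(0, 1), c(10, 1))
  # within: every point is L1 distance 1 from its centroid; between: 10
  expect_equal(validity_index(X, labels, centroids), 1 / 10)
  # degenerate separated clusters: zero within-distance
  Xd <- rbind(c(0, 0), c(0, 0), c(4, 4))
  expect_equal(validity_index(Xd, c(1, 1, 2), rbind(c(0, 0), c(4, 4))), 0)
  expect_warning(vi <- validity_index(Xd, c(1, 1, 2),
                                      rbind(c(1, 1), c(1, 1))), "coincident")
  expect_true(is.infinite(vi))
})

test_that("elbow selection recovers the planted cluster count", {
  hits3 <- 0; hits2 <- 0
  for (s in 1:10) {
    pl3 <- planted_clusters(40, rbind(c(0, 0, 0), c(4, 4, 0), c(0, 4, 4)),
                            spread = 0.3, seed = s)
    sel3 <- elbow_select_k(pl3$X, k_range = 2:6, n_replicates = 15, seed = s)
    hits3 <- hits3 + (sel3$k == 3)
    pl2 <- planted_clusters(40, rbind(c(0, 0, 0), c(4, 4, 4)),
                            spread = 0.3, seed = s)
    sel2 <- elbow_select_k(pl2$X, k_range = 2:6, n_replicates = 15, seed = s)
    hits2 <- hits2 + (sel2$k == 2)
  }
  expect_gte(hits3, 9)
  expect_gte(hits2, 9)
})

test_that("flat validity curves fall back to the smallest k with a warning", {
  # two distinct locations repeated: within-distance 0 for every k
  X <- rbind(matrix(rep(c(0, 0), 10), 10, 2, byrow = TRUE),
             matrix(rep(c(6, 6), 10), 10, 2, byrow = TRUE))
  expect_warning(sel <- elbow_select_k(X, k_range = 2:4, n_replicates = 5,
                                       seed = 1), "flat")
  expect_equal(sel$k, 2)
})

test_that("elbow selection recovers a planted 4-cluster structure", {
  hits <- 0
  for (s in 1:5) {
    pl <- planted_clusters(30, rbind(c(0, 0, 0, 0), c(3, 3, 0, 0),
                                     c(0, 3, 3, 0), c(3, 0, 0, 3)),
                           spread = 0.3, seed = s)
    sel <- elbow_select_k(pl$X, k_range = 2:6, n_replicates = 15, seed = s)
    hits <- hits + (sel$k == 4)
  }
  expect_gte(hits, 4)
})

test_that("unstructured data never drives the elbow to the top of the range", {
  # pure noise has no true k; the knee rule must stay at the low end
  # rather than inflating toward max(k_range)
  picks <- vapply(c(9, 17, 42), function(s) {
    set.seed(s)
    X <- matrix(rnorm(120 * 6), 120, 6)
    elbow_select_k(X, k_range = 2:6, n_replicates = 15, seed = s)$k
  }, numeric(1))
  expect_true(all(picks <= 4))
})

test_that("two-level clustering is consistent on degenerate cohorts", {
  # single-dyad cohort: group average equals the dyad, labels coincide
  set.seed(12)
  n_win <- 60
  arr <- array(0, dim = c(3, 3, n_win))
  for (w in seq_len(n_win)) {
    base <- if (w %% 2 == 0) 1 else 3
    m <- matrix(base, 3, 3) + matrix(rnorm(9, sd = 0.05), 3, 3)
    m <- (m + t(m)) / 2
    arr[, , w] <- m
  }
  series <- list(structure(list(dyad_id = "d1", win = arr,
                                window_task = rep("AUT", n_win),
                                window_start = seq_len(n_win) - 1,
                                window_length = 10, step = 1),
                           class = "ibs_window_series"))
  part1 <- cluster_group_then_dyads(series, k = 2, n_replicates = 30, seed = 3)
  expect_equal(part1$labels[[1]], part1$group_labels)

  # identical dyads: identical partitions
  series2 <- c(series, series)
  series2[[2]]$dyad_id <- "d2"
  part2 <- cluster_group_then_dyads(series2, k = 2, n_replicates = 30, seed = 3)
  expect_identical(part2$labels[[1]], part2$labels[[2]])

  # state 1 is the densest: group centroid globE must be descending
  expect_true(all(diff(part2$globE) <= 0))

  # mismatched grids are rejected
  bad <- series2
  bad[[2]]$win <- bad[[2]]$win[, , 1:10]
  bad[[2]]$window_task <- bad[[2]]$window_task[1:10]
  expect_error(cluster_group_then_dyads(bad, k = 2), "mismatched")
})

test_that("label alignment finds the best permutation", {
  est <- c(2, 2, 1, 1, 3, 3)
  truth <- c(1, 1, 2, 2, 3, 3)
  al <- align_states(est, truth, 3)
  expect_equal(al$accuracy, 1.0)
  expect_equal(al$mapping[c(2, 1, 3)], c(1, 2, 3))
})
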