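test_that("the two-cluster 1-D worked example evaluates to its hand value", {
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  labels <- c(1, 1, 2, 2)
  # hand oracle: a = 1 everywhere; b in {10.5, 9.5, 9.5, 10.5}
  hand <- mean(c(9.5 / 10.5, 8.5 / 9.5, 8.5 / 9.5, 9.5 / 10.5))
  expect_equal(meanSilhouette(X, labels), hand)
  expect_equal(round(hand, 4), 0.8997)
})

test_that("silhouette conventions: singletons score zero, one cluster errors", {
  X <- matrix(rnorm(8), ncol = 2)
  expect_equal(meanSilhouette(X, 1:4), 0)
  expect_error(meanSilhouette(X, rep(1, 4)), "single cluster")
})

test_that("silhouette matches the brute-force oracle and cluster::silhouette", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(8:30, 1)
    k <- sample(2:4, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    labels <- sample(rep_len(seq_len(k), n))
    expect_equal(meanSilhouette(X, labels), brute_silhouette(X, labels),
                 tolerance = 1e-9)
    expect_equal(
      meanSilhouette(X, labels),
      mean(cluster::silhouette(labels, stats::dist(X))[, "sil_width"]),
      tolerance = 1e-9
    )
  }
})

test_that("random labels on i.i.d. data give silhouettes near zero", {
  set.seed(22)
  for (rep in 1:5) {
    X <- matrix(rnorm(200 * 4), 200, 4)
    labels <- sample(1:3, 200, replace = TRUE)
    expect_lt(abs(meanSilhouette(X, labels)), 0.2)
  }
})

test_that("local distances are plain Euclidean norms to the own centroid", {
  X <- rbind(c(3, 4), c(0, 0), c(1, 1))
  centroids <- rbind(c(0, 0), c(1, 1))
  d <- localDistances(X, c(1, 1, 2), centroids)
  expect_equal(unname(d), c(5, 0, 0))
  expect_error(localDistances(X, c(1, 1, 2), centroids[, 1, drop = FALSE]),
               "dimension mismatch")
})

test_that("a clustering with one unit per cluster has all-zero distances", {
  set.seed(23)
  X <- matrix(rnorm(10), 5, 2)
  d <- localDistances(X, 1:5, X)
  expect_equal(unname(d), rep(0, 5))
})

test_that("percentile flagging follows the order-statistics identity", {
  set.seed(24)
  d183 <- stats::setNames(runif(183), paste0("H", 1:183))
  fl <- flagOutliers(d183, 95)
  expect_length(fl$outlier_ids, 10L)
  d100 <- stats::setNames(runif(100), paste0("H", 1:100))
  expect_length(flagOutliers(d100, 95)$outlier_ids, 5L)
  expect_length(flagOutliers(stats::setNames(rep(1, 50), 1:50))$outlier_ids, 0L)
  # property over random N and p with distinct distances
  for (rep in 1:25) {
    N <- sample(10:400, 1)
    p <- runif(1, 50, 99)
    d <- stats::setNames(sample(N) / N, seq_len(N))
    expect_length(flagOutliers(d, p)$outlier_ids,
                  N - floor(1 + (p / 100) * (N - 1)))
  }
})

test_that("a single-cell grid returns that cell", {
  set.seed(25)
  vals <- matrix(rnorm(30 * 6), 30, 6,
                 dimnames = list(paste0("u", 1:30), paste0("f", 1:6)))
  fm <- featureMatrix(rownames(vals), colnames(vals), vals)
  res <- gridSearch(fm, gridConfig(n_grid = 4, k_grid = 2, pfa_runs = 5,
                                   seed = 1))
  expect_equal(res$best_n, 4L)
  expect_equal(res$best_k, 2L)
  expect_length(res$selected_features, 4L)
})

test_that("the grid recovers the planted number of separable groups", {
  set.seed(26)
  centers <- rbind(c(8, 0, 0, 0, 0), c(0, 8, 0, 0, 0), c(0, 0, 8, 0, 0))
  lab <- rep(1:3, each = 20)
  vals <- centers[lab, ] + matrix(rnorm(60 * 5), 60, 5)
  vals <- cbind(vals, matrix(rnorm(60 * 5), 60, 5))  # 5 noise features
  colnames(vals) <- paste0("f", 1:10)
  fm <- featureMatrix(paste0("u", 1:60), colnames(vals), vals)
  res <- gridSearch(fm, gridConfig(k_grid = 2:4, use_feature_selection = FALSE,
                                   seed = 2))
  expect_equal(res$best_k, 3L)
})

test_that("grid cells with too many clusters are skipped with a warning", {
  set.seed(27)
  vals <- matrix(rnorm(6 * 4), 6, 4,
                 dimnames = list(paste0("u", 1:6), paste0("f", 1:4)))
  fm <- featureMatrix(rownames(vals), colnames(vals), vals)
  expect_warning(
    res <- gridSearch(fm, gridConfig(n_grid = 3, k_grid = c(2, 10),
                                     pfa_runs = 3, seed = 1)),
    "k must be below"
  )
  expect_equal(res$grid_table$k, 2L)
})

test_that("the chosen cell attains the grid maximum and the fit is a k-means fixed point", {
  sim <- small_sim()
  res <- screen(sim$hospitals$features, gridConfig(pfa_runs = 10, seed = 30))
  expect_equal(res$silhouette_mean, max(res$grid_table$silhouette))
  expect_true(all(c(res$best_n, res$best_k) ==
                    res$grid_table[which.max(res$grid_table$silhouette),
                                   c("n", "k")]))
  # nearest-centroid reassignment leaves labels unchanged
  D <- as.matrix(stats::dist(rbind(res$X_selected, res$centroids)))
  n <- nrow(res$X_selected)
  nearest <- apply(D[seq_len(n), n + seq_len(res$best_k), drop = FALSE], 1,
                   which.min)
  expect_equal(unname(nearest), unname(as.integer(res$labels)))
  # flagged set = strictly above threshold
  expect_setequal(res$outlier_ids,
                  names(res$distances)[res$distances > res$threshold])
})

test_that("screening is deterministic under a fixed seed", {
  sim <- small_sim()
  r1 <- screen(sim$hospitals$features, gridConfig(pfa_runs = 5, seed = 7))
  r2 <- screen(sim$hospitals$features, gridConfig(pfa_runs = 5, seed = 7))
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$outlier_ids, r2$outlier_ids)
  expect_identical(r1$grid_table, r2$grid_table)
})

test_that("screening results serialize and the distance plot builds", {
  sim <- small_sim()
  res <- screen(sim$hospitals$features, gridConfig(pfa_runs = 5, seed = 7))
  dir <- withr::local_tempdir()
  writeScreening(res, dir)
  units <- utils::read.csv(file.path(dir, "units.csv"))
  expect_equal(nrow(units), length(res$distances))
  expect_equal(sum(units$outlier), length(res$outlier_ids))
  expect_s3_class(plotDistances(res), "ggplot")
})
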