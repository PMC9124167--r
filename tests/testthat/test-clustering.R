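test_that("kmeans_points recovers perfectly separated duplicate groups", {
  pts <- rbind(matrix(0.1, 5, 2), matrix(0.6, 5, 2))
  colnames(pts) <- c("fA2", "fT2")
  fit <- kmeans_points(pts, k = 2, n_restarts = 10)
  expect_equal(fit$inertia, 0)
  expect_length(unique(fit$labels[1:5]), 1)
  expect_length(unique(fit$labels[6:10]), 1)
  expect_false(fit$labels[1] == fit$labels[6])
})

test_that("kmeans_points is deterministic under a fixed seed", {
  set.seed(99)
  pts <- make_blobs(list(c(0.3, 0.3), c(0.5, 0.5)), c(40, 20), sd = 0.05)
  a <- kmeans_points(pts, 3, seed = 123, n_restarts = 20)
  b <- kmeans_points(pts, 3, seed = 123, n_restarts = 20)
  expect_identical(a$labels, b$labels)
  expect_identical(a$centroids, b$centroids)
  expect_identical(a$inertia, b$inertia)
})

test_that("kmeans_points errors on degenerate input", {
  pts <- matrix(0.5, 10, 2)
  expect_error(kmeans_points(pts, 2), "degenerate")
  expect_error(kmeans_points(make_blobs(list(c(0.5, 0.5)), 5), 1), "at least 2")
})

test_that("best-of-restarts inertia matches the exhaustive K=2 oracle", {
  set.seed(2024)
  for (rep in 1:5) {
    m <- matrix(runif(16), 8, 2)
    colnames(m) <- c("fA2", "fT2")
    fit <- kmeans_points(m, 2, seed = rep, n_restarts = 50)
    expect_equal(fit$inertia, exhaustive_k2_inertia(m), tolerance = 1e-9)
  }
})

test_that("inertia is non-increasing in K on the same points", {
  set.seed(31)
  pts <- make_blobs(list(c(0.3, 0.27), c(0.22, 0.45), c(0.6, 0.1)),
                    c(60, 30, 30), sd = 0.04)
  inertias <- vapply(2:6, function(k) {
    kmeans_points(pts, k, n_restarts = 20)$inertia
  }, numeric(1))
  expect_true(all(diff(inertias) <= 1e-9))
})

test_that("silhouette_mean matches closed forms and degenerate rules", {
  # two coincident pairs, separation sqrt(2): a = 0, b = sqrt(2), s = 1
  pts <- rbind(matrix(0, 2, 2), matrix(1, 2, 2))
  expect_equal(silhouette_mean(pts, c(1, 1, 2, 2)), 1)
  # all points identical, arbitrary split: a = b = 0 -> s = 0
  pts2 <- matrix(0.4, 6, 2)
  expect_equal(silhouette_mean(pts2, rep(1:2, 3)), 0)
  # singleton cluster scores 0
  pts3 <- rbind(c(0, 0), c(0, 0.1), c(1, 1))
  s <- silhouette_mean(pts3, c(1, 1, 2))
  naive <- naive_silhouette(pts3, c(1, 1, 2))
  expect_equal(s, naive, tolerance = 1e-12)
  # single cluster errors
  expect_error(silhouette_mean(pts3, c(1, 1, 1)), "single cluster")
})

test_that("silhouette_mean equals the O(n^2) double-loop oracle", {
  set.seed(55)
  for (rep in 1:10) {
    n <- sample(10:25, 1)
    m <- matrix(runif(2 * n), n, 2)
    labels <- sample(1:3, n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(silhouette_mean(m, labels), naive_silhouette(m, labels),
                 tolerance = 1e-12)
  }
})

test_that("silhouette_mean agrees with cluster::silhouette when defined", {
  skip_if_not_installed("cluster")
  set.seed(66)
  m <- matrix(runif(60), 30, 2)
  labels <- sample(1:3, 30, replace = TRUE)
  ours <- silhouette_mean(m, labels)
  ref <- mean(cluster::silhouette(labels, stats::dist(m))[, "sil_width"])
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("select_optimal_k finds K=2 for two blobs and K=4 for four", {
  set.seed(7)
  pts2 <- make_blobs(list(c(0.32, 0.27), c(0.22, 0.45)), c(270, 30))
  prof2 <- select_optimal_k(pts2, n_restarts = 10)
  expect_equal(prof2$optimal_k, 2)
  expect_true(all(prof2$per_k$silhouette >= -1 & prof2$per_k$silhouette <= 1))

  pts4 <- make_blobs(list(c(0.1, 0.1), c(0.1, 0.6), c(0.6, 0.1), c(0.6, 0.6)),
                     rep(40, 4), sd = 0.02)
  prof4 <- select_optimal_k(pts4, n_restarts = 10)
  expect_equal(prof4$optimal_k, 4)
})

test_that("optimal-K ties break toward smaller K", {
  prof <- structure(
    list(per_k = tibble::tibble(k = c(2L, 3L), silhouette = c(0.5, 0.5)),
         optimal_k = 2L),
    class = "silhouette_profile"
  )
  # the constructor rule: which.max on ascending k picks the smaller
  expect_equal(prof$per_k$k[which.max(prof$per_k$silhouette)], 2L)
  # and end to end on a symmetric 4-point square, scores tie across K
  sq <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  colnames(sq) <- c("fA2", "fT2")
  p <- select_optimal_k(sq, k_range = 2:4, n_restarts = 20)
  ties <- p$per_k$k[p$per_k$silhouette == max(p$per_k$silhouette)]
  expect_equal(p$optimal_k, min(ties))
})

test_that("infeasible K values are skipped with a warning", {
  pts <- rbind(c(0, 0), c(0, 1), c(1, 0))
  colnames(pts) <- c("fA2", "fT2")
  expect_warning(p <- select_optimal_k(pts, k_range = 2:9, n_restarts = 5),
                 "infeasible")
  expect_true(all(p$per_k$k <= 3))
})

test_that("designate_small_large puts the minority cluster in SMALL", {
  set.seed(12)
  pts <- make_blobs(list(c(0.32, 0.27), c(0.22, 0.45)), c(90, 10))
  km <- kmeans_points(pts, 2, n_restarts = 10)
  d <- designate_small_large(km)
  expect_equal(d$small_size, 10)
  expect_equal(d$large_size, 90)
  expect_equal(sum(d$cluster == "SMALL"), 10)
  expect_equal(d$centroids$cluster, c("SMALL", "LARGE"))
  # the small blob is the high-T2 one by construction
  expect_gt(d$centroids$fT2[1], d$centroids$fT2[2])
})

test_that("exact size ties resolve by higher centroid f(T2)", {
  km <- list(k = 2L, labels = c(1L, 1L, 2L, 2L),
             centroids = rbind(c(0.32, 0.27), c(0.22, 0.45)),
             inertia = 0, seed = 1L, n_restarts = 1L)
  expect_message(d <- designate_small_large(km), "tie")
  expect_equal(d$cluster, c("LARGE", "LARGE", "SMALL", "SMALL"))
})

test_that("small/large recovery matches the generator's minority component", {
  hits <- 0
  for (s in 1:5) {
    sim <- simulate_genome(paste0("rec", s), n_genes = 600, seed = 100 + s)
    tbl <- genome_frequency_table(sim$genes)
    cl <- cluster_genome(tbl, k_range = 2:3, n_restarts = 10)
    truth <- sim$genes$component[match(cl$assignments$gene_id,
                                       sim$genes$gene_id)]
    small_ids <- cl$assignments$cluster == "SMALL"
    recovered <- sum(truth[small_ids] == "small") /
      sum(truth == "small")
    if (recovered >= 0.95) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("cluster_genome is a pure function of points, seed and parameters", {
  sim <- simulate_genome("det", n_genes = 300, seed = 9)
  tbl <- genome_frequency_table(sim$genes)
  a <- cluster_genome(tbl, "det", k_range = 2:4, n_restarts = 10)
  b <- cluster_genome(tbl, "det", k_range = 2:4, n_restarts = 10)
  expect_identical(tidy(a), tidy(b))
  expect_identical(a$silhouette$per_k, b$silhouette$per_k)
  expect_identical(glance(a), glance(b))
})

test_that("silhouette subsampling approximates the full score", {
  set.seed(21)
  pts <- make_blobs(list(c(0.32, 0.27), c(0.22, 0.45)), c(450, 50))
  full <- select_optimal_k(pts, k_range = 2:4, n_restarts = 10)
  capped <- select_optimal_k(pts, k_range = 2:4, n_restarts = 10,
                             subsample_cap = 200)
  expect_equal(capped$optimal_k, full$optimal_k)
  expect_lt(max(abs(capped$per_k$silhouette - full$per_k$silhouette)), 0.1)
})
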