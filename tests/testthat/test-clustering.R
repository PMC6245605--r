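# k-medoids, agglomerative, DBSCAN, silhouettes, and optimal-k selection.

test_that("k_medoids recovers separated blobs and matches exhaustive search", {
  bl <- blob_matrix(c(4, 4))
  cl <- k_medoids(bl$d, 2)
  expect_equal(rand_index(cl$labels, bl$labels), 1)
  expect_equal(cl$params$objective,
               exhaustive_kmedoids_objective(bl$d$values, 2))
  # random matrices: heuristic with 10 restarts attains the exhaustive optimum
  set.seed(77)
  for (trial in 1:8) {
    n <- sample(6:8, 1)
    k <- sample(2:3, 1)
    v <- matrix(runif(n * n), n, n); v <- (v + t(v)) / 2; diag(v) <- 0
    d <- distance_matrix(v, sprintf("m%d", 1:n))
    cl <- k_medoids(d, k, seed = trial, restarts = 10)
    expect_equal(cl$params$objective, exhaustive_kmedoids_objective(v, k),
                 tolerance = 1e-12)
  }
})

test_that("k_medoids respects its k range and is deterministic in its seed", {
  set.seed(3)
  v <- matrix(runif(36), 6, 6); v <- (v + t(v)) / 2; diag(v) <- 0
  d <- distance_matrix(v, sprintf("m%d", 1:6))
  expect_error(k_medoids(d, 6), "k must be")
  expect_error(k_medoids(d, 1), "k must be")
  # k = n - 1 on distinct points: one 2-cluster and n - 2 singletons
  cl <- k_medoids(d, 5)
  expect_equal(sort(as.numeric(table(cl$labels))), c(1, 1, 1, 1, 2))
  expect_identical(k_medoids(d, 3, seed = 9)$labels, k_medoids(d, 3, seed = 9)$labels)
})

test_that("agglomerative average linkage cuts behave at the extremes and on pairs", {
  # two tight pairs
  v <- matrix(c(0, 0.1, 5, 5,
                0.1, 0, 5, 5,
                5, 5, 0, 0.1,
                5, 5, 0.1, 0), 4, 4)
  d <- distance_matrix(v, c("a", "b", "c", "d"))
  cl <- agglomerative(d, 2)
  expect_equal(rand_index(cl$labels,
                          stats::setNames(c(1, 1, 2, 2), c("a", "b", "c", "d"))), 1)
  expect_equal(length(unique(agglomerative(d, 4)$labels)), 4L)
  expect_equal(length(unique(agglomerative(d, 1)$labels)), 1L)
  expect_error(agglomerative(d, 5), "k must be")
})

test_that("dbscan forms density clusters and isolates noise as singletons", {
  bl <- blob_matrix(c(5, 5), within = 0.1, between = 2)
  one <- dbscan_cluster(bl$d, eps = 5, min_pts = 2)
  expect_equal(length(unique(one$labels)), 1L)
  two <- dbscan_cluster(bl$d, eps = 0.5, min_pts = 2)
  expect_equal(rand_index(two$labels, bl$labels), 1)
  # everything isolated: n singleton clusters
  flat <- distance_matrix(matrix(1, 5, 5) - diag(5), sprintf("m%d", 1:5))
  all_noise <- dbscan_cluster(flat, eps = 0.5, min_pts = 2)
  expect_equal(length(unique(all_noise$labels)), 5L)
  expect_equal(all_noise$params$n_noise, 5L)
})

test_that("dbscan is invariant to id permutation up to relabeling", {
  bl <- blob_matrix(c(4, 3, 5), within = 0.1, between = 2)
  base <- dbscan_cluster(bl$d, eps = 0.5, min_pts = 2)
  set.seed(15)
  perm <- sample(length(bl$d$ids))
  dperm <- distance_matrix(bl$d$values[perm, perm], bl$d$ids[perm])
  permed <- dbscan_cluster(dperm, eps = 0.5, min_pts = 2)
  expect_equal(rand_index(base$labels, permed$labels), 1)
})

test_that("silhouette widths follow the definition exactly", {
  bl <- blob_matrix(c(5, 5))
  truth <- clustering(bl$d$ids, bl$labels, "truth")
  prof <- silhouette_widths(bl$d, truth)
  expect_equal(unname(prof$widths), rep(1, 10))
  expect_equal(prof$average, 1)
  # object equidistant between its own and the other cluster: s = 0
  v <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3)
  d <- distance_matrix(v, c("a", "b", "c"))
  cl <- clustering(d$ids, c(1, 1, 2), "fix")
  prof2 <- silhouette_widths(d, cl)
  expect_equal(unname(prof2$widths[1]), 0)    # a: a_i = b_i = 1
  expect_equal(unname(prof2$widths[3]), 0)    # singleton convention
  # 4-point hand-computed fixture
  v4 <- matrix(c(0, 1, 4, 5,
                 1, 0, 3, 6,
                 4, 3, 0, 2,
                 5, 6, 2, 0), 4, 4)
  d4 <- distance_matrix(v4, c("p", "q", "r", "s"))
  cl4 <- clustering(d4$ids, c(1, 1, 2, 2), "fix")
  prof4 <- silhouette_widths(d4, cl4)
  expected <- c((4.5 - 1) / 4.5, (4.5 - 1) / 4.5, (3.5 - 2) / 3.5, (5.5 - 2) / 5.5)
  expect_equal(unname(prof4$widths), expected, tolerance = 1e-12)
  expect_error(silhouette_widths(d4, clustering(d4$ids, rep(1, 4), "one")),
               "single cluster")
})

test_that("silhouette widths agree with the reference implementation", {
  skip_if_not_installed("cluster")
  set.seed(44)
  v <- matrix(runif(100, 0.2, 2), 10, 10); v <- (v + t(v)) / 2; diag(v) <- 0
  d <- distance_matrix(v, sprintf("m%d", 1:10))
  labels <- sample(1:3, 10, replace = TRUE)
  labels[1:3] <- 1:3                      # ensure all clusters non-empty
  cl <- clustering(d$ids, labels, "fix")
  mine <- silhouette_widths(d, cl)
  ref <- cluster::silhouette(labels, dmatrix = v)
  expect_equal(unname(mine$widths), unname(ref[, "sil_width"]), tolerance = 1e-12)
})

test_that("select_k maximizes average silhouette width with parsimony ties", {
  bl3 <- blob_matrix(c(4, 5, 6), within = 0.05, between = 1)
  res <- select_k(bl3$d, "kmedoids", 2:6)
  expect_equal(res$k, 3L)
  expect_equal(rand_index(res$clustering$labels, bl3$labels), 1)
  expect_equal(nrow(res$profile$per_k), 5L)
  bl2 <- blob_matrix(c(5, 5))
  res2 <- select_k(bl2$d, "kmedoids", 2:4)
  expect_equal(res2$k, 2L)
  expect_equal(res2$profile$average, 1)
  # k range is capped at n - 1
  res3 <- select_k(bl2$d, "agglomerative", 3:25)
  expect_lte(res3$k, 9L)
  expect_error(select_k(bl2$d, "kmedoids", 30:40), "empty effective")
})

test_that("ground-truth silhouette degrades monotonically with noise", {
  set.seed(91)
  sep <- 1
  avg_for_noise <- function(noise) {
    bl <- blob_matrix(c(5, 5), within = noise, between = sep)
    v <- bl$d$values
    jitter <- matrix(abs(rnorm(100, 0, noise / 10)), 10, 10)
    jitter <- (jitter + t(jitter)) / 2; diag(jitter) <- 0
    d <- distance_matrix(v + jitter, bl$d$ids)
    silhouette_widths(d, clustering(d$ids, bl$labels, "truth"))$average
  }
  a <- vapply(c(0.01, 0.3, 0.8), avg_for_noise, numeric(1))
  expect_true(all(diff(a) < 0))
  expect_gt(a[1], 0.9)
})
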