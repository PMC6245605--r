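# Descriptor-space RMSD, distance matrices, normalization and fusion.

test_that("descriptor_rmsd evaluates the per-point RMSD formula", {
  fi <- descriptor_set("a", "rsd", rbind(c(1, 2), c(3, 4)), 1:2)
  expect_equal(descriptor_rmsd(fi, fi), 0)
  # L = 1 reduces to the Euclidean distance (3-4-5 triangle)
  g1 <- descriptor_set("a", "vfh", matrix(c(0, 0, 0), 1))
  g2 <- descriptor_set("b", "vfh", matrix(c(3, 4, 0), 1))
  expect_equal(descriptor_rmsd(g1, g2), 5)
  # L = 2, per-point difference norms 3 and 4 -> sqrt((9 + 16) / 2)
  h1 <- descriptor_set("a", "rsd", rbind(c(0, 0), c(0, 0)), 1:2)
  h2 <- descriptor_set("b", "rsd", rbind(c(3, 0), c(0, 4)), 1:2)
  expect_equal(descriptor_rmsd(h1, h2), sqrt(25 / 2))
  # mismatches are named in the error
  expect_error(descriptor_rmsd(g1, fi), "type mismatch")
  j <- descriptor_set("c", "rsd", rbind(c(1, 2)), 1L)
  expect_error(descriptor_rmsd(fi, j), "2 x 2 vs 1 x 2")
})

test_that("distance_matrix enforces its invariants", {
  v <- matrix(c(0, 1, 1, 0), 2, 2)
  d <- distance_matrix(v, c("a", "b"))
  expect_equal(diag(d$values), c(0, 0), ignore_attr = TRUE)
  expect_error(distance_matrix(matrix(c(0, 1, 2, 0), 2, 2), c("a", "b")), "symmetric")
  expect_error(distance_matrix(matrix(c(1, 1, 1, 1), 2, 2), c("a", "b")), "diagonal")
  expect_error(distance_matrix(-v, c("a", "b")), "negative")
})

test_that("pairwise matrices separate families and zero duplicates", {
  ds <- small_dataset(c(2, 1), seed = 19, length = 40)
  models <- ds$models
  # append an exact duplicate of the first model under a new id
  dup <- models[[1]]
  dup$model_id <- "zz_dup"
  models <- c(models, list(zz_dup = dup))
  d <- pairwise_distance_matrix(models, "fpfh", selection = "calpha")
  v <- d$values
  expect_equal(v[models[[1]]$model_id, "zz_dup"], 0, tolerance = 1e-6)
  # within-family distance below cross-family distances
  ids <- d$ids
  fam <- ifelse(ids == "zz_dup", "T1", substr(ids, 1, 2))
  within <- v[fam[row(v)] == fam[col(v)] & upper.tri(v)]
  across <- v[fam[row(v)] != fam[col(v)] & upper.tri(v)]
  expect_lt(max(within), min(across))
  # 2-model edge case
  d2 <- pairwise_distance_matrix(models[1:2], "rsd", selection = "calpha")
  expect_equal(dim(d2$values), c(2L, 2L))
  expect_equal(diag(d2$values), c(0, 0), ignore_attr = TRUE)
})

test_that("fpfh pairwise distances are invariant to a common rigid motion", {
  ds <- small_dataset(c(2, 1), seed = 23, length = 40)
  base <- pairwise_distance_matrix(ds$models, "fpfh", selection = "calpha")
  set.seed(31)
  mv <- random_rigid()
  moved <- lapply(ds$models, function(m) {
    xyz <- rigid_move(as.matrix(m$atoms[, c("x", "y", "z")]), mv$rotation, mv$translation)
    m$atoms$x <- xyz[, 1]; m$atoms$y <- xyz[, 2]; m$atoms$z <- xyz[, 3]
    m
  })
  d2 <- pairwise_distance_matrix(moved, "fpfh", selection = "calpha")
  expect_lt(max(abs(base$values - d2$values)), 1e-6)
})

test_that("tm distance averages both score directions", {
  m <- generate_template(30, seed = 2)
  m2 <- m; m2$model_id <- "copy"
  m3 <- generate_template(30, seed = 9, model_id = "other")
  d <- tm_distance_matrix(list(m, m2, m3))
  expect_equal(d$values[m$model_id, "copy"], 0, tolerance = 1e-9)
  expect_true(all(d$values >= 0 & d$values < 1))
  # precomputed-score path: distance = 1 - mean(tm_ab, tm_ba)
  scores <- data.frame(model_a = c("x", "x", "y"), model_b = c("y", "z", "z"),
                       tm_ab = c(0.6, 0.5, 0.9), tm_ba = c(0.6, 0.7, 0.9))
  dt <- tm_distance_matrix(scores = scores)
  expect_equal(dt$values["x", "y"], 0.4)
  expect_equal(dt$values["x", "z"], 0.4)
  expect_equal(dt$values["y", "z"], 0.1, tolerance = 1e-12)
})

test_that("normalize_matrix maps to [0, 1] elementwise and is idempotent", {
  set.seed(12)
  v <- matrix(runif(25, 0, 10), 5, 5)
  v <- (v + t(v)) / 2
  diag(v) <- 0
  d <- distance_matrix(v, letters[1:5])
  nd <- normalize_matrix(d)
  expect_equal(max(nd$values), 1)
  expect_equal(nd$values, d$values / max(d$values), ignore_attr = TRUE)
  expect_true(nd$normalized)
  expect_equal(normalize_matrix(nd)$values, nd$values)
  zero <- distance_matrix(matrix(0, 3, 3), letters[1:3])
  expect_error(normalize_matrix(zero), "all-zero")
})

test_that("fuse computes the exact weighted sum and validates inputs", {
  v1 <- matrix(c(0, 0.2, 0.2, 0), 2, 2)
  v2 <- matrix(c(0, 0.8, 0.8, 0), 2, 2)
  d1 <- distance_matrix(v1, c("a", "b"), normalized = TRUE)
  d2 <- distance_matrix(v2, c("a", "b"), normalized = TRUE)
  expect_equal(fuse(list(d1, d1), c(1, 1))$values, 2 * v1, ignore_attr = TRUE)
  expect_equal(fuse(list(d1, d2), c(1, 0))$values, v1, ignore_attr = TRUE)
  f <- fuse(list(d1, d2), c(0.07, 0.057))
  expect_equal(f$values[1, 2], 0.07 * 0.2 + 0.057 * 0.8, tolerance = 1e-15)
  # linearity in the matrices
  c3 <- distance_matrix(3 * v1, c("a", "b"), normalized = TRUE)
  expect_equal(3 * fuse(list(d1), 2)$values, fuse(list(c3), 2)$values)
  expect_error(fuse(list(d1, d2), c(0, 0)), "positive")
  d3 <- distance_matrix(v1, c("a", "c"), normalized = TRUE)
  expect_error(fuse(list(d1, d3), c(1, 1)), "id ordering")
  raw <- distance_matrix(v1, c("a", "b"))
  expect_error(fuse(list(d1, raw), c(1, 1)), "not normalized")
})

test_that("silhouette weights reward structured matrices", {
  bl <- blob_matrix(c(5, 5))
  w <- silhouette_weights(list(bl$d), k_range = 2:4)
  expect_equal(w$w, 1)                       # perfectly separated -> weight 1
  flat <- distance_matrix(matrix(1, 8, 8) - diag(8), sprintf("m%d", 1:8))
  # structureless alone: clamps to 0 and falls back to equal weights
  expect_warning(wf <- silhouette_weights(list(flat), k_range = 2:4), "equal weights")
  expect_equal(wf$w, 1)
  # next to a structured matrix, the structureless one gets weight 0
  wb <- silhouette_weights(list(bl$d, flat), k_range = 2:4)
  expect_equal(wb$w[2], 0)
  set.seed(5)
  rv <- matrix(runif(64, 0.8, 1.2), 8, 8)
  rv <- (rv + t(rv)) / 2; diag(rv) <- 0
  noisy <- distance_matrix(rv, sprintf("m%d", 1:8))
  w2 <- silhouette_weights(list(bl$d, noisy), k_range = 2:4)
  expect_gt(w2$w[1], w2$w[2])                # structure outweighs noise
})

test_that("distance matrices survive a TSV round trip", {
  set.seed(2)
  v <- matrix(runif(16), 4, 4); v <- (v + t(v)) / 2; diag(v) <- 0
  d <- distance_matrix(v, c("a", "b", "c", "d"), provenance = "fpfh")
  path <- tempfile(fileext = ".tsv")
  write_distance_matrix(d, path)
  d2 <- read_distance_matrix(path, provenance = "fpfh")
  expect_equal(d2$values, d$values, tolerance = 1e-12)
  expect_equal(d2$ids, d$ids)
})
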