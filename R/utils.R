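# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded internals never
#' disturb the user's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' All-pairs Euclidean distances between two coordinate sets
#' @param a n x 3 matrix
#' @param b m x 3 matrix
#' @return n x m matrix
#' @noRd
cross_dist <- function(a, b) {
  d2 <- matrix(rowSums(a^2), nrow(a), nrow(b)) +
    matrix(rowSums(b^2), nrow(a), nrow(b), byrow = TRUE) -
    2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' All-pairs distances of one point set, with an exactly zero diagonal
#'
#' The Gram-matrix formula leaves ~1e-8 noise on self-distances, which would
#' let points count themselves as neighbors; the diagonal is forced to zero.
#' @noRd
self_dist <- function(points) {
  d <- cross_dist(points, points)
  diag(d) <- 0
  d
}

#' k nearest neighbours of every point (self excluded)
#'
#' Exact search on the full distance matrix; distance ties are broken by the
#' lower point index (order() is stable).
#' @return list(idx = n x k integer matrix, dist = n x k numeric matrix)
#' @noRd
knn_all <- function(points, k) {
  n <- nrow(points)
  if (k >= n) stop("neighbor_k must be smaller than the number of points")
  dm <- self_dist(points)
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    # quantize before ordering so exact geometric ties (common in regular
    # synthetic backbones) resolve by point index, not by fp rounding noise
    ord <- order(round(dm[i, ], 6), seq_len(n))
    ord <- ord[ord != i][seq_len(k)]
    idx[i, ] <- ord
    dst[i, ] <- dm[i, ord]
  }
  list(idx = idx, dist = dst)
}

#' Normalize rows of a matrix to unit Euclidean norm
#' @noRd
unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

#' Random rotation matrix (uniform over SO(3), via quaternions)
#' @noRd
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Apply a rigid motion to an n x 3 coordinate matrix
#' @noRd
apply_rigid <- function(coords, rotation, translation) {
  sweep(coords %*% t(rotation), 2, translation, `+`)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
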