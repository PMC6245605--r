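# Local and global 3D shape descriptors over protein point clouds.
#
# Four descriptor types are implemented, all operating on the atom point cloud
# of a (pairwise-aligned) protein model:
#   FPFH  - fast point feature histogram: per-point angular-relation histograms
#           in local Darboux frames, accumulated from an intermediate SPFH.
#   SC3D  - 3D shape context: per-point density-weighted histogram over
#           azimuth x elevation x log-radius bins of a support sphere.
#   RSD   - radius-based surface descriptor: per-point (min, max) radius of
#           spheres consistent with neighbor positions and normals.
#   VFH   - viewpoint feature histogram: one global vector combining a
#           centroid-anchored SPFH with a viewpoint-direction angle histogram.

#' Descriptor configuration
#'
#' Tunable parameters of the shape descriptors, with defaults in the range
#' customary for the reference implementations of these descriptors. All
#' lengths are in Angstrom.
#'
#' @param neighbor_k Neighborhood size for normal estimation and FPFH.
#' @param support_radius Radius of the SC3D/RSD support sphere.
#' @param sc_bins Integer triple (azimuth, elevation, radial) of SC3D bins.
#' @param sc_min_radius_fraction Inner radius of the SC3D log-radial binning,
#'   as a fraction of `support_radius` (in (0, 1)).
#' @param sc_density_radius Radius `delta` of the sphere used for the SC3D
#'   point-density weight.
#' @param rsd_plane_radius Clamp radius returned for (near-)flat surfaces.
#' @param rsd_taylor_crossover Normal angle (radians) below which the
#'   first-order Taylor inversion `r = d / alpha` is used instead of the exact
#'   chord inversion.
#' @param fpfh_bins_per_feature Histogram bins per angular feature (the
#'   default 11 yields the standard 33-dimensional FPFH).
#' @param viewpoint Optional 3-vector; when `NULL`, descriptor functions that
#'   need a viewpoint place it at the cloud centroid plus three bounding radii
#'   along +z.
#' @return A list of class `descriptor_config`.
#' @export
descriptor_config <- function(neighbor_k = 10L,
                              support_radius = 8,
                              sc_bins = c(azimuth = 12L, elevation = 11L, radial = 15L),
                              sc_min_radius_fraction = 0.1,
                              sc_density_radius = 2,
                              rsd_plane_radius = 20,
                              rsd_taylor_crossover = 0.1,
                              fpfh_bins_per_feature = 11L,
                              viewpoint = NULL) {
  stopifnot(neighbor_k >= 1, support_radius > 0, length(sc_bins) == 3L,
            all(sc_bins >= 1), sc_min_radius_fraction > 0,
            sc_min_radius_fraction < 1, sc_density_radius > 0,
            rsd_plane_radius > 0, fpfh_bins_per_feature >= 1)
  structure(list(
    neighbor_k = as.integer(neighbor_k),
    support_radius = support_radius,
    sc_bins = as.integer(sc_bins),
    sc_min_radius_fraction = sc_min_radius_fraction,
    sc_density_radius = sc_density_radius,
    rsd_plane_radius = rsd_plane_radius,
    rsd_taylor_crossover = rsd_taylor_crossover,
    fpfh_bins_per_feature = as.integer(fpfh_bins_per_feature),
    viewpoint = viewpoint
  ), class = "descriptor_config")
}

#' Construct a descriptor set
#'
#' The set of feature vectors `F_i = {f_i1, ..., f_iL}` extracted from one
#' protein under one descriptor type; an `L x D` matrix plus the anchor-point
#' indices the rows correspond to.
#'
#' @param model_id Model identifier.
#' @param type One of `"fpfh"`, `"sc3d"`, `"rsd"`, `"vfh"`.
#' @param vectors L x D numeric matrix (finite, non-negative).
#' @param anchors Integer vector of the L query-point indices (may be `NA` for
#'   global descriptors).
#' @return An object of class `descriptor_set`.
#' @export
descriptor_set <- function(model_id, type, vectors, anchors = NA_integer_) {
  type <- match.arg(type, c("fpfh", "sc3d", "rsd", "vfh"))
  vectors <- as.matrix(vectors)
  if (!all(is.finite(vectors))) stopf("descriptor vectors must be finite")
  if (any(vectors < 0)) stopf("descriptor vectors must be non-negative")
  if (type == "vfh" && nrow(vectors) != 1L) stopf("vfh descriptor sets must have L = 1")
  structure(list(model_id = model_id, type = type, vectors = vectors,
                 anchors = as.integer(anchors)),
            class = "descriptor_set")
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf("<descriptor_set> %s/%s: L = %d, D = %d\n",
              x$model_id, x$type, nrow(x$vectors), ncol(x$vectors)))
  invisible(x)
}

#' Write / read a descriptor set as TSV
#'
#' One row per feature vector, keyed by model id, descriptor type and anchor
#' index, so sets from several models can share a directory.
#'
#' @param x A [descriptor_set()].
#' @param path File path.
#' @return `path` / a [descriptor_set()].
#' @export
write_descriptor_set <- function(x, path) {
  df <- data.frame(model_id = x$model_id, type = x$type,
                   anchor = x$anchors, x$vectors, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_descriptor_set
#' @export
read_descriptor_set <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  descriptor_set(unique(df$model_id), unique(df$type),
                 as.matrix(df[, -(1:3), drop = FALSE]), df$anchor)
}

#' Estimate per-point surface normals
#'
#' Each point's normal is the smallest-eigenvalue direction of the covariance
#' of its `neighbor_k`-neighborhood (neighbors plus the point itself). With an
#' explicit `viewpoint`, normals are flipped to face it; with
#' `viewpoint = NULL` (the default) they are oriented away from the cloud
#' centroid, which makes the orientation equivariant under rigid motions of
#' the cloud.
#'
#' @param cloud A [point_cloud()] with at least `neighbor_k + 1` points.
#' @param neighbor_k Neighborhood size.
#' @param viewpoint Optional 3-vector to face.
#' @return The cloud with unit `normals` filled in.
#' @export
estimate_normals <- function(cloud, neighbor_k = 10L, viewpoint = NULL) {
  pts <- cloud$points
  n <- nrow(pts)
  if (n < neighbor_k + 1L) {
    stopf("estimate_normals: need at least neighbor_k + 1 = %d points, got %d",
          neighbor_k + 1L, n)
  }
  nn <- knn_all(pts, neighbor_k)
  centroid <- colMeans(pts)
  normals <- matrix(0, n, 3)
  degenerate <- FALSE
  for (i in seq_len(n)) {
    nbh <- pts[c(i, nn$idx[i, ]), , drop = FALSE]
    cv <- stats::cov(nbh)
    if (!all(is.finite(cv)) || sum(abs(cv)) < 1e-24) {
      normals[i, ] <- c(0, 0, 1)
      degenerate <- TRUE
      next
    }
    eg <- eigen(cv, symmetric = TRUE)
    v <- eg$vectors[, 3L]
    ref <- if (is.null(viewpoint)) pts[i, ] - centroid else viewpoint - pts[i, ]
    if (sum(v * ref) < 0) v <- -v
    normals[i, ] <- v / sqrt(sum(v^2))
  }
  if (degenerate) warnf("estimate_normals: degenerate neighborhood(s); defaulted normal to (0, 0, 1)")
  point_cloud(pts, normals = normals, anchor_index = cloud$anchor_index)
}

#' Darboux-frame pair features
#'
#' The three angular features between an oriented source point and an oriented
#' target point: with `u = n1`, `v = u x (p2 - p1) / d` (normalized),
#' `w = u x v`, they are `alpha = v . n2`, `phi = u . (p2 - p1) / d`,
#' `theta = atan2(w . n2, u . n2)`. Invariant under a common rigid motion of
#' all four inputs.
#'
#' @param p1,p2 Distinct 3D points.
#' @param n1,n2 Unit normals at `p1`, `p2`.
#' @return Named numeric vector `(alpha, phi, theta)` with
#'   `alpha, phi \in [-1, 1]`, `theta \in (-pi, pi]`.
#' @export
pair_features <- function(p1, n1, p2, n2) {
  f <- pair_features_block(p1, n1, matrix(p2, 1), matrix(n2, 1))
  c(alpha = f[1, 1], phi = f[1, 2], theta = f[1, 3])
}

# vectorized pair features from one source to many targets; rows (alpha, phi, theta)
pair_features_block <- function(p1, n1, P2, N2) {
  dp <- sweep(P2, 2, p1)
  d <- sqrt(rowSums(dp^2))
  if (any(d < 1e-12)) stopf("pair_features: coincident points")
  dh <- dp / d
  u <- n1
  v <- cbind(u[2] * dh[, 3] - u[3] * dh[, 2],
             u[3] * dh[, 1] - u[1] * dh[, 3],
             u[1] * dh[, 2] - u[2] * dh[, 1])
  vn <- sqrt(rowSums(v^2))
  bad <- vn < 1e-9
  if (any(bad)) {
    # u parallel to the connecting line: any unit vector orthogonal to u works
    e <- diag(3)[, which.min(abs(u))]
    fb <- c(u[2] * e[3] - u[3] * e[2], u[3] * e[1] - u[1] * e[3], u[1] * e[2] - u[2] * e[1])
    fb <- fb / sqrt(sum(fb^2))
    v[bad, ] <- matrix(fb, sum(bad), 3, byrow = TRUE)
    vn[bad] <- 1
  }
  v <- v / vn
  w <- cbind(u[2] * v[, 3] - u[3] * v[, 2],
             u[3] * v[, 1] - u[1] * v[, 3],
             u[1] * v[, 2] - u[2] * v[, 1])
  alpha <- rowSums(v * N2)
  phi <- as.numeric(dh %*% u)
  # snap the atan2 arguments so exactly-coplanar geometry yields theta = +pi
  # stably instead of flipping between +pi and -pi under fp noise
  wy <- rowSums(w * N2)
  ux <- as.numeric(N2 %*% u)
  wy[abs(wy) < 1e-9] <- 0
  ux[abs(ux) < 1e-9] <- 0
  theta <- atan2(wy, ux)
  cbind(alpha = pmin(pmax(alpha, -1), 1), phi = pmin(pmax(phi, -1), 1), theta = theta)
}

# histogram of one feature column over nb uniform bins in [lo, hi]
feature_hist <- function(x, nb, lo, hi) {
  idx <- pmin(pmax(floor((x - lo) / (hi - lo) * nb) + 1L, 1L), nb)
  tabulate(idx, nbins = nb)
}

# SPFH histogram (3 concatenated blocks, each normalized to sum 100) from a
# feature matrix with rows (alpha, phi, theta)
spfh_from_features <- function(feat, nb) {
  h <- c(feature_hist(feat[, 1], nb, -1, 1),
         feature_hist(feat[, 2], nb, -1, 1),
         feature_hist(feat[, 3], nb, -pi, pi))
  blocks <- rep(seq_len(3L), each = nb)
  sums <- tapply(h, blocks, sum)
  sums[sums == 0] <- 1
  as.numeric(100 * h / sums[blocks])
}

#' Simplified point feature histogram of one query point
#'
#' Histograms of the pair features between the query point and each of its
#' `neighbor_k` nearest neighbors; three concatenated blocks (alpha, phi,
#' theta), each normalized to sum 100.
#'
#' @param cloud A [point_cloud()] with normals.
#' @param query_index Index of the query point.
#' @param neighbor_k Neighborhood size (capped, with a warning, at the number
#'   of available neighbors).
#' @param bins_per_feature Bins per feature block.
#' @return Numeric vector of length `3 * bins_per_feature`.
#' @export
spfh <- function(cloud, query_index, neighbor_k = 10L, bins_per_feature = 11L) {
  if (is.null(cloud$normals)) stopf("spfh: cloud has no normals; run estimate_normals() first")
  n <- nrow(cloud$points)
  if (neighbor_k > n - 1L) {
    warnf("spfh: only %d neighbors available; using all of them", n - 1L)
    neighbor_k <- n - 1L
  }
  nn <- knn_all(cloud$points, neighbor_k)
  idx <- nn$idx[query_index, ]
  feat <- pair_features_block(cloud$points[query_index, ], cloud$normals[query_index, ],
                              cloud$points[idx, , drop = FALSE],
                              cloud$normals[idx, , drop = FALSE])
  spfh_from_features(feat, bins_per_feature)
}

#' Fast point feature histograms
#'
#' `FPFH(p) = SPFH(p) + (1/k) * sum_i (1/d_i) SPFH(p_i)` over the k nearest
#' neighbors `p_i` of `p` at distances `d_i`. With the default 11 bins per
#' feature each vector is 33-dimensional. Translation-invariant; rotational
#' variation is handled by aligning the models before extraction.
#'
#' @param cloud A [point_cloud()] with normals.
#' @param config A [descriptor_config()].
#' @param anchors Indices of the query points; defaults to the cloud's
#'   `anchor_index` (or every point if absent).
#' @param model_id Identifier stored in the result.
#' @return A [descriptor_set()] with one row per anchor.
#' @export
fpfh <- function(cloud, config = descriptor_config(), anchors = NULL,
                 model_id = "cloud") {
  if (is.null(cloud$normals)) stopf("fpfh: cloud has no normals; run estimate_normals() first")
  pts <- cloud$points
  n <- nrow(pts)
  anchors <- default_anchors(cloud, anchors)
  k <- min(config$neighbor_k, n - 1L)
  if (k < config$neighbor_k) warnf("fpfh: neighbor_k reduced to %d (cloud has %d points)", k, n)
  nn <- knn_all(pts, k)
  nb <- config$fpfh_bins_per_feature
  needed <- sort(unique(c(anchors, as.integer(nn$idx[anchors, ]))))
  sp <- matrix(0, n, 3L * nb)
  for (i in needed) {
    idx <- nn$idx[i, ]
    feat <- pair_features_block(pts[i, ], cloud$normals[i, ],
                                pts[idx, , drop = FALSE],
                                cloud$normals[idx, , drop = FALSE])
    sp[i, ] <- spfh_from_features(feat, nb)
  }
  out <- matrix(0, length(anchors), 3L * nb)
  for (j in seq_along(anchors)) {
    i <- anchors[j]
    idx <- nn$idx[i, ]
    wts <- 1 / pmax(nn$dist[i, ], 1e-12)
    out[j, ] <- sp[i, ] + colSums(sp[idx, , drop = FALSE] * wts) / k
  }
  descriptor_set(model_id, "fpfh", out, anchors)
}

default_anchors <- function(cloud, anchors) {
  if (!is.null(anchors)) return(as.integer(anchors))
  if (!is.null(cloud$anchor_index)) return(as.integer(cloud$anchor_index))
  seq_len(nrow(cloud$points))
}

#' 3D shape context descriptors
#'
#' For each anchor point, a histogram over the support sphere centered at it,
#' binned uniformly in azimuth and elevation and logarithmically in radius.
#' The sphere's polar axis is the surface normal at the anchor. Each
#' in-support point `p_i` contributes `w(p_i) = 1 / (rho_i * V(bin)^(1/3))`,
#' where `V` is the bin volume and the local density `rho_i` counts the cloud
#' points within `sc_density_radius` of `p_i` (itself included).
#'
#' Azimuth needs a reference direction orthogonal to the normal; the global
#' axis least parallel to the normal is projected onto the tangent plane,
#' which is deterministic for a fixed input pose.
#'
#' @inheritParams fpfh
#' @return A [descriptor_set()] with `prod(sc_bins)` columns.
#' @export
shape_context_3d <- function(cloud, config = descriptor_config(), anchors = NULL,
                             model_id = "cloud") {
  if (is.null(cloud$normals)) stopf("shape_context_3d: cloud has no normals")
  pts <- cloud$points
  anchors <- default_anchors(cloud, anchors)
  J <- config$sc_bins[1]; K <- config$sc_bins[2]; R <- config$sc_bins[3]
  rmax <- config$support_radius
  rmin <- config$sc_min_radius_fraction * rmax
  redges <- exp(seq(log(rmin), log(rmax), length.out = R + 1L))
  # local point density within delta (self included); distances quantized so
  # that boundary membership is stable under fp-level coordinate noise
  dm <- round(self_dist(pts), 6)
  rho <- rowSums(dm <= config$sc_density_radius)
  # bin volumes: V = (daz / 3) (r_hi^3 - r_lo^3) (cos el_lo - cos el_hi)
  daz <- 2 * pi / J
  eedges <- seq(0, pi, length.out = K + 1L)
  vshell <- (redges[-1L]^3 - redges[-(R + 1L)]^3) / 3
  vband <- cos(eedges[-(K + 1L)]) - cos(eedges[-1L])
  vol <- array(0, c(J, K, R))
  for (j in seq_len(J)) vol[j, , ] <- daz * outer(vband, vshell)
  empty <- FALSE
  out <- matrix(0, length(anchors), J * K * R)
  for (qi in seq_along(anchors)) {
    i <- anchors[qi]
    r <- dm[i, ]
    insup <- which(r > 1e-12 & r <= rmax)
    if (!length(insup)) { empty <- TRUE; next }
    z <- cloud$normals[i, ]
    e <- diag(3)[, which.min(abs(z))]
    x <- e - sum(e * z) * z
    x <- x / sqrt(sum(x^2))
    y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3], z[1] * x[2] - z[2] * x[1])
    dp <- sweep(pts[insup, , drop = FALSE], 2, pts[i, ])
    lx <- as.numeric(dp %*% x); ly <- as.numeric(dp %*% y); lz <- as.numeric(dp %*% z)
    rr <- r[insup]
    az <- atan2(ly, lx) %% (2 * pi)
    el <- acos(pmin(pmax(lz / rr, -1), 1))
    jb <- pmin(floor(az / daz) + 1L, J)
    kb <- pmin(pmax(floor(el / pi * K) + 1L, 1L), K)
    rb <- pmin(pmax(findInterval(rr, redges, rightmost.closed = TRUE), 1L), R)
    flat <- (rb - 1L) * J * K + (kb - 1L) * J + jb
    w <- 1 / (rho[insup] * vol[cbind(jb, kb, rb)]^(1 / 3))
    acc <- rowsum(w, flat)
    out[qi, as.integer(rownames(acc))] <- acc[, 1L]
  }
  if (empty) warnf("shape_context_3d: empty support region(s); zero descriptor emitted")
  descriptor_set(model_id, "sc3d", out, anchors)
}

#' Radius-based surface descriptors
#'
#' For each anchor, fits a sphere through the anchor and each in-support
#' neighbor consistent with their normals: with point distance `d` and normal
#' angle `alpha`, the chord relation `d = r * sqrt(2 - 2 cos(alpha))` gives
#' the sphere radius. Below `rsd_taylor_crossover` the first-order Taylor
#' inversion `r = d / alpha` is used. Radii are clamped at
#' `rsd_plane_radius` (the flat-surface limit); the descriptor is the pair
#' `(r_min, r_max)` over the neighbors.
#'
#' @inheritParams fpfh
#' @return A [descriptor_set()] with columns `(r_min, r_max)`.
#' @export
rsd <- function(cloud, config = descriptor_config(), anchors = NULL,
                model_id = "cloud") {
  if (is.null(cloud$normals)) stopf("rsd: cloud has no normals")
  pts <- cloud$points
  anchors <- default_anchors(cloud, anchors)
  dm <- round(self_dist(pts), 6)
  rmax_clamp <- config$rsd_plane_radius
  out <- matrix(0, length(anchors), 2L)
  empty <- FALSE
  for (qi in seq_along(anchors)) {
    i <- anchors[qi]
    r <- dm[i, ]
    insup <- which(r > 1e-12 & r <= config$support_radius)
    if (!length(insup)) {
      out[qi, ] <- c(rmax_clamp, rmax_clamp)
      empty <- TRUE
      next
    }
    ca <- pmin(pmax(as.numeric(cloud$normals[insup, , drop = FALSE] %*% cloud$normals[i, ]), -1), 1)
    alpha <- acos(ca)
    d <- r[insup]
    rad <- ifelse(alpha < config$rsd_taylor_crossover,
                  d / pmax(alpha, 1e-12),
                  d / sqrt(2 - 2 * cos(alpha)))
    rad <- pmin(rad, rmax_clamp)
    out[qi, ] <- c(min(rad), max(rad))
  }
  if (empty) warnf("rsd: anchor(s) with empty support; plane radius emitted")
  colnames(out) <- c("r_min", "r_max")
  descriptor_set(model_id, "rsd", out, anchors)
}

#' Viewpoint feature histogram (global descriptor)
#'
#' A single vector per cloud: (a) an SPFH computed at the centroid treating
#' every point as a neighbor (centroid normal = renormalized mean of the point
#' normals), and (b) a histogram of the angles between the viewpoint-to-
#' centroid direction and each point normal. Using the fixed
#' viewpoint-to-centroid direction (rather than per-point directions) makes
#' the viewpoint component scale-invariant; the descriptor is not rotation
#' invariant, which is why models are aligned first.
#'
#' @inheritParams fpfh
#' @param viewpoint 3-vector; defaults to `config$viewpoint`, or the centroid
#'   plus three bounding radii along +z when that is `NULL`.
#' @return A [descriptor_set()] with a single row of length
#'   `4 * fpfh_bins_per_feature`.
#' @export
vfh <- function(cloud, config = descriptor_config(), viewpoint = NULL,
                model_id = "cloud") {
  if (is.null(cloud$normals)) stopf("vfh: cloud has no normals")
  pts <- cloud$points
  if (nrow(pts) < 2L) stopf("vfh: need at least 2 points")
  centroid <- colMeans(pts)
  viewpoint <- viewpoint %||% config$viewpoint
  if (is.null(viewpoint)) {
    brad <- max(sqrt(rowSums(sweep(pts, 2, centroid)^2)))
    viewpoint <- centroid + c(0, 0, 3 * max(brad, 1))
  }
  if (sqrt(sum((viewpoint - centroid)^2)) < 1e-9) {
    stopf("vfh: viewpoint coincides with the cloud centroid")
  }
  nc <- colSums(cloud$normals)
  if (sqrt(sum(nc^2)) < 1e-12) nc <- c(0, 0, 1)
  nc <- nc / sqrt(sum(nc^2))
  keep <- sqrt(rowSums(sweep(pts, 2, centroid)^2)) > 1e-12
  feat <- pair_features_block(centroid, nc, pts[keep, , drop = FALSE],
                              cloud$normals[keep, , drop = FALSE])
  nb <- config$fpfh_bins_per_feature
  central <- spfh_from_features(feat, nb)
  dir <- centroid - viewpoint
  dir <- dir / sqrt(sum(dir^2))
  cosang <- pmin(pmax(as.numeric(cloud$normals %*% dir), -1), 1)
  vh <- feature_hist(cosang, nb, -1, 1)
  vh <- 100 * vh / sum(vh)
  descriptor_set(model_id, "vfh", matrix(c(central, vh), 1), NA_integer_)
}
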