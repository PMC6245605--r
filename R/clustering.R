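# Distance-matrix clustering and silhouette-based model selection.
#
# k-medoids is a PAM-style alternating heuristic (random initial medoids,
# assignment / medoid-update until stable, best of several restarts);
# agglomerative clustering is average linkage via stats::hclust; DBSCAN is a
# standard density-reachable expansion with noise points re-labelled as
# singleton clusters so that silhouettes and the Rand index stay computable.
# The number of clusters is selected by maximizing the average silhouette
# width s_i = (b_i - a_i) / max(a_i, b_i) over a candidate range.

#' Construct a clustering
#'
#' @param ids Object (model) ids.
#' @param labels Integer cluster label per id (>= 1 cluster).
#' @param method Clustering method name.
#' @param params Method parameters (k, or eps / min_pts).
#' @param seed RNG seed used, if any.
#' @return An object of class `protein_clustering`.
#' @export
clustering <- function(ids, labels, method, params = list(), seed = NA_integer_) {
  if (length(ids) != length(labels)) stopf("ids and labels must have equal length")
  if (anyNA(labels)) stopf("labels must not contain NA")
  if (!is.numeric(labels)) labels <- match(labels, unique(labels))
  labels <- as.integer(labels)
  if (anyNA(labels)) stopf("labels must not contain NA")
  structure(list(ids = as.character(ids), labels = stats::setNames(labels, ids),
                 method = method, params = params, seed = seed),
            class = "protein_clustering")
}

#' @export
print.protein_clustering <- function(x, ...) {
  cat(sprintf("<protein_clustering> %s: %d objects in %d clusters\n",
              x$method, length(x$ids), length(unique(x$labels))))
  invisible(x)
}

#' k-medoids clustering of a distance matrix
#'
#' PAM-style alternating heuristic: assign every object to its nearest medoid,
#' then update each medoid to the cluster member with the smallest sum of
#' distances to its co-members, until the medoid set is stable. The best of
#' `restarts` random initializations (by total within-cluster distance to the
#' medoids) is returned. Deterministic given `seed`; assignment and update
#' ties are broken by the lowest object index.
#'
#' @param d A [distance_matrix()].
#' @param k Number of clusters, `2 <= k <= n - 1`.
#' @param seed RNG seed for the restarts.
#' @param restarts Number of random initializations.
#' @return A `protein_clustering`; the medoid indices and the objective are
#'   attached as `params$medoids` / `params$objective`.
#' @export
k_medoids <- function(d, k, seed = 42L, restarts = 10L) {
  dm <- d$values
  n <- nrow(dm)
  if (k < 2L || k > n - 1L) stopf("k_medoids: k must be in [2, %d], got %d", n - 1L, k)
  run_once <- function(medoids) {
    for (iter in seq_len(100L)) {
      # medoids kept sorted so assignment ties go to the lowest object index
      assign_d <- dm[, medoids, drop = FALSE]
      cl <- max.col(-assign_d, ties.method = "first")
      new_medoids <- sort(vapply(seq_len(k), function(g) {
        members <- which(cl == g)
        if (!length(members)) return(medoids[g])
        sums <- rowSums(dm[members, members, drop = FALSE])
        members[which.min(sums)]
      }, integer(1)))
      if (identical(new_medoids, medoids)) break
      medoids <- new_medoids
    }
    assign_d <- dm[, medoids, drop = FALSE]
    cl <- max.col(-assign_d, ties.method = "first")
    obj <- sum(assign_d[cbind(seq_len(n), cl)])
    list(medoids = medoids, labels = cl, objective = obj)
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      res <- run_once(sort(sample.int(n, k)))
      if (is.null(best) || res$objective < best$objective) best <- res
    }
  })
  # relabel clusters by order of first appearance for determinism
  relab <- match(best$labels, unique(best$labels))
  clustering(d$ids, relab, "kmedoids",
             params = list(k = k, medoids = best$medoids, objective = best$objective,
                           restarts = restarts),
             seed = seed)
}

#' Agglomerative (average-linkage) clustering of a distance matrix
#'
#' Bottom-up merging of the nearest pair of clusters under average linkage
#' (UPGMA, via [stats::hclust()]), with the tree cut at `k` clusters.
#'
#' @param d A [distance_matrix()].
#' @param k Number of clusters, `1 <= k <= n`.
#' @return A `protein_clustering`.
#' @export
agglomerative <- function(d, k) {
  n <- nrow(d$values)
  if (k < 1L || k > n) stopf("agglomerative: k must be in [1, %d], got %d", n, k)
  hc <- stats::hclust(stats::as.dist(d$values), method = "average")
  cl <- stats::cutree(hc, k = k)
  clustering(d$ids, cl, "agglomerative", params = list(k = k))
}

#' DBSCAN clustering of a distance matrix
#'
#' Density-based clustering: points with at least `min_pts` neighbors within
#' `eps` (the point itself included) are core points; clusters are grown by
#' density-reachable expansion in id order, which makes the result
#' deterministic. Noise points receive fresh singleton labels so downstream
#' silhouette / Rand computations remain defined.
#'
#' @param d A [distance_matrix()].
#' @param eps Neighborhood radius; default is the 25th percentile of the
#'   off-diagonal distances.
#' @param min_pts Minimum neighborhood size for a core point.
#' @return A `protein_clustering`; `params$n_noise` counts the noise points.
#' @export
dbscan_cluster <- function(d, eps = NULL, min_pts = 4L) {
  dm <- d$values
  n <- nrow(dm)
  if (is.null(eps)) eps <- stats::quantile(dm[upper.tri(dm)], 0.25, names = FALSE)
  if (eps <= 0) stopf("dbscan: eps must be positive")
  if (min_pts < 1L) stopf("dbscan: min_pts must be >= 1")
  nb <- lapply(seq_len(n), function(i) which(dm[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  labels <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[1L]
      queue <- queue[-1L]
      if (!core[p]) next
      for (q in nb[[p]]) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          queue <- c(queue, q)
        }
      }
    }
  }
  noise <- which(labels == 0L)
  for (i in noise) {
    cl <- cl + 1L
    labels[i] <- cl
  }
  clustering(d$ids, labels, "dbscan",
             params = list(eps = eps, min_pts = min_pts, n_noise = length(noise)))
}

#' Silhouette widths of a clustering
#'
#' For object i, `a_i` is its mean distance to co-members of its own cluster
#' and `b_i` the minimum over other clusters of its mean distance to that
#' cluster's members; `s_i = (b_i - a_i) / max(a_i, b_i)`. Members of
#' singleton clusters get `s_i = 0`.
#'
#' @param d A [distance_matrix()].
#' @param cl A `protein_clustering` with at least 2 clusters over the same
#'   ids.
#' @return A list of class `silhouette_profile` with per-object `widths`
#'   (named by id, all in `[-1, 1]`) and their `average`.
#' @export
silhouette_widths <- function(d, cl) {
  if (!identical(d$ids, cl$ids)) stopf("silhouette_widths: id mismatch")
  labels <- cl$labels
  groups <- unique(labels)
  if (length(groups) < 2L) stopf("silhouette is undefined for a single cluster")
  dm <- d$values
  n <- nrow(dm)
  # mean distance of every object to every cluster
  member_count <- as.numeric(table(factor(labels, levels = groups)))
  agg <- vapply(groups, function(g) rowSums(dm[, labels == g, drop = FALSE]), numeric(n))
  own_col <- match(labels, groups)
  s <- numeric(n)
  for (i in seq_len(n)) {
    sz <- member_count[own_col[i]]
    if (sz <= 1) { s[i] <- 0; next }
    a_i <- agg[i, own_col[i]] / (sz - 1)
    b_i <- min(agg[i, -own_col[i]] / member_count[-own_col[i]])
    s[i] <- if (max(a_i, b_i) > 0) (b_i - a_i) / max(a_i, b_i) else 0
  }
  structure(list(widths = stats::setNames(s, d$ids), average = mean(s), per_k = NULL),
            class = "silhouette_profile")
}

#' @export
print.silhouette_profile <- function(x, ...) {
  cat(sprintf("<silhouette_profile> average width %.4f over %d objects\n",
              x$average, length(x$widths)))
  invisible(x)
}

#' Select the number of clusters by average silhouette width
#'
#' Clusters the matrix for every k in the candidate range (capped at n - 1)
#' and returns the k with the largest average silhouette width; ties go to
#' the smallest k. The per-k table is kept for reporting.
#'
#' @param d A [distance_matrix()].
#' @param method `"kmedoids"`, `"agglomerative"` or `"dbscan"` (DBSCAN
#'   ignores k; it is evaluated once at its own parameters).
#' @param k_range Candidate cluster numbers (default 3:25).
#' @param seed,restarts Passed to [k_medoids()].
#' @return List with `k` (the selected number), `clustering`, and `profile`
#'   (a `silhouette_profile` whose `per_k` table maps k to average width).
#' @export
select_k <- function(d, method = c("kmedoids", "agglomerative"), k_range = 3:25,
                     seed = 42L, restarts = 10L) {
  method <- match.arg(method)
  n <- nrow(d$values)
  ks <- sort(unique(k_range[k_range >= 2L & k_range <= n - 1L]))
  if (!length(ks)) stopf("select_k: empty effective k range for n = %d", n)
  cls <- lapply(ks, function(k) {
    switch(method,
           kmedoids = k_medoids(d, k, seed = seed, restarts = restarts),
           agglomerative = agglomerative(d, k))
  })
  widths <- vapply(cls, function(cl) silhouette_widths(d, cl)$average, numeric(1))
  best <- which.max(widths)   # which.max returns the first (smallest-k) maximum
  prof <- silhouette_widths(d, cls[[best]])
  prof$per_k <- data.frame(k = ks, avg_silhouette = widths)
  list(k = ks[best], clustering = cls[[best]], profile = prof)
}

#' Write cluster assignments as TSV
#' @param cl A `protein_clustering`.
#' @param path File path.
#' @export
write_clustering <- function(cl, path) {
  utils::write.table(data.frame(model_id = cl$ids, cluster = as.integer(cl$labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
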