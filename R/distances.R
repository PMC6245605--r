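# Descriptor-space distance matrices and their fusion.
#
# The distance between two proteins under one descriptor type is the RMSD of
# their corresponding feature vectors,
#   RMSD(F_i, F_j) = sqrt( (1/L) * sum_k || f_ik - f_jk ||^2 ),
# with the point correspondence k <-> k given by shared alignment anchors
# (the C-alpha atoms of aligned residue pairs). For global descriptors
# (L = 1) this reduces to the Euclidean distance. Matrices from different
# descriptors are min-max normalized and fused as a weighted sum, with equal
# or silhouette-derived weights.

#' Construct a distance matrix over model ids
#'
#' @param values Square numeric matrix (symmetric within 1e-9, zero diagonal,
#'   finite, non-negative).
#' @param ids Model ids (row/column order).
#' @param provenance Descriptor type, `"tm"`, or `"combined"`.
#' @param normalized Has the matrix been min-max normalized?
#' @return An object of class `distance_matrix`.
#' @export
distance_matrix <- function(values, ids = rownames(values),
                            provenance = "unknown", normalized = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stopf("distance matrix must be square")
  if (is.null(ids)) ids <- as.character(seq_len(nrow(values)))
  ids <- unname(as.character(ids))
  if (length(ids) != nrow(values)) stopf("ids length must match matrix dimension")
  if (!all(is.finite(values))) stopf("distance matrix has non-finite entries")
  if (any(values < 0)) stopf("distance matrix has negative entries")
  if (max(abs(values - t(values))) > 1e-9) stopf("distance matrix is not symmetric (tolerance 1e-9)")
  if (any(abs(diag(values)) > 1e-12)) stopf("distance matrix diagonal must be zero")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  dimnames(values) <- list(ids, ids)
  structure(list(ids = as.character(ids), values = values,
                 provenance = provenance, normalized = isTRUE(normalized)),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d x %d (%s%s)\n", nrow(x$values), ncol(x$values),
              x$provenance, if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Descriptor-space RMSD between two descriptor sets
#'
#' @param f_i,f_j [descriptor_set()]s of the same type and shape, with row
#'   correspondence given by shared anchors.
#' @return Non-negative scalar; 0 iff the vectors are identical; the plain
#'   Euclidean distance when L = 1.
#' @export
descriptor_rmsd <- function(f_i, f_j) {
  if (!identical(f_i$type, f_j$type)) {
    stopf("descriptor type mismatch: %s vs %s", f_i$type, f_j$type)
  }
  if (!identical(dim(f_i$vectors), dim(f_j$vectors))) {
    stopf("descriptor shape mismatch: %d x %d vs %d x %d",
          nrow(f_i$vectors), ncol(f_i$vectors), nrow(f_j$vectors), ncol(f_j$vectors))
  }
  sqrt(mean(rowSums((f_i$vectors - f_j$vectors)^2)))
}

# sorted-by-id model list with basic checks
prep_models <- function(models) {
  if (length(models) < 2L) stopf("need at least 2 models")
  ids <- vapply(models, function(m) m$model_id, character(1))
  if (anyDuplicated(ids)) stopf("duplicate model ids: %s",
                                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  models[order(ids)]
}

# descriptor extraction on an aligned pose: given transformed-atom model
# coordinates, build the support cloud, estimate normals, extract one type.
# The VFH viewpoint is passed in so that it can be shared across a pair (or a
# whole reference-aligned set).
extract_on_pose <- function(coords_atoms, anchor_atom_rows, type, config,
                            model_id, viewpoint = NULL) {
  cloud <- point_cloud(coords_atoms)
  cloud <- estimate_normals(cloud, min(config$neighbor_k, nrow(coords_atoms) - 1L))
  anchors <- match(anchor_atom_rows, seq_len(nrow(coords_atoms)))
  switch(type,
    fpfh = fpfh(cloud, config, anchors = anchors, model_id = model_id),
    sc3d = shape_context_3d(cloud, config, anchors = anchors, model_id = model_id),
    rsd = rsd(cloud, config, anchors = anchors, model_id = model_id),
    vfh = vfh(cloud, config, viewpoint = viewpoint, model_id = model_id),
    stopf("unknown descriptor type '%s'", type))
}

# shared VFH viewpoint for an aligned frame: centroid of the frame-defining
# cloud plus three bounding radii along +z
frame_viewpoint <- function(coords) {
  centroid <- colMeans(coords)
  brad <- max(sqrt(rowSums(sweep(coords, 2, centroid)^2)))
  centroid + c(0, 0, 3 * max(brad, 1))
}

# support-cloud atoms and the map from residue key to the row of its CA atom
support_atoms <- function(model, selection) {
  cl <- to_point_cloud(model, selection)
  list(coords = cl$points, anchor = cl$anchor_index)
}

#' Pairwise descriptor distance matrix
#'
#' In `"pairwise"` mode (the default, faithful to extracting descriptors from
#' aligned pairs), every unordered model pair is structurally aligned with
#' [tm_align()], descriptors are extracted from both models in the aligned
#' pose with anchor points at the C-alpha atoms of the aligned residue pairs,
#' and the descriptor-space RMSD fills the matrix entry. Models that fail
#' alignment against every partner are dropped with a warning.
#'
#' In `"reference"` mode every model is aligned once to a reference model,
#' descriptors are extracted once per model at the anchor core (reference
#' residues aligned in all models), and all pairwise distances are computed
#' from those shared-anchor descriptor matrices. This costs n alignments
#' instead of n(n-1)/2 and is intended for large model sets.
#'
#' @param models List of [protein_model()]s (>= 2).
#' @param descriptor_type `"fpfh"`, `"sc3d"`, `"rsd"` or `"vfh"`.
#' @param config A [descriptor_config()].
#' @param selection Atom selection for the support cloud (`"all_heavy"` or
#'   `"calpha"`).
#' @param mode `"pairwise"` or `"reference"`.
#' @param reference Index of the reference model (reference mode).
#' @return A [distance_matrix()] over the (lexicographically sorted) model
#'   ids.
#' @export
pairwise_distance_matrix <- function(models,
                                     descriptor_type = c("fpfh", "sc3d", "rsd", "vfh"),
                                     config = descriptor_config(),
                                     selection = c("all_heavy", "calpha"),
                                     mode = c("pairwise", "reference"),
                                     reference = 1L) {
  descriptor_type <- match.arg(descriptor_type)
  selection <- match.arg(selection)
  mode <- match.arg(mode)
  models <- prep_models(models)
  if (mode == "reference") {
    return(reference_mode_matrix(models, descriptor_type, config, selection, reference))
  }
  n <- length(models)
  ids <- vapply(models, function(m) m$model_id, character(1))
  sup <- lapply(models, support_atoms, selection = selection)
  vals <- matrix(0, n, n)
  failed <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      entry <- tryCatch({
        aln <- tm_align(models[[i]], models[[j]])
        ca_i <- rownames(calpha_coords(models[[i]]))
        ca_j <- rownames(calpha_coords(models[[j]]))
        key_i <- ca_i[aln$alignment[, 1]]
        key_j <- ca_j[aln$alignment[, 2]]
        anchors_i <- sup[[i]]$anchor[key_i]
        anchors_j <- sup[[j]]$anchor[key_j]
        ok <- !is.na(anchors_i) & !is.na(anchors_j)
        coords_j <- apply_rigid(sup[[j]]$coords, aln$rotation, aln$translation)
        vp <- frame_viewpoint(sup[[i]]$coords)
        fi <- extract_on_pose(sup[[i]]$coords, anchors_i[ok], descriptor_type,
                              config, ids[i], viewpoint = vp)
        fj <- extract_on_pose(coords_j, anchors_j[ok], descriptor_type,
                              config, ids[j], viewpoint = vp)
        descriptor_rmsd(fi, fj)
      }, error = function(e) e)
      if (inherits(entry, "error")) {
        warnf("pair (%s, %s) failed: %s", ids[i], ids[j], conditionMessage(entry))
        failed[i, j] <- failed[j, i] <- TRUE
      } else {
        vals[i, j] <- vals[j, i] <- entry
      }
    }
  }
  bad <- which(vapply(seq_len(n), function(i) all(failed[i, -i]), logical(1)))
  if (length(bad)) {
    warnf("excluding model(s) failing all alignments: %s", paste(ids[bad], collapse = ", "))
    keep <- setdiff(seq_len(n), bad)
    vals <- vals[keep, keep, drop = FALSE]
    ids <- ids[keep]
    if (length(ids) < 2L) stopf("fewer than 2 models survived alignment")
  } else if (any(failed)) {
    stopf("some pairs failed alignment but no model failed consistently; cannot build a complete matrix")
  }
  distance_matrix(vals, ids, provenance = descriptor_type)
}

# Reference mode: every model is aligned once to the reference; descriptors
# are extracted once per model at its C-alphas aligned to reference residues.
# For a pair (i, j) the anchor correspondence is the set of reference
# residues aligned in both models, so L varies per pair exactly as it does
# under pairwise alignment. The masked descriptor matrices make all n(n-1)/2
# RMSDs a few dense matrix products.
reference_mode_matrix <- function(models, descriptor_type, config, selection, reference) {
  n <- length(models)
  ids <- vapply(models, function(m) m$model_id, character(1))
  ref <- models[[reference]]
  ref_keys <- rownames(calpha_coords(ref))
  lref <- length(ref_keys)
  sup <- lapply(models, support_atoms, selection = selection)
  # align every model to the reference; record pose + reference-residue map
  poses <- vector("list", n)
  aligned_to_ref <- vector("list", n)
  for (i in seq_len(n)) {
    if (i == reference) {
      poses[[i]] <- sup[[i]]$coords
      map <- stats::setNames(ref_keys, ref_keys)
    } else {
      aln <- tm_align(ref, models[[i]])
      poses[[i]] <- apply_rigid(sup[[i]]$coords, aln$rotation, aln$translation)
      keys_i <- rownames(calpha_coords(models[[i]]))
      map <- stats::setNames(keys_i[aln$alignment_dp[, 2]], ref_keys[aln$alignment_dp[, 1]])
    }
    aligned_to_ref[[i]] <- map
  }
  vp <- frame_viewpoint(poses[[reference]])

  if (descriptor_type == "vfh") {
    feats <- t(vapply(seq_len(n), function(i) {
      as.numeric(extract_on_pose(poses[[i]], NULL, "vfh", config, ids[i],
                                 viewpoint = vp)$vectors)
    }, numeric(4L * config$fpfh_bins_per_feature)))
    g <- tcrossprod(feats)
    sq <- diag(g)
    d2 <- matrix(sq, n, n) + matrix(sq, n, n, byrow = TRUE) - 2 * g
    d2[d2 < 0] <- 0
    vals <- sqrt(d2)
    diag(vals) <- 0
    return(distance_matrix(vals, ids, provenance = "vfh"))
  }

  # per-model feature matrix indexed by reference residue; mask marks the
  # residues this model has aligned to the reference
  mask <- matrix(FALSE, n, lref)
  feat_by_ref <- vector("list", n)
  dim_d <- NULL
  for (i in seq_len(n)) {
    map <- aligned_to_ref[[i]]
    anchors <- sup[[i]]$anchor[map]
    ok <- !is.na(anchors)
    ref_rows <- match(names(map)[ok], ref_keys)
    fs <- extract_on_pose(poses[[i]], anchors[ok], descriptor_type, config, ids[i],
                          viewpoint = vp)$vectors
    dim_d <- dim_d %||% ncol(fs)
    fm <- matrix(0, lref, dim_d)
    fm[ref_rows, ] <- fs
    mask[i, ref_rows] <- TRUE
    feat_by_ref[[i]] <- fm
  }
  flat <- t(vapply(feat_by_ref, as.numeric, numeric(lref * dim_d)))
  msk <- mask * 1
  l_ij <- tcrossprod(msk)
  no_overlap <- l_ij < 1 & !diag(TRUE, n)
  l_ij[l_ij < 1] <- 1
  # per-residue squared feature norms, n x lref
  q <- t(vapply(feat_by_ref, function(fm) rowSums(fm^2), numeric(lref)))
  t1 <- tcrossprod(q, msk)               # sum over j-aligned residues of |f_i|^2
  crossterm <- tcrossprod(flat)
  d2 <- (t1 + t(t1) - 2 * crossterm) / l_ij
  d2[d2 < 0] <- 0
  vals <- sqrt(d2)
  diag(vals) <- 0
  if (any(no_overlap)) {
    warnf("reference mode: %d pair(s) share no aligned reference residue; assigned the matrix maximum",
          sum(no_overlap) / 2)
    vals[no_overlap] <- max(vals)
  }
  distance_matrix(vals, ids, provenance = descriptor_type)
}

#' TM-score baseline distance matrix
#'
#' Structural-similarity baseline: every pair is aligned with [tm_align()] and
#' the matrix entry is `1 - (TM_ab + TM_ba) / 2` (the TM-score is asymmetric
#' in its normalizing length, so both directions are averaged).
#'
#' Alternatively `scores` supplies precomputed pairwise TM-scores (a data
#' frame with columns `model_a`, `model_b`, `tm_ab`, `tm_ba`) to bypass the
#' internal aligner.
#'
#' @param models List of [protein_model()]s (ignored when `scores` is given,
#'   except that ids must match if both are supplied).
#' @param scores Optional precomputed score table.
#' @return A [distance_matrix()] with provenance `"tm"`, entries in `[0, 1)`.
#' @export
tm_distance_matrix <- function(models = NULL, scores = NULL) {
  if (!is.null(scores)) {
    req <- c("model_a", "model_b", "tm_ab", "tm_ba")
    if (!all(req %in% names(scores))) {
      stopf("scores must have columns %s", paste(req, collapse = ", "))
    }
    ids <- sort(unique(c(scores$model_a, scores$model_b)))
    vals <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    for (r in seq_len(nrow(scores))) {
      i <- scores$model_a[r]; j <- scores$model_b[r]
      d <- 1 - (scores$tm_ab[r] + scores$tm_ba[r]) / 2
      vals[i, j] <- vals[j, i] <- d
    }
    return(distance_matrix(vals, ids, provenance = "tm"))
  }
  models <- prep_models(models)
  n <- length(models)
  ids <- vapply(models, function(m) m$model_id, character(1))
  vals <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      aln <- tm_align(models[[i]], models[[j]])
      vals[i, j] <- vals[j, i] <- 1 - (aln$tm_score_ab + aln$tm_score_ba) / 2
    }
  }
  vals[vals < 0] <- 0
  distance_matrix(vals, ids, provenance = "tm")
}

#' Min-max normalize a distance matrix
#'
#' Divides all entries by the maximum off-diagonal entry, mapping the matrix
#' into `[0, 1]`. Idempotent. Needed so that matrices of descriptors with
#' very different raw scales are comparable before fusion.
#'
#' @param d A [distance_matrix()] with a positive off-diagonal maximum.
#' @return The normalized [distance_matrix()] (flag set).
#' @export
normalize_matrix <- function(d) {
  off <- d$values[upper.tri(d$values)]
  m <- max(off)
  if (m <= 0) stopf("cannot normalize an all-zero distance matrix")
  distance_matrix(d$values / m, d$ids, provenance = d$provenance, normalized = TRUE)
}

#' Fusion weights
#'
#' @param w Non-negative per-matrix weights (at least one positive).
#' @param scheme `"equal"` or `"silhouette"`.
#' @return An object of class `fusion_weights`.
#' @export
fusion_weights <- function(w, scheme = c("equal", "silhouette")) {
  scheme <- match.arg(scheme)
  if (any(w < 0)) stopf("fusion weights must be non-negative")
  if (all(w == 0)) stopf("at least one fusion weight must be positive")
  structure(list(w = as.numeric(w), scheme = scheme), class = "fusion_weights")
}

#' Fuse distance matrices as a weighted sum
#'
#' `D = sum_m w_m D_m` over normalized matrices with identical id ordering.
#'
#' @param matrices List of normalized [distance_matrix()]s.
#' @param weights A [fusion_weights()] or plain non-negative numeric vector.
#' @return A [distance_matrix()] with provenance `"combined"`.
#' @export
fuse <- function(matrices, weights) {
  if (!inherits(weights, "fusion_weights")) weights <- fusion_weights(weights)
  w <- weights$w
  if (length(w) != length(matrices)) stopf("need one weight per matrix")
  ids <- matrices[[1]]$ids
  for (m in matrices) {
    if (!identical(m$ids, ids)) stopf("fuse: id ordering mismatch between matrices")
    if (!m$normalized) stopf("fuse: matrix '%s' is not normalized", m$provenance)
  }
  vals <- Reduce(`+`, Map(function(m, wi) wi * m$values, matrices, w))
  distance_matrix(vals, ids, provenance = "combined")
}

#' Silhouette-based fusion weights
#'
#' The weight of each descriptor's matrix is the maximum, over a range of
#' cluster numbers, of the average silhouette width of its k-medoids
#' clustering — i.e. how much cluster structure that descriptor exposes.
#' Negative maxima are clamped to 0; if every weight clamps to 0, equal
#' weights are returned with a warning.
#'
#' @param matrices List of [distance_matrix()]s over the same ids (n >= 3).
#' @param k_range Candidate cluster numbers (capped at n - 1).
#' @param seed,restarts Passed to [k_medoids()].
#' @return A [fusion_weights()] with scheme `"silhouette"`.
#' @export
silhouette_weights <- function(matrices, k_range = 3:25, seed = 42L, restarts = 10L) {
  n <- length(matrices[[1]]$ids)
  if (n < 3L) stopf("silhouette_weights: need at least 3 models")
  ks <- k_range[k_range >= 2L & k_range <= n - 1L]
  if (!length(ks)) stopf("silhouette_weights: empty effective k range")
  w <- vapply(matrices, function(m) {
    widths <- vapply(ks, function(k) {
      cl <- k_medoids(m, k, seed = seed, restarts = restarts)
      silhouette_widths(m, cl)$average
    }, numeric(1))
    max(widths)
  }, numeric(1))
  w <- pmax(w, 0)
  if (all(w == 0)) {
    warnf("silhouette_weights: no descriptor shows positive silhouette; falling back to equal weights")
    w <- rep(1, length(matrices))
  }
  fusion_weights(w, "silhouette")
}

#' Write / read a distance matrix as TSV
#'
#' TSV with a header row and a leading id column; ids are kept in the
#' matrix's (lexicographic) order.
#' @param d A [distance_matrix()].
#' @param path File path.
#' @return `path` / a [distance_matrix()].
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(id = d$ids, d$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @param provenance,normalized Metadata for the reloaded matrix.
#' @export
read_distance_matrix <- function(path, provenance = "unknown", normalized = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  # symmetrize away TSV rounding
  vals <- (vals + t(vals)) / 2
  distance_matrix(vals, ids, provenance = provenance, normalized = normalized)
}
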