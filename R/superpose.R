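# Structural superposition: Kabsch rotations, TM-score, secondary-structure
# assignment from C-alpha pseudo-geometry, dynamic-programming alignment, and
# a simplified iterative TM-align.
#
# The aligner follows the classic scheme: several seed alignments (best
# gapless threading, secondary-structure DP, and their equally weighted
# combination) are each refined by alternating a Kabsch superposition on the
# current residue pairs with a DP pass over the TM-score matrix
# S_ij = 1 / (1 + (d_ij / d0)^2), until the pair set is stable or an
# iteration cap is hit; the best-scoring alignment seen anywhere is returned,
# so refinement never falls below the best seed.

#' Optimal rigid superposition of paired point sets (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD of
#' `R q + t` against `P` over paired rows. Reflections are excluded
#' (`det(R) = +1`).
#'
#' @param P,Q n x 3 coordinate matrices with paired rows, n >= 3.
#' @return A list of class `superposition` with elements `rotation` (3 x 3),
#'   `translation` (length 3, maps Q into P's frame as `Q %*% t(R) + t`) and
#'   `rmsd` (Angstrom).
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q)) stopf("kabsch: P and Q must have the same number of rows")
  if (nrow(P) < 3L) stopf("kabsch: need at least 3 paired points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Qc, Pc)               # 3 x 3 covariance
  sv <- svd(H)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300)) {
    warnf("kabsch: points are (near-)collinear; rotation is ill-determined")
  }
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  if (d == 0) d <- 1
  rotation <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  translation <- cp - as.numeric(rotation %*% cq)
  fitted <- apply_rigid(Q, rotation, translation)
  rmsd <- sqrt(mean(rowSums((P - fitted)^2)))
  structure(list(rotation = rotation, translation = translation, rmsd = rmsd),
            class = "superposition")
}

#' TM-score distance scale d0
#'
#' `d0(L) = 1.24 (L - 15)^(1/3) - 1.8`, clamped below at 0.5 Angstrom (the raw
#' formula is negative for L <= 18).
#'
#' @param l_target Length (residue count) of the target protein, >= 1.
#' @return d0 in Angstrom.
#' @export
d0 <- function(l_target) {
  stopifnot(l_target >= 1)
  raw <- 1.24 * sign(l_target - 15) * abs(l_target - 15)^(1 / 3) - 1.8
  pmax(raw, 0.5)
}

#' TM-score of an alignment
#'
#' `TM = (1 / L_target) * sum_i 1 / (1 + (d_i / d0(L_target))^2)` over aligned
#' residue pairs. The caller is responsible for having maximized the aligned
#' distances over superpositions.
#'
#' @param d Distances (Angstrom) of the aligned residue pairs.
#' @param l_target Length of the target (normalizing) protein;
#'   `l_target >= length(d)`.
#' @return TM-score in `(0, 1]` (0, with a warning, for an empty alignment).
#' @export
tm_score <- function(d, l_target) {
  if (!length(d)) {
    warnf("tm_score: empty alignment")
    return(0)
  }
  stopifnot(l_target >= length(d))
  sum(1 / (1 + (d / d0(l_target))^2)) / l_target
}

#' Global alignment by dynamic programming
#'
#' Maximizes the total cell score with a linear gap penalty. Ties are broken
#' deterministically (diagonal, then up, then left).
#'
#' @param score_matrix |A| x |B| matrix of finite pairing scores.
#' @param gap_open Linear gap penalty (default -0.6).
#' @return Integer matrix of aligned index pairs (columns `a`, `b`), strictly
#'   increasing in both coordinates.
#' @export
dp_align <- function(score_matrix, gap_open = -0.6) {
  score_matrix <- as.matrix(score_matrix)
  if (!length(score_matrix)) stopf("dp_align: empty score matrix")
  if (!all(is.finite(score_matrix))) stopf("dp_align: scores must be finite")
  pairs <- dp_align_cpp(score_matrix, gap_open)
  colnames(pairs) <- c("a", "b")
  pairs
}

#' Secondary-structure assignment from C-alpha geometry
#'
#' A lightweight assignment using only C-alpha i->i+2 / i->i+3 / i->i+4
#' distance windows (no hydrogen bonds or side chains): windows matching
#' alpha-helix geometry label their interior residues `H`, extended-strand
#' geometry labels `E`, everything else (including termini and chains shorter
#' than the 5-residue window) stays `C`. Residues without a C-alpha are `C`.
#'
#' @param model A [protein_model()].
#' @param helix_d13,helix_d14,helix_d15 Acceptance windows (Angstrom) for the
#'   helix i,i+2 / i,i+3 / i,i+4 distances.
#' @param strand_d13 Acceptance window for the strand i,i+2 distance.
#' @param strand_d15_min Minimum strand i,i+4 distance.
#' @return Character vector of labels in `{H, E, C}`, one per residue (all
#'   chains concatenated in file order), named `"chain:resno"`.
#' @export
assign_secondary_structure <- function(model,
                                       helix_d13 = c(4.8, 5.9),
                                       helix_d14 = c(4.2, 6.0),
                                       helix_d15 = c(5.3, 7.3),
                                       strand_d13 = c(6.2, 7.3),
                                       strand_d15_min = 11.8) {
  res <- unique(model$atoms[, c("chain", "resno")])
  labels <- rep("C", nrow(res))
  names(labels) <- paste(res$chain, res$resno, sep = ":")
  ca <- calpha_coords(model)
  for (ch in unique(res$chain)) {
    keys <- names(labels)[res$chain == ch]
    keys <- keys[keys %in% rownames(ca)]
    n <- length(keys)
    if (n < 5L) next
    x <- ca[keys, , drop = FALSE]
    dwin <- function(off) {
      i <- seq_len(n - off)
      sqrt(rowSums((x[i, , drop = FALSE] - x[i + off, , drop = FALSE])^2))
    }
    d13 <- dwin(2L); d14 <- dwin(3L); d15 <- dwin(4L)
    inw <- function(v, w) v >= w[1] & v <= w[2]
    for (i in seq_len(n - 4L)) {
      is_h <- inw(d13[i], helix_d13) && inw(d13[i + 2L], helix_d13) &&
        inw(d14[i], helix_d14) && inw(d15[i], helix_d15)
      is_e <- !is_h && inw(d13[i], strand_d13) && inw(d13[i + 2L], strand_d13) &&
        d15[i] >= strand_d15_min
      if (is_h) labels[keys[(i + 1L):(i + 3L)]] <- "H"
      if (is_e) {
        tgt <- keys[(i + 1L):(i + 3L)]
        tgt <- tgt[labels[tgt] != "H"]
        labels[tgt] <- "E"
      }
    }
  }
  labels
}

# score(pairs): superpose on the aligned pairs and evaluate the TM-score of
# their distances, normalized by l_target.
tm_eval <- function(xa, xb, pairs, l_target) {
  if (nrow(pairs) < 3L) return(list(score = -Inf, sup = NULL, d = numeric(0)))
  sup <- suppressWarnings(kabsch(xa[pairs[, 1], , drop = FALSE],
                                 xb[pairs[, 2], , drop = FALSE]))
  fitted <- apply_rigid(xb[pairs[, 2], , drop = FALSE], sup$rotation, sup$translation)
  d <- sqrt(rowSums((xa[pairs[, 1], , drop = FALSE] - fitted)^2))
  list(score = tm_score(d, l_target), sup = sup, d = d)
}

# best gapless threading of xb against xa by TM-score (normalized by l_target)
gapless_seed <- function(xa, xb, l_target, min_overlap = 5L) {
  la <- nrow(xa); lb <- nrow(xb)
  best <- NULL; best_score <- -Inf
  for (off in seq(-(lb - min_overlap), la - min_overlap)) {
    ia <- max(1L, 1L + off):min(la, lb + off)
    if (length(ia) < min_overlap) next
    pairs <- cbind(a = ia, b = ia - off)
    sc <- tm_eval(xa, xb, pairs, l_target)$score
    if (sc > best_score) { best_score <- sc; best <- pairs }
  }
  best
}

#' Pairwise structural alignment (simplified TM-align)
#'
#' Aligns model `b` onto model `a` by iterating Kabsch superposition and
#' dynamic programming over the TM-score matrix, starting from three seeds:
#' the best gapless threading, a secondary-structure DP alignment, and their
#' equally weighted combination. The returned alignment is the best-scoring
#' one encountered, so the result never scores below the best seed.
#'
#' The TM-score is asymmetric in its normalizing length; both directions are
#' reported: `tm_score_ab` treats `b` as the target (normalizes by
#' `length(b)`), `tm_score_ba` by `length(a)`.
#'
#' @param a,b [protein_model()]s with at least 5 C-alpha atoms each.
#' @param gap_open Linear gap penalty for the DP passes.
#' @param max_iter Refinement cap per seed.
#' @return A list of class `tm_alignment`: `rotation`, `translation` (rigid
#'   motion taking `b`'s coordinates into `a`'s frame), `rmsd` over aligned
#'   pairs, `tm_score_ab`, `tm_score_ba`, `alignment` (index pairs into the
#'   C-alpha sequences of `a` and `b`), `l_align`, `seed`, `iterations`.
#' @export
tm_align <- function(a, b, gap_open = -0.6, max_iter = 30L) {
  xa <- calpha_coords(a); xb <- calpha_coords(b)
  la <- nrow(xa); lb <- nrow(xb)
  if (la < 5L || lb < 5L) stopf("tm_align: both models need at least 5 C-alpha atoms")
  d0b <- d0(lb)

  seeds <- list()
  seeds$gapless <- gapless_seed(xa, xb, lb)
  ssa <- assign_secondary_structure(a); ssb <- assign_secondary_structure(b)
  ssa <- ssa[rownames(xa)]; ssb <- ssb[rownames(xb)]
  s_ss <- outer(ssa, ssb, `==`) * 1.0
  seeds$secondary <- dp_align(s_ss, gap_open)
  gl <- tm_eval(xa, xb, seeds$gapless, lb)
  if (!is.null(gl$sup)) {
    bt <- apply_rigid(xb, gl$sup$rotation, gl$sup$translation)
    s_geo <- 1 / (1 + (cross_dist(xa, bt) / d0b)^2)
    seeds$combined <- dp_align(0.5 * s_geo + 0.5 * s_ss, gap_open)
  }

  best <- list(score = -Inf, pairs = NULL, sup = NULL, seed = NA_character_, iter = 0L)
  for (seed_name in names(seeds)) {
    pairs <- seeds[[seed_name]]
    if (is.null(pairs) || nrow(pairs) < 3L) next
    for (iter in 0:max_iter) {
      ev <- tm_eval(xa, xb, pairs, lb)
      if (ev$score > best$score) {
        best <- list(score = ev$score, pairs = pairs, sup = ev$sup,
                     seed = seed_name, iter = iter)
      }
      if (iter == max_iter) break
      bt <- apply_rigid(xb, ev$sup$rotation, ev$sup$translation)
      s <- 1 / (1 + (cross_dist(xa, bt) / d0b)^2)
      new_pairs <- dp_align(s, gap_open)
      if (nrow(new_pairs) == nrow(pairs) && all(new_pairs == pairs)) break
      pairs <- new_pairs
    }
  }
  if (is.null(best$pairs)) stopf("tm_align: no usable alignment between '%s' and '%s'",
                                 a$model_id, b$model_id)

  ev <- tm_eval(xa, xb, best$pairs, lb)
  # full-coverage DP alignment under the final superposition: the TM-optimal
  # pair set can be short for dissimilar structures, but downstream anchor
  # correspondence benefits from the longest consistent residue pairing
  bt <- apply_rigid(xb, ev$sup$rotation, ev$sup$translation)
  alignment_dp <- dp_align(1 / (1 + (cross_dist(xa, bt) / d0b)^2), gap_open)
  structure(list(
    rotation = ev$sup$rotation,
    translation = ev$sup$translation,
    rmsd = ev$sup$rmsd,
    tm_score_ab = max(best$score, ev$score),
    tm_score_ba = tm_score(ev$d, la),
    alignment = best$pairs,
    alignment_dp = alignment_dp,
    l_align = nrow(best$pairs),
    seed = best$seed,
    iterations = best$iter
  ), class = "tm_alignment")
}

#' @export
print.tm_alignment <- function(x, ...) {
  cat(sprintf("<tm_alignment> L_align = %d, TM(ab) = %.4f, TM(ba) = %.4f, rmsd = %.3f A (seed: %s)\n",
              x$l_align, x$tm_score_ab, x$tm_score_ba, x$rmsd, x$seed))
  invisible(x)
}
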