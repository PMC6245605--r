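# Fixtures and independent oracles used across the test files.

# --- PDB text fixtures -------------------------------------------------------

pdb_atom_line <- function(eleno, elety, resname, chain, resno, x, y, z,
                          occ = 1, alt = " ", elesy = NULL) {
  if (is.null(elesy)) elesy <- substr(gsub("[0-9]", "", elety), 1, 1)
  name_field <- if (nchar(elety) < 4) sprintf(" %-3s", elety) else sprintf("%-4s", elety)
  sprintf("ATOM  %5d %s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          eleno, name_field, alt, resname, chain, resno, x, y, z, occ, 0, elesy)
}

write_pdb_text <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# small 3-atom fixture with known coordinates
three_atom_pdb <- function() {
  write_pdb_text(c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 11.104, 6.134, -6.504),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 11.639, 6.071, -5.147),
    pdb_atom_line(3, "C", "ALA", "A", 1, 12.345, 7.890, -4.000)
  ))
}

# protein_model from a bare CA trace (plus N/C dummies so each residue has
# several heavy atoms when needed)
trace_model <- function(coords, model_id = "trace", ca_only = TRUE) {
  n <- nrow(coords)
  if (ca_only) {
    atoms <- data.frame(chain = "A", resno = seq_len(n), resname = "ALA",
                        elety = "CA", elesy = "C",
                        x = coords[, 1], y = coords[, 2], z = coords[, 3])
    return(protein_model(model_id, atoms))
  }
  rows <- lapply(seq_len(n), function(i) {
    data.frame(chain = "A", resno = i, resname = "ALA",
               elety = c("N", "CA", "C"), elesy = c("N", "C", "C"),
               x = coords[i, 1] + c(-1.2, 0, 1.2), y = coords[i, 2] + c(0.4, 0, 0.4),
               z = coords[i, 3])
  })
  protein_model(model_id, do.call(rbind, rows))
}

# ideal alpha-helix C-alpha trace (rise 1.5 A, 100 deg/residue, radius such
# that consecutive spacing is 3.8 A)
helix_trace <- function(n) {
  t <- 0:(n - 1)
  turn <- 100 * pi / 180
  r <- sqrt(3.8^2 - 1.5^2) / (2 * sin(turn / 2))
  cbind(r * cos(turn * t), r * sin(turn * t), 1.5 * t)
}

# extended zigzag strand trace (3.3 A rise, 3.8 A consecutive spacing)
strand_trace <- function(n) {
  t <- 0:(n - 1)
  a <- sqrt(3.8^2 - 3.3^2) / 2
  cbind(0, a * (-1)^t, 3.3 * t)
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

rigid_move <- function(coords, rotation, translation) {
  sweep(coords %*% t(rotation), 2, translation, `+`)
}

random_rigid <- function() {
  list(rotation = shapeclust:::random_rotation(),
       translation = stats::runif(3, -15, 15))
}

# points approximately uniform on a sphere, with exact radial normals
sphere_cloud <- function(n, radius = 5, center = c(0, 0, 0)) {
  i <- seq_len(n)
  phi <- acos(1 - 2 * (i - 0.5) / n)
  theta <- pi * (1 + sqrt(5)) * i
  dirs <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  list(points = sweep(radius * dirs, 2, center, `+`), normals = dirs)
}

# --- independent oracles -----------------------------------------------------

# numeric superposition oracle: minimize rmsd over Euler angles + translation
numeric_kabsch_rmsd <- function(P, Q) {
  obj <- function(par) {
    cx <- cos(par[1]); sx <- sin(par[1])
    cy <- cos(par[2]); sy <- sin(par[2])
    cz <- cos(par[3]); sz <- sin(par[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    R <- Rz %*% Ry %*% Rx
    fitted <- sweep(Q %*% t(R), 2, par[4:6], `+`)
    sqrt(mean(rowSums((P - fitted)^2)))
  }
  best <- Inf
  for (start in list(rep(0, 6), c(0.5, -0.4, 0.3, 0, 0, 0), c(2, 1, -2, 1, -1, 1),
                     c(-1.5, 2.5, 0.5, -2, 2, 0))) {
    res <- stats::optim(start, obj, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-14))
    res <- stats::optim(res$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-15))
    best <- min(best, res$value)
  }
  best
}

# enumerate all global alignments of an n x m score matrix (linear gap
# penalty), return the maximal total score
enumerate_best_alignment <- function(S, gap) {
  n <- nrow(S); m <- ncol(S)
  rec <- function(i, j) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) best <- max(best, S[i, j] + rec(i + 1, j + 1))
    if (i <= n) best <- max(best, gap + rec(i + 1, j))
    if (j <= m) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

alignment_score <- function(S, pairs, gap) {
  matched <- sum(S[pairs])
  gaps <- (nrow(S) - nrow(pairs)) + (ncol(S) - nrow(pairs))
  matched + gap * gaps
}

# pair-counting Rand index oracle
rand_oracle <- function(x, y) {
  y <- y[names(x)]
  n <- length(x)
  agree <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_x <- x[i] == x[j]
      same_y <- y[i] == y[j]
      if (same_x == same_y) agree <- agree + 1
    }
  }
  agree / choose(n, 2)
}

# exhaustive k-medoids: optimal objective over all medoid subsets
exhaustive_kmedoids_objective <- function(dm, k) {
  n <- nrow(dm)
  best <- Inf
  combs <- utils::combn(n, k)
  for (c in seq_len(ncol(combs))) {
    med <- combs[, c]
    obj <- sum(apply(dm[, med, drop = FALSE], 1, min))
    best <- min(best, obj)
  }
  best
}

# small separable distance-matrix fixture: g blobs of given sizes, zero (or
# tiny) diameter, unit separation
blob_matrix <- function(sizes, within = 0, between = 1) {
  labels <- rep(seq_along(sizes), sizes)
  n <- length(labels)
  vals <- matrix(between, n, n)
  for (g in seq_along(sizes)) {
    idx <- which(labels == g)
    vals[idx, idx] <- within
  }
  diag(vals) <- 0
  list(d = distance_matrix(vals, sprintf("m%02d", seq_len(n)), provenance = "fixture"),
       labels = stats::setNames(labels, sprintf("m%02d", seq_len(n))))
}

# small synthetic dataset reused by the cross-module tests
small_dataset <- function(sizes = c(4, 4, 4), seed = 7, length = 60) {
  specs <- Map(function(i, s) family_spec(sprintf("T%d", i), s, template_length = length),
               seq_along(sizes), sizes)
  generate_dataset(specs, global_seed = seed)
}
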