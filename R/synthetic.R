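# Synthetic families of protein-like 3D models.
#
# The generator emulates the structure of an annotated immunoglobulin model
# set: a handful of families ("subsets"), each family sharing a backbone
# template, members differing by small per-atom Gaussian noise and an
# arbitrary rigid motion, families differing by large torsion-level backbone
# perturbations. Traces are built in internal coordinates (fixed 3.8 A
# consecutive C-alpha spacing, per-residue virtual bond angles and torsions)
# with mixed helix / strand / coil segments, and self-avoidance is enforced
# by resampling clashing conformations.

CA_SPACING <- 3.8

# ideal-geometry constants (computed once at load): virtual bond angle and
# torsion of an ideal alpha-helix C-alpha trace (rise 1.5 A, 100 deg/residue)
# and of an extended zigzag strand trace
ideal_internal <- local({
  dihedral <- function(p1, p2, p3, p4) {
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3], b1[1] * b2[2] - b1[2] * b2[1])
    n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3], b2[1] * b3[2] - b2[2] * b3[1])
    m <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3], n1[1] * b2[2] - n1[2] * b2[1])
    b2n <- sqrt(sum(b2^2))
    atan2(sum(m * n2) / b2n, sum(n1 * n2))
  }
  bond_angle <- function(p1, p2, p3) {
    v1 <- p1 - p2; v2 <- p3 - p2
    acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
  }
  helix_pts <- function(t) {
    rise <- 1.5; turn <- 100 * pi / 180
    chord <- sqrt(CA_SPACING^2 - rise^2)
    r <- chord / (2 * sin(turn / 2))
    cbind(r * cos(turn * t), r * sin(turn * t), rise * t)
  }
  strand_pts <- function(t) {
    rise <- 3.3
    a <- sqrt(CA_SPACING^2 - rise^2) / 2
    cbind(0, a * (-1)^t, rise * t)
  }
  hp <- helix_pts(0:3); sp <- strand_pts(0:3)
  list(
    helix_theta = bond_angle(hp[1, ], hp[2, ], hp[3, ]),
    helix_tau = dihedral(hp[1, ], hp[2, ], hp[3, ], hp[4, ]),
    strand_theta = bond_angle(sp[1, ], sp[2, ], sp[3, ]),
    strand_tau = dihedral(sp[1, ], sp[2, ], sp[3, ], sp[4, ])
  )
})

# segment plan + internal coordinates for a template trace; deterministic
# given the RNG state
draw_plan <- function(length) {
  types <- character(0)
  segs <- c("helix", "strand")
  i <- 1L
  while (length(types) < length) {
    seg <- segs[i %% 2L + 1L]
    len <- switch(seg,
                  helix = sample(8:15, 1),
                  strand = sample(5:8, 1),
                  coil = sample(3:5, 1))
    types <- c(types, rep(seg, len))
    coil_len <- sample(3:5, 1)
    types <- c(types, rep("coil", coil_len))
    i <- i + 1L
  }
  types <- types[seq_len(length)]
  theta <- numeric(length); tau <- numeric(length)
  for (j in seq_len(length)) {
    theta[j] <- switch(types[j],
                       helix = ideal_internal$helix_theta,
                       strand = ideal_internal$strand_theta,
                       coil = stats::runif(1, 85, 140) * pi / 180)
    tau[j] <- switch(types[j],
                     helix = ideal_internal$helix_tau,
                     strand = ideal_internal$strand_tau,
                     coil = stats::runif(1, -pi, pi))
  }
  list(types = types, theta = theta, tau = tau)
}

# NeRF-style chain build from internal coordinates
build_trace <- function(plan) {
  n <- length(plan$theta)
  pts <- matrix(0, n, 3)
  pts[1, ] <- c(0, 0, 0)
  pts[2, ] <- c(CA_SPACING, 0, 0)
  for (i in 3:n) {
    a <- if (i == 3L) pts[1, ] + c(0, 0, 1) else pts[i - 3L, ]
    b <- pts[i - 2L, ]; cc <- pts[i - 1L, ]
    theta <- plan$theta[i]; tau <- if (i == 3L) 0 else plan$tau[i]
    bc <- cc - b; bc <- bc / sqrt(sum(bc^2))
    ab <- b - a
    nv <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3], ab[1] * bc[2] - ab[2] * bc[1])
    nn <- sqrt(sum(nv^2))
    if (nn < 1e-9) {
      e <- diag(3)[, which.min(abs(bc))]
      nv <- c(e[2] * bc[3] - e[3] * bc[2], e[3] * bc[1] - e[1] * bc[3], e[1] * bc[2] - e[2] * bc[1])
      nn <- sqrt(sum(nv^2))
    }
    nv <- nv / nn
    m <- c(nv[2] * bc[3] - nv[3] * bc[2], nv[3] * bc[1] - nv[1] * bc[3], nv[1] * bc[2] - nv[2] * bc[1])
    d_local <- CA_SPACING * c(-cos(theta), sin(theta) * cos(tau), sin(theta) * sin(tau))
    pts[i, ] <- cc + d_local[1] * bc + d_local[2] * m + d_local[3] * nv
  }
  pts
}

# minimum distance between non-local residue pairs (|i - j| >= 3)
min_nonlocal_dist <- function(pts) {
  n <- nrow(pts)
  if (n < 5L) return(Inf)
  dm <- self_dist(pts)
  mask <- abs(outer(seq_len(n), seq_len(n), `-`)) >= 3L
  min(dm[mask])
}

# resample coil angles until the trace is self-avoiding (clearance 3.0 A);
# after `tries` failures, the attempt with the best clearance wins
settle_plan <- function(plan, tries = 30L, clearance = 3.0) {
  best <- plan; best_clear <- min_nonlocal_dist(build_trace(plan))
  attempt <- plan
  t <- 0L
  while (best_clear < clearance && t < tries) {
    coil <- attempt$types == "coil"
    attempt$theta[coil] <- stats::runif(sum(coil), 85, 140) * pi / 180
    attempt$tau[coil] <- stats::runif(sum(coil), -pi, pi)
    cl <- min_nonlocal_dist(build_trace(attempt))
    if (cl > best_clear) { best <- attempt; best_clear <- cl }
    t <- t + 1L
  }
  best
}

# dummy backbone atoms (N, CA, C, O) around a C-alpha trace
trace_to_model <- function(pts, model_id) {
  n <- nrow(pts)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    d <- if (i < n) pts[i + 1L, ] - pts[i, ] else pts[i, ] - pts[i - 1L, ]
    d <- d / sqrt(sum(d^2))
    e <- diag(3)[, which.min(abs(d))]
    u <- c(d[2] * e[3] - d[3] * e[2], d[3] * e[1] - d[1] * e[3], d[1] * e[2] - d[2] * e[1])
    u <- u / sqrt(sum(u^2))
    ca <- pts[i, ]
    at <- rbind(N = ca - 1.2 * d + 0.7 * u,
                CA = ca,
                C = ca + 1.2 * d + 0.7 * u,
                O = ca + 1.4 * d + 1.8 * u)
    rows[[i]] <- data.frame(
      chain = "A", resno = i, resname = "ALA",
      elety = rownames(at), elesy = c("N", "C", "C", "O"),
      x = at[, 1], y = at[, 2], z = at[, 3],
      stringsAsFactors = FALSE
    )
  }
  protein_model(model_id, do.call(rbind, rows))
}

#' Generate a protein-like template model
#'
#' A self-avoiding C-alpha trace with exact 3.8 A consecutive spacing and
#' mixed helix / strand / coil segments, decorated with dummy N, C and O
#' atoms per residue. Deterministic given `seed`.
#'
#' @param length Number of residues (>= 10).
#' @param seed RNG seed.
#' @param model_id Identifier for the resulting model.
#' @return A [protein_model()].
#' @export
generate_template <- function(length, seed = 1L, model_id = "template") {
  if (length < 10L) stopf("generate_template: length must be >= 10")
  plan <- with_seed(seed, settle_plan(draw_plan(length)))
  trace_to_model(build_trace(plan), model_id)
}

#' Specification of one synthetic family
#'
#' @param family_id Family label (used as the ground-truth label).
#' @param size Number of member models (>= 1).
#' @param template_length Residue count of the family template.
#' @param within_noise Per-atom Gaussian sigma (Angstrom) within the family.
#' @param between_divergence Scale (Angstrom) of the torsion-level backbone
#'   perturbation separating this family's template from the shared base
#'   fold; must exceed `within_noise` for separable fixtures.
#' @param seed Optional family seed (derived from the dataset seed if NULL).
#' @return A list of class `family_spec`.
#' @export
family_spec <- function(family_id, size, template_length = 110L,
                        within_noise = 0.3, between_divergence = 3,
                        seed = NULL) {
  stopifnot(size >= 1, within_noise >= 0, between_divergence >= 0)
  structure(list(family_id = family_id, size = as.integer(size),
                 template_length = as.integer(template_length),
                 within_noise = within_noise,
                 between_divergence = between_divergence, seed = seed),
            class = "family_spec")
}

#' Default synthetic family layout
#'
#' Six families with sizes 38, 42, 22, 12, 12 and 11 (137 models in total,
#' matching the subset-size distribution of a well-characterized annotated
#' immunoglobulin set), 110-residue templates, 0.3 A within-family noise and
#' 3 A between-family divergence (separation-to-noise ratio 10).
#'
#' @return List of [family_spec()]s.
#' @export
default_family_specs <- function() {
  sizes <- c(38L, 42L, 22L, 12L, 12L, 11L)
  Map(function(i, s) family_spec(sprintf("F%d", i), s), seq_along(sizes), sizes)
}

#' Generate a labelled synthetic dataset
#'
#' Each family is a torsion-perturbed variant of a shared base fold; each
#' member is the family template plus per-atom Gaussian noise and a random
#' rigid motion. Fully deterministic given `global_seed` (and any per-family
#' seeds).
#'
#' @param specs List of [family_spec()]s (>= 2 families, unique ids).
#' @param global_seed Master seed.
#' @return List with `models` (named list of [protein_model()]s) and `labels`
#'   (named character vector, the ground-truth partition).
#' @export
generate_dataset <- function(specs = default_family_specs(), global_seed = 1L) {
  if (length(specs) < 2L) stopf("generate_dataset: need at least 2 families")
  fam_ids <- vapply(specs, function(s) s$family_id, character(1))
  if (anyDuplicated(fam_ids)) stopf("generate_dataset: duplicate family ids")
  models <- list()
  labels <- character(0)
  for (fi in seq_along(specs)) {
    sp <- specs[[fi]]
    fam_seed <- sp$seed %||% (global_seed + 7919L * fi)
    base_plan <- with_seed(global_seed, settle_plan(draw_plan(sp$template_length)))
    # torsion-level divergence: ~4 deg of torsion and ~1.5 deg of bond-angle
    # jitter per Angstrom of requested divergence
    plan <- with_seed(fam_seed, {
      p <- base_plan
      p$tau <- p$tau + stats::rnorm(length(p$tau), 0, sp$between_divergence * 4 * pi / 180)
      p$theta <- pmin(pmax(
        p$theta + stats::rnorm(length(p$theta), 0, sp$between_divergence * 1.5 * pi / 180),
        60 * pi / 180), 170 * pi / 180)
      settle_plan(p)
    })
    template <- trace_to_model(build_trace(plan), sp$family_id)
    coords <- as.matrix(template$atoms[, c("x", "y", "z")])
    member_models <- with_seed(fam_seed + 1L, {
      lapply(seq_len(sp$size), function(j) {
        xyz <- coords + matrix(stats::rnorm(length(coords), 0, sp$within_noise),
                               nrow(coords), 3)
        xyz <- apply_rigid(xyz, random_rotation(), stats::runif(3, -20, 20))
        at <- template$atoms
        at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
        protein_model(sprintf("%s_%03d", sp$family_id, j), at)
      })
    })
    names(member_models) <- vapply(member_models, function(m) m$model_id, character(1))
    models <- c(models, member_models)
    labels <- c(labels, stats::setNames(rep(sp$family_id, sp$size), names(member_models)))
  }
  list(models = models, labels = labels)
}

#' Write a synthetic dataset as PDB files plus a labels TSV
#'
#' Models are written as legal PDB files (and are meant to be re-read through
#' [read_pdb()], so fixtures exercise the real I/O path); ground-truth labels
#' go to `labels.tsv` in the same directory.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in dataset$models) {
    write_pdb(m, file.path(dir, paste0(m$model_id, ".pdb")))
  }
  write_labels(dataset$labels, file.path(dir, "labels.tsv"))
  invisible(dir)
}
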