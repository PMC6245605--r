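# PDB input/output and point-cloud conversion.
#
# Parsing is delegated to bio3d::read.pdb (fixed-column PDB, first MODEL only);
# on top of it this module enforces the contracts the rest of the pipeline
# relies on: HETATM and hydrogens are dropped, alternate locations are resolved
# to the highest-occupancy record (ties -> altLoc "A", then first), malformed
# coordinate fields are reported with their line number, and residue numbering
# must be unique within a chain.

#' Construct a protein model
#'
#' A `protein_model` is the in-memory form of one PDB model: an id plus a
#' per-atom table. Coordinates are in Angstrom and are never rescaled.
#'
#' @param model_id Character scalar identifying the model.
#' @param atoms Data frame with columns `chain`, `resno`, `resname`, `elety`
#'   (atom name), `elesy` (element symbol), `x`, `y`, `z`.
#' @return An object of class `protein_model`.
#' @export
protein_model <- function(model_id, atoms) {
  stopifnot(is.character(model_id), length(model_id) == 1L)
  req <- c("chain", "resno", "resname", "elety", "elesy", "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols)) {
    stopf("atoms table is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  atoms <- as.data.frame(atoms)[, req]
  if (nrow(atoms) < 1L) stopf("protein model '%s' has no atoms", model_id)
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stopf("protein model '%s' has non-finite coordinates", model_id)
  res <- unique(atoms[, c("chain", "resno", "resname")])
  if (anyDuplicated(res[, c("chain", "resno")])) {
    stopf("protein model '%s': duplicated residue numbers within a chain", model_id)
  }
  structure(list(model_id = model_id, atoms = atoms), class = "protein_model")
}

#' @export
print.protein_model <- function(x, ...) {
  cat(sprintf("<protein_model> %s: %d atoms, %d residues, %d chain(s)\n",
              x$model_id, nrow(x$atoms),
              nrow(unique(x$atoms[, c("chain", "resno")])),
              length(unique(x$atoms$chain))))
  invisible(x)
}

#' Number of residues of a protein model
#' @param model A `protein_model`.
#' @return Integer residue count (over all chains).
#' @export
n_residues <- function(model) {
  nrow(unique(model$atoms[, c("chain", "resno")]))
}

#' Read a protein model from a PDB file
#'
#' Only ATOM records of the first MODEL are kept; HETATM records and hydrogens
#' are skipped. Alternate locations are resolved by occupancy (tie: altLoc "A",
#' then first record). Coordinates are taken from the fixed PDB columns 31-54.
#'
#' @param path Path to a PDB file containing at least one ATOM record.
#' @param model_id Model identifier; defaults to the file name without its
#'   extension.
#' @return A [protein_model()].
#' @export
read_pdb <- function(path, model_id = NULL) {
  if (!file.exists(path)) stopf("PDB file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  atom_lines <- grep("^ATOM ", lines)
  if (!length(atom_lines)) stopf("no ATOM records in %s", path)
  # validate the fixed-width coordinate fields before handing over to bio3d,
  # so the error can name the offending line
  for (ln in atom_lines) {
    fields <- substring(lines[ln], c(31, 39, 47), c(38, 46, 54))
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) {
      stopf("malformed coordinate field at line %d of %s", ln, path)
    }
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  # element symbol: prefer column 77-78, fall back to first letter of atom name
  elesy <- at$elesy
  guess <- sub("^[0-9]*", "", at$elety)
  elesy[is.na(elesy) | elesy == ""] <- substr(guess[is.na(elesy) | elesy == ""], 1, 1)
  at$elesy <- toupper(elesy)
  at <- at[at$elesy != "H", , drop = FALSE]
  if (!nrow(at)) stopf("no heavy-atom ATOM records in %s", path)
  at$chain[is.na(at$chain)] <- " "
  at$insert[is.na(at$insert)] <- ""
  # altLoc resolution: highest occupancy, tie -> 'A', then file order
  if (any(!is.na(at$alt))) {
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
    occ <- ifelse(is.na(at$o), 1, at$o)
    pref <- ifelse(is.na(at$alt), 0L, ifelse(at$alt == "A", 1L, 2L))
    ord <- order(key, -occ, pref, seq_len(nrow(at)))
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(key[ord]), , drop = FALSE]
    at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  }
  if (is.null(model_id)) model_id <- sub("\\.[^.]*$", "", basename(path))
  protein_model(model_id, data.frame(
    chain = at$chain, resno = at$resno, resname = at$resid,
    elety = at$elety, elesy = at$elesy,
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  ))
}

#' Write a protein model to a PDB file
#'
#' Coordinates are written in the fixed 8.3 PDB format, i.e. preserved to three
#' decimals on a read/write round trip. Models exceeding the PDB numbering
#' limits (9999 residues or 99999 atoms) are rejected rather than silently
#' renumbered.
#'
#' @param model A [protein_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  at <- model$atoms
  if (max(at$resno) > 9999L) {
    stopf("model '%s' has residue numbers beyond the PDB limit of 9999", model$model_id)
  }
  if (nrow(at) > 99999L) {
    stopf("model '%s' has more atoms than the PDB limit of 99999", model$model_id)
  }
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    resno = at$resno, resid = at$resname, chain = at$chain,
    eleno = seq_len(nrow(at)), elety = at$elety, elesy = at$elesy,
    o = rep(1, nrow(at)), b = rep(0, nrow(at))
  )
  invisible(path)
}

#' Construct a point cloud
#'
#' Ordered 3D points (one per selected atom, Angstrom), optional unit normals,
#' and an optional anchor index mapping residues to the point index of their
#' C-alpha atom.
#'
#' @param points n x 3 numeric matrix.
#' @param normals Optional n x 3 matrix of unit vectors.
#' @param anchor_index Optional named integer vector (names `"chain:resno"`).
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(points, normals = NULL, anchor_index = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 1L || ncol(points) != 3L) stopf("points must be a non-empty n x 3 matrix")
  if (!all(is.finite(points))) stopf("point cloud has non-finite coordinates")
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    if (!identical(dim(normals), dim(points))) {
      stopf("normals must have the same dimensions as points")
    }
    nrm <- sqrt(rowSums(normals^2))
    if (any(abs(nrm - 1) > 1e-9)) stopf("normals must have unit norm (tolerance 1e-9)")
  }
  structure(list(points = points, normals = normals, anchor_index = anchor_index),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points%s%s\n", nrow(x$points),
              if (is.null(x$normals)) "" else ", with normals",
              if (is.null(x$anchor_index)) "" else
                sprintf(", %d anchors", length(x$anchor_index))))
  invisible(x)
}

#' Convert a protein model to a point cloud
#'
#' Point order follows atom order in the file. Under `"calpha"` exactly the
#' atoms named `CA` are kept; under `"all_heavy"` every non-hydrogen atom is a
#' point. In both cases `anchor_index` maps each residue that has a C-alpha to
#' the index of that point within the cloud.
#'
#' @param model A [protein_model()].
#' @param selection `"all_heavy"` (default) or `"calpha"`.
#' @return A [point_cloud()].
#' @export
to_point_cloud <- function(model, selection = c("all_heavy", "calpha")) {
  selection <- match.arg(selection)
  at <- model$atoms
  keep <- at$elesy != "H"
  if (selection == "calpha") keep <- keep & at$elety == "CA"
  if (!any(keep)) {
    stopf("model '%s' has no %s atoms", model$model_id,
          if (selection == "calpha") "C-alpha" else "heavy")
  }
  at <- at[keep, , drop = FALSE]
  is_ca <- at$elety == "CA"
  anchor <- which(is_ca)
  names(anchor) <- paste(at$chain[is_ca], at$resno[is_ca], sep = ":")
  point_cloud(as.matrix(at[, c("x", "y", "z")]), anchor_index = anchor)
}

#' C-alpha coordinates of a model, in residue order
#' @return Matrix with one row per residue having a CA atom; rownames
#'   `"chain:resno"`.
#' @noRd
calpha_coords <- function(model) {
  cl <- to_point_cloud(model, "calpha")
  m <- cl$points
  rownames(m) <- names(cl$anchor_index)
  m
}
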