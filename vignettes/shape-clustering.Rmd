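---
title: "Shape-based clustering of protein 3D structures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-based clustering of protein 3D structures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Groups of patients with chronic lymphocytic leukemia express quasi-identical
B-cell receptor immunoglobulins ("stereotyped subsets"), and homology models
of those immunoglobulin variable domains are expected to form structurally
coherent groups. More generally, given a directory of single-model PDB files,
one often wants to discover groups of models with similar 3D shape without
any sequence-level annotation. `shapeclust` treats each protein as a 3D point
cloud (one point per atom) and clusters the models by the geometry of those
clouds, borrowing local and global shape descriptors from 3D object
recognition rather than relying only on bioinformatics similarity scores.

The pipeline is: structural superposition of model pairs; extraction of shape
descriptors from the aligned clouds; a descriptor-space distance matrix per
descriptor type; optional fusion of the matrices; distance-based clustering
with silhouette-driven selection of the number of clusters; and external
evaluation against ground-truth labels with the Rand index.

# Structural superposition

`tm_align()` is a deliberately simplified re-implementation of the classic
iterative superposition scheme. Three seed alignments are built: the best
gapless threading of one C-alpha sequence along the other (scored by
TM-score after a Kabsch superposition of the threaded pairs), a dynamic
programming (DP) alignment of secondary-structure strings, and a DP alignment
of the equally weighted sum of the secondary-structure score matrix and the
geometric TM-score matrix obtained from the gapless seed's superposition.
Each seed is refined by alternating (i) a Kabsch superposition on the current
residue pairs and (ii) a DP pass over the score matrix
`S_ij = 1 / (1 + (d_ij / d0)^2)`, until the pair set stops changing or 30
iterations are reached. The best-scoring alignment seen anywhere (seeds
included) is returned, so refinement is monotone with respect to the seeds.

The TM-score of an alignment is

```
TM = (1 / L_target) * sum_i 1 / (1 + (d_i / d0(L_target))^2),
d0(L) = 1.24 * (L - 15)^(1/3) - 1.8   (clamped below at 0.5 Angstrom)
```

The clamp matters only for targets of 18 residues or fewer, where the raw
formula is non-positive; 0.5 Angstrom is the conventional floor. The score is
asymmetric in the normalizing length, so both directions are reported
(`tm_score_ab` normalizes by the second model's length, `tm_score_ba` by the
first's) and the TM-based baseline distance uses their mean:
`d = 1 - (TM_ab + TM_ba) / 2`.

Secondary structure is assigned from C-alpha pseudo-geometry alone
(i,i+2 / i,i+3 / i,i+4 distance windows, thresholds exposed as arguments),
because the pipeline never needs side chains or hydrogen-bond geometry; the
assignment only seeds the aligner. DP uses a linear gap penalty (default
-0.6 on a score matrix whose entries live in [0, 1]) and breaks ties
deterministically (diagonal, then up, then left).

Two choices here are the package's own, where the method description leaves
the question open: which protein of a pair is the TM-score "target" (we keep
both directions and average for distances), and the exact DP tie-break order.

# Shape descriptors

All descriptors operate on the point cloud of a model in its *aligned* pose;
none of them is rotation invariant in general, which is exactly why pairs are
superposed first. Surface normals are estimated per point as the
smallest-eigenvalue direction of the covariance of its k-nearest-neighbor
neighborhood.

**Normal orientation.** By default normals are oriented away from the cloud
centroid. An explicit viewpoint (flip-to-face semantics) is also supported,
but the centroid convention is the default because it is equivariant under
rigid motions of the cloud: with a fixed external viewpoint, rotating the
input could silently flip normal signs and change every descriptor, whereas
with the centroid convention the whole pipeline is invariant (to ~1e-6) under
a common rigid motion of all input models.

**FPFH** (fast point feature histogram, local). For a query point, the
simplified point feature histogram (SPFH) bins the three Darboux-frame
angular features (alpha, phi, theta) between the query and each of its k
nearest neighbors, one block of 11 bins per feature, each block normalized to
sum 100. The final descriptor accumulates the neighbors' SPFHs weighted by
inverse distance:

```
FPFH(p) = SPFH(p) + (1/k) * sum_i (1/d_i) * SPFH(p_i)
```

With 11 bins per feature the vector is 33-dimensional. Note the accumulation
is applied literally — the FPFH blocks are *not* renormalized to 100
afterwards (the three blocks still carry equal total mass).

**3DSC** (3D shape context, local). A histogram over a support sphere
centered at the query point, oriented by its normal: uniform azimuth and
elevation bins, logarithmic radial bins between `0.1 * support_radius` and
`support_radius`. Each in-support point contributes
`w = 1 / (rho * V^(1/3))`, where `V` is the bin volume and `rho` counts the
cloud points within `sc_density_radius` of the contributing point (itself
included). The azimuth reference direction is the global axis least parallel
to the normal, projected onto the tangent plane — deterministic for a fixed
pose. Points closer than the innermost radial edge are clamped into the first
radial shell.

**RSD** (radius-based surface descriptor, local). For each in-support
neighbor at distance `d` whose normal makes angle `alpha` with the query
normal, the sphere through both points consistent with the normals has radius
`r` given by the chord relation `d = r * sqrt(2 - 2 cos(alpha))`. Below
`alpha = 0.1` rad the first-order inversion `r = d / alpha` is used (the
first term of the Taylor expansion of the chord relation; its relative error
at the crossover is under 0.05%). Radii are clamped at `rsd_plane_radius`
(20 Angstrom), the flat-surface limit, and the descriptor is `(r_min, r_max)`
over the neighbors.

**VFH** (viewpoint feature histogram, global). One vector per cloud: an SPFH
computed at the centroid treating every point as a neighbor (centroid normal
= renormalized mean normal), concatenated with an 11-bin histogram of the
cosines between each point normal and the fixed viewpoint-to-centroid
direction. Using the fixed direction (rather than per-point directions) makes
the viewpoint block scale invariant. The viewpoint is placed at the centroid
plus three bounding radii along +z of the aligned frame and is shared by both
models of a pair (or by a whole reference-aligned set).

## Defaults

| parameter | default | units | why |
|---|---|---|---|
| `neighbor_k` | 10 | points | typical for normal/FPFH neighborhoods at C-alpha density |
| `support_radius` | 8 | Angstrom | ~2 residue shells around a C-alpha |
| `sc_bins` | (12, 11, 15) | — | the customary shape-context binning |
| `sc_min_radius_fraction` | 0.1 | — | keeps log-binning away from r = 0 |
| `sc_density_radius` | 2 | Angstrom | resolves duplicate-dense regions without flattening the histogram |
| `rsd_plane_radius` | 20 | Angstrom | beyond any curvature resolvable at 8 Angstrom support |
| `fpfh_bins_per_feature` | 11 | bins | fixed by the 33-dimensional FPFH |

None of these are dictated by the method description; they follow the
conventions of the reference implementations of these descriptor families and
are all exposed in `descriptor_config()`.

# Distance matrices and fusion

The distance between two models under one descriptor type is the RMSD over
corresponding feature vectors,

```
RMSD(F_i, F_j) = sqrt( (1/L) * sum_k || f_ik - f_jk ||^2 ),
```

which for a global descriptor (L = 1) is the plain Euclidean distance. The
formula presumes a point correspondence between two different proteins, which
is genuinely undefined a priori; the package's convention is that anchors are
the C-alpha atoms of *aligned residue pairs*, so `k <-> k` correspondence is
given by the structural alignment and L is the alignment length. This is
flagged here because it is this artifact's resolution of an underdetermined
step, not something the method description prescribes.

Two extraction modes exist:

* **pairwise** (default): every unordered pair is aligned, descriptors are
  extracted from both models in that pair's pose at the pair's anchors. Cost:
  n(n-1)/2 alignments and 2 extractions per pair. Faithful, used for small
  sets.
* **reference**: every model is aligned once to a reference model (the
  first); descriptors are extracted once per model; for a pair (i, j) the
  anchor set is the reference residues aligned in both (so L still varies per
  pair). The full-coverage DP alignment under the final superposition is used
  for these anchor maps, because the TM-optimal pair set can be very short
  for dissimilar structures and two such sets may not intersect at all; any
  residual pair with an empty intersection is assigned the matrix maximum,
  with a warning. All pairwise RMSDs then reduce to masked Gram-matrix
  products, so the mode costs n alignments instead of n^2/2.

Each descriptor's matrix is min-max normalized (divided by its largest
off-diagonal entry) before fusion. This is a deliberate deviation from
summing raw matrices: raw descriptor scales differ by orders of magnitude
(RSD distances live on ~1 Angstrom scales, 3DSC histogram distances can be in
the hundreds), and an unnormalized sum would silently let one descriptor
dominate. `normalize = FALSE` restores the literal raw sum.

Fusion is the weighted sum `D = sum_m w_m D_m` with either equal weights or
silhouette weights: `w_m` is the maximum, over the candidate cluster-number
range, of the average silhouette width of the k-medoids clustering of
`D_m` — a descriptor that exposes more cluster structure counts more.
Negative maxima clamp to 0; if everything clamps, equal weights are used with
a warning.

# Clustering and model selection

* **k-medoids**: PAM-style alternating heuristic on the distance matrix —
  assign to nearest medoid, update each medoid to the member minimizing total
  within-cluster distance, repeat until stable; best of 10 random restarts
  under a named seed (default 42). Ties break toward the lowest object index.
  The restart heuristic matches exhaustive medoid search on every small
  fixture we test (n <= 8, k <= 3).
* **agglomerative**: average linkage (UPGMA) via `stats::hclust`, cut at k.
* **DBSCAN**: standard density-reachable expansion; `eps` defaults to the
  25th percentile of off-diagonal distances, `min_pts = 4`. Noise points get
  fresh singleton labels so silhouettes and the Rand index stay defined —
  a documented convention, not an inference from the method description.

The number of clusters is chosen by maximizing the average silhouette width
`s_i = (b_i - a_i) / max(a_i, b_i)` over a candidate range (default 3–25),
ties to the smallest k; members of singleton clusters get `s_i = 0` (the
standard convention). External accuracy is the plain Rand index
`R = (a + b) / C(N, 2)`; the adjusted Rand index is reported as an extra
column but is not the headline number. When only a subset of models carries
ground-truth labels, the Rand index is computed on that subset.

# The synthetic generator

No immunoglobulin model set is distributed with the package, so the generator
emulates one: a small number of families, each sharing a backbone template,
members differing by per-atom Gaussian noise and a random rigid motion,
families differing by large backbone perturbations. Templates are
self-avoiding C-alpha traces built in internal coordinates — exact 3.8
Angstrom consecutive spacing, ideal helix (1.5 Angstrom rise, 100
degrees/residue) and extended-strand segments joined by random coils — with
clashes resolved by resampling coil torsions. Family divergence is applied at
the torsion level (~4 degrees of torsion jitter per Angstrom of requested
divergence) to a shared base fold, which changes global shape while
preserving local backbone geometry. Dummy N/C/O atoms decorate each residue
so files are legal PDBs and the real I/O path is exercised.

The default layout is six families of sizes 38/42/22/12/12/11 (137 models,
mirroring the subset-size distribution of a well-characterized annotated
immunoglobulin cohort), 110-residue templates, 0.3 Angstrom within-family
noise and 3 Angstrom between-family divergence — a separation-to-noise ratio
of 10.

What the generator does *not* emulate: side chains, sequence-dependent
geometry, Ramachandran statistics, homology-modelling artifacts, or families
related by anything subtler than global backbone divergence. Recovery results
on synthetic data therefore demonstrate that the machinery is correct and
discriminative for well-separated shape families; they do not certify
accuracy on real immunoglobulin model sets, whose family structure is far
less clean.

# Numerical choices

* Distances used for neighbor selection and support membership are quantized
  to 1e-6 Angstrom before comparison, with ties broken by point index. The
  regular synthetic geometry produces exactly tied neighbor distances, and
  without quantization fp-level coordinate noise (e.g. from an extra rigid
  motion) reorders neighbors and visibly changes histograms.
* The Darboux theta feature snaps its `atan2` arguments to zero below 1e-9 so
  exactly coplanar, antiparallel normals give theta = +pi stably instead of
  flipping between +pi and -pi.
* Self-distances from the Gram-matrix formula are forced to exact zero so
  points never count themselves as neighbors.
* Kabsch excludes reflections (`det = +1`) and warns on (near-)collinear
  input; degenerate normal neighborhoods fall back to (0, 0, 1) with a
  warning; an empty RSD support yields the plane radius, an empty 3DSC
  support a zero vector, both with warnings.
* Multi-model PDB files contribute only their first MODEL; alternate
  locations resolve to the highest-occupancy record (ties prefer altLoc "A").

# Problem sizes and reproducibility

The test suite runs the full combined-descriptor pipeline (C-alpha clouds,
reference mode, silhouette fusion, k selected over 3–25) on the default
137-model fixture — about a minute on one core — plus property and oracle
tests on small fixtures; the whole suite takes under two minutes. All
randomness flows through named seeds (`seed` arguments, pipeline `seed`), and
repeated runs are byte-identical. `scripts/acceptance.R` recomputes the
self-contained headline quantities from a fresh session.

# Known limitations

* The aligner is a simplified TM-align: three seeds, linear-gap DP, a
  30-iteration cap. It is not intended to reproduce the published TM-align
  executable bit for bit; a TSV import path for externally computed TM-scores
  exists for users who need the reference aligner.
* Pairwise mode is O(n^2) alignments; reference mode trades fidelity of the
  anchor correspondence for an O(n) alignment count and is the intended mode
  for hundreds of models.
* 3DSC's azimuth frame is deterministic in the aligned pose but not
  rotation-equivariant, so 3DSC matrices are only meaningful after alignment
  (FPFH and RSD are the robust choices when alignment quality is doubtful —
  and empirically 3DSC receives the smallest silhouette weight on the default
  fixture).
* DBSCAN's singleton-noise convention inflates the cluster count when eps is
  chosen poorly; silhouette-based selection does not apply to it.
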