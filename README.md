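# shapeclust

Shape-based clustering of protein 3D structures.

`shapeclust` discovers groups of structurally similar protein models in a set
of PDB files by treating each protein as a 3D point cloud (one point per
atom) and comparing clouds with shape descriptors from 3D object recognition,
instead of (or alongside) classic bioinformatics similarity scores. It was
built for sets of B-cell receptor immunoglobulin variable-domain models —
where groups of quasi-identical ("stereotyped") receptors are expected to
share 3D shape — but accepts any directory of single-model PDB files.

## Method

For a pair of models the pipeline:

1. **superposes** them with a simplified iterative TM-align
   (Kabsch rotations alternating with dynamic programming over the TM-score
   matrix `S_ij = 1/(1 + (d_ij/d0)^2)`, `d0(L) = 1.24 (L-15)^{1/3} - 1.8`,
   seeded by gapless threading and secondary-structure alignment);
2. **extracts descriptors** from the aligned point clouds, anchored at the
   C-alpha atoms of aligned residue pairs:
   FPFH (33-dimensional local histograms of Darboux-frame angles),
   3DSC (local histograms over azimuth x elevation x log-radius bins),
   RSD (per-point min/max radius of normal-consistent fitted spheres),
   and VFH (one global vector per model);
3. **computes the descriptor-space distance**
   `RMSD(F_i, F_j) = sqrt((1/L) * sum_k ||f_ik - f_jk||^2)`
   (the Euclidean distance when L = 1).

Per-descriptor distance matrices are min-max normalized and optionally fused
as a weighted sum `D = sum_m w_m D_m` with equal or silhouette-based weights
(`w_m` = the best average silhouette width that descriptor achieves over a
range of cluster numbers). The fused (or single) matrix is clustered with
k-medoids, average-linkage agglomerative clustering, or DBSCAN; the number of
clusters is selected by maximizing the average silhouette width
`s_i = (b_i - a_i)/max(a_i, b_i)` over k = 3..25. Against ground-truth labels
the clustering is scored with the Rand index `R = (a + b) / C(N, 2)`,
restricted to the labelled subset when only part of the set is annotated.

A synthetic-data module generates labelled families of protein-like models
(shared self-avoiding backbone template per family, 3.8 Angstrom C-alpha
spacing, Gaussian within-family noise, torsion-level between-family
divergence), so the entire pipeline is testable without external data.

See `vignettes/shape-clustering.Rmd` for the full model description, defaults
and design decisions.

## Worked example

```r
library(shapeclust)

# three synthetic families of five 60-residue models each
specs <- list(family_spec("A", 5, template_length = 60),
              family_spec("B", 5, template_length = 60),
              family_spec("C", 5, template_length = 60))
ds <- generate_dataset(specs, global_seed = 7)

cfg <- pipeline_config(models = ds$models, labels = ds$labels,
                       descriptors = c("fpfh", "rsd", "vfh"),
                       selection = "calpha", mode = "reference",
                       fusion = "silhouette", method = "kmedoids",
                       k_range = 2:8, seed = 42)
res <- run_pipeline(cfg)
print(res$report, row.names = FALSE)
```

```
 descriptor   method k avg_silhouette      rand adjusted_rand
       fpfh kmedoids 3      0.1681529 1.0000000     1.0000000
        rsd kmedoids 2      0.2232182 0.6285714     0.3053435
        vfh kmedoids 3      0.3559008 1.0000000     1.0000000
   combined kmedoids 3      0.2566395 1.0000000     1.0000000
```

Each row is one distance matrix: the silhouette-selected number of clusters
`k`, its average silhouette width (internal quality), and the Rand /
adjusted-Rand agreement with the planted family labels. Here FPFH and VFH
recover the three families exactly (Rand 1.0); RSD under-splits at k = 2; the
silhouette-weighted combination recovers k = 3 with Rand 1.0.

Single pairs can be aligned directly:

```r
tm_align(ds$models[["A_001"]], ds$models[["B_001"]])
#> <tm_alignment> L_align = 57, TM(ab) = 0.2635, TM(ba) = 0.2635, rmsd = 5.657 A (seed: gapless)
```

(A TM-score of ~0.26 is what unrelated folds look like; members of the same
family score ~1.)

A command-line interface wrapping the same functions ships at
`inst/cli/shapeclust` with subcommands `simulate`, `align`, `describe`,
`distances`, `cluster`, `evaluate`, `run-all`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "shapeclust", package = "shapeclust"))')
Rscript $CLI simulate --out fixtures --seed 3 --families 4,4,4 --length 50
Rscript $CLI run-all --in fixtures --out results --selection calpha --mode reference
```

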