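# End-to-end pipeline: read models -> align -> extract descriptors ->
# distance matrices -> (normalize, fuse) -> cluster -> evaluate -> report.

#' Pipeline configuration
#'
#' Validates and assembles the configuration of a full run. Every source of
#' randomness is funnelled through `seed`.
#'
#' @param input_dir Directory of PDB files (`*.pdb`), or `NULL` when `models`
#'   is given directly.
#' @param models Optional named list of [protein_model()]s (bypasses
#'   `input_dir`).
#' @param labels Optional ground-truth labels: a named vector or a TSV path
#'   (`model_id`, `label`).
#' @param descriptors Subset of `c("fpfh", "sc3d", "rsd", "vfh", "tm")`.
#' @param selection Atom selection for descriptor support clouds.
#' @param mode Distance-matrix mode, `"pairwise"` or `"reference"`.
#' @param fusion `"equal"`, `"silhouette"`, or `"none"` (no combined matrix).
#' @param method Clustering method.
#' @param k Fixed number of clusters, or `NULL` to select it by silhouette.
#' @param k_range Candidate k values when `k` is `NULL` (default 3:25, also
#'   used for silhouette fusion weights).
#' @param normalize Min-max normalize matrices before fusion (kept on by
#'   default; turning it off sums raw matrices, letting large-scale
#'   descriptors dominate).
#' @param seed Master RNG seed.
#' @param restarts k-medoids restarts.
#' @param config A [descriptor_config()].
#' @param output_dir Optional directory for TSV artifacts.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, models = NULL, labels = NULL,
                            descriptors = c("fpfh", "sc3d", "rsd", "vfh"),
                            selection = c("all_heavy", "calpha"),
                            mode = c("pairwise", "reference"),
                            fusion = c("silhouette", "equal", "none"),
                            method = c("kmedoids", "agglomerative", "dbscan"),
                            k = NULL, k_range = 3:25,
                            normalize = TRUE,
                            seed = 42L, restarts = 10L,
                            config = descriptor_config(),
                            output_dir = NULL) {
  selection <- match.arg(selection)
  mode <- match.arg(mode)
  fusion <- match.arg(fusion)
  method <- match.arg(method)
  bad <- setdiff(descriptors, c("fpfh", "sc3d", "rsd", "vfh", "tm"))
  if (length(bad)) stopf("config field 'descriptors': unknown type(s) %s", paste(bad, collapse = ", "))
  if (!length(descriptors)) stopf("config field 'descriptors': need at least one descriptor")
  if (is.null(input_dir) && is.null(models)) {
    stopf("config: one of 'input_dir' or 'models' is required")
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stopf("config field 'input_dir': directory '%s' does not exist", input_dir)
  }
  if (!is.null(k) && (!is.numeric(k) || length(k) != 1L || k < 1L)) {
    stopf("config field 'k': must be a single number >= 1")
  }
  if (!length(k_range) || any(k_range < 2L)) {
    stopf("config field 'k_range': values must be >= 2")
  }
  structure(list(input_dir = input_dir, models = models, labels = labels,
                 descriptors = descriptors, selection = selection, mode = mode,
                 fusion = fusion, method = method, k = k, k_range = k_range,
                 normalize = normalize, seed = as.integer(seed),
                 restarts = as.integer(restarts),
                 config = config, output_dir = output_dir),
            class = "pipeline_config")
}

load_models <- function(cfg) {
  if (!is.null(cfg$models)) return(cfg$models)
  files <- sort(list.files(cfg$input_dir, pattern = "\\.pdb$", full.names = TRUE))
  if (length(files) < 3L) stopf("input_dir '%s' holds %d PDB files; need at least 3",
                                cfg$input_dir, length(files))
  models <- lapply(files, read_pdb)
  names(models) <- vapply(models, function(m) m$model_id, character(1))
  models
}

load_truth <- function(cfg) {
  if (is.null(cfg$labels)) return(NULL)
  if (is.character(cfg$labels) && length(cfg$labels) == 1L && file.exists(cfg$labels)) {
    return(read_labels(cfg$labels))
  }
  as_partition(cfg$labels)
}

cluster_one <- function(d, cfg) {
  if (cfg$method == "dbscan") {
    cl <- dbscan_cluster(d)
    prof <- tryCatch(silhouette_widths(d, cl), error = function(e) NULL)
    return(list(k = length(unique(cl$labels)), clustering = cl, profile = prof))
  }
  if (!is.null(cfg$k)) {
    cl <- switch(cfg$method,
                 kmedoids = k_medoids(d, cfg$k, seed = cfg$seed, restarts = cfg$restarts),
                 agglomerative = agglomerative(d, cfg$k))
    prof <- tryCatch(silhouette_widths(d, cl), error = function(e) NULL)
    list(k = cfg$k, clustering = cl, profile = prof)
  } else {
    select_k(d, cfg$method, cfg$k_range, seed = cfg$seed, restarts = cfg$restarts)
  }
}

#' Run the full shape-clustering pipeline
#'
#' Executes read -> align -> descriptors -> distance matrices -> (normalize,
#' fuse) -> cluster -> evaluate, and writes TSV artifacts when
#' `output_dir` is set: one distance matrix per descriptor (plus the combined
#' one), cluster assignments, the per-k silhouette table of the primary
#' result, a summary report, and a log of non-default decisions. Reproducible
#' given the config's seed.
#'
#' @param cfg A [pipeline_config()].
#' @return List with `matrices`, `combined` (fused matrix or `NULL`),
#'   `weights`, `results` (per-descriptor and combined: k, clustering,
#'   silhouette profile, Rand index columns when labels are given), `report`
#'   (a data frame), and `log`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  models <- load_models(cfg)
  if (length(models) < 3L) stopf("need at least 3 models, got %d", length(models))
  truth <- load_truth(cfg)
  note("loaded %d models", length(models))

  shape_types <- setdiff(cfg$descriptors, "tm")
  matrices <- list()
  for (ty in shape_types) {
    matrices[[ty]] <- withCallingHandlers(
      pairwise_distance_matrix(models, ty, cfg$config, cfg$selection, cfg$mode),
      warning = function(w) {
        note("descriptor %s: %s", ty, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  if ("tm" %in% cfg$descriptors) {
    matrices[["tm"]] <- tm_distance_matrix(models)
  }

  norm_matrices <- matrices
  if (cfg$normalize) {
    norm_matrices <- lapply(matrices, normalize_matrix)
  } else {
    note("normalization disabled: fusing raw matrices")
  }

  combined <- NULL
  weights <- NULL
  if (cfg$fusion != "none" && length(norm_matrices) > 1L) {
    weights <- if (cfg$fusion == "equal") {
      fusion_weights(rep(1, length(norm_matrices)), "equal")
    } else {
      withCallingHandlers(
        silhouette_weights(norm_matrices, cfg$k_range, seed = cfg$seed,
                           restarts = cfg$restarts),
        warning = function(w) {
          note("silhouette weights: %s", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    }
    combined <- fuse(norm_matrices, weights)
    note("fused %s with %s weights: %s", paste(names(norm_matrices), collapse = "+"),
         weights$scheme, paste(signif(weights$w, 4), collapse = ", "))
  }

  evaluate <- function(res) {
    row <- data.frame(k = res$k,
                      avg_silhouette = if (is.null(res$profile)) NA_real_ else res$profile$average,
                      rand = NA_real_, adjusted_rand = NA_real_)
    if (!is.null(truth)) {
      row$rand <- evaluate_on_subset(res$clustering, truth)
      common <- intersect(res$clustering$ids, names(truth))
      row$adjusted_rand <- adjusted_rand_index(res$clustering$labels[common], truth[common])
    }
    row
  }

  results <- list()
  report <- NULL
  for (nm in names(norm_matrices)) {
    res <- cluster_one(norm_matrices[[nm]], cfg)
    res$evaluation <- evaluate(res)
    results[[nm]] <- res
    report <- rbind(report, cbind(descriptor = nm, method = cfg$method, res$evaluation))
  }
  if (!is.null(combined)) {
    res <- cluster_one(combined, cfg)
    res$evaluation <- evaluate(res)
    results[["combined"]] <- res
    report <- rbind(report, cbind(descriptor = "combined", method = cfg$method,
                                  res$evaluation))
  }

  primary <- results[["combined"]] %||% results[[1L]]

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(...) file.path(cfg$output_dir, sprintf(...))
    for (nm in names(matrices)) {
      write_distance_matrix(matrices[[nm]], out("distance_%s.tsv", nm))
    }
    if (!is.null(combined)) write_distance_matrix(combined, out("distance_combined.tsv"))
    write_clustering(primary$clustering, out("assignments.tsv"))
    if (!is.null(primary$profile$per_k)) {
      utils::write.table(primary$profile$per_k, out("silhouette_per_k.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(report, out("report.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeLines(c(sprintf("seed\t%d", cfg$seed), log), out("run_log.txt"))
  }

  list(matrices = matrices, normalized = norm_matrices, combined = combined,
       weights = weights, results = results, report = report, log = log)
}
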