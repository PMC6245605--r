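# External evaluation of clusterings against ground-truth labels.

# coerce a clustering / named vector / (ids, labels) frame to a named label vector
as_partition <- function(x) {
  if (inherits(x, "protein_clustering")) return(x$labels)
  if (is.data.frame(x)) {
    if (!all(c("model_id", "label") %in% names(x))) {
      stopf("partition data frames need columns model_id, label")
    }
    return(stats::setNames(x$label, x$model_id))
  }
  if (is.null(names(x))) stopf("partitions must be named by object id")
  x
}

#' Rand index between two partitions
#'
#' The fraction of object pairs on which the two partitions agree:
#' `R = (a + b) / C(N, 2)`, where `a` counts pairs co-clustered in both and
#' `b` pairs separated in both. `R` lies in `[0, 1]`, is symmetric, and is
#' invariant to label renaming; 1 means the partitions are identical.
#'
#' @param x,y Partitions over the same id set (>= 2 objects): named label
#'   vectors, `protein_clustering`s, or data frames with `model_id`/`label`.
#' @return The Rand index.
#' @export
rand_index <- function(x, y) {
  x <- as_partition(x); y <- as_partition(y)
  if (!setequal(names(x), names(y)) || length(x) != length(y)) {
    stopf("rand_index: partitions must cover the same ids")
  }
  y <- y[names(x)]
  n <- length(x)
  if (n < 2L) stopf("rand_index: need at least 2 objects")
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- choose(n, 2) - sum(choose(rowSums(tab), 2)) - sum(choose(colSums(tab), 2)) + a
  (a + b) / choose(n, 2)
}

#' Adjusted Rand index
#'
#' Chance-corrected companion of [rand_index()] (Hubert & Arabie), offered as
#' an extra report column; the headline accuracy of the pipeline is the plain
#' Rand index.
#'
#' @inheritParams rand_index
#' @return The adjusted Rand index (can be negative).
#' @export
adjusted_rand_index <- function(x, y) {
  x <- as_partition(x); y <- as_partition(y)
  if (!setequal(names(x), names(y)) || length(x) != length(y)) {
    stopf("adjusted_rand_index: partitions must cover the same ids")
  }
  y <- y[names(x)]
  n <- length(x)
  tab <- table(x, y)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxidx <- (si + sj) / 2
  if (maxidx == expected) return(1)
  (sij - expected) / (maxidx - expected)
}

#' Rand index restricted to the labelled subset
#'
#' Compares a clustering to ground truth over only the ids present in the
#' truth table; unlabelled models are ignored. This is how a clustering of a
#' mixed annotated/unannotated set is scored against its annotated part.
#'
#' @param cl A `protein_clustering` (or named label vector).
#' @param truth Ground-truth partition covering a subset of the clustering's
#'   ids.
#' @return The Rand index over the labelled ids.
#' @export
evaluate_on_subset <- function(cl, truth) {
  cl <- as_partition(cl); truth <- as_partition(truth)
  common <- intersect(names(cl), names(truth))
  if (!length(common)) stopf("evaluate_on_subset: no labelled ids in the clustering")
  rand_index(cl[common], truth[common])
}

#' Read / write ground-truth labels as TSV
#'
#' Two-column TSV `model_id`, `label`.
#' @param path File path.
#' @return A named label vector / `path`.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character"))
  stats::setNames(df$label, df$model_id)
}

#' @rdname read_labels
#' @param labels Named label vector.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(model_id = names(labels), label = as.character(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
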