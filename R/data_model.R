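# Core dataset container, normalization, standardization, fold construction
# and random-gene supplementation.

#' Expression dataset with a binary disease-state label
#'
#' The central data container: a samples x features matrix of (typically
#' standardized) expression values, a binary class label per sample
#' (disease = 1, control = 0), and a feature-to-gene map.  At
#' `level = "transcript"` several features (probes/isoforms) may map to the
#' same gene; at `level = "gene"` the map must be one feature per gene.
#'
#' @param values numeric matrix, samples in rows, features in columns; column
#'   names are the feature identifiers.
#' @param class_labels integer/numeric vector of 0 (control) / 1 (disease),
#'   one per sample.  Both states must occur at least once.
#' @param feature_to_gene named character vector mapping each feature id
#'   (names) to a gene id (values).
#' @param species_id species label carried through translation and
#'   confidence counting.
#' @param level `"transcript"` or `"gene"`.
#' @param sample_ids sample identifiers; defaults to `rownames(values)` or
#'   `s1..sn`.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, class_labels, feature_to_gene,
                               species_id = "species",
                               level = c("transcript", "gene"),
                               sample_ids = NULL) {
  level <- match.arg(level)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (samples x features)")
  if (is.null(colnames(values)))
    stop("'values' must have feature ids as column names")
  if (anyNA(values))
    stop("expression values must be complete (no missing values) at this layer")
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature ids in 'values'")
  if (CLASS_NODE %in% colnames(values))
    stop(sprintf("feature id '%s' is reserved for the class node", CLASS_NODE))
  class_labels <- as.integer(class_labels)
  if (length(class_labels) != nrow(values))
    stop("one class label per sample required")
  if (!all(class_labels %in% c(0L, 1L)))
    stop("class labels must be 0 (control) or 1 (disease)")
  if (length(unique(class_labels)) < 2L)
    stop("class labels must contain both states at least once")
  feats <- colnames(values)
  if (!all(feats %in% names(feature_to_gene)))
    stop("features without a gene mapping: ",
         paste(setdiff(feats, names(feature_to_gene)), collapse = ", "))
  feature_to_gene <- feature_to_gene[feats]
  if (anyNA(feature_to_gene))
    stop("feature_to_gene contains missing gene ids")
  if (level == "gene" && anyDuplicated(feature_to_gene))
    stop("multiple features per gene are only allowed at transcript level")
  if (is.null(sample_ids))
    sample_ids <- rownames(values) %||% paste0("s", seq_len(nrow(values)))
  rownames(values) <- sample_ids
  structure(
    list(species_id = species_id, values = values,
         sample_ids = sample_ids, class_labels = class_labels,
         feature_ids = feats, feature_to_gene = feature_to_gene,
         level = level),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "<expression_dataset> species=%s level=%s: %d samples x %d features (%d genes), %d disease / %d control\n",
    x$species_id, x$level, nrow(x$values), ncol(x$values),
    length(unique(x$feature_to_gene)),
    sum(x$class_labels == 1L), sum(x$class_labels == 0L)))
  invisible(x)
}

#' Genes of an expression dataset
#' @param dataset an [expression_dataset()].
#' @return character vector of distinct gene ids.
#' @export
dataset_genes <- function(dataset) unique(unname(dataset$feature_to_gene))

#' Restrict a dataset to a subset of samples
#' @param dataset an [expression_dataset()].
#' @param idx integer or logical sample index.
#' @return a new `expression_dataset`.
#' @export
subset_samples <- function(dataset, idx) {
  expression_dataset(dataset$values[idx, , drop = FALSE],
                     dataset$class_labels[idx],
                     dataset$feature_to_gene,
                     species_id = dataset$species_id,
                     level = dataset$level,
                     sample_ids = dataset$sample_ids[idx])
}

#' Restrict a dataset to the features of a gene subset
#' @param dataset an [expression_dataset()].
#' @param genes character vector of gene ids to keep.
#' @return a new `expression_dataset` containing every feature of the kept genes.
#' @export
subset_genes <- function(dataset, genes) {
  keep <- dataset$feature_ids[dataset$feature_to_gene %in% genes]
  if (length(keep) == 0L) stop("no features left after gene restriction")
  expression_dataset(dataset$values[, keep, drop = FALSE],
                     dataset$class_labels,
                     dataset$feature_to_gene[keep],
                     species_id = dataset$species_id,
                     level = dataset$level,
                     sample_ids = dataset$sample_ids)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the identical reference distribution:
#' the per-rank mean across columns.  Ranks within each column are preserved;
#' ties receive the mean of the tied ranks' reference values.  Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param raw numeric matrix, features in rows, samples in columns; must be
#'   complete.
#' @return matrix of the same shape, quantile-normalized.
#' @export
quantile_normalize <- function(raw) {
  if (!is.matrix(raw) || !is.numeric(raw))
    stop("'raw' must be a numeric matrix (features x samples)")
  if (nrow(raw) == 0L || ncol(raw) == 0L)
    stop("cannot quantile-normalize an empty matrix")
  if (anyNA(raw))
    stop("missing values are not allowed in quantile normalization")
  out <- limma::normalizeQuantiles(raw, ties = TRUE)
  dimnames(out) <- dimnames(raw)
  out
}

standardize_matrix <- function(m) {
  mu <- colMeans(m)
  sd <- apply(m, 2L, stats::sd)   # sample sd, n - 1 denominator
  bad <- !is.finite(sd) | sd < .Machine$double.eps^0.5
  if (any(bad))
    stop("constant feature(s) cannot be standardized: ",
         paste(colnames(m)[bad], collapse = ", "))
  scale(m, center = mu, scale = sd)[, , drop = FALSE]
}

#' Standardize each feature to mean 0 and standard deviation 1
#'
#' Uses the sample standard deviation (n - 1 denominator).  Constant features
#' are an error, named in the message.
#'
#' @param dataset an [expression_dataset()] (or a plain samples x features
#'   matrix).
#' @return the standardized dataset (or matrix).
#' @export
standardize <- function(dataset) {
  if (is.matrix(dataset)) return(standardize_matrix(dataset))
  v <- standardize_matrix(dataset$values)
  attr(v, "scaled:center") <- NULL
  attr(v, "scaled:scale") <- NULL
  dataset$values <- v
  dataset
}

#' Class-stratified cross-validation fold plan
#'
#' Assigns every sample to one of `k` folds so that, within each class, fold
#' sizes differ by at most one.  The human design of the motivating study (4
#' disease cases, 4 folds) is only evaluable when every fold holds a case, so
#' stratification is required and a minority class smaller than `k` is an
#' error.
#'
#' @param dataset an [expression_dataset()].
#' @param k integer number of folds, `>= 2`.
#' @param seed integer; the assignment is deterministic given the seed.
#' @return a `fold_plan`: list with `k` and `assignment`, a fold index in
#'   `1..k` named by sample id.
#' @export
make_folds <- function(dataset, k, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  cls <- dataset$class_labels
  minority <- min(table(cls))
  if (minority < k)
    stop(sprintf(
      "minority class has %d samples but k = %d folds; every fold needs a case from each class",
      minority, k))
  assignment <- integer(length(cls))
  with_seed(seed, {
    for (c0 in unique(cls)) {
      idx <- which(cls == c0)
      idx <- idx[sample.int(length(idx))]
      assignment[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  names(assignment) <- dataset$sample_ids
  structure(list(k = k, assignment = assignment), class = "fold_plan")
}

#' Module / random gene-set split
#'
#' Records which genes form the disease module and which were added as the
#' randomly selected performance/overfitting control set; the two must be
#' disjoint.
#'
#' @param module_genes,random_genes character vectors of gene ids.
#' @return a `gene_set_spec`.
#' @export
gene_set_spec <- function(module_genes, random_genes = character()) {
  module_genes <- unique(as.character(module_genes))
  random_genes <- unique(as.character(random_genes))
  if (length(intersect(module_genes, random_genes)))
    stop("module and random gene sets must be disjoint")
  structure(list(module_genes = module_genes, random_genes = random_genes),
            class = "gene_set_spec")
}

#' Supplement a disease module with randomly selected control genes
#'
#' Restricts the dataset to the module genes plus `n_random` genes drawn
#' uniformly (seed-reproducible) from the remaining genes.  The random set
#' serves as the network-performance and overfitting control.
#'
#' @param dataset an [expression_dataset()].
#' @param module_genes character vector of disease-module gene ids.
#' @param n_random number of control genes to draw.
#' @param seed integer seed for the draw.
#' @return list with elements `dataset` (restricted) and `genes`
#'   (a [gene_set_spec()]).
#' @export
supplement_random_genes <- function(dataset, module_genes, n_random,
                                    seed = 1L) {
  module_genes <- intersect(unique(module_genes), dataset_genes(dataset))
  if (length(module_genes) == 0L)
    stop("none of the module genes are present in the dataset")
  pool <- setdiff(dataset_genes(dataset), module_genes)
  n_random <- as.integer(n_random)
  if (n_random > length(pool))
    stop(sprintf("requested %d random genes but only %d non-module genes available",
                 n_random, length(pool)))
  random_genes <- if (n_random > 0L)
    with_seed(seed, sort(sample(pool, n_random))) else character()
  list(dataset = subset_genes(dataset, c(module_genes, random_genes)),
       genes = gene_set_spec(module_genes, random_genes))
}
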