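# Cross-validation driver, per-network evaluation metrics and run-plan
# combinatorics.

#' Classification metrics from a confusion matrix
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), accuracy =
#' (TP+TN)/total; a zero denominator flags the metric as undefined (`NA`)
#' rather than coercing it to 0.  The ROC-space point is
#' (1 - specificity, sensitivity), one per network.
#'
#' @param tp,fp,tn,fn confusion counts (disease = positive).
#' @return list with the counts, the three metrics, `roc_point` and a
#'   `flagged` field naming undefined metrics.
#' @export
class_metrics <- function(tp, fp, tn, fn) {
  total <- tp + fp + tn + fn
  if (total <= 0) stop("empty confusion matrix")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  flagged <- c(if (is.na(sens)) "sensitivity", if (is.na(spec)) "specificity")
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = sens, specificity = spec,
       accuracy = (tp + tn) / total,
       roc_point = c(fpr = 1 - spec, tpr = sens),
       flagged = flagged)
}

#' Evaluate a structure on held-out samples
#'
#' Fits parameters on the training portion and, on the held-out portion,
#' computes the per-node sum of squared prediction errors (each gene
#' predicted from all others, class marginalized), the disease-state
#' confusion matrix (argmax posterior; ties decided to control) and the
#' class SSE, the squared posterior shortfall `sum((1 - P(true class))^2)`.
#'
#' @param structure a [dag_structure()].
#' @param train_data,test_data [expression_dataset()]s over the same
#'   features.
#' @param condition_on_class condition expression predictions on the
#'   observed class label instead of marginalizing.
#' @return a metrics report: list with `node_sse` (named), `total_sse`,
#'   `class_sse`, `class_posterior`, and the [class_metrics()] fields.
#' @export
evaluate_network <- function(structure, train_data, test_data,
                             condition_on_class = FALSE) {
  fitted <- fit_parameters(structure, train_data, warn = FALSE)
  genes <- names(fitted$families)
  node_sse <- vapply(genes, function(g)
    predict_expression(fitted, test_data, g,
                       condition_on_class = condition_on_class)$sse,
    numeric(1))
  post <- predict_class(fitted, test_data$values[, genes, drop = FALSE])
  truth <- test_data$class_labels
  pred <- as.integer(post[, "1"] > post[, "0"])  # tie -> control
  cm <- class_metrics(tp = sum(pred == 1L & truth == 1L),
                      fp = sum(pred == 1L & truth == 0L),
                      tn = sum(pred == 0L & truth == 0L),
                      fn = sum(pred == 0L & truth == 1L))
  p_true <- post[cbind(seq_along(truth), truth + 1L)]
  c(list(node_sse = node_sse, total_sse = sum(node_sse),
         class_sse = sum((1 - p_true)^2),
         class_posterior = post), cm)
}

#' Learn and evaluate intraspecies fold-networks
#'
#' For every cross-validation fold, runs the unconstrained annealing search
#' (training budget, default 1000 proposals) on the fold's training portion
#' and evaluates the learned structure on the held-out portion, which the
#' search never sees.
#'
#' @param dataset a standardized [expression_dataset()].
#' @param folds a [make_folds()] plan.
#' @param config an [anneal_config()]; per-fold seeds are derived as
#'   `seed + fold`.
#' @param candidates optional [candidate_edge_set()] restriction.
#' @return list with one element per fold: `fold`, `structure`, `score`,
#'   `metrics`.
#' @export
run_intraspecies <- function(dataset, folds, config = anneal_config(),
                             candidates = NULL) {
  lapply(seq_len(folds$k), function(f) {
    train <- subset_samples(dataset, folds$assignment != f)
    test <- subset_samples(dataset, folds$assignment == f)
    cfg <- anneal_config(t0 = config$t0, tn = config$tn,
                         maxfc = config$maxfc, mode = config$mode,
                         seed = config$seed + f)
    res <- anneal(train, cfg, candidates)
    list(fold = f, structure = res$structure, score = res$score,
         metrics = evaluate_network(res$structure, train, test))
  })
}

#' Run-plan combinatorics for one training species
#'
#' With `k_train` cross-validation folds in the training species, the run
#' produces `k_train` intraspecies networks and, for a test species with
#' `k_test` folds, `k_train * k_test` interspecies networks (every training
#' fold's network map is re-optimized on every test fold).
#'
#' @param k_train training species fold count (`>= 2`).
#' @param k_tests named integer vector of test species fold counts.
#' @return a `run_plan`: list with `k_train`, `k_tests`,
#'   `intraspecies_networks` and named `interspecies_networks`.
#' @export
enumerate_run_plan <- function(k_train, k_tests = integer()) {
  ks <- c(k_train, k_tests)
  if (any(ks < 2L)) stop("all fold counts must be >= 2")
  structure(list(k_train = as.integer(k_train),
                 k_tests = as.integer(k_tests) |>
                   stats::setNames(names(k_tests)),
                 intraspecies_networks = as.integer(k_train),
                 interspecies_networks =
                   as.integer(k_train * k_tests) |>
                   stats::setNames(names(k_tests))),
            class = "run_plan")
}

#' Full network-count grid across training species
#'
#' Entry `[i, j]` is the number of networks built for species `j` when
#' training on species `i`: `k_i` on the diagonal (intraspecies
#' fold-networks) and `k_i * k_j` off it (interspecies re-optimizations).
#'
#' @param folds named integer vector of per-species fold counts.
#' @return integer matrix, training species in rows.
#' @export
run_plan_grid <- function(folds) {
  if (is.null(names(folds))) names(folds) <- paste0("species", seq_along(folds))
  if (any(folds < 2L)) stop("all fold counts must be >= 2")
  n <- length(folds)
  g <- outer(as.integer(folds), as.integer(folds))
  diag(g) <- as.integer(folds)
  storage.mode(g) <- "integer"
  dimnames(g) <- list(train = names(folds), network = names(folds))
  g
}

#' Compare disease-module gene sets through the full pipeline
#'
#' Runs the complete train / translate / evaluate loop once per gene-set
#' variant (e.g. the disease module vs random genes vs a structurally
#' related pathway) under identical seeds and reports the pooled class
#' metrics and SSE per variant.
#'
#' @param datasets named list of per-species transcript-level
#'   [expression_dataset()]s.
#' @param train_species species to train on.
#' @param variants named list of gene-id vectors defining each variant.
#' @param orthology an [orthology_map()].
#' @param folds named integer vector of per-species fold counts.
#' @param config run configuration, see [dandelion_run()].
#' @param variant `"exhaustive"` or `"naive"`.
#' @return named list of per-variant summaries (`metrics`, `class_sse`,
#'   `run`).
#' @export
compare_gene_sets <- function(datasets, train_species, variants, orthology,
                              folds, config = run_config(),
                              variant = "exhaustive") {
  lapply(variants, function(genes) {
    sub <- lapply(datasets, function(d) {
      keep <- intersect(genes, dataset_genes(d))
      subset_genes(d, keep)
    })
    run <- dandelion_run(sub, train_species, orthology, folds,
                         config = config, variant = variant)
    list(metrics = run$pooled_metrics,
         class_sse = run$mean_class_sse,
         run = run)
  })
}

# pooled confusion over a list of fold results
pool_metrics <- function(results) {
  cm <- vapply(results, function(r)
    c(r$metrics$tp, r$metrics$fp, r$metrics$tn, r$metrics$fn), numeric(4))
  tot <- rowSums(cm)
  pooled <- class_metrics(tot[1L], tot[2L], tot[3L], tot[4L])
  pooled$mean_accuracy <-
    mean(vapply(results, function(r) r$metrics$accuracy, numeric(1)))
  pooled$mean_class_sse <-
    mean(vapply(results, function(r) r$metrics$class_sse, numeric(1)))
  pooled$sd_class_sse <-
    stats::sd(vapply(results, function(r) r$metrics$class_sse, numeric(1)))
  pooled
}
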