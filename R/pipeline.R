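# End-to-end driver: intraspecies training, interspecies translation,
# confidence counting, consensus and disease-domain extraction.

#' Run configuration
#'
#' Bundles the published run constants: annealing temperatures 10 -> 0.001,
#' 1000 proposals for intraspecies training, 500 during interspecies
#' translation, and a default consensus confidence threshold of 0.1.
#'
#' @param t0,tn annealing temperature endpoints.
#' @param maxfc_train,maxfc_test proposal budgets for training and
#'   translation searches.
#' @param threshold consensus confidence threshold.
#' @param seed master seed; all per-fold seeds derive from it.
#' @param condition_on_class condition expression prediction on the
#'   observed class label (default: marginalize the class node).
#' @return a `run_config` list.
#' @export
run_config <- function(t0 = 10, tn = 0.001, maxfc_train = 1000L,
                       maxfc_test = 500L, threshold = 0.1, seed = 1L,
                       condition_on_class = FALSE) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  structure(list(t0 = t0, tn = tn, maxfc_train = as.integer(maxfc_train),
                 maxfc_test = as.integer(maxfc_test),
                 threshold = threshold, seed = as.integer(seed),
                 condition_on_class = condition_on_class),
            class = "run_config")
}

#' Train, translate and integrate disease networks across species
#'
#' The complete procedure: (1) learn one intraspecies network per
#' cross-validation fold of the training species; (2) collapse each to a
#' gene-level network map and translate it through ortholog groups to every
#' test species, re-optimizing on each of that species' folds (so a test
#' species with `k_test` folds yields `k_train * k_test` interspecies
#' networks); (3) count link occurrences per species and form the consensus
#' of links whose confidence passes the threshold in every species;
#' (4) extract the Markov-blanket disease domain around the class node.
#'
#' @param datasets named list of standardized per-species
#'   [expression_dataset()]s (transcript level for the exhaustive variant;
#'   the naive variant averages transcripts per gene first).
#' @param train_species name of the training species.
#' @param orthology an [orthology_map()] covering all species.
#' @param folds named integer vector of per-species fold counts, or a named
#'   list of [make_folds()] plans.
#' @param config a [run_config()].
#' @param variant `"exhaustive"` or `"naive"`.
#' @return a `dandelion_run` list: `intraspecies` (per-fold results),
#'   `maps`, `interspecies` (per test species), `confidence` table,
#'   `consensus`, `domain`, `translatability`, `pooled_metrics`, plus
#'   bookkeeping fields.
#' @export
dandelion_run <- function(datasets, train_species, orthology, folds,
                          config = run_config(),
                          variant = c("exhaustive", "naive")) {
  variant <- match.arg(variant)
  if (!train_species %in% names(datasets))
    stop("unknown training species: ", train_species)
  if (variant == "naive")
    datasets <- lapply(datasets, function(d)
      if (d$level == "transcript") naive_summarize(d) else d)
  species <- names(datasets)
  test_species <- setdiff(species, train_species)

  fold_plans <- if (is.list(folds)) folds else
    lapply(stats::setNames(species, species), function(sp)
      make_folds(datasets[[sp]], folds[[sp]], seed = config$seed))

  log_info("training on %s (%d folds), variant=%s",
           train_species, fold_plans[[train_species]]$k, variant)
  intra <- run_intraspecies(
    datasets[[train_species]], fold_plans[[train_species]],
    anneal_config(config$t0, config$tn, config$maxfc_train,
                  mode = "train", seed = config$seed))
  maps <- lapply(intra, function(r)
    collapse_to_gene_map(r$structure,
                         datasets[[train_species]]$feature_to_gene,
                         source_species = train_species))

  inter <- lapply(stats::setNames(test_species, test_species), function(sp) {
    log_info("translating to %s", sp)
    res <- lapply(seq_along(maps), function(i)
      translate_and_test(
        maps[[i]], datasets[[sp]], fold_plans[[sp]], orthology,
        config = anneal_config(config$t0, config$tn, config$maxfc_test,
                               mode = "test",
                               seed = config$seed + 101L * i +
                                 7919L * match(sp, species)),
        variant = variant, source_species = train_species))
    unlist(res, recursive = FALSE)
  })

  structures <- c(
    stats::setNames(list(lapply(intra, `[[`, "structure")), train_species),
    lapply(inter, function(rs) lapply(rs, `[[`, "structure")))
  feature_maps <- lapply(datasets, `[[`, "feature_to_gene")
  conf_table <- count_links(structures, feature_maps, orthology)

  cons <- consensus(conf_table, config$threshold)
  intra_table <- count_links(structures[train_species],
                             feature_maps[train_species], orthology)
  trained_links <- consensus(intra_table, config$threshold,
                             species_scope = train_species)
  transl <- if (nrow(trained_links))
    translatability(trained_links, conf_table, config$threshold)
  else NULL

  best_fold <- which.max(vapply(intra, function(r) r$score$total_bic,
                                numeric(1)))
  domain <- extract_domain(cons, intra[[best_fold]]$structure,
                           datasets[[train_species]]$feature_to_gene,
                           orthology = orthology, species = train_species)

  all_results <- c(intra, unlist(unname(inter), recursive = FALSE))
  pooled <- pool_metrics(all_results)

  structure(list(variant = variant, train_species = train_species,
                 config = config, fold_plans = fold_plans,
                 intraspecies = intra, maps = maps, interspecies = inter,
                 confidence = conf_table, consensus = cons,
                 trained_links = trained_links,
                 translatability = transl, domain = domain,
                 pooled_metrics = pooled,
                 mean_class_sse = pooled$mean_class_sse,
                 best_training_fold = best_fold),
            class = "dandelion_run")
}

#' @export
print.dandelion_run <- function(x, ...) {
  cat(sprintf("<dandelion_run> %s variant trained on %s\n",
              x$variant, x$train_species))
  cat(sprintf("  consensus links (tau=%.2f): %d; domain genes: %d\n",
              x$config$threshold, nrow(x$consensus), length(x$domain$genes)))
  cat(sprintf("  pooled accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
              x$pooled_metrics$accuracy, x$pooled_metrics$sensitivity,
              x$pooled_metrics$specificity))
  invisible(x)
}
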