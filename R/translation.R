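# Interspecies translation: collapse transcript-level structures to
# gene-level network maps, push maps through ortholog groups, and re-learn
# constrained networks on the target species (naive and exhaustive variants).

#' Gene-level network map
#'
#' The direction-free set of gene-level links distilled from a
#' transcript-level structure; the unit that crosses species.  Links are
#' unordered gene-gene or class-gene pairs; `provenance` counts the
#' supporting transcript-level edges.
#'
#' @param links data frame with columns `gene_a`, `gene_b` and optionally
#'   `provenance` (default 1 each).
#' @param source_species species label the map was learned in.
#' @return a `network_map` (a data frame with canonicalized pair order).
#' @export
network_map <- function(links, source_species = NA_character_) {
  if (is.matrix(links)) links <- as.data.frame(links)
  if (nrow(links) == 0L) {
    out <- data.frame(gene_a = character(), gene_b = character(),
                      provenance = integer())
    return(structure(out, class = c("network_map", "data.frame"),
                     source_species = source_species))
  }
  if (is.null(links$provenance)) links$provenance <- 1L
  if (any(links$gene_a == links$gene_b))
    stop("self-pairs are not allowed in a network map")
  sp <- sort_pair(as.character(links$gene_a), as.character(links$gene_b))
  out <- stats::aggregate(list(provenance = links$provenance),
                          by = list(gene_a = sp[, 1L], gene_b = sp[, 2L]),
                          FUN = sum)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("network_map", "data.frame"),
            source_species = source_species)
}

map_keys <- function(map) {
  if (nrow(map) == 0L) character() else pair_key(map$gene_a, map$gene_b)
}

#' Collapse a transcript-level structure to a gene-level network map
#'
#' Every transcript edge becomes the unordered pair of its endpoints' genes
#' (the class node maps to itself); duplicate pairs merge with a provenance
#' count and edges between transcripts of the same gene are dropped, since
#' they cannot be expressed as gene-gene relationships.
#'
#' @param structure a [dag_structure()].
#' @param feature_to_gene named feature-to-gene map covering every node.
#' @param source_species optional species tag for the map.
#' @return a [network_map()].
#' @export
collapse_to_gene_map <- function(structure, feature_to_gene,
                                 source_species = NA_character_) {
  e <- structure$edges
  if (nrow(e) == 0L)
    return(network_map(data.frame(gene_a = character(),
                                  gene_b = character()),
                       source_species))
  ga <- node_gene(e[, 1L], feature_to_gene)
  gb <- node_gene(e[, 2L], feature_to_gene)
  keep <- ga != gb
  network_map(data.frame(gene_a = ga[keep], gene_b = gb[keep]),
              source_species)
}

#' Cross-species orthology map
#'
#' Long-format table of (species, gene, ortholog group) rows; a gene may
#' belong to several groups and groups may be one-to-many within a species.
#'
#' @param rows data frame with columns `species_id`, `gene_id`, `group_id`.
#' @return an `orthology_map`.
#' @export
orthology_map <- function(rows) {
  need <- c("species_id", "gene_id", "group_id")
  if (!all(need %in% names(rows)))
    stop("orthology rows need columns: ", paste(need, collapse = ", "))
  rows <- unique(rows[need])
  rownames(rows) <- NULL
  structure(rows, class = c("orthology_map", "data.frame"))
}

ortho_groups_of <- function(orthology, species, genes) {
  sub <- orthology[orthology$species_id == species, ]
  split(sub$group_id, sub$gene_id)[genes] |> stats::setNames(genes)
}

ortho_members_of <- function(orthology, species, groups) {
  sub <- orthology[orthology$species_id == species &
                     orthology$group_id %in% groups, ]
  unique(sub$gene_id)
}

#' Map a network map into a target species through ortholog groups
#'
#' Each link `{A, B}` expands to every pair `{A', B'}` of target-species
#' members of A's and B's ortholog groups (one-to-many orthology expands to
#' all combinations; no one-to-one mapping is forced).  Class-gene links map
#' the gene side only.  Links touching a gene with no target ortholog are
#' dropped and reported in the `dropped` attribute.
#'
#' @param map a [network_map()] in the source species' gene ids.
#' @param orthology an [orthology_map()] covering source and target species.
#' @param source_species,target_species species labels.
#' @return a [candidate_edge_set()] over target-species gene ids, with
#'   attribute `dropped` listing untranslatable source links.
#' @export
map_via_orthology <- function(map, orthology, source_species,
                              target_species) {
  if (nrow(map) == 0L) {
    out <- candidate_edge_set(matrix(character(), ncol = 2L))
    attr(out, "dropped") <- map
    return(out)
  }
  genes <- setdiff(unique(c(map$gene_a, map$gene_b)), CLASS_NODE)
  src_groups <- ortho_groups_of(orthology, source_species, genes)
  targets <- lapply(src_groups, function(gr) {
    if (is.null(gr)) character()
    else ortho_members_of(orthology, target_species, gr)
  })
  targets[[CLASS_NODE]] <- CLASS_NODE
  pairs <- vector("list", nrow(map))
  dropped <- logical(nrow(map))
  for (i in seq_len(nrow(map))) {
    ta <- targets[[map$gene_a[i]]]
    tb <- targets[[map$gene_b[i]]]
    if (length(ta) == 0L || length(tb) == 0L) { dropped[i] <- TRUE; next }
    g <- expand.grid(a = ta, b = tb, stringsAsFactors = FALSE)
    g <- g[g$a != g$b, , drop = FALSE]
    if (nrow(g) == 0L) { dropped[i] <- TRUE; next }
    pairs[[i]] <- as.matrix(g)
  }
  pm <- do.call(rbind, pairs)
  if (is.null(pm)) pm <- matrix(character(), ncol = 2L)
  out <- candidate_edge_set(pm)
  attr(out, "dropped") <- map[dropped, , drop = FALSE]
  if (nrow(attr(out, "dropped")))
    log_info("orthology translation dropped %d of %d links",
             sum(dropped), nrow(map))
  out
}

#' Average transcript profiles per gene (the naive variant's input)
#'
#' Summarizes a transcript-level dataset to one expression profile per gene
#' by the per-sample arithmetic mean of the gene's transcripts, then
#' re-standardizes.  Anti-correlated isoforms can average to a constant
#' profile, in which case re-standardization raises an error -- the
#' information loss this variant is prone to.
#'
#' @param dataset a transcript-level [expression_dataset()].
#' @return a gene-level `expression_dataset`.
#' @export
naive_summarize <- function(dataset) {
  if (dataset$level != "transcript")
    stop("naive_summarize expects a transcript-level dataset")
  genes <- unique(unname(dataset$feature_to_gene))
  m <- vapply(genes, function(g) {
    cols <- dataset$feature_ids[dataset$feature_to_gene == g]
    rowMeans(dataset$values[, cols, drop = FALSE])
  }, numeric(nrow(dataset$values)))
  dimnames(m) <- list(dataset$sample_ids, genes)
  standardize(expression_dataset(
    m, dataset$class_labels, stats::setNames(genes, genes),
    species_id = dataset$species_id, level = "gene",
    sample_ids = dataset$sample_ids))
}

#' Translate a network map into a target species and test it fold-wise
#'
#' For every cross-validation fold of the target species the search is run
#' in test mode (default budget 500 proposals) on the fold's training
#' portion, constrained to the orthology-mapped candidate pairs; in the
#' exhaustive variant the candidates are gene-level but may be instantiated
#' by any transcript pair of the admissible genes (model-driven transcript
#' selection), while the naive variant requires gene-level target data.
#' Each learned structure is then evaluated on the fold's held-out samples.
#'
#' @param map a [network_map()] learned in the training species.
#' @param target_data the target species' [expression_dataset()]
#'   (gene-level for `variant = "naive"`, transcript-level for
#'   `"exhaustive"`).
#' @param target_folds a fold plan from [make_folds()].
#' @param orthology an [orthology_map()].
#' @param config an [anneal_config()]; `mode` is forced to `"test"`.
#' @param variant `"naive"` or `"exhaustive"`.
#' @param source_species training species id (defaults to the map's tag).
#' @return list with one element per fold: `fold`, `structure`, `score`,
#'   `metrics` (see [evaluate_network()]), plus attribute `candidates`.
#' @export
translate_and_test <- function(map, target_data, target_folds, orthology,
                               config = anneal_config(maxfc = 500L,
                                                      mode = "test"),
                               variant = c("exhaustive", "naive"),
                               source_species = attr(map, "source_species")) {
  variant <- match.arg(variant)
  if (variant == "naive" && target_data$level != "gene")
    stop("the naive variant requires gene-level target data (naive_summarize first)")
  candidates <- map_via_orthology(map, orthology, source_species,
                                  target_data$species_id)
  empty <- length(candidates$keys) == 0L
  if (empty)
    warning("empty candidate set after orthology mapping; returning prior-only networks")
  out <- lapply(seq_len(target_folds$k), function(f) {
    train <- subset_samples(target_data, target_folds$assignment != f)
    test <- subset_samples(target_data, target_folds$assignment == f)
    cfg <- anneal_config(t0 = config$t0, tn = config$tn,
                         maxfc = config$maxfc, mode = "test",
                         seed = config$seed + f)
    res <- anneal(train, cfg, candidates)
    list(fold = f, structure = res$structure, score = res$score,
         metrics = evaluate_network(res$structure, train, test),
         flagged = empty)
  })
  attr(out, "candidates") <- candidates
  out
}
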