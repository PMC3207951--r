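# Link-occurrence counting across fold-networks and species, confidence
# scores, consensus thresholding, translatability and robustness profiles.

# Gene-level (or ortholog-group-level) link keys found in one structure.
# A link is "found" when any edge, in either direction, projects onto the
# pair; parallel transcript instantiations count once per structure.
structure_link_keys <- function(structure, feature_to_gene,
                                gene_to_groups = NULL) {
  e <- structure$edges
  if (nrow(e) == 0L) return(character())
  ga <- node_gene(e[, 1L], feature_to_gene)
  gb <- node_gene(e[, 2L], feature_to_gene)
  keep <- ga != gb
  ga <- ga[keep]; gb <- gb[keep]
  if (!is.null(gene_to_groups)) {
    expand <- function(g) if (g == CLASS_NODE) CLASS_NODE
                          else gene_to_groups[[g]] %||% character()
    keys <- unlist(lapply(seq_along(ga), function(i) {
      a <- expand(ga[i]); b <- expand(gb[i])
      if (length(a) == 0L || length(b) == 0L) return(character())
      p <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
      p <- p[p$a != p$b, , drop = FALSE]
      pair_key(p$a, p$b)
    }))
  } else {
    keys <- pair_key(ga, gb)
  }
  unique(keys)
}

#' Count link occurrences across fold-networks per species
#'
#' For every gene-level link, counts in how many of each species' networks
#' it appears (in either direction, at most once per structure) and derives
#' the confidence score: the ratio of the found count to the maximum number
#' of times the link could have been found given the run plan.  When an
#' orthology map is supplied, links are keyed by ortholog-group pairs so
#' that counts are comparable across species; otherwise gene ids are taken
#' to be shared already.
#'
#' @param structures_by_species named list (species -> list of
#'   [dag_structure()]s).
#' @param feature_maps named list (species -> feature-to-gene map).
#' @param orthology optional [orthology_map()] used to project each
#'   species' genes onto ortholog groups.
#' @param max_counts named integer vector of the maximum network count per
#'   species (defaults to the number of structures supplied, which matches
#'   the run plan when all fold-networks are passed).
#' @return a `confidence_table`: data frame with `gene_a`, `gene_b` and,
#'   per species, `found_<sp>`, `max_<sp>`, `confidence_<sp>` columns.
#' @export
count_links <- function(structures_by_species, feature_maps,
                        orthology = NULL, max_counts = NULL) {
  species <- names(structures_by_species)
  counts <- lapply(species, function(sp) {
    g2g <- if (!is.null(orthology)) {
      sub <- orthology[orthology$species_id == sp, ]
      split(sub$group_id, sub$gene_id)
    } else NULL
    keys <- unlist(lapply(structures_by_species[[sp]],
                          structure_link_keys,
                          feature_to_gene = feature_maps[[sp]],
                          gene_to_groups = g2g))
    table(keys)
  })
  names(counts) <- species
  all_keys <- sort(unique(unlist(lapply(counts, names))))
  pairs <- split_pair_key(all_keys)
  tab <- data.frame(gene_a = if (length(all_keys)) pairs[, 1L] else character(),
                    gene_b = if (length(all_keys)) pairs[, 2L] else character())
  for (sp in species) {
    found <- integer(length(all_keys))
    hit <- match(names(counts[[sp]]), all_keys)
    found[hit] <- as.integer(counts[[sp]])
    mx <- if (!is.null(max_counts)) max_counts[[sp]]
          else length(structures_by_species[[sp]])
    tab[[paste0("found_", sp)]] <- found
    tab[[paste0("max_", sp)]] <- rep(as.integer(mx), nrow(tab))
    tab[[paste0("confidence_", sp)]] <- found / mx
  }
  structure(tab, class = c("confidence_table", "data.frame"),
            species = species)
}

confidence_matrix <- function(table, species = attr(table, "species")) {
  m <- as.matrix(as.data.frame(table)[paste0("confidence_", species)])
  colnames(m) <- species
  m
}

#' Consensus network at a confidence threshold
#'
#' Keeps links whose confidence reaches the threshold in every species in
#' scope -- the all-species intersection rule that makes the thresholds
#' stringent.
#'
#' @param table a [count_links()] confidence table.
#' @param threshold confidence threshold in `[0, 1]`.
#' @param species_scope species that must all reach the threshold;
#'   defaults to every species in the table.
#' @return a [network_map()] of surviving links (provenance = total found
#'   count over the scope), with the scope confidences kept in attribute
#'   `confidence`.
#' @export
consensus <- function(table, threshold,
                      species_scope = attr(table, "species")) {
  if (threshold < 0) stop("threshold must be >= 0")
  cm <- confidence_matrix(table, species_scope)
  keep <- if (nrow(table) == 0L) logical() else
    apply(cm >= threshold, 1L, all)
  kept <- as.data.frame(table)[keep, , drop = FALSE]
  prov <- if (nrow(kept)) {
    rowSums(as.matrix(kept[paste0("found_", species_scope)]))
  } else integer()
  out <- network_map(data.frame(gene_a = kept$gene_a, gene_b = kept$gene_b,
                                provenance = as.integer(prov)))
  conf <- kept[c("gene_a", "gene_b", paste0("confidence_", species_scope))]
  rownames(conf) <- NULL
  attr(out, "confidence") <- conf
  attr(out, "threshold") <- threshold
  out
}

#' Translatability of trained links into other species
#'
#' Fraction of the training species' links that reappear with at least the
#' given confidence in each species.
#'
#' @param trained_links a [network_map()] of links found during training
#'   (e.g. the training species' intraspecies consensus).
#' @param table a [count_links()] confidence table over the full run.
#' @param threshold confidence threshold.
#' @param species species to report; defaults to all in the table.
#' @return named numeric vector of fractions in `[0, 1]`.
#' @export
translatability <- function(trained_links, table, threshold,
                            species = attr(table, "species")) {
  if (nrow(trained_links) == 0L)
    stop("translatability is undefined for an empty trained link set")
  keys <- map_keys(trained_links)
  tab_keys <- if (nrow(table)) pair_key(table$gene_a, table$gene_b)
              else character()
  idx <- match(keys, tab_keys)
  vapply(species, function(sp) {
    conf <- rep(0, length(keys))
    hit <- !is.na(idx)
    conf[hit] <- table[[paste0("confidence_", sp)]][idx[hit]]
    mean(conf >= threshold)
  }, numeric(1))
}

#' Robustness profile: module vs random link survival across thresholds
#'
#' For each threshold, counts the surviving links (all-species rule over
#' the scope) that touch at least one disease-module gene versus those
#' incident only to random control genes; class-gene links are classified
#' by their gene endpoint.
#'
#' @param table a [count_links()] confidence table.
#' @param gene_sets a [gene_set_spec()] in the table's gene id space.
#' @param thresholds numeric vector of confidence thresholds.
#' @param species_scope species whose confidence must all pass.
#' @return data frame with columns `threshold`, `module_links`,
#'   `random_links`.
#' @export
robustness_profile <- function(table, gene_sets, thresholds,
                               species_scope = attr(table, "species")) {
  cm <- confidence_matrix(table, species_scope)
  genes_of_row <- function(i) setdiff(c(table$gene_a[i], table$gene_b[i]),
                                      CLASS_NODE)
  classify <- vapply(seq_len(nrow(table)), function(i) {
    g <- genes_of_row(i)
    if (any(g %in% gene_sets$module_genes)) "module"
    else if (length(g) && all(g %in% gene_sets$random_genes)) "random"
    else "other"
  }, character(1))
  do.call(rbind, lapply(thresholds, function(tau) {
    keep <- if (nrow(table) == 0L) logical() else
      apply(cm >= tau, 1L, all)
    data.frame(threshold = tau,
               module_links = sum(keep & classify == "module"),
               random_links = sum(keep & classify == "random"))
  }))
}
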