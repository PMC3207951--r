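# Markov-blanket extraction of the disease domain from the thresholded
# consensus network.

#' Markov blanket of a node in a DAG
#'
#' Parents, children, and the children's other parents (spouses).  Under
#' the class-as-root restriction of the CLG model, the blanket of the class
#' node reduces to its children plus their co-parents.
#'
#' @param structure a [dag_structure()].
#' @param node node name (default: the class node).
#' @return character vector of blanket nodes.
#' @export
markov_blanket <- function(structure, node = CLASS_NODE) {
  if (!node %in% structure$nodes) stop("unknown node: ", node)
  pa <- parents_of(structure, node)
  ch <- children_of(structure, node)
  spouses <- unlist(lapply(ch, function(c0) parents_of(structure, c0)))
  setdiff(unique(c(pa, ch, spouses)), node)
}

#' Extract the interspecies disease domain
#'
#' The disease domain is the Markov blanket of the class node, read off a
#' representative directed structure (the undirected consensus carries no
#' orientations; by default the highest-BIC intraspecies fold-network of
#' the training species is used), intersected with the thresholded
#' consensus links: only blanket genes whose links survive the confidence
#' threshold in every species remain.
#'
#' @param consensus a [consensus()] network map (links in the shared
#'   gene/ortholog-group space).
#' @param representative_structure a directed [dag_structure()] supplying
#'   the blanket orientation.
#' @param feature_to_gene feature-to-gene map for the representative
#'   structure's nodes.
#' @param orthology optional [orthology_map()]; with `species`, projects
#'   the representative structure's genes onto ortholog groups.
#' @param species species id of the representative structure.
#' @return a `disease_domain`: list with `genes`, `links` (a
#'   [network_map()] with the consensus confidence annotation) and
#'   `blanket` (the unpruned blanket in the shared space).
#' @export
extract_domain <- function(consensus, representative_structure,
                           feature_to_gene = NULL, orthology = NULL,
                           species = NULL) {
  if (is.null(feature_to_gene)) {
    nd <- representative_structure$nodes
    feature_to_gene <- stats::setNames(nd, nd)
  }
  blanket_feats <- markov_blanket(representative_structure, CLASS_NODE)
  blanket_genes <- unique(node_gene(blanket_feats, feature_to_gene))
  if (!is.null(orthology) && !is.null(species)) {
    sub <- orthology[orthology$species_id == species &
                       orthology$gene_id %in% blanket_genes, ]
    blanket_genes <- unique(sub$group_id)
  }
  scope <- c(CLASS_NODE, blanket_genes)
  keep <- consensus$gene_a %in% scope & consensus$gene_b %in% scope
  links <- network_map(as.data.frame(consensus)[keep, , drop = FALSE])
  conf <- attr(consensus, "confidence")
  if (!is.null(conf)) {
    ck <- pair_key(conf$gene_a, conf$gene_b)
    attr(links, "confidence") <- conf[ck %in% map_keys(links), , drop = FALSE]
  }
  genes <- setdiff(unique(c(links$gene_a, links$gene_b)), CLASS_NODE)
  if (length(genes) == 0L)
    warning("class node is isolated at this threshold; empty disease domain")
  structure(list(genes = genes, links = links, blanket = blanket_genes),
            class = "disease_domain")
}

#' @export
print.disease_domain <- function(x, ...) {
  cat(sprintf("<disease_domain> %d genes, %d links (blanket of %d genes before pruning)\n",
              length(x$genes), nrow(x$links), length(x$blanket)))
  invisible(x)
}
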