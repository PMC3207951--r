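# Ground-truth generator: multiple species sharing a disease network, with
# transcript-isoform heterogeneity, orthology dropout and species-private
# spurious structure, so every pipeline stage is testable without external
# downloads.

#' Per-species generative settings
#'
#' @param n_samples samples to draw.
#' @param class_balance fraction of disease samples (the exact count is
#'   `round(n_samples * class_balance)`, so small designs stay evaluable).
#' @param transcripts_per_gene single integer, or a named integer vector of
#'   per-gene counts (unnamed default taken from the unnamed element or 1).
#' @param fidelity correlation of each transcript with its gene's signal,
#'   indexed by transcript rank and recycled (`c(1, 0.3)` gives every
#'   second isoform fidelity 0.3).
#' @param ortholog_dropout probability that a gene is missing from this
#'   species' orthology rows.
#' @param n_spurious_edges count of species-private confounding gene-gene
#'   edges added to the generative model.
#' @param quantile_normalize apply quantile normalization to the sampled
#'   transcript matrix (disable to keep transcripts exactly affine in the
#'   gene signals).
#' @return a `species_spec` list.
#' @export
species_spec <- function(n_samples = 40L, class_balance = 0.5,
                         transcripts_per_gene = 1L, fidelity = 1,
                         ortholog_dropout = 0, n_spurious_edges = 0L,
                         quantile_normalize = TRUE) {
  if (ortholog_dropout < 0 || ortholog_dropout >= 1)
    stop("ortholog_dropout must be in [0, 1)")
  if (any(fidelity <= 0 | fidelity > 1))
    stop("fidelity must be in (0, 1]")
  structure(list(n_samples = as.integer(n_samples),
                 class_balance = class_balance,
                 transcripts_per_gene = transcripts_per_gene,
                 fidelity = fidelity,
                 ortholog_dropout = ortholog_dropout,
                 n_spurious_edges = as.integer(n_spurious_edges),
                 quantile_normalize = isTRUE(quantile_normalize)),
            class = "species_spec")
}

#' Ground-truth specification
#'
#' Defines the shared disease network: gene count, true weighted gene-gene
#' edges (acyclic), the class-node children with their per-class mean
#' shifts (in residual-sd units), and per-species sampling settings.
#'
#' @param n_genes number of genes (named `g01`, `g02`, ...).
#' @param edges data frame `from`, `to`, `weight` over gene names.
#' @param class_children named numeric vector: gene -> effect size (mean
#'   shift of disease vs control, in units of the gene's residual sd).
#' @param species named list of [species_spec()]s.
#' @param seed master seed; everything derives deterministically from it.
#' @return a `truth_spec`.
#' @export
truth_spec <- function(n_genes, edges = NULL, class_children = numeric(),
                       species = list(), seed = 1L) {
  genes <- sprintf("g%02d", seq_len(n_genes))
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric())
  if (!all(c(edges$from, edges$to) %in% genes))
    stop("edge endpoints must be among the genes")
  if (!all(names(class_children) %in% genes))
    stop("class children must be among the genes")
  if (!all(is.finite(class_children))) stop("effect sizes must be finite")
  em <- cbind(as.character(edges$from), as.character(edges$to))
  if (nrow(em) && !edges_acyclic(genes, em))
    stop("requested true edges contain a cycle")
  structure(list(n_genes = n_genes, genes = genes, edges = edges,
                 class_children = class_children, species = species,
                 seed = as.integer(seed)),
            class = "truth_spec")
}

topo_order <- function(genes, edges) {
  # Kahn order; edges: 2-col matrix
  indeg <- stats::setNames(integer(length(genes)), genes)
  if (nrow(edges)) {
    tab <- table(edges[, 2L])
    indeg[names(tab)] <- as.integer(tab)
  }
  kids <- if (nrow(edges)) split(edges[, 2L], edges[, 1L]) else list()
  queue <- names(indeg)[indeg == 0L]
  out <- character()
  while (length(queue)) {
    n <- queue[[1L]]; queue <- queue[-1L]; out <- c(out, n)
    for (ch in kids[[n]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  out
}

#' Instantiate the ground truth
#'
#' Fixes, per species, the private spurious edges (drawn forward along a
#' topological order of the true graph, so the union stays acyclic), the
#' ortholog-dropout draws and a derived sampling seed.
#'
#' @param spec a [truth_spec()].
#' @return a `truth` object consumed by [sample_species()].
#' @export
generate_truth <- function(spec) {
  genes <- spec$genes
  em <- cbind(as.character(spec$edges$from), as.character(spec$edges$to))
  ord <- topo_order(genes, em)
  true_keys <- if (nrow(em)) pair_key(em[, 1L], em[, 2L]) else character()
  per_species <- with_seed(spec$seed, {
    lapply(stats::setNames(names(spec$species), names(spec$species)),
           function(sp) {
      s <- spec$species[[sp]]
      extra <- NULL
      if (s$n_spurious_edges > 0L) {
        pos <- which(upper.tri(matrix(0, length(ord), length(ord))),
                     arr.ind = TRUE)
        cand <- cbind(ord[pos[, 1L]], ord[pos[, 2L]])
        cand <- cand[!pair_key(cand[, 1L], cand[, 2L]) %in% true_keys, ,
                     drop = FALSE]
        take <- sample(nrow(cand), min(s$n_spurious_edges, nrow(cand)))
        extra <- data.frame(
          from = cand[take, 1L], to = cand[take, 2L],
          weight = stats::runif(length(take), 0.5, 0.9) *
            sample(c(-1, 1), length(take), replace = TRUE))
      }
      dropout <- genes[stats::runif(length(genes)) < s$ortholog_dropout]
      list(spec = s,
           edges = rbind(spec$edges, extra),
           dropout_genes = dropout,
           seed = sample.int(.Machine$integer.max, 1L))
    })
  })
  structure(list(spec = spec, genes = genes, order = ord,
                 per_species = per_species),
            class = "truth")
}

#' Sample one species' transcript-level dataset from the truth
#'
#' Gene signals follow the species' linear system in topological order
#' (`g = sum(w * parents) + effect * class + N(0, 1)`); each gene then
#' expands to its transcripts via
#' `t = fidelity * scale(g) + sqrt(1 - fidelity^2) * noise` (an
#' equicorrelated Gaussian isoform model).  The transcript matrix is
#' quantile-normalized and standardized.  Species gene ids are prefixed
#' (`<species>.<gene>`), and orthology rows link them to shared groups
#' (`og.<gene>`) except for dropout genes.
#'
#' @param truth a [generate_truth()] object.
#' @param species_id one of the truth's species.
#' @return list with `dataset` (an [expression_dataset()]) and `orthology`
#'   (a data frame of orthology rows for this species).
#' @export
sample_species <- function(truth, species_id) {
  info <- truth$per_species[[species_id]]
  if (is.null(info)) stop("unknown species: ", species_id)
  s <- info$spec
  genes <- truth$genes
  eff <- truth$spec$class_children
  edges <- info$edges
  ord <- topo_order(genes, cbind(as.character(edges$from),
                                 as.character(edges$to)))
  n <- s$n_samples
  tpg_setting <- s$transcripts_per_gene
  tpg <- stats::setNames(rep(if (is.null(names(tpg_setting))) tpg_setting[[1L]]
                             else 1L, length(genes)), genes)
  if (!is.null(names(tpg_setting)))
    tpg[names(tpg_setting)] <- tpg_setting
  with_seed(info$seed, {
    n1 <- max(1L, round(n * s$class_balance))
    cls <- sample(rep(c(1L, 0L), c(n1, n - n1)))
    g <- matrix(0, n, length(genes), dimnames = list(NULL, genes))
    for (gn in ord) {
      mu <- numeric(n)
      pa <- edges[edges$to == gn, , drop = FALSE]
      for (j in seq_len(nrow(pa)))
        mu <- mu + pa$weight[j] * g[, pa$from[j]]
      if (gn %in% names(eff)) mu <- mu + eff[[gn]] * cls
      g[, gn] <- mu + stats::rnorm(n)
    }
    cols <- list(); f2g <- character()
    for (gn in genes) {
      gs <- as.numeric(scale(g[, gn]))
      for (t in seq_len(tpg[[gn]])) {
        fid <- s$fidelity[((t - 1L) %% length(s$fidelity)) + 1L]
        x <- if (fid >= 1) gs
             else fid * gs + sqrt(1 - fid^2) * stats::rnorm(n)
        id <- sprintf("%s.%s.t%d", species_id, gn, t)
        cols[[id]] <- x
        f2g[[id]] <- paste(species_id, gn, sep = ".")
      }
    }
    m <- do.call(cbind, cols)
    if (s$quantile_normalize) m <- t(quantile_normalize(t(m)))
    colnames(m) <- names(cols)
    ds <- standardize(expression_dataset(
      m, cls, f2g, species_id = species_id, level = "transcript",
      sample_ids = sprintf("%s.s%02d", species_id, seq_len(n))))
    keep <- setdiff(genes, info$dropout_genes)
    ortho <- data.frame(species_id = species_id,
                        gene_id = paste(species_id, keep, sep = "."),
                        group_id = paste0("og.", keep))
    list(dataset = ds, orthology = ortho)
  })
}

#' Convenience: sample every species and pool the orthology
#'
#' @param truth a [generate_truth()] object.
#' @return list with `datasets` (named list) and `orthology`
#'   (an [orthology_map()]).
#' @export
sample_all_species <- function(truth) {
  sps <- names(truth$per_species)
  out <- lapply(stats::setNames(sps, sps), sample_species, truth = truth)
  list(datasets = lapply(out, `[[`, "dataset"),
       orthology = orthology_map(do.call(rbind,
                                         lapply(out, `[[`, "orthology"))))
}

#' True links in the shared ortholog-group space
#'
#' The ground truth against which learned consensus networks are scored:
#' true gene-gene edges as unordered `og.*` pairs, plus (optionally) the
#' class links to the class children.
#'
#' @param truth a [generate_truth()] object (or a [truth_spec()]).
#' @param include_class include class-gene links for the class children.
#' @return a [network_map()].
#' @export
truth_group_links <- function(truth, include_class = TRUE) {
  spec <- if (inherits(truth, "truth")) truth$spec else truth
  links <- data.frame(gene_a = character(), gene_b = character())
  if (nrow(spec$edges))
    links <- data.frame(gene_a = paste0("og.", spec$edges$from),
                        gene_b = paste0("og.", spec$edges$to))
  if (include_class && length(spec$class_children))
    links <- rbind(links,
                   data.frame(gene_a = CLASS_NODE,
                              gene_b = paste0("og.",
                                              names(spec$class_children))))
  network_map(links)
}
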