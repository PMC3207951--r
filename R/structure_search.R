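# Simulated-annealing search over DAG structures maximizing the BIC, with
# optional gene-level candidate-edge constraints used during interspecies
# translation ("test" mode).

#' Annealing configuration
#'
#' Defaults follow the published run constants: initial temperature 10,
#' final temperature 0.001, and an iteration budget of 1000 proposals for
#' intraspecies training, reduced to 500 during interspecies translation.
#' The cooling schedule is geometric: at proposal `i` the temperature is
#' `t0 * r^i` with `r = (tn/t0)^(1/maxfc)`.
#'
#' @param t0,tn initial and final temperature, `t0 > tn > 0`.
#' @param maxfc number of proposals (the iteration budget).
#' @param mode `"train"` (unconstrained) or `"test"` (candidate-constrained).
#' @param seed integer seed; the search is deterministic given it.
#' @return an `anneal_config`.
#' @export
anneal_config <- function(t0 = 10, tn = 0.001, maxfc = 1000L,
                          mode = c("train", "test"), seed = 1L) {
  mode <- match.arg(mode)
  if (!(t0 > tn && tn > 0)) stop("need t0 > tn > 0")
  maxfc <- as.integer(maxfc)
  if (maxfc < 1L) stop("maxfc must be >= 1")
  structure(list(t0 = t0, tn = tn, maxfc = maxfc, mode = mode,
                 seed = as.integer(seed)),
            class = "anneal_config")
}

#' Candidate edge set constraining the search
#'
#' Unordered gene-level pairs (gene-gene, or class-gene) that the search in
#' test mode may instantiate; a transcript-level edge is admissible when its
#' gene-level projection is among the pairs.  `NULL` means unconstrained
#' (training mode); a zero-row set means no edge is allowed.
#'
#' @param pairs two-column matrix/data frame of gene ids (the class node is
#'   referenced by `"class"`), or `NULL` for unconstrained.
#' @return a `candidate_edge_set` or `NULL`.
#' @export
candidate_edge_set <- function(pairs) {
  if (is.null(pairs)) return(NULL)
  pairs <- as.matrix(pairs)
  storage.mode(pairs) <- "character"
  if (length(pairs) && ncol(pairs) != 2L)
    stop("pairs must have two columns")
  if (length(pairs) == 0L) pairs <- matrix(character(), ncol = 2L)
  if (any(pairs[, 1L] == pairs[, 2L])) stop("self-pairs are not allowed")
  keys <- unique(pair_key(pairs[, 1L], pairs[, 2L]))
  ord <- split_pair_key(keys)
  structure(list(pairs = ord, keys = keys), class = "candidate_edge_set")
}

candidate_allows <- function(candidates, gene_a, gene_b) {
  if (is.null(candidates)) return(rep(TRUE, length(gene_a)))
  pair_key(gene_a, gene_b) %in% candidates$keys
}

# project a node to its gene (class node projects to itself)
node_gene <- function(nodes, feature_to_gene) {
  out <- unname(feature_to_gene[nodes])
  out[nodes == CLASS_NODE] <- CLASS_NODE
  if (anyNA(out))
    stop("unmapped feature(s): ", paste(nodes[is.na(out)], collapse = ", "))
  out
}

# ---- search state ----------------------------------------------------------
# adjacency kept as a logical matrix over nodes; class node has index `ci`.

new_search_state <- function(nodes) {
  p <- length(nodes)
  list(nodes = nodes,
       adj = matrix(FALSE, p, p, dimnames = list(nodes, nodes)))
}

# is there a directed path from `a` to `b`? (BFS over the adjacency matrix)
has_path <- function(adj, a, b) {
  if (a == b) return(TRUE)
  p <- nrow(adj)
  seen <- logical(p); frontier <- a; seen[a] <- TRUE
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    if (length(nxt) == 0L) break
    if (b %in% nxt) return(TRUE)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  FALSE
}

state_edges <- function(state) {
  idx <- which(state$adj, arr.ind = TRUE)
  cbind(from = state$nodes[idx[, 1L]], to = state$nodes[idx[, 2L]])
}

# all ordered (parent, child) slots the constraint admits; child is never
# the class node
allowed_ordered_pairs <- function(nodes, gene_of, candidates) {
  ci <- which(nodes == CLASS_NODE)
  idx <- expand.grid(from = seq_along(nodes), to = seq_along(nodes))
  idx <- idx[idx$from != idx$to & idx$to != ci, , drop = FALSE]
  ok <- candidate_allows(candidates,
                         gene_of[idx$from], gene_of[idx$to]) &
    # a pair projecting onto a single gene is only meaningful unconstrained
    (is.null(candidates) | gene_of[idx$from] != gene_of[idx$to])
  as.matrix(idx[ok, , drop = FALSE])
}

# One proposal: uniform over {add, remove, swap}, then uniform over slots of
# that operator; illegal draws (existing edge, cycle, constraint violation)
# are re-drawn up to `max_attempts` times before the neighborhood is
# declared exhausted (NULL return).
propose_move_state <- function(state, allowed, max_attempts = 50L) {
  adj <- state$adj
  for (attempt in seq_len(max_attempts)) {
    op <- sample(3L, 1L)
    if (op == 1L) {                       # add
      if (nrow(allowed) == 0L) next
      slot <- allowed[sample(nrow(allowed), 1L), ]
      u <- slot[[1L]]; v <- slot[[2L]]
      if (adj[u, v] || adj[v, u]) next
      if (has_path(adj, v, u)) next       # would close a cycle
      return(list(type = "add", u = u, v = v, changed = v))
    }
    edges <- which(adj, arr.ind = TRUE)
    if (nrow(edges) == 0L) next
    e <- edges[sample(nrow(edges), 1L), ]
    u <- e[[1L]]; v <- e[[2L]]
    if (op == 2L) {                       # remove
      return(list(type = "remove", u = u, v = v, changed = v))
    }
    # swap: reverse u -> v; class node may not become a child
    if (state$nodes[u] == CLASS_NODE) next
    adj2 <- adj; adj2[u, v] <- FALSE
    if (has_path(adj2, u, v)) next        # reversal would close a cycle
    return(list(type = "swap", u = u, v = v, changed = c(u, v)))
  }
  NULL
}

apply_move <- function(state, move) {
  if (move$type == "add") state$adj[move$u, move$v] <- TRUE
  else if (move$type == "remove") state$adj[move$u, move$v] <- FALSE
  else { state$adj[move$u, move$v] <- FALSE; state$adj[move$v, move$u] <- TRUE }
  state
}

#' Propose a single neighbor structure
#'
#' Applies one uniformly drawn add / remove / swap (edge reversal) operator,
#' respecting acyclicity, the class-as-root restriction and, when
#' `candidates` is given, the gene-level candidate constraint.
#'
#' @param structure a [dag_structure()].
#' @param candidates a [candidate_edge_set()] or `NULL`.
#' @param feature_to_gene named map used to project nodes onto genes when the
#'   structure is at transcript level; defaults to the identity.
#' @return a neighboring `dag_structure`, or `NULL` when no legal move was
#'   found (exhausted neighborhood).
#' @export
propose_move <- function(structure, candidates = NULL,
                         feature_to_gene = NULL) {
  nodes <- structure$nodes
  if (is.null(feature_to_gene))
    feature_to_gene <- stats::setNames(nodes, nodes)
  gene_of <- node_gene(nodes, feature_to_gene)
  state <- new_search_state(nodes)
  if (nrow(structure$edges))
    state$adj[cbind(match(structure$edges[, 1L], nodes),
                    match(structure$edges[, 2L], nodes))] <- TRUE
  allowed <- allowed_ordered_pairs(nodes, gene_of, candidates)
  move <- propose_move_state(state, allowed)
  if (is.null(move)) return(NULL)
  dag_structure(nodes, state_edges(apply_move(state, move)))
}

# ---- family score with cache ----------------------------------------------

make_family_scorer <- function(data) {
  values <- data$values
  cls <- data$class_labels
  n <- nrow(values)
  logn <- log(n)
  cache <- new.env(parent = emptyenv())
  function(child, parents) {
    key <- paste(child, paste(sort(parents), collapse = ","), sep = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    fam <- fit_family(child, setdiff(parents, CLASS_NODE),
                      CLASS_NODE %in% parents, values, cls, warn = FALSE)
    sc <- family_loglik(fam, child, values, cls) -
      family_param_count(fam) / 2 * logn
    cache[[key]] <- sc
    sc
  }
}

#' Learn a DAG by simulated annealing over the BIC
#'
#' Starts from the empty DAG and performs `maxfc` single-edge proposals
#' (add / remove / swap), accepting improvements always and worsening moves
#' with probability `exp(delta / t_i)` under a geometric cooling schedule.
#' Thanks to BIC decomposability only the families touched by a move are
#' re-scored, with a per-(child, parent set) cache.  The best-scoring
#' structure ever visited is returned, not the final one.
#'
#' @param data a standardized [expression_dataset()].
#' @param config an [anneal_config()].
#' @param candidates a [candidate_edge_set()] (required meaningfully in
#'   `"test"` mode) or `NULL` for unconstrained search.
#' @param keep_trace record the per-iteration score trace.
#' @return list with `structure` (best [dag_structure()]), `score`
#'   (its [bic_score()] report) and `trace` (data frame of iteration,
#'   temperature, current/best score, acceptance flag; `NULL` unless
#'   `keep_trace`).
#' @export
anneal <- function(data, config = anneal_config(), candidates = NULL,
                   keep_trace = FALSE) {
  if (config$mode == "test" && is.null(candidates))
    stop("test mode requires a candidate edge set")
  nodes <- c(data$feature_ids, CLASS_NODE)
  gene_of <- node_gene(nodes, data$feature_to_gene)
  scorer <- make_family_scorer(data)
  state <- new_search_state(nodes)
  allowed <- allowed_ordered_pairs(nodes, gene_of, candidates)

  fam_parents <- function(state, v)
    state$nodes[which(state$adj[, v])]
  current_fam <- vapply(nodes, function(nd) {
    if (nd == CLASS_NODE) {
      n <- nrow(data$values)
      sum(log(c(mean(data$class_labels == 0L),
                mean(data$class_labels == 1L))[data$class_labels + 1L])) -
        0.5 * log(n)
    } else scorer(nd, character())
  }, numeric(1))
  current <- sum(current_fam)
  best <- current
  best_adj <- state$adj
  r <- (config$tn / config$t0)^(1 / config$maxfc)
  trace <- if (keep_trace)
    data.frame(iter = seq_len(config$maxfc), temperature = NA_real_,
               score = NA_real_, best = NA_real_, accepted = NA)
  else NULL

  with_seed(config$seed, {
    temp <- config$t0
    for (i in seq_len(config$maxfc)) {
      temp <- temp * r
      move <- propose_move_state(state, allowed)
      accepted <- FALSE
      if (!is.null(move)) {
        cand_state <- apply_move(state, move)
        ch <- state$nodes[move$changed]
        new_sc <- vapply(ch, function(nd)
          scorer(nd, fam_parents(cand_state, match(nd, nodes))), numeric(1))
        delta <- sum(new_sc) - sum(current_fam[ch])
        if (delta > 0 ||
            (delta < 0 && stats::runif(1L) < exp(delta / temp))) {
          state <- cand_state
          current_fam[ch] <- new_sc
          current <- current + delta
          accepted <- TRUE
          if (current > best) {
            best <- current
            best_adj <- state$adj
          }
        }
      }
      if (keep_trace) {
        trace$temperature[i] <- temp
        trace$score[i] <- current
        trace$best[i] <- best
        trace$accepted[i] <- accepted
      }
    }
  })
  best_state <- state; best_state$adj <- best_adj
  structure_out <- dag_structure(nodes, state_edges(best_state))
  list(structure = structure_out,
       score = bic_score(structure_out, data),
       trace = trace)
}
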