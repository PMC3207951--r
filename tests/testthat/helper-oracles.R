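# Independent oracle implementations used to cross-check the package.
# These deliberately use different algorithms / code paths than R/.

# --- quantile normalization: sort / average-by-rank / unsort ---------------
qn_oracle <- function(m) {
  ref <- rowMeans(apply(m, 2L, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    rk <- rank(m[, j], ties.method = "average")
    lo <- ref[floor(rk)]
    hi <- ref[ceiling(rk)]
    out[, j] <- (lo + hi) / 2
  }
  out
}

# --- per-sample log-likelihood summation -----------------------------------
ll_oracle <- function(network, data) {
  total <- 0
  for (i in seq_len(nrow(data$values))) {
    cls <- as.character(data$class_labels[i])
    total <- total + log(network$class_prior[[cls]])
    for (g in names(network$families)) {
      fam <- network$families[[g]]
      par <- if (fam$class_parent && !fam$pooled) fam$params[[cls]]
             else fam$params[[1L]]
      mu <- par$intercept
      for (p in fam$parents) mu <- mu + par$weights[[p]] * data$values[i, p]
      total <- total + dnorm(data$values[i, g], mu, sqrt(par$sigma2),
                             log = TRUE)
    }
  }
  total
}

# --- joint Gaussian of a fitted CLG by moment recursion --------------------
# mean/covariance built gene by gene in topological order (different route
# than the (I - W)^-1 assembly used by the package)
joint_oracle <- function(network, cls) {
  genes <- names(network$families)
  edges <- network$structure$edges
  gene_edges <- edges[edges[, 1L] != "class", , drop = FALSE]
  ord <- character()
  left <- genes
  while (length(left)) {
    ready <- left[vapply(left, function(g) {
      pa <- gene_edges[gene_edges[, 2L] == g, 1L]
      all(pa %in% ord)
    }, logical(1))]
    ord <- c(ord, ready)
    left <- setdiff(left, ready)
  }
  mu <- setNames(numeric(length(genes)), genes)
  S <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  for (g in ord) {
    fam <- network$families[[g]]
    par <- if (fam$class_parent && !fam$pooled) fam$params[[cls]]
           else fam$params[[1L]]
    pa <- fam$parents
    mu[g] <- par$intercept + sum(par$weights[pa] * mu[pa])
    for (h in genes) {
      if (h == g) next
      S[g, h] <- S[h, g] <- sum(par$weights[pa] * S[pa, h])
    }
    S[g, g] <- par$sigma2 +
      if (length(pa))
        drop(t(par$weights[pa]) %*% S[pa, pa, drop = FALSE] %*%
               par$weights[pa])
      else 0
  }
  list(mu = mu, Sigma = S)
}

# conditional mean of `target` given the others, explicit matrix inversion
predict_expression_oracle <- function(network, data, target) {
  genes <- names(network$families)
  others <- setdiff(genes, target)
  preds <- numeric(nrow(data$values))
  for (i in seq_len(nrow(data$values))) {
    x <- data$values[i, others]
    post <- numeric(2); m <- numeric(2)
    for (j in 1:2) {
      cfg <- c("0", "1")[j]
      jg <- joint_oracle(network, cfg)
      So <- jg$Sigma[others, others, drop = FALSE]
      dens <- exp(-0.5 * t(x - jg$mu[others]) %*% solve(So) %*%
                    (x - jg$mu[others])) /
        sqrt((2 * pi)^length(others) * det(So))
      post[j] <- network$class_prior[[cfg]] * dens
      m[j] <- jg$mu[[target]] +
        drop(jg$Sigma[target, others, drop = FALSE] %*% solve(So) %*%
               (x - jg$mu[others]))
    }
    w <- post / sum(post)
    preds[i] <- sum(w * m)
  }
  preds
}

# --- d-separation via moralized ancestral graphs ---------------------------
# edges: 2-col character matrix; returns TRUE when x and y are d-separated
# given z in the DAG
dsep_oracle <- function(nodes, edges, x, y, z) {
  anc_closure <- function(targets) {
    out <- unique(targets)
    repeat {
      pa <- unique(edges[edges[, 2L] %in% out, 1L])
      new <- setdiff(pa, out)
      if (!length(new)) break
      out <- c(out, new)
    }
    out
  }
  keep <- anc_closure(c(x, y, z))
  e <- edges[edges[, 1L] %in% keep & edges[, 2L] %in% keep, , drop = FALSE]
  # moralize: marry co-parents, drop directions
  undirected <- rbind(e, e[, 2:1, drop = FALSE])
  for (v in keep) {
    pa <- e[e[, 2L] == v, 1L]
    if (length(pa) > 1L) {
      comb <- t(combn(pa, 2L))
      undirected <- rbind(undirected, comb, comb[, 2:1, drop = FALSE])
    }
  }
  # BFS from x avoiding z
  frontier <- x; seen <- c(x, z)
  while (length(frontier)) {
    nxt <- setdiff(unique(undirected[undirected[, 1L] %in% frontier, 2L]),
                   seen)
    if (y %in% nxt) return(FALSE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  TRUE
}

# minimal subset S of V \ {x} rendering x independent of the rest, by
# exhaustive subset search; unique minimum returned (or NULL if ambiguous)
blanket_oracle <- function(nodes, edges, x) {
  others <- setdiff(nodes, x)
  best <- NULL
  for (size in 0:length(others)) {
    subs <- if (size == 0L) list(character()) else
      combn(others, size, simplify = FALSE)
    hits <- Filter(function(s) {
      rest <- setdiff(others, s)
      all(vapply(rest, function(v) dsep_oracle(nodes, edges, x, v, s),
                 logical(1)))
    }, subs)
    if (length(hits)) { best <- hits; break }
  }
  if (length(best) == 1L) best[[1L]] else NULL
}

# random DAG over the given nodes: each forward pair (in a random order)
# becomes an edge with probability p
random_dag_edges <- function(nodes, p = 0.35) {
  ord <- sample(nodes)
  e <- NULL
  for (i in seq_along(ord))
    for (j in seq_len(i - 1L))
      if (runif(1) < p) e <- rbind(e, c(ord[j], ord[i]))
  if (is.null(e)) matrix(character(), ncol = 2L) else e
}

# --- exhaustive enumeration of all DAGs over a small node set --------------
all_dags <- function(nodes) {
  pairs <- t(combn(nodes, 2L))
  n <- nrow(pairs)
  out <- list()
  states <- expand.grid(rep(list(0:2), n))  # 0 none, 1 a->b, 2 b->a
  for (r in seq_len(nrow(states))) {
    st <- as.integer(states[r, ])
    e <- NULL
    for (k in seq_len(n)) {
      if (st[k] == 1L) e <- rbind(e, pairs[k, ])
      if (st[k] == 2L) e <- rbind(e, pairs[k, 2:1])
    }
    s <- tryCatch(dag_structure(nodes, e), error = function(err) NULL)
    if (!is.null(s)) out[[length(out) + 1L]] <- s
  }
  out
}
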