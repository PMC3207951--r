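# Conditional linear Gaussian (CLG) Bayesian network over expression
# features plus one discrete class node: structure container, maximum
# likelihood parameter fitting, log-likelihood, BIC scoring and prediction.

VARIANCE_FLOOR <- 1e-6
RIDGE_LAMBDA <- 1e-6

#' Directed acyclic graph over feature nodes and the class node
#'
#' The class node is always present and, being the only discrete node in a
#' CLG model, may not have parents: links with the disease state are encoded
#' as class-to-gene edges.
#'
#' @param nodes character vector of feature ids (the class node is added
#'   automatically when absent).
#' @param edges two-column character matrix (or data frame) of directed
#'   edges, `from` (parent) to `to` (child).  May have zero rows.
#' @return a `dag_structure`.
#' @export
dag_structure <- function(nodes, edges = NULL) {
  nodes <- unique(as.character(nodes))
  if (!CLASS_NODE %in% nodes) nodes <- c(nodes, CLASS_NODE)
  if (is.null(edges)) {
    edges <- matrix(character(), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    storage.mode(edges) <- "character"
    if (ncol(edges) != 2L) stop("edges must have two columns (from, to)")
  }
  colnames(edges) <- c("from", "to")
  rownames(edges) <- NULL
  if (nrow(edges)) {
    if (!all(c(edges) %in% nodes))
      stop("edge endpoints not in node set: ",
           paste(setdiff(c(edges), nodes), collapse = ", "))
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
    if (anyDuplicated(paste(edges[, 1L], edges[, 2L])))
      stop("duplicate edges are not allowed")
    if (any(edges[, 2L] == CLASS_NODE))
      stop("the class node may not have parents in a CLG model")
    if (!edges_acyclic(nodes, edges)) stop("graph contains a cycle")
  }
  structure(list(nodes = nodes, edges = edges), class = "dag_structure")
}

#' @export
print.dag_structure <- function(x, ...) {
  cat(sprintf("<dag_structure> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# Kahn's algorithm on an edge list
edges_acyclic <- function(nodes, edges) {
  if (nrow(edges) == 0L) return(TRUE)
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(edges[, 2L])
  indeg[names(tab)] <- as.integer(tab)
  kids <- split(edges[, 2L], edges[, 1L])
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    n <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in kids[[n]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  seen == length(nodes)
}

parents_of <- function(structure, node)
  structure$edges[structure$edges[, 2L] == node, 1L]

children_of <- function(structure, node)
  structure$edges[structure$edges[, 1L] == node, 2L]

gene_nodes <- function(structure) setdiff(structure$nodes, CLASS_NODE)

# ---- parameter fitting -----------------------------------------------------

# OLS via normal equations with a ridge fallback on singular designs.
ols_fit <- function(X, y, warn = TRUE) {
  XtX <- crossprod(X)
  coef <- tryCatch(solve(XtX, crossprod(X, y)),
                   error = function(e) NULL)
  if (is.null(coef)) {
    if (warn) warning("singular design matrix; using ridge fallback")
    coef <- solve(XtX + diag(RIDGE_LAMBDA, ncol(X)), crossprod(X, y))
  }
  resid <- y - X %*% coef
  list(coef = drop(coef), rss = sum(resid^2))
}

# Fit one gene-node family.  `parents_cont` are continuous parents;
# `class_parent` says whether the class node is a parent.  Falls back to a
# class-pooled fit when a class stratum is smaller than parents + 2.
fit_family <- function(child, parents_cont, class_parent, values, cls,
                       warn = TRUE) {
  y <- values[, child]
  X <- cbind(`(Intercept)` = 1, values[, parents_cont, drop = FALSE])
  p <- length(parents_cont)
  n <- length(y)
  fit_one <- function(rows) {
    f <- ols_fit(X[rows, , drop = FALSE], y[rows], warn = warn)
    sigma2 <- max(f$rss / length(rows), VARIANCE_FLOOR)
    list(intercept = unname(f$coef[1L]),
         weights = stats::setNames(f$coef[-1L][seq_len(p)], parents_cont),
         sigma2 = sigma2, n = length(rows))
  }
  pooled <- FALSE
  if (class_parent) {
    strata <- split(seq_len(n), cls)
    if (any(vapply(strata, length, 1L) < p + 2L)) {
      if (warn)
        warning(sprintf(
          "family '%s': a class stratum has fewer samples than parents + 2; fitting pooled across classes",
          child))
      pooled <- TRUE
    }
  }
  if (class_parent && !pooled) {
    params <- lapply(strata, fit_one)
    names(params) <- names(strata)
  } else {
    params <- list(pooled = fit_one(seq_len(n)))
  }
  list(parents = parents_cont, class_parent = class_parent,
       pooled = pooled, params = params)
}

family_param_count <- function(fam) {
  per_config <- 2L + length(fam$parents)      # intercept + weights + variance
  nconf <- if (fam$class_parent && !fam$pooled) length(fam$params) else 1L
  per_config * nconf
}

family_loglik <- function(fam, child, values, cls) {
  y <- values[, child]
  X <- cbind(1, values[, fam$parents, drop = FALSE])
  ll <- 0
  if (fam$class_parent && !fam$pooled) {
    for (cfg in names(fam$params)) {
      rows <- which(cls == as.integer(cfg))
      p <- fam$params[[cfg]]
      mu <- drop(X[rows, , drop = FALSE] %*% c(p$intercept, p$weights))
      ll <- ll + sum(stats::dnorm(y[rows], mu, sqrt(p$sigma2), log = TRUE))
    }
  } else {
    p <- fam$params[[1L]]
    mu <- drop(X %*% c(p$intercept, p$weights))
    ll <- ll + sum(stats::dnorm(y, mu, sqrt(p$sigma2), log = TRUE))
  }
  ll
}

#' Fit CLG parameters by maximum likelihood
#'
#' For every gene node, an ordinary-least-squares regression on its
#' continuous parents is fitted per class-parent configuration (residual
#' variance is the MLE, floored at `1e-6`); the class prior is the empirical
#' class frequency.  A class stratum with fewer samples than parents + 2
#' triggers a class-pooled fit for that family, and a singular design
#' triggers a small ridge fallback, each with a warning.
#'
#' @param structure a [dag_structure()].
#' @param data an [expression_dataset()] whose features cover the gene nodes.
#' @param warn emit fallback warnings (disabled inside the structure search).
#' @return a `fitted_network`.
#' @export
fit_parameters <- function(structure, data, warn = TRUE) {
  genes <- gene_nodes(structure)
  missing <- setdiff(genes, data$feature_ids)
  if (length(missing))
    stop("structure nodes absent from data: ", paste(missing, collapse = ", "))
  values <- data$values
  cls <- data$class_labels
  prior <- c(`0` = mean(cls == 0L), `1` = mean(cls == 1L))
  families <- lapply(genes, function(g) {
    pa <- parents_of(structure, g)
    fit_family(g, setdiff(pa, CLASS_NODE), CLASS_NODE %in% pa,
               values, cls, warn = warn)
  })
  names(families) <- genes
  structure(list(structure = structure, class_prior = prior,
                 families = families, n_samples = nrow(values)),
            class = "fitted_network")
}

#' Log-likelihood of a dataset under a fitted network
#'
#' Sum over samples of the log class prior plus each gene node's conditional
#' Gaussian log density.
#'
#' @param network a `fitted_network` from [fit_parameters()].
#' @param data an [expression_dataset()] containing all network features.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(network, data) {
  genes <- names(network$families)
  missing <- setdiff(genes, data$feature_ids)
  if (length(missing))
    stop("unknown feature(s) in network: ", paste(missing, collapse = ", "))
  values <- data$values
  cls <- data$class_labels
  ll <- sum(log(network$class_prior[as.character(cls)]))
  for (g in genes)
    ll <- ll + family_loglik(network$families[[g]], g, values, cls)
  unname(ll)
}

#' BIC score of a structure on a dataset
#'
#' Penalized log-likelihood, higher is better:
#' `logLik(MLE fit) - (n_params / 2) * log(n_samples)`, decomposed into
#' per-node family contributions (each family carries its own penalty
#' share).  Parameter count covers intercepts, regression weights, residual
#' variances and the `n_classes - 1` free prior probabilities.
#'
#' @param structure a [dag_structure()].
#' @param data an [expression_dataset()].
#' @return a `score_report`: list with `total_bic`, named `family_scores`,
#'   `n_params`, `n_samples`.
#' @export
bic_score <- function(structure, data) {
  fitted <- fit_parameters(structure, data, warn = FALSE)
  values <- data$values
  cls <- data$class_labels
  n <- nrow(values)
  logn <- log(n)
  fam_scores <- numeric(0)
  n_params <- 0L
  for (g in names(fitted$families)) {
    fam <- fitted$families[[g]]
    k <- family_param_count(fam)
    fam_scores[[g]] <- family_loglik(fam, g, values, cls) - k / 2 * logn
    n_params <- n_params + k
  }
  k_class <- length(fitted$class_prior) - 1L
  fam_scores[[CLASS_NODE]] <-
    sum(log(fitted$class_prior[as.character(cls)])) - k_class / 2 * logn
  n_params <- n_params + k_class
  structure(list(total_bic = unname(sum(fam_scores)),
                 family_scores = fam_scores,
                 n_params = n_params, n_samples = n),
            class = "score_report")
}

# ---- joint Gaussian assembly and prediction --------------------------------

# Per class state, the CLG implies a joint multivariate normal over the gene
# nodes: x = a_c + W_c x + e, e ~ N(0, D_c), hence
# mu = (I - W)^-1 a and Sigma = (I - W)^-1 D (I - W)^-T.
joint_gaussians <- function(network) {
  genes <- names(network$families)
  p <- length(genes)
  lapply(c("0", "1"), function(cfg) {
    a <- numeric(p); W <- matrix(0, p, p, dimnames = list(genes, genes))
    d <- numeric(p)
    for (i in seq_len(p)) {
      fam <- network$families[[i]]
      par <- if (fam$class_parent && !fam$pooled) fam$params[[cfg]]
             else fam$params[[1L]]
      a[i] <- par$intercept
      if (length(fam$parents)) W[i, fam$parents] <- par$weights
      d[i] <- par$sigma2
    }
    M <- solve(diag(p) - W)
    mu <- drop(M %*% a)
    Sigma <- M %*% (d * t(M))
    names(mu) <- genes
    dimnames(Sigma) <- list(genes, genes)
    list(mu = mu, Sigma = Sigma)
  }) |> stats::setNames(c("0", "1"))
}

# rowwise log density of X (n x p) under N(mu, Sigma); R = chol(Sigma)
mvn_logdens <- function(X, mu, R) {
  p <- length(mu)
  Z <- backsolve(R, t(X) - mu, transpose = TRUE)
  quad <- if (p == 1L) drop(Z)^2 else colSums(Z^2)
  -0.5 * (p * log(2 * pi) + 2 * sum(log(diag(R))) + quad)
}

#' Predict the expression of one gene node from all others
#'
#' The prediction is the posterior mean of the target given every other
#' continuous node, with the class node marginalized: a mixture of the
#' per-class conditional Gaussian means weighted by the class posterior
#' given the other nodes.  Set `condition_on_class = TRUE` to condition on
#' the observed class label instead.
#'
#' @param network a `fitted_network`.
#' @param data an [expression_dataset()] holding the evaluation samples.
#' @param target_node a gene node of the network.
#' @param condition_on_class use the observed class label rather than
#'   marginalizing over it.
#' @return list with `predictions` (one per sample) and `sse`, the summed
#'   squared prediction error.
#' @export
predict_expression <- function(network, data, target_node,
                               condition_on_class = FALSE) {
  genes <- names(network$families)
  if (identical(target_node, CLASS_NODE))
    stop("use predict_class() for the class node")
  if (!target_node %in% genes) stop("unknown target node: ", target_node)
  others <- setdiff(genes, target_node)
  jg <- joint_gaussians(network)
  n <- nrow(data$values)
  Xo <- data$values[, others, drop = FALSE]
  m <- matrix(0, n, 2L); lw <- matrix(0, n, 2L)
  for (j in 1:2) {
    cfg <- c("0", "1")[j]
    g <- jg[[cfg]]
    if (length(others)) {
      Soo <- g$Sigma[others, others, drop = FALSE]
      Sot <- g$Sigma[others, target_node]
      R <- chol(Soo)
      b <- backsolve(R, backsolve(R, Sot, transpose = TRUE))
      centered <- sweep(Xo, 2L, g$mu[others])
      m[, j] <- g$mu[[target_node]] + drop(centered %*% b)
      lw[, j] <- log(network$class_prior[[cfg]]) +
        mvn_logdens(Xo, g$mu[others], R)
    } else {
      m[, j] <- g$mu[[target_node]]
      lw[, j] <- log(network$class_prior[[cfg]])
    }
  }
  if (condition_on_class) {
    w <- cbind(data$class_labels == 0L, data$class_labels == 1L) * 1
  } else {
    w <- exp(lw - apply(lw, 1L, logsumexp))
  }
  pred <- rowSums(w * m)
  obs <- data$values[, target_node]
  list(predictions = stats::setNames(pred, data$sample_ids),
       sse = sum((pred - obs)^2))
}

#' Posterior probability of the disease state given expression evidence
#'
#' The posterior is proportional to the class prior times the per-class
#' joint Gaussian density of the observed gene values; missing entries
#' (`NA`) are marginalized exactly through the joint.
#'
#' @param network a `fitted_network`.
#' @param evidence named numeric vector over the network's gene nodes, or a
#'   samples x genes matrix; `NA` entries are marginalized.
#' @return named probability vector `c("0", "1")` (control, disease), or a
#'   matrix of such rows.
#' @export
predict_class <- function(network, evidence) {
  genes <- names(network$families)
  if (is.matrix(evidence)) {
    out <- t(apply(evidence, 1L, function(r) predict_class(network, r)))
    colnames(out) <- c("0", "1")
    return(out)
  }
  if (length(genes) && is.null(names(evidence)) &&
      length(evidence) == length(genes))
    names(evidence) <- genes
  obs <- intersect(genes, names(evidence)[!is.na(evidence)])
  lp <- log(c(network$class_prior[["0"]], network$class_prior[["1"]]))
  if (length(obs)) {
    jg <- joint_gaussians(network)
    x <- matrix(evidence[obs], nrow = 1L)
    for (j in 1:2) {
      g <- jg[[j]]
      R <- chol(g$Sigma[obs, obs, drop = FALSE])
      lp[j] <- lp[j] + mvn_logdens(x, g$mu[obs], R)
    }
  }
  post <- exp(lp - logsumexp(lp))
  stats::setNames(post / sum(post), c("0", "1"))
}

# ---- serialization ---------------------------------------------------------

#' Serialize a fitted network to JSON
#'
#' Structured, human-readable text holding the edge list, class prior and
#' per-family parameter blocks; [network_from_json()] restores it exactly.
#'
#' @param network a `fitted_network`.
#' @param path file to write; when `NULL` the JSON string is returned.
#' @export
network_to_json <- function(network, path = NULL) {
  obj <- list(
    nodes = network$structure$nodes,
    edges = apply(network$structure$edges, 1L,
                  function(e) list(from = e[[1L]], to = e[[2L]])),
    class_prior = as.list(network$class_prior),
    n_samples = network$n_samples,
    families = lapply(network$families, function(fam) {
      list(parents = fam$parents, class_parent = fam$class_parent,
           pooled = fam$pooled,
           params = lapply(fam$params, function(p)
             list(intercept = p$intercept, weights = as.list(p$weights),
                  sigma2 = p$sigma2, n = p$n)))
    }))
  if (is.null(path))
    return(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a fitted network written by [network_to_json()]
#' @param path file path or a JSON string.
#' @return a `fitted_network`.
#' @export
network_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  edges <- if (length(obj$edges))
    do.call(rbind, lapply(obj$edges, function(e) c(e$from, e$to)))
  else NULL
  families <- lapply(obj$families, function(fam) {
    list(parents = as.character(unlist(fam$parents)),
         class_parent = fam$class_parent, pooled = fam$pooled,
         params = lapply(fam$params, function(p)
           list(intercept = p$intercept,
                weights = unlist(p$weights) %||%
                  stats::setNames(numeric(), character()),
                sigma2 = p$sigma2, n = p$n)))
  })
  structure(list(
    structure = dag_structure(unlist(obj$nodes), edges),
    class_prior = unlist(obj$class_prior),
    families = families, n_samples = obj$n_samples),
    class = "fitted_network")
}
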