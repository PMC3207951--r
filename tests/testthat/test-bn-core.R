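test_that("DAG invariants are enforced", {
  expect_error(dag_structure(c("a", "b"), rbind(c("a", "a"))), "self-loop")
  expect_error(dag_structure(c("a", "b"),
                             rbind(c("a", "b"), c("a", "b"))), "duplicate")
  expect_error(dag_structure(c("a", "b"), rbind(c("a", CLASS_NODE))),
               "class node")
  expect_error(dag_structure(c("a", "b", "c"),
                             rbind(c("a", "b"), c("b", "c"), c("c", "a"))),
               "cycle")
  s <- dag_structure(c("a", "b"), rbind(c(CLASS_NODE, "a"), c("a", "b")))
  expect_setequal(s$nodes, c("a", "b", CLASS_NODE))
})

test_that("parameter fitting recovers the generative model", {
  # parentless node on standardized data
  ds <- noise_dataset(n = 200L, p = 2L, seed = 1L)
  net <- fit_parameters(dag_structure(ds$feature_ids), ds)
  fam <- net$families[["f01"]]
  expect_lt(abs(fam$params[[1L]]$intercept), 1e-9)
  expect_equal(fam$params[[1L]]$sigma2, 1, tolerance = 0.02)

  # B = 0.8 A + e, sd(B) = 1: weight recovered within +/- 0.1 at n = 500
  set.seed(123)
  a <- rnorm(500)
  b <- 0.8 * a + 0.6 * rnorm(500)
  m <- cbind(A = a, B = b)
  dsr <- expression_dataset(m, rep_len(0:1, 500),
                            c(A = "A", B = "B"), species_id = "toy")
  netr <- fit_parameters(dag_structure(c("A", "B"), rbind(c("A", "B"))), dsr)
  expect_equal(unname(netr$families[["B"]]$params[[1L]]$weights[["A"]]),
               0.8, tolerance = 0.1)

  # empirical class prior for 4 disease / 18 control samples
  ds22 <- noise_dataset(n = 22L, p = 2L, seed = 2L)
  ds22$class_labels <- c(rep(1L, 4L), rep(0L, 18L))
  pr <- fit_parameters(dag_structure(ds22$feature_ids), ds22)$class_prior
  expect_equal(unname(pr), c(18, 4) / 22, tolerance = 1e-12)

  # tiny class stratum triggers the pooled fallback, with a warning
  tiny <- noise_dataset(n = 10L, p = 3L, seed = 3L)
  tiny$class_labels <- c(1L, 1L, rep(0L, 8L))
  s <- dag_structure(tiny$feature_ids,
                     rbind(c(CLASS_NODE, "f01"), c("f02", "f01"),
                           c("f03", "f01")))
  expect_warning(net2 <- fit_parameters(s, tiny), "pooled")
  expect_true(net2$families[["f01"]]$pooled)
})

test_that("log-likelihood matches closed form, additivity and the oracle", {
  ds <- noise_dataset(n = 50L, p = 1L, seed = 4L)
  s <- dag_structure(ds$feature_ids)
  net <- fit_parameters(s, ds)
  # class prior part is exact; the Gaussian part hits the MLE identity
  sigma2 <- net$families[["f01"]]$params[[1L]]$sigma2
  n <- 50
  expected_gauss <- -(n / 2) * (log(2 * pi * sigma2) + 1)
  prior_part <- sum(log(net$class_prior[as.character(ds$class_labels)]))
  expect_equal(log_likelihood(net, ds), expected_gauss + prior_part,
               tolerance = 1e-9)

  # duplicating every sample doubles the refitted log-likelihood exactly
  dup <- expression_dataset(rbind(ds$values, ds$values),
                            rep(ds$class_labels, 2L), ds$feature_to_gene,
                            species_id = "dup")
  net_dup <- fit_parameters(s, dup)
  expect_equal(log_likelihood(net_dup, dup), 2 * log_likelihood(net, ds),
               tolerance = 1e-9)

  # three-node fixture vs the per-sample summation oracle
  ds3 <- chain_dataset(n = 40L, seed = 5L)
  s3 <- dag_structure(ds3$feature_ids,
                      rbind(c("A", "B"), c("B", "C"), c(CLASS_NODE, "A")))
  net3 <- fit_parameters(s3, ds3)
  expect_equal(log_likelihood(net3, ds3), ll_oracle(net3, ds3),
               tolerance = 1e-9)

  expect_error(log_likelihood(net3, noise_dataset(p = 2L)), "unknown")
})

test_that("BIC is family-decomposable and matches an lm-based scorer", {
  ds <- chain_dataset(n = 100L, seed = 6L)
  base <- dag_structure(ds$feature_ids, rbind(c("A", "B")))
  plus <- dag_structure(ds$feature_ids, rbind(c("A", "B"), c("B", "C")))
  r0 <- bic_score(base, ds)
  r1 <- bic_score(plus, ds)
  expect_equal(r0$total_bic, sum(r0$family_scores))
  # adding B -> C changes only C's family score, bit-identically elsewhere
  expect_identical(r0$family_scores[c("A", "B", "class")],
                   r1$family_scores[c("A", "B", "class")])
  expect_false(r0$family_scores[["C"]] == r1$family_scores[["C"]])

  # scoring oracle: lm() log-likelihood minus the parameter penalty
  lm_family_score <- function(child, parents, ds) {
    df <- as.data.frame(ds$values)
    f <- if (length(parents))
      reformulate(parents, response = child) else
      stats::as.formula(paste(child, "~ 1"))
    k <- length(parents) + 2L
    as.numeric(logLik(lm(f, df))) - k / 2 * log(nrow(df))
  }
  for (s in list(base, plus)) {
    rep_ <- bic_score(s, ds)
    for (g in c("A", "B", "C")) {
      pa <- setdiff(s$edges[s$edges[, 2L] == g, 1L], CLASS_NODE)
      expect_equal(rep_$family_scores[[g]], lm_family_score(g, pa, ds),
                   tolerance = 1e-9)
    }
  }
})

test_that("the BIC penalty rejects spurious edges on independent noise", {
  wins <- 0L
  for (seed in 1:100) {
    ds <- noise_dataset(n = 100L, p = 2L, seed = seed)
    empty <- bic_score(dag_structure(ds$feature_ids), ds)$total_bic
    one <- bic_score(dag_structure(ds$feature_ids,
                                   rbind(c("f01", "f02"))), ds)$total_bic
    if (empty > one) wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})

test_that("BIC decomposability holds on random structures", {
  set.seed(77)
  ds <- noise_dataset(n = 30L, p = 6L, seed = 8L)
  for (i in 1:10) {
    e <- random_dag_edges(ds$feature_ids, p = 0.3)
    rep_ <- bic_score(dag_structure(ds$feature_ids, e), ds)
    expect_equal(rep_$total_bic, sum(rep_$family_scores))
  }
})

test_that("expression prediction agrees with joint-Gaussian conditioning", {
  # isolated node: prediction is the class-mixture of intercepts, ~0
  ds <- noise_dataset(n = 60L, p = 3L, seed = 9L)
  net <- fit_parameters(dag_structure(ds$feature_ids), ds)
  pr <- predict_expression(net, ds, "f01")
  expect_true(all(abs(pr$predictions) < 1e-6))

  # A -> B only: prediction of B is exactly intercept + weight * A
  set.seed(10)
  a <- rnorm(80); b <- 0.7 * a + 0.5 * rnorm(80)
  ds2 <- expression_dataset(cbind(A = a, B = b), rep_len(0:1, 80),
                            c(A = "A", B = "B"), species_id = "t")
  net2 <- fit_parameters(dag_structure(c("A", "B"), rbind(c("A", "B"))), ds2)
  p2 <- predict_expression(net2, ds2, "B")
  par <- net2$families[["B"]]$params[[1L]]
  expect_equal(unname(p2$predictions),
               unname(par$intercept + par$weights[["A"]] * a),
               tolerance = 1e-9)

  # 4-node fixture with a class-dependent family vs the moment-recursion
  # + explicit-inverse oracle
  set.seed(11)
  n <- 80L
  cls <- rep_len(c(0L, 1L), n)
  x1 <- 0.8 * cls + rnorm(n)
  x2 <- 0.9 * x1 + rnorm(n)
  x3 <- -0.7 * x1 + 0.5 * x2 + rnorm(n)
  x4 <- rnorm(n)
  m <- cbind(x1 = x1, x2 = x2, x3 = x3, x4 = x4)
  ds4 <- expression_dataset(m, cls, setNames(colnames(m), colnames(m)),
                            species_id = "t4")
  s4 <- dag_structure(colnames(m),
                      rbind(c(CLASS_NODE, "x1"), c("x1", "x2"),
                            c("x1", "x3"), c("x2", "x3")))
  net4 <- fit_parameters(s4, ds4)
  for (target in colnames(m)) {
    got <- predict_expression(net4, ds4, target)$predictions
    expect_equal(unname(got), predict_expression_oracle(net4, ds4, target),
                 tolerance = 1e-8)
  }
  expect_error(predict_expression(net4, ds4, CLASS_NODE), "predict_class")
})

test_that("in-sample SSE of a fitted chain never exceeds the empty network", {
  ds <- chain_dataset(n = 120L, seed = 12L)
  chain <- dag_structure(ds$feature_ids, rbind(c("A", "B"), c("B", "C")))
  net_c <- fit_parameters(chain, ds)
  net_e <- fit_parameters(dag_structure(ds$feature_ids), ds)
  sse <- function(net) sum(vapply(c("A", "B", "C"), function(g)
    predict_expression(net, ds, g)$sse, numeric(1)))
  expect_lte(sse(net_c), sse(net_e))
})

test_that("class posterior follows the closed-form Gaussian ratio", {
  # class with no children: posterior equals the prior for any evidence
  ds <- noise_dataset(n = 40L, p = 3L, seed = 13L, balance = 0.3)
  net <- fit_parameters(dag_structure(ds$feature_ids), ds)
  for (i in 1:5) {
    post <- predict_class(net, ds$values[i, ])
    expect_equal(unname(post), unname(net$class_prior), tolerance = 1e-9)
    expect_equal(sum(post), 1, tolerance = 1e-12)
  }

  # one child with per-class means -1/+1, unit variance, uniform prior
  hand <- list(
    structure = dag_structure("X", rbind(c(CLASS_NODE, "X"))),
    class_prior = c(`0` = 0.5, `1` = 0.5),
    families = list(X = list(
      parents = character(), class_parent = TRUE, pooled = FALSE,
      params = list(`0` = list(intercept = -1,
                               weights = setNames(numeric(), character()),
                               sigma2 = 1, n = 10),
                    `1` = list(intercept = 1,
                               weights = setNames(numeric(), character()),
                               sigma2 = 1, n = 10)))),
    n_samples = 20)
  class(hand) <- "fitted_network"
  expect_equal(unname(predict_class(hand, c(X = 0))), c(0.5, 0.5),
               tolerance = 1e-12)
  p1 <- predict_class(hand, c(X = 1))
  expect_equal(unname(p1), c(exp(-2), 1) / (1 + exp(-2)), tolerance = 1e-4)
  expect_equal(unname(p1[["1"]]), 0.8808, tolerance = 1e-4)

  # missing evidence is marginalized: an NA on an isolated node is neutral
  pNA <- predict_class(hand, c(X = NA_real_))
  expect_equal(unname(pNA), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("fitted networks round-trip through JSON", {
  ds <- chain_dataset(n = 30L, seed = 14L)
  s <- dag_structure(ds$feature_ids,
                     rbind(c("A", "B"), c(CLASS_NODE, "C"), c("B", "C")))
  net <- fit_parameters(s, ds)
  js <- network_to_json(net)
  back <- network_from_json(js)
  expect_equal(back$class_prior, net$class_prior)
  expect_setequal(back$structure$nodes, net$structure$nodes)
  expect_equal(back$families, net$families, tolerance = 1e-12)
  expect_equal(log_likelihood(back, ds), log_likelihood(net, ds),
               tolerance = 1e-12)

  tmp <- tempfile(fileext = ".json")
  network_to_json(net, tmp)
  expect_equal(network_from_json(tmp)$families, net$families,
               tolerance = 1e-12)
})
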