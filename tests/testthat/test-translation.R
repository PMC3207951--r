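f2g_toy <- c(t1 = "A", t2 = "B", t3 = "A", t4 = "B", t5 = "C")

test_that("collapsing to a gene map merges, drops and ignores direction", {
  s <- dag_structure(names(f2g_toy),
                     rbind(c("t1", "t2"), c("t3", "t4"), c("t1", "t3")))
  map <- collapse_to_gene_map(s, f2g_toy, "spA")
  # two transcript edges merge into one A-B link; the within-gene edge
  # t1(A) -> t3(A) is dropped
  expect_equal(nrow(map), 1L)
  expect_equal(map$gene_a, "A")
  expect_equal(map$gene_b, "B")
  expect_equal(map$provenance, 2L)

  # flipping every edge direction leaves the map unchanged
  s_flip <- dag_structure(names(f2g_toy),
                          rbind(c("t2", "t1"), c("t4", "t3"), c("t3", "t1")))
  flip <- collapse_to_gene_map(s_flip, f2g_toy)
  expect_equal(as.data.frame(flip)[c("gene_a", "gene_b", "provenance")],
               as.data.frame(map)[c("gene_a", "gene_b", "provenance")])

  # class edges survive as class-gene links
  s_cls <- dag_structure(names(f2g_toy), rbind(c(CLASS_NODE, "t5")))
  map_cls <- collapse_to_gene_map(s_cls, f2g_toy)
  expect_setequal(c(map_cls$gene_a, map_cls$gene_b), c(CLASS_NODE, "C"))

  expect_error(collapse_to_gene_map(
    dag_structure(c("tX", "t1"), rbind(c("tX", "t1"))), f2g_toy),
    "unmapped")
})

test_that("orthology mapping expands, drops and reports losses", {
  orth <- orthology_map(data.frame(
    species_id = c("spA", "spA", "spA", "spB", "spB", "spB"),
    gene_id =    c("A",   "B",   "C",   "A2",  "B2a", "B2b"),
    group_id =   c("ogA", "ogB", "ogC", "ogA", "ogB", "ogB")))

  # one-to-one
  m1 <- network_map(data.frame(gene_a = "A", gene_b = "C"), "spA")
  r1 <- map_via_orthology(m1, orth, "spA", "spB")
  expect_equal(nrow(attr(r1, "dropped")), 1L)  # C has no spB ortholog
  expect_length(r1$keys, 0L)

  # one-to-many: B maps to two spB genes
  m2 <- network_map(data.frame(gene_a = c("A", CLASS_NODE),
                               gene_b = c("B", "B")), "spA")
  r2 <- map_via_orthology(m2, orth, "spA", "spB")
  expect_setequal(
    apply(r2$pairs, 1L, function(p) paste(sort(p), collapse = "-")),
    c("A2-B2a", "A2-B2b", "B2a-class", "B2b-class"))
  expect_equal(nrow(attr(r2, "dropped")), 0L)
})

test_that("naive summarization averages transcripts and re-standardizes", {
  # single-transcript genes: unchanged up to re-standardization
  m <- cbind(t1 = c(1, -1, 0.5, -0.5), t2 = c(3, 1, -2, -2))
  ds <- expression_dataset(m, c(1L, 0L, 1L, 0L), c(t1 = "gA", t2 = "gB"),
                           species_id = "sp", level = "transcript")
  ns <- naive_summarize(ds)
  expect_equal(ns$level, "gene")
  expect_equal(unname(ns$values[, "gA"]),
               unname(standardize(m)[, "t1"]), tolerance = 1e-12)

  # the gene profile is the arithmetic transcript mean: (1,3) and (-1,1)
  # average to (2,0) before re-standardization
  m2 <- cbind(t1 = c(1, -1, 2, 0), t2 = c(3, 1, 0, -2))
  ds2 <- expression_dataset(m2, c(1L, 0L, 1L, 0L),
                            c(t1 = "gA", t2 = "gA"),
                            species_id = "sp", level = "transcript")
  ns2 <- naive_summarize(ds2)
  raw_mean <- rowMeans(m2)
  expect_equal(unname(ns2$values[, "gA"]),
               unname(standardize(matrix(raw_mean,
                                         dimnames = list(NULL, "gA")))[, 1L]),
               tolerance = 1e-12)

  # anti-correlated isoforms of equal sd average to a constant profile:
  # the naive variant's information loss surfaces as an error
  x <- c(1.2, -0.3, 0.8, -1.7)
  m3 <- cbind(t1 = x, t2 = -x, t3 = rnorm(4))
  ds3 <- expression_dataset(m3, c(1L, 0L, 1L, 0L),
                            c(t1 = "gA", t2 = "gA", t3 = "gB"),
                            species_id = "sp", level = "transcript")
  expect_error(naive_summarize(ds3), "constant|standardized")
})

test_that("translation returns prior-only networks on an empty map", {
  ds <- noise_dataset(n = 24L, p = 4L, seed = 21L, species = "spB",
                      genes = paste0("spB.g", 1:4))
  orth <- toy_orthology(paste0("g", 1:4))
  folds <- make_folds(ds, 2L, seed = 1L)
  empty_map <- network_map(data.frame(gene_a = character(),
                                      gene_b = character()), "spA")
  expect_warning(
    res <- translate_and_test(empty_map, ds, folds, orth,
                              anneal_config(maxfc = 20L, mode = "test"),
                              variant = "exhaustive",
                              source_species = "spA"),
    "empty candidate")
  for (r in res) {
    expect_equal(nrow(r$structure$edges), 0L)
    expect_true(r$flagged)
    # class prediction falls back to the training prior
    post <- r$metrics$class_posterior
    expect_true(all(abs(post[, "1"] - post[1L, "1"]) < 1e-12))
  }
})

test_that("exhaustive translation selects the informative transcript", {
  wins <- 0L
  n_runs <- 20L
  for (seed in seq_len(n_runs)) {
    set.seed(seed + 400L)
    n <- 40L
    gA <- rnorm(n)
    a1 <- gA                                    # faithful isoform
    a2 <- rnorm(n)                              # pure-noise isoform
    b1 <- 0.9 * gA + sqrt(1 - 0.81) * rnorm(n)
    m <- cbind(a1 = a1, a2 = a2, b1 = b1)
    ds <- standardize(expression_dataset(
      m, rep_len(0:1, n), c(a1 = "A", a2 = "A", b1 = "B"),
      species_id = "spB", level = "transcript"))
    cands <- candidate_edge_set(rbind(c("A", "B")))
    res <- anneal(ds, anneal_config(maxfc = 200L, mode = "test",
                                    seed = seed), cands)
    e <- res$structure$edges
    via_a1 <- any((e[, 1L] == "a1" & e[, 2L] == "b1") |
                    (e[, 1L] == "b1" & e[, 2L] == "a1"))
    via_a2 <- any((e[, 1L] == "a2" & e[, 2L] == "b1") |
                    (e[, 1L] == "b1" & e[, 2L] == "a2"))
    if (via_a1 && !via_a2) wins <- wins + 1L
  }
  expect_gte(wins, 0.9 * n_runs)
})

test_that("naive and exhaustive agree when every gene has one transcript", {
  set.seed(31)
  n <- 30L
  g1 <- rnorm(n); g2 <- 0.9 * g1 + 0.45 * rnorm(n); g3 <- rnorm(n)
  m <- cbind(sp.g1.t1 = g1, sp.g2.t1 = g2, sp.g3.t1 = g3)
  ds <- standardize(expression_dataset(
    m, rep_len(0:1, n),
    c(sp.g1.t1 = "sp.g1", sp.g2.t1 = "sp.g2", sp.g3.t1 = "sp.g3"),
    species_id = "sp", level = "transcript"))
  cfg <- anneal_config(maxfc = 150L, seed = 5L)
  map_ex <- collapse_to_gene_map(anneal(ds, cfg)$structure,
                                 ds$feature_to_gene)
  naive <- naive_summarize(ds)
  map_nv <- collapse_to_gene_map(anneal(naive, cfg)$structure,
                                 naive$feature_to_gene)
  expect_equal(as.data.frame(map_ex)[c("gene_a", "gene_b")],
               as.data.frame(map_nv)[c("gene_a", "gene_b")])
})
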