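f2g_two <- c(x1 = "A", x2 = "B", x3 = "A", y1 = "C")

mk_structure <- function(...) dag_structure(names(f2g_two), rbind(...))

test_that("link counting gives the found/max ratio and dedups per structure", {
  with_link <- mk_structure(c("x1", "x2"))
  with_link_rev <- mk_structure(c("x2", "x1"))
  parallel <- mk_structure(c("x1", "x2"), c("x3", "x2"))  # both A-B
  empty <- mk_structure()
  tab <- count_links(
    list(sp = list(with_link, with_link_rev, parallel, empty,
                   empty, empty)),
    list(sp = f2g_two))
  expect_equal(nrow(tab), 1L)
  expect_setequal(c(tab$gene_a, tab$gene_b), c("A", "B"))
  # found in 3 of 6 networks (direction-free, parallel isoforms once)
  expect_equal(tab$found_sp, 3L)
  expect_equal(tab$max_sp, 6L)
  expect_equal(tab$confidence_sp, 0.5)

  # bounds: present in all / absent
  tab2 <- count_links(list(sp = list(with_link, with_link)),
                      list(sp = f2g_two))
  expect_equal(tab2$confidence_sp, 1.0)
  tab3 <- count_links(list(sp = list(empty, empty)), list(sp = f2g_two))
  expect_equal(nrow(tab3), 0L)
})

test_that("consensus applies the all-species intersection rule", {
  mk_tab <- function(conf) {
    tab <- data.frame(gene_a = paste0("a", seq_along(conf[[1]])),
                      gene_b = paste0("b", seq_along(conf[[1]])))
    for (sp in names(conf)) {
      tab[[paste0("found_", sp)]] <- round(conf[[sp]] * 10)
      tab[[paste0("max_", sp)]] <- 10L
      tab[[paste0("confidence_", sp)]] <- conf[[sp]]
    }
    structure(tab, class = c("confidence_table", "data.frame"),
              species = names(conf))
  }
  tab <- mk_tab(list(s1 = c(0.5, 0.9, 0.0), s2 = c(0.5, 0.0, 0.0),
                     s3 = c(0.5, 0.9, 0.0)))
  expect_equal(nrow(consensus(tab, 0.1)), 1L)       # only the (0.5,0.5,0.5) link
  expect_equal(consensus(tab, 0.1)$gene_a, "a1")
  expect_equal(nrow(consensus(tab, 0)), 3L)         # tau = 0 keeps everything
  expect_equal(nrow(consensus(tab, 1 + 1e-9)), 0L)  # tau > 1 keeps nothing

  # monotone nesting over randomized tables
  set.seed(99)
  for (i in 1:200) {
    n <- sample(1:8, 1L)
    conf <- list(s1 = round(runif(n), 2), s2 = round(runif(n), 2),
                 s3 = round(runif(n), 2))
    rt <- mk_tab(conf)
    taus <- sort(runif(2))
    lo <- consensus(rt, taus[1L]); hi <- consensus(rt, taus[2L])
    keys_lo <- paste(lo$gene_a, lo$gene_b)
    keys_hi <- paste(hi$gene_a, hi$gene_b)
    expect_true(all(keys_hi %in% keys_lo))
    # intersection rule: kept iff the minimum across species passes
    idx <- which(pmin(conf$s1, conf$s2, conf$s3) >= taus[1L])
    expect_setequal(keys_lo,
                    if (length(idx)) paste0("a", idx, " b", idx)
                    else character(0))
  }
})

test_that("translatability is the fraction of trained links re-found", {
  trained <- network_map(data.frame(
    gene_a = paste0("g", 1:10), gene_b = paste0("h", 1:10)))
  tab <- data.frame(gene_a = paste0("g", 1:10), gene_b = paste0("h", 1:10))
  tab$found_m <- c(rep(5L, 4L), rep(0L, 6L))
  tab$max_m <- 10L
  tab$confidence_m <- tab$found_m / 10
  tab <- structure(tab, class = c("confidence_table", "data.frame"),
                   species = "m")
  expect_equal(unname(translatability(trained, tab, 0.1, "m")), 0.4)

  # sweep is non-increasing in the threshold
  sweep <- vapply(seq(0, 1, by = 0.1), function(tau)
    unname(translatability(trained, tab, tau, "m")), numeric(1))
  expect_true(all(diff(sweep) <= 0))

  expect_error(
    translatability(network_map(data.frame(gene_a = character(),
                                           gene_b = character())),
                    tab, 0.1),
    "undefined")
})

test_that("robustness profiles separate module from random links", {
  sets <- gene_set_spec(paste0("m", 1:3), paste0("r", 1:3))
  tab <- data.frame(
    gene_a = c("m1", "m2", "r1", CLASS_NODE),
    gene_b = c("m2", "r1", "r2", "m3"),
    found_s = c(9L, 5L, 1L, 8L), max_s = 10L,
    confidence_s = c(0.9, 0.5, 0.1, 0.8))
  tab <- structure(tab, class = c("confidence_table", "data.frame"),
                   species = "s")
  prof <- robustness_profile(tab, sets, c(0, 0.1, 0.6, 0.95))
  # class-m3 and m-incident links are module links; r1-r2 is random-only
  expect_equal(prof$module_links, c(3L, 3L, 2L, 0L))
  expect_equal(prof$random_links, c(1L, 1L, 0L, 0L))
  expect_true(all(diff(prof$module_links) <= 0))
  expect_true(all(diff(prof$random_links) <= 0))

  # an all-module network has zero random-set links at any threshold
  tab2 <- tab[1L, ]
  expect_equal(robustness_profile(tab2, sets, c(0, 0.5))$random_links,
               c(0L, 0L))
})

test_that("confidence counting can key links by ortholog groups", {
  orth <- toy_orthology(c("A", "B"), species = c("spA", "spB"))
  sA <- dag_structure(c("a1", "b1"), rbind(c("a1", "b1")))
  sB <- dag_structure(c("a2", "b2"), rbind(c("b2", "a2")))
  tab <- count_links(
    list(spA = list(sA), spB = list(sB)),
    list(spA = c(a1 = "spA.A", b1 = "spA.B"),
         spB = c(a2 = "spB.A", b2 = "spB.B")),
    orthology = orth)
  expect_equal(nrow(tab), 1L)
  expect_setequal(c(tab$gene_a, tab$gene_b), c("og.A", "og.B"))
  expect_equal(tab$confidence_spA, 1)
  expect_equal(tab$confidence_spB, 1)
})
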