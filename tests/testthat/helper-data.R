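# Programmatic fixtures shared across tests.

# standardized dataset with independent noise features
noise_dataset <- function(n = 40L, p = 5L, seed = 1L, balance = 0.5,
                          species = "sp", genes = NULL) {
  set.seed(seed)
  feats <- sprintf("f%02d", seq_len(p))
  if (is.null(genes)) genes <- feats
  m <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, feats))
  n1 <- max(1L, round(n * balance))
  cls <- sample(rep(c(1L, 0L), c(n1, n - n1)))
  standardize(expression_dataset(m, cls, setNames(genes, feats),
                                 species_id = species))
}

# chain A -> B -> C with the given standardized-scale weights (unit-variance
# variables, noise sd sqrt(1 - w^2)), plus class labels
chain_dataset <- function(n = 300L, w = c(0.9, 0.9), seed = 1L) {
  set.seed(seed)
  a <- rnorm(n)
  b <- w[1L] * a + sqrt(1 - w[1L]^2) * rnorm(n)
  c0 <- w[2L] * b + sqrt(1 - w[2L]^2) * rnorm(n)
  m <- cbind(A = a, B = b, C = c0)
  cls <- rep_len(c(0L, 1L), n)
  standardize(expression_dataset(m, cls, setNames(colnames(m), colnames(m)),
                                 species_id = "chain"))
}

# dataset where `k_signal` genes are shifted by `effect` sd between classes
signal_dataset <- function(n = 60L, p = 10L, k_signal = 5L, effect = 2,
                           seed = 1L, species = "sig") {
  set.seed(seed)
  feats <- sprintf("f%02d", seq_len(p))
  n1 <- n %/% 2L
  cls <- sample(rep(c(1L, 0L), c(n1, n - n1)))
  m <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, feats))
  for (j in seq_len(k_signal)) m[, j] <- m[, j] + effect * cls
  standardize(expression_dataset(m, cls, setNames(feats, feats),
                                 species_id = species))
}

# tiny two-species orthology over shared base gene names
toy_orthology <- function(genes, species = c("spA", "spB")) {
  orthology_map(do.call(rbind, lapply(species, function(sp)
    data.frame(species_id = sp,
               gene_id = paste(sp, genes, sep = "."),
               group_id = paste0("og.", genes)))))
}

# unordered pair keys of an edge matrix (internal key format)
pair_key_vec <- function(edges)
  dandelion:::pair_key(edges[, 1L], edges[, 2L])
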