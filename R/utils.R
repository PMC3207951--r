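# internal helpers shared across modules

#' Name of the distinguished discrete class node
#'
#' Every network learned by dandelion contains one discrete node encoding the
#' per-sample disease state (disease/control) alongside the continuous
#' expression nodes.  The node is addressed everywhere by this fixed name, so
#' `"class"` is reserved and may not be used as a feature or gene identifier.
#' @export
CLASS_NODE <- "class"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards, so seeded internals do not
#' perturb the global random stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# canonical key for an unordered node/gene pair
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "")
}

split_pair_key <- function(key) {
  if (length(key) == 0L) {
    out <- matrix(character(), ncol = 2L)
    colnames(out) <- c("a", "b")
    return(out)
  }
  out <- do.call(rbind, strsplit(key, "", fixed = TRUE))
  colnames(out) <- c("a", "b")
  out
}

# order an unordered pair canonically, class node first when present
sort_pair <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  cbind(a, b)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

log_info <- function(...) {
  if (isTRUE(getOption("dandelion.verbose", FALSE)))
    message("[dandelion] ", sprintf(...))
}
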