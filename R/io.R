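# Readers/writers for the interchange formats: expression TSV trio,
# network-map and structure edge lists, confidence tables, DOT export.
# All TSVs tolerate '#' comment lines.

read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression dataset from TSV files
#'
#' The expression file has `feature_id` as its first column and one column
#' per sample; the metadata file has columns `sample_id`, `class`
#' (`"disease"`/`"control"`) and optionally `species`; the feature map has
#' columns `feature_id`, `gene_id`.
#'
#' @param path expression TSV.
#' @param metadata_path sample metadata TSV.
#' @param feature_map_path feature-to-gene TSV; when `NULL`, features map
#'   to themselves and the dataset is gene-level.
#' @param level override the level (`"transcript"`/`"gene"`).
#' @return an [expression_dataset()].
#' @export
read_expression <- function(path, metadata_path, feature_map_path = NULL,
                            level = NULL) {
  expr <- read_tsv(path)
  meta <- read_tsv(metadata_path)
  if (!all(c("sample_id", "class") %in% names(meta)))
    stop("metadata needs columns sample_id and class")
  feats <- as.character(expr[[1L]])
  if (anyDuplicated(feats))
    stop("duplicate feature ids in ", path, ": ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "))
  m <- t(as.matrix(expr[, -1L, drop = FALSE]))
  colnames(m) <- feats
  missing_meta <- setdiff(rownames(m), meta$sample_id)
  if (length(missing_meta))
    stop("samples missing from metadata: ",
         paste(missing_meta, collapse = ", "))
  meta <- meta[match(rownames(m), meta$sample_id), ]
  cls_str <- tolower(meta$class)
  bad <- !cls_str %in% c("disease", "control")
  if (any(bad))
    stop("unknown class labels: ", paste(unique(meta$class[bad]),
                                         collapse = ", "))
  cls <- as.integer(cls_str == "disease")
  if (is.null(feature_map_path)) {
    f2g <- stats::setNames(feats, feats)
    lvl <- level %||% "gene"
  } else {
    fm <- read_tsv(feature_map_path)
    if (!all(c("feature_id", "gene_id") %in% names(fm)))
      stop("feature map needs columns feature_id and gene_id")
    f2g <- stats::setNames(as.character(fm$gene_id),
                           as.character(fm$feature_id))
    lvl <- level %||% "transcript"
  }
  expression_dataset(m, cls, f2g,
                     species_id = meta$species[1L] %||% "species",
                     level = lvl, sample_ids = rownames(m))
}

#' Write an expression dataset as the standard TSV trio
#'
#' @param dataset an [expression_dataset()].
#' @param prefix path prefix; writes `<prefix>_expression.tsv`,
#'   `<prefix>_samples.tsv` and `<prefix>_features.tsv`.
#' @return the three paths, invisibly.
#' @export
write_expression <- function(dataset, prefix) {
  ep <- paste0(prefix, "_expression.tsv")
  sp <- paste0(prefix, "_samples.tsv")
  fp <- paste0(prefix, "_features.tsv")
  expr <- data.frame(feature_id = dataset$feature_ids,
                     t(dataset$values), check.names = FALSE)
  write_tsv(expr, ep)
  write_tsv(data.frame(
    sample_id = dataset$sample_ids,
    class = ifelse(dataset$class_labels == 1L, "disease", "control"),
    species = dataset$species_id), sp)
  write_tsv(data.frame(feature_id = dataset$feature_ids,
                       gene_id = unname(dataset$feature_to_gene)), fp)
  invisible(c(ep, sp, fp))
}

#' Write / read a gene-level network map
#'
#' Link-list TSV with columns `gene_a`, `gene_b`, `provenance`, plus any
#' per-species confidence columns carried by the map; round-trips exactly.
#'
#' @param map a [network_map()].
#' @param path output TSV.
#' @export
write_network <- function(map, path) {
  df <- as.data.frame(map)
  conf <- attr(map, "confidence")
  if (!is.null(conf) && nrow(df)) {
    ck <- pair_key(conf$gene_a, conf$gene_b)
    df <- cbind(df, conf[match(pair_key(df$gene_a, df$gene_b), ck),
                         setdiff(names(conf), c("gene_a", "gene_b")),
                         drop = FALSE])
  }
  write_tsv(df, path)
}

#' @rdname write_network
#' @return `read_network()` returns a [network_map()].
#' @export
read_network <- function(path) {
  df <- read_tsv(path, colClasses = NA)
  need <- c("gene_a", "gene_b")
  if (!all(need %in% names(df)))
    stop("malformed network file (need gene_a/gene_b columns): ", path)
  bad <- which(is.na(df$gene_a) | is.na(df$gene_b) | df$gene_a == "" |
                 df$gene_b == "")
  if (length(bad))
    stop(sprintf("malformed row(s) %s in %s",
                 paste(bad + 1L, collapse = ","), path))
  map <- network_map(df[c("gene_a", "gene_b",
                          intersect("provenance", names(df)))])
  extra <- setdiff(names(df), c("gene_a", "gene_b", "provenance"))
  if (length(extra))
    attr(map, "confidence") <- df[c("gene_a", "gene_b", extra)]
  map
}

#' Write / read a directed structure edge list
#' @param structure a [dag_structure()].
#' @param path TSV path (columns `from`, `to`; nodes listed in a header
#'   comment are restored on read).
#' @export
write_structure <- function(structure, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# nodes: ", paste(structure$nodes, collapse = ",")), con)
  utils::write.table(as.data.frame(structure$edges), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_structure
#' @export
read_structure <- function(path) {
  first <- readLines(path, n = 1L)
  nodes <- if (startsWith(first, "# nodes: "))
    strsplit(sub("^# nodes: ", "", first), ",", fixed = TRUE)[[1L]]
  else character()
  df <- read_tsv(path)
  dag_structure(unique(c(nodes, df$from, df$to)),
                if (nrow(df)) as.matrix(df[c("from", "to")]) else NULL)
}

#' Write a confidence table
#' @param table a [count_links()] confidence table.
#' @param path output TSV.
#' @export
write_confidence_table <- function(table, path) {
  write_tsv(as.data.frame(table), path)
}

#' @rdname write_confidence_table
#' @export
read_confidence_table <- function(path) {
  df <- read_tsv(path)
  species <- sub("^confidence_", "", grep("^confidence_", names(df),
                                          value = TRUE))
  structure(df, class = c("confidence_table", "data.frame"),
            species = species)
}

confidence_bin <- function(conf, bins = c(0.25, 0.75)) {
  findInterval(conf, bins) + 1L   # 1 = weak, 2 = moderate, 3 = strong
}

#' Export a network map as DOT with confidence-binned edge styles
#'
#' Edge lines are styled by the minimum across-species confidence: dotted
#' below the lower bin bound, dashed between the bounds, solid above
#' (default bins 0.25 / 0.75).
#'
#' @param map a [network_map()] (confidence attribute used when present).
#' @param path output `.dot` file.
#' @param bins two ascending bin boundaries.
#' @export
write_network_dot <- function(map, path, bins = c(0.25, 0.75)) {
  styles <- c("dotted", "dashed", "solid")
  conf <- attr(map, "confidence")
  lines <- c("graph consensus {", "  node [shape=ellipse];")
  for (i in seq_len(nrow(map))) {
    style <- "solid"
    if (!is.null(conf)) {
      ck <- pair_key(conf$gene_a, conf$gene_b)
      row <- match(pair_key(map$gene_a[i], map$gene_b[i]), ck)
      if (!is.na(row)) {
        cc <- as.numeric(conf[row, grep("^confidence_", names(conf)),
                              drop = TRUE])
        style <- styles[confidence_bin(min(cc), bins)]
      }
    }
    lines <- c(lines, sprintf('  "%s" -- "%s" [style=%s];',
                              map$gene_a[i], map$gene_b[i], style))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}

#' Write / read an orthology table
#' @param orthology an [orthology_map()].
#' @param path TSV with columns species_id, gene_id, group_id.
#' @export
write_orthology <- function(orthology, path) {
  write_tsv(as.data.frame(orthology), path)
}

#' @rdname write_orthology
#' @export
read_orthology <- function(path) orthology_map(read_tsv(path))
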