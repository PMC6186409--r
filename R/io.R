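#' Write / read an expression matrix TSV with a group-label row
#'
#' Layout: a header line of sample ids (first field `gene`), then a row
#' labelled `__group__` carrying the case/control label of each sample,
#' then one row per gene. Detection-call matrices use the same layout
#' without the group row.
#'
#' @param ds An [expression_dataset()].
#' @param path Output TSV path.
#' @param detection_path Optional path for the parallel P/A call matrix.
#' @export
write_expression_tsv <- function(ds, path, detection_path = NULL) {
  m <- rbind(`__group__` = unname(ds$groups), format(ds$values, trim = TRUE))
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene", colnames(ds$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(detection_path) && !is.null(ds$detection)) {
    dd <- data.frame(gene = rownames(ds$detection), ds$detection,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(dd, detection_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param dataset_id,view Identity of the dataset being read back.
#' @return `read_expression_tsv()` returns an [expression_dataset()].
#' @export
read_expression_tsv <- function(path, dataset_id, view,
                                detection_path = NULL) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (raw$gene[1] != "__group__")
    stop(sprintf("%s:2: expected the __group__ label row", path),
         call. = FALSE)
  groups <- unlist(raw[1, -1])
  vals <- as.matrix(raw[-1, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- raw$gene[-1]
  detection <- NULL
  if (!is.null(detection_path)) {
    dd <- utils::read.table(detection_path, sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
    detection <- as.matrix(dd[, -1, drop = FALSE])
    rownames(detection) <- dd$gene
    detection <- detection[rownames(vals), colnames(vals), drop = FALSE]
  }
  expression_dataset(dataset_id, view, vals, unname(groups), detection)
}

#' Write / read gene sets in GMT format
#'
#' One set per line: id TAB description TAB gene TAB gene ... Lines with
#' fewer than three fields are rejected with the file and line number.
#'
#' @param sets Named list of character vectors (set id -> genes).
#' @param path File path.
#' @param descriptions Optional named character vector of descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(id) {
    desc <- if (!is.null(descriptions) && id %in% names(descriptions))
      descriptions[[id]] else id
    paste(c(id, desc, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @return `read_gmt()` returns a named list of gene vectors with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    if (!nzchar(lines[i])) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("%s:%d: GMT line needs id, description and >=1 gene",
                   path, i), call. = FALSE)
    sets[[f[1]]] <- f[-(1:2)]
    desc[f[1]] <- f[2]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write / read interaction tables
#'
#' TSV with columns node_a, node_b, kind, direction (ab/ba/none), score,
#' evidence.
#'
#' @param records Interaction data frame.
#' @param path File path.
#' @export
write_interactions_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_interactions_tsv
#' @export
read_interactions_tsv <- function(path) {
  rec <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("node_a", "node_b", "kind", "direction", "score", "evidence")
  if (!all(need %in% names(rec)))
    stop(sprintf("%s:1: expected columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  rec
}

#' Write a network in SIF format (one interaction type token per line)
#'
#' @param net A `phenotype_network` or `overlap_network`.
#' @param path File path.
#' @export
write_sif <- function(net, path) {
  if (inherits(net, "overlap_network")) {
    lines <- sprintf("%s\toverlap\t%s", net$edges$a, net$edges$b)
    iso <- setdiff(net$nodes$id, c(net$edges$a, net$edges$b))
  } else {
    lines <- sprintf("%s\t%s\t%s", net$edges$from, net$edges$kind,
                     net$edges$to)
    iso <- setdiff(net$nodes$id, c(net$edges$from, net$edges$to))
  }
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Read a SIF file into an edge table
#'
#' @param path File path.
#' @return Data frame with columns from, kind, to (isolated nodes get NA
#'   kind/to).
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) == 2)
  if (length(bad))
    stop(sprintf("%s:%d: SIF line must have 1 or >=3 fields", path, bad[1]),
         call. = FALSE)
  do.call(rbind, lapply(parts, function(f) {
    if (length(f) == 1) data.frame(from = f, kind = NA, to = NA,
                                   stringsAsFactors = FALSE)
    else data.frame(from = f[1], kind = f[2], to = f[3:length(f)],
                    stringsAsFactors = FALSE)
  }))
}

#' Export a phenotype network to GraphML with all attributes
#'
#' @param net A `phenotype_network`.
#' @param path File path.
#' @export
write_graphml <- function(net, path) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = within(net$nodes,
                                                       drugs <- vapply(
                                                         drugs, paste,
                                                         character(1),
                                                         collapse = ";")))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a JSON run manifest
#'
#' @param manifest Named list of counts and the configuration echo.
#' @param path File path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
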