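#' Filter a scored interaction table
#'
#' Keeps records whose evidence tag matches `required_evidence` and whose
#' confidence score is at least `min_score` (inclusive).
#'
#' @param records Data frame with columns node_a, node_b, kind, direction,
#'   score, evidence.
#' @param min_score Minimum confidence score (default 0.9).
#' @param required_evidence Evidence tag to require (default "experimental");
#'   `NULL` keeps all evidence classes.
#' @return The filtered data frame.
#' @export
filter_interactions <- function(records, min_score = 0.9,
                                required_evidence = "experimental") {
  stopifnot(all(records$score >= 0 & records$score <= 1))
  keep <- records$score >= min_score
  if (!is.null(required_evidence))
    keep <- keep & records$evidence == required_evidence
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

new_phenotype_network <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "phenotype_network")
}

#' @export
print.phenotype_network <- function(x, ...) {
  cat(sprintf("<phenotype_network> %d nodes (%d core, %d shell), %d edge records\n",
              nrow(x$nodes), sum(x$nodes$role == "core"),
              sum(x$nodes$role == "shell"), nrow(x$edges)))
  invisible(x)
}

#' Assemble the core + first-shell phenotype network
#'
#' The node set is the core plus every node sharing a qualifying record with
#' a core node (the first shell); the edge set is every qualifying record
#' with both endpoints in that node set — so shell-shell edges among
#' first-shell nodes are retained, but nodes reachable only through shell
#' nodes are not. Core nodes without any edge stay as isolates.
#'
#' @param core Character vector of core node ids (non-empty).
#' @param records Pre-filtered interaction data frame (see
#'   [filter_interactions()]).
#' @return A `phenotype_network`: `nodes` data.frame (id, role, regulation,
#'   magnitude, dna_binding, drugs) and `edges` data.frame (from, to, kind,
#'   direction, score, evidence).
#' @export
assemble_network <- function(core, records) {
  if (!length(core)) stop("core set is empty", call. = FALSE)
  if (all(c("from", "to") %in% names(records))) {  # accept edge-table form
    names(records)[match(c("from", "to"), names(records))] <-
      c("node_a", "node_b")
  }
  touches_core <- records$node_a %in% core | records$node_b %in% core
  shell <- setdiff(unique(c(records$node_a[touches_core],
                            records$node_b[touches_core])), core)
  node_ids <- c(sort(unique(core)), sort(shell))
  keep <- records$node_a %in% node_ids & records$node_b %in% node_ids
  e <- records[keep, , drop = FALSE]
  edges <- data.frame(from = e$node_a, to = e$node_b, kind = e$kind,
                      direction = e$direction, score = e$score,
                      evidence = e$evidence, stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  nodes <- data.frame(id = node_ids,
                      role = ifelse(node_ids %in% core, "core", "shell"),
                      regulation = "none", magnitude = NA_real_,
                      dna_binding = FALSE, stringsAsFactors = FALSE)
  nodes$drugs <- replicate(nrow(nodes), character(0), simplify = FALSE)
  new_phenotype_network(nodes, edges)
}

#' Remove a node (and optional curated extra edges) from the network
#'
#' Deletes the node with all incident edge records, plus any explicitly
#' listed extra edges (curated removals that go beyond the node's own
#' incident edges, e.g. redundant partner edges). Reports the bookkeeping
#' as a message.
#'
#' @param net A `phenotype_network`.
#' @param node_id Node to remove (must be present).
#' @param extra_edges Optional data frame with columns `from`, `to` naming
#'   additional undirected pairs to delete.
#' @return The reduced `phenotype_network`.
#' @export
remove_node <- function(net, node_id, extra_edges = NULL) {
  if (!node_id %in% net$nodes$id)
    stop("node not in network: ", node_id, call. = FALSE)
  n0 <- nrow(net$nodes); e0 <- nrow(net$edges)
  keep <- net$edges$from != node_id & net$edges$to != node_id
  edges <- net$edges[keep, , drop = FALSE]
  if (!is.null(extra_edges)) {
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    drop_key <- paste(pmin(extra_edges$from, extra_edges$to),
                      pmax(extra_edges$from, extra_edges$to))
    edges <- edges[!key %in% drop_key, , drop = FALSE]
  }
  nodes <- net$nodes[net$nodes$id != node_id, , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  out <- new_phenotype_network(nodes, edges)
  message(sprintf("removed %s: %d -> %d nodes, %d -> %d edge records",
                  node_id, n0, nrow(nodes), e0, nrow(edges)))
  out
}

pn_igraph <- function(net, directed = FALSE) {
  igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                directed = directed,
                                vertices = net$nodes$id)
}

#' Connected components of the phenotype network
#'
#' Components over the underlying undirected adjacency, ordered by node
#' count descending, then edge-record count descending, then smallest node
#' id.
#'
#' @param net A `phenotype_network`.
#' @return List of `phenotype_network`s, largest component first.
#' @export
connected_components <- function(net) {
  if (!nrow(net$nodes)) return(list())
  g <- pn_igraph(net)
  comp <- igraph::components(g)
  membership <- comp$membership[net$nodes$id]
  nets <- lapply(seq_len(comp$no), function(k) {
    ids <- net$nodes$id[membership == k]
    subset_network(net, ids)
  })
  nn <- vapply(nets, function(x) nrow(x$nodes), integer(1))
  ne <- vapply(nets, function(x) nrow(x$edges), integer(1))
  first <- vapply(nets, function(x) min(x$nodes$id), character(1))
  nets[order(-nn, -ne, first)]
}

subset_network <- function(net, ids) {
  nodes <- net$nodes[net$nodes$id %in% ids, , drop = FALSE]
  edges <- net$edges[net$edges$from %in% ids & net$edges$to %in% ids, ,
                     drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  new_phenotype_network(nodes, edges)
}

#' Split a network into its core and shell parts
#'
#' The core network is the subgraph induced on core-role nodes (edges with
#' both endpoints core); the shell network holds every remaining edge with
#' its incident nodes. The two edge sets partition the full edge multiset.
#'
#' @param net A `phenotype_network` with roles assigned.
#' @return List with `core` and `shell`, both `phenotype_network`s.
#' @export
core_shell_split <- function(net) {
  core_ids <- net$nodes$id[net$nodes$role == "core"]
  core_edge <- net$edges$from %in% core_ids & net$edges$to %in% core_ids
  core_net <- new_phenotype_network(
    net$nodes[net$nodes$role == "core", , drop = FALSE],
    net$edges[core_edge, , drop = FALSE])
  shell_edges <- net$edges[!core_edge, , drop = FALSE]
  shell_ids <- unique(c(shell_edges$from, shell_edges$to,
                        net$nodes$id[net$nodes$role == "shell"]))
  shell_net <- new_phenotype_network(
    net$nodes[net$nodes$id %in% shell_ids, , drop = FALSE], shell_edges)
  rownames(core_net$nodes) <- rownames(core_net$edges) <- NULL
  rownames(shell_net$nodes) <- rownames(shell_net$edges) <- NULL
  list(core = core_net, shell = shell_net)
}

#' Induce a subnetwork on an annotation-term gene union
#'
#' Subgraph induced on the network nodes belonging to the union; members
#' left without edges are retained as isolates (in the full network they
#' connect through nodes outside the term union).
#'
#' @param net A `phenotype_network`.
#' @param ids Character vector, union of the selected terms' genes.
#' @return The induced `phenotype_network`.
#' @export
induce_subnetwork <- function(net, ids) {
  present <- intersect(net$nodes$id, ids)
  if (!length(present))
    warning("term union does not intersect the network", call. = FALSE)
  subset_network(net, present)
}

#' Annotate network nodes with regulation, DNA binding and drug targets
#'
#' @param net A `phenotype_network`.
#' @param calls Data frame with columns gene, final ("up"/"down"/"none")
#'   and optionally magnitude (log2 fold change); genes not listed keep
#'   regulation "none".
#' @param dna_binding Character vector of DNA-binding node ids.
#' @param drug_targets Data frame with columns drug, target.
#' @return The annotated `phenotype_network`.
#' @export
annotate_network <- function(net, calls = NULL, dna_binding = character(),
                             drug_targets = NULL) {
  nodes <- net$nodes
  if (!is.null(calls) && nrow(calls)) {
    idx <- match(nodes$id, calls$gene)
    hit <- !is.na(idx)
    nodes$regulation[hit] <- calls$final[idx[hit]]
    if ("magnitude" %in% names(calls))
      nodes$magnitude[hit] <- calls$magnitude[idx[hit]]
  }
  nodes$dna_binding <- nodes$id %in% dna_binding
  if (!is.null(drug_targets) && nrow(drug_targets)) {
    nodes$drugs <- lapply(nodes$id, function(id)
      sort(drug_targets$drug[drug_targets$target == id]))
  }
  new_phenotype_network(nodes, net$edges)
}

#' Collapse the mixed multigraph to a simple undirected graph
#'
#' Parallel records and directed records between the same node pair collapse
#' to one undirected edge; self-loops are dropped. This projection is the
#' input for topology summaries and molecular-complex detection.
#'
#' @param net A `phenotype_network`.
#' @return An undirected simple `igraph` graph carrying the node attributes.
#' @export
to_undirected_simple <- function(net) {
  e <- net$edges[net$edges$from != net$edges$to, , drop = FALSE]
  g <- igraph::graph_from_data_frame(e[, c("from", "to")], directed = FALSE,
                                     vertices = net$nodes$id)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  for (attr in c("role", "regulation", "dna_binding"))
    if (attr %in% names(net$nodes))
      g <- igraph::set_vertex_attr(g, attr,
                                   value = net$nodes[[attr]][
                                     match(igraph::V(g)$name, net$nodes$id)])
  g
}

#' Topology summary of a simple undirected graph
#'
#' Node and edge counts, degree distribution, mean local clustering
#' coefficient (degree < 2 nodes contribute 0), connected-component count
#' and density.
#'
#' @param g An undirected simple `igraph` graph.
#' @return List with n_nodes, n_edges, degree (named vector),
#'   mean_clustering, n_components, density.
#' @export
topology_summary <- function(g) {
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  if (n == 0)
    return(list(n_nodes = 0L, n_edges = 0L, degree = integer(0),
                mean_clustering = 0, n_components = 0L, density = 0))
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[is.na(cc)] <- 0
  list(n_nodes = n, n_edges = m,
       degree = stats::setNames(igraph::degree(g), igraph::V(g)$name),
       mean_clustering = mean(cc),
       n_components = as.integer(igraph::components(g)$no),
       density = if (n > 1) 2 * m / (n * (n - 1)) else 0)
}
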