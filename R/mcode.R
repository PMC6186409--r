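#' Parameters for molecular-complex detection
#'
#' Defaults follow the documented MCODE v1.5.1 defaults: degree cutoff 2,
#' node score cutoff 0.2, k-core filter 2, haircut on, fluff off.
#'
#' @param degree_cutoff Minimum degree for a node to be scored (>= 2).
#' @param node_score_cutoff Fraction in [0, 1); a neighbor joins a complex
#'   when its weight is >= seed weight x (1 - node_score_cutoff).
#' @param k_core_filter Complexes not containing a k-core of this order are
#'   discarded.
#' @param haircut Iteratively remove complex members with intra-complex
#'   degree < 2.
#' @param fluff Add boundary neighbors whose closed-neighborhood density
#'   exceeds `fluff_density` (complexes may then overlap).
#' @param fluff_density Density threshold for fluff.
#' @param max_depth Maximum expansion distance from the seed node.
#' @return Object of class `mcode_params`.
#' @export
mcode_params <- function(degree_cutoff = 2L, node_score_cutoff = 0.2,
                         k_core_filter = 2L, haircut = TRUE, fluff = FALSE,
                         fluff_density = 0.1, max_depth = 100L) {
  stopifnot(degree_cutoff >= 2, node_score_cutoff >= 0,
            node_score_cutoff < 1, k_core_filter >= 0, max_depth >= 1)
  structure(list(degree_cutoff = as.integer(degree_cutoff),
                 node_score_cutoff = node_score_cutoff,
                 k_core_filter = as.integer(k_core_filter),
                 haircut = haircut, fluff = fluff,
                 fluff_density = fluff_density,
                 max_depth = as.integer(max_depth)),
            class = "mcode_params")
}

graph_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' MCODE vertex weights (core-clustering coefficient x k)
#'
#' For each vertex v, take the closed neighborhood N[v], find its highest
#' k-core, and set w(v) = k x density of that k-core (density = 2E/(n(n-1)),
#' loops excluded). Vertices with degree below the degree cutoff — and
#' isolated vertices — get weight 0.
#'
#' @param g Simple undirected `igraph` graph.
#' @param degree_cutoff Minimum degree to receive a non-zero weight.
#' @return Named numeric vector of weights.
#' @export
ensure_named <- function(g) {
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  g
}

mcode_vertex_weights <- function(g, degree_cutoff = 2L) {
  stopifnot(!igraph::is_directed(g))
  g <- ensure_named(g)
  vs <- igraph::V(g)$name
  deg <- igraph::degree(g)
  w <- stats::setNames(numeric(length(vs)), vs)
  for (v in vs) {
    if (deg[v] < degree_cutoff) next
    nb <- c(v, igraph::neighbors(g, v)$name)
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    k <- max(core)
    if (k == 0) next
    kcore <- igraph::induced_subgraph(sub, names(core)[core >= k])
    w[v] <- k * graph_density(kcore)
  }
  w
}

#' Molecular-complex detection by weighted greedy expansion
#'
#' Seeds are unvisited vertices in decreasing weight order (ties by vertex
#' id). From each seed, a breadth-limited greedy expansion adds unvisited
#' neighbors whose weight is at least seed weight x (1 - node_score_cutoff);
#' every included vertex is marked visited and excluded from later seeds.
#' Complexes that do not contain a `k_core_filter`-core are discarded.
#' Post-processing (haircut, optionally fluff) then prunes or pads the
#' complexes. Complex score = density x size, recomputed from the final
#' node set; complexes are sorted by score descending (ties by size, then
#' smallest member id).
#'
#' @param g Simple undirected `igraph` graph.
#' @param params An [mcode_params()] object.
#' @return List of complexes, each a list with `nodes`, `seed`, `score`,
#'   `n_edges`.
#' @export
find_complexes <- function(g, params = mcode_params()) {
  g <- ensure_named(g)
  w <- mcode_vertex_weights(g, params$degree_cutoff)
  if (!length(w)) return(list())
  order_ids <- names(sort(w, decreasing = TRUE))
  # stable tie-break by id within equal weights
  order_ids <- order_ids[order(-w[order_ids], order_ids)]
  visited <- stats::setNames(logical(length(w)), names(w))
  clusters <- list()
  for (seed in order_ids) {
    if (visited[seed] || w[seed] <= 0) next
    threshold <- w[seed] * (1 - params$node_score_cutoff)
    members <- seed
    visited[seed] <- TRUE
    frontier <- seed
    depth <- 0L
    while (length(frontier) && depth < params$max_depth) {
      nxt <- character(0)
      for (u in frontier) {
        for (nb in igraph::neighbors(g, u)$name) {
          if (!visited[nb] && w[nb] >= threshold) {
            visited[nb] <- TRUE
            members <- c(members, nb)
            nxt <- c(nxt, nb)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    sub <- igraph::induced_subgraph(g, members)
    if (params$k_core_filter > 0 &&
        max(igraph::coreness(sub)) < params$k_core_filter) next
    clusters[[length(clusters) + 1L]] <- list(nodes = sort(members),
                                              seed = seed)
  }
  postprocess_complexes(g, clusters, params)
}

#' Post-process complexes (haircut / fluff) and recompute scores
#'
#' @param g The graph the complexes were found in.
#' @param clusters List of complexes (lists with at least `nodes`, `seed`).
#' @param params An [mcode_params()] object.
#' @return The processed, score-sorted complex list.
#' @export
postprocess_complexes <- function(g, clusters, params = mcode_params()) {
  out <- list()
  for (cl in clusters) {
    nodes <- cl$nodes
    if (params$haircut) {
      repeat {
        sub <- igraph::induced_subgraph(g, nodes)
        d <- igraph::degree(sub)
        bad <- names(d)[d < 2]
        if (!length(bad) || length(nodes) <= 2) break
        nodes <- setdiff(nodes, bad)
        if (!length(nodes)) break
      }
    }
    if (params$fluff && length(nodes)) {
      boundary <- setdiff(unique(unlist(lapply(nodes, function(u)
        igraph::neighbors(g, u)$name))), nodes)
      add <- boundary[vapply(boundary, function(u) {
        nb <- c(u, igraph::neighbors(g, u)$name)
        graph_density(igraph::induced_subgraph(g, nb)) > params$fluff_density
      }, logical(1))]
      nodes <- sort(c(nodes, add))
    }
    if (length(nodes) < 2) next
    sub <- igraph::induced_subgraph(g, nodes)
    score <- graph_density(sub) * length(nodes)
    out[[length(out) + 1L]] <- list(nodes = sort(nodes), seed = cl$seed,
                                    score = score,
                                    n_edges = igraph::ecount(sub))
  }
  if (!length(out)) return(out)
  sz <- vapply(out, function(x) length(x$nodes), integer(1))
  sc <- vapply(out, function(x) x$score, numeric(1))
  first <- vapply(out, function(x) x$nodes[1], character(1))
  out[order(-sc, -sz, first)]
}

#' Write a complex report TSV
#'
#' One row per complex: id, node and edge counts, member list, and counts
#' of differentially regulated members and of core-role members (when the
#' graph carries `regulation` / `role` vertex attributes).
#'
#' @param clusters Complex list from [find_complexes()].
#' @param g The graph (for vertex attributes).
#' @param path Output file path.
#' @export
write_cluster_tsv <- function(clusters, g, path) {
  reg <- igraph::vertex_attr(g, "regulation")
  role <- igraph::vertex_attr(g, "role")
  if (!is.null(reg)) names(reg) <- igraph::V(g)$name
  if (!is.null(role)) names(role) <- igraph::V(g)$name
  rows <- lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    data.frame(cluster = i, n_nodes = length(cl$nodes),
               n_edges = cl$n_edges, score = cl$score,
               nodes = paste(cl$nodes, collapse = ","),
               n_up = if (is.null(reg)) NA else sum(reg[cl$nodes] == "up"),
               n_down = if (is.null(reg)) NA else sum(reg[cl$nodes] == "down"),
               n_core = if (is.null(role)) NA else sum(role[cl$nodes] == "core"),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(), n_nodes = integer(), n_edges = integer(),
               score = numeric(), nodes = character(), n_up = integer(),
               n_down = integer(), n_core = integer())
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
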