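#' S-list: a pathway's genes restricted to the measurable platform union
#'
#' @param term_genes Character vector, the pathway's gene set.
#' @param platform_union Character vector, union of genes measurable on the
#'   study's platforms.
#' @return Character vector (sorted intersection).
#' @export
compute_s_list <- function(term_genes, platform_union) {
  sort(intersect(term_genes, platform_union))
}

#' Shared differentially expressed genes of two S-lists
#'
#' @param s_list_a,s_list_b Character vectors (S-lists of two pathways).
#' @param up,down Disjoint character vectors of up-/downregulated genes.
#' @return List with `n_up`, `n_down`, `shared_up`, `shared_down`.
#' @export
shared_deg_counts <- function(s_list_a, s_list_b, up, down) {
  if (length(intersect(up, down)))
    stop("up and down gene lists overlap", call. = FALSE)
  both <- intersect(s_list_a, s_list_b)
  shared_up <- sort(intersect(both, up))
  shared_down <- sort(intersect(both, down))
  list(n_up = length(shared_up), n_down = length(shared_down),
       shared_up = shared_up, shared_down = shared_down)
}

#' Pathway-overlap network from shared differentially expressed genes
#'
#' Candidate pairs are all unordered pairs of distinct catalog terms with at
#' least one process-tagged member (process-process pairs qualify). A pair
#' becomes an edge iff its S-lists share at least `min_shared` upregulated
#' genes OR at least `min_shared` downregulated genes. Node size is the full
#' pathway gene count (platform-restricted size available via
#' `node_size = "s_list"`).
#'
#' @param catalog A `gene_set_catalog`, already category-filtered; its
#'   `meta$functional_tag` supplies the process/signaling/other tags.
#' @param up,down Disjoint up-/downregulated gene vectors.
#' @param platform_union Measurable-gene union used to form S-lists.
#' @param min_shared Minimum shared up or down genes for an edge (default 5).
#' @param node_size `"pathway"` (default, full gene count) or `"s_list"`.
#' @return Object of class `overlap_network`: list with `nodes` (data.frame:
#'   id, tag, size) and `edges` (data.frame: a, b, n_up, n_down plus
#'   list-columns shared_up, shared_down; a < b canonical).
#' @export
build_overlap_network <- function(catalog, up, down, platform_union,
                                  min_shared = 5,
                                  node_size = c("pathway", "s_list")) {
  node_size <- match.arg(node_size)
  ids <- catalog$meta$id
  tags <- catalog$meta$functional_tag
  s_lists <- lapply(catalog$genes, compute_s_list, platform_union)
  sizes <- if (node_size == "pathway") lengths(catalog$genes) else lengths(s_lists)
  nodes <- data.frame(id = ids, tag = tags, size = as.integer(sizes),
                      stringsAsFactors = FALSE)
  if (!any(tags == "process")) {
    warning("no process-tagged terms: overlap network is empty", call. = FALSE)
    return(structure(list(nodes = nodes, edges = empty_overlap_edges()),
                     class = "overlap_network"))
  }
  rows <- list()
  n <- length(ids)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (tags[i] != "process" && tags[j] != "process") next
    sh <- shared_deg_counts(s_lists[[i]], s_lists[[j]], up, down)
    if (sh$n_up >= min_shared || sh$n_down >= min_shared) {
      a <- min(ids[i], ids[j]); b <- max(ids[i], ids[j])
      rows[[length(rows) + 1L]] <-
        data.frame(a = a, b = b, n_up = sh$n_up, n_down = sh$n_down,
                   shared_up = I(list(sh$shared_up)),
                   shared_down = I(list(sh$shared_down)),
                   stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else empty_overlap_edges()
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "overlap_network")
}

empty_overlap_edges <- function() {
  data.frame(a = character(), b = character(), n_up = integer(),
             n_down = integer(), shared_up = I(list()),
             shared_down = I(list()), stringsAsFactors = FALSE)
}

#' @export
print.overlap_network <- function(x, ...) {
  cat(sprintf("<overlap_network> %d terms, %d overlap edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Overlap partners of one pathway
#'
#' Lists the pathways sharing an overlap edge with `term`, sorted by total
#' shared DEG count descending (ties by partner id), with each partner's
#' functional tag — the data behind per-pathway overlap bar charts.
#'
#' @param term Term id present in the network.
#' @param network An `overlap_network`.
#' @return Data frame: partner, n_up, n_down, partner_tag.
#' @export
partner_profile <- function(term, network) {
  if (!term %in% network$nodes$id)
    stop("term not in network: ", term, call. = FALSE)
  e <- network$edges
  hit <- e$a == term | e$b == term
  partner <- ifelse(e$a[hit] == term, e$b[hit], e$a[hit])
  out <- data.frame(partner = partner, n_up = e$n_up[hit],
                    n_down = e$n_down[hit],
                    partner_tag = network$nodes$tag[match(partner,
                                                          network$nodes$id)],
                    stringsAsFactors = FALSE)
  out <- out[order(-(out$n_up + out$n_down), out$partner), , drop = FALSE]
  rownames(out) <- NULL
  out
}
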