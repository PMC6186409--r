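# Shared fixtures and independent oracles used across test files.

# Brute-force hypergeometric upper tail by combinatorial summation
# (log-space so large binomial coefficients do not overflow).
brute_hyper_tail <- function(count, list_total, pop_hits, pop_total) {
  if (count <= 0) return(1)
  ks <- count:min(list_total, pop_hits)
  terms <- lchoose(pop_hits, ks) +
    lchoose(pop_total - pop_hits, list_total - ks) -
    lchoose(pop_total, list_total)
  sum(exp(terms))
}

# Literal interpreter of the cross-dataset selection rules, working from the
# per-dataset (rma, mas5) call pairs rather than from grades.
# up iff: some dataset is (+,+), or one dataset is (+,0) and a different
# dataset is (0,+) -- and no dataset shows any "-" call; down mirrored.
brute_consensus <- function(pairs) {
  pairs <- Filter(function(p) !identical(p, "unmeasured"), pairs)
  if (!length(pairs)) stop("all unmeasured")
  rma <- vapply(pairs, `[`, character(1), 1)
  mas <- vapply(pairs, `[`, character(1), 2)
  mas[mas == "filtered"] <- "0"
  any_minus <- any(rma == "-") || any(mas == "-")
  any_plus <- any(rma == "+") || any(mas == "+")
  up <- !any_minus &&
    (any(rma == "+" & mas == "+") ||
       (any(rma == "+" & mas == "0") && any(rma == "0" & mas == "+")))
  down <- !any_plus &&
    (any(rma == "-" & mas == "-") ||
       (any(rma == "-" & mas == "0") && any(rma == "0" & mas == "-")))
  if (up) "up" else if (down) "down" else "none"
}

# Map a per-dataset call pair to the package's grade alphabet.
pair_to_grade <- function(p) {
  if (identical(p, "unmeasured")) return("unmeasured")
  dataset_consensus(p[1], p[2])
}

# Tiny phenotype network built directly from an interaction table.
toy_records <- function(a, b, kind = "binding", direction = "none",
                        score = 0.95, evidence = "experimental") {
  data.frame(node_a = a, node_b = b, kind = kind, direction = direction,
             score = score, evidence = evidence, stringsAsFactors = FALSE)
}

# igraph helpers for MCODE tests
complete_graph <- function(ids) {
  pairs <- utils::combn(ids, 2)
  igraph::graph_from_data_frame(
    data.frame(from = pairs[1, ], to = pairs[2, ]),
    directed = FALSE, vertices = ids)
}

edge_graph <- function(from, to, vertices = NULL) {
  igraph::graph_from_data_frame(data.frame(from = from, to = to),
                                directed = FALSE, vertices = vertices)
}
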