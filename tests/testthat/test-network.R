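test_that("interaction filter keeps qualifying records only (inclusive score)", {
  rec <- toy_records(c("A", "A", "A"), c("B", "C", "D"),
                     score = c(0.9, 0.89, 0.95),
                     evidence = c("experimental", "experimental", "other"))
  out <- filter_interactions(rec)
  expect_identical(out$node_b, "B")
  expect_identical(nrow(filter_interactions(rec, required_evidence = NULL)),
                   2L)
})

test_that("assembly takes the core plus first shell and their mutual edges", {
  rec <- toy_records(c("A", "B", "C"), c("B", "C", "D"))
  net <- assemble_network("A", rec)
  expect_setequal(net$nodes$id, c("A", "B"))
  expect_identical(nrow(net$edges), 1L)
  expect_identical(net$nodes$role, c("core", "shell"))

  # no qualifying records: isolated core nodes survive
  empty <- assemble_network(c("A", "B"), rec[0, ])
  expect_identical(nrow(empty$edges), 0L)
  expect_setequal(empty$nodes$id, c("A", "B"))

  both_core <- assemble_network(c("A", "B"), toy_records("A", "B"))
  expect_identical(both_core$nodes$role, c("core", "core"))
  expect_identical(nrow(both_core$edges), 1L)
  expect_error(assemble_network(character(0), rec), "empty")
})

test_that("assembly is idempotent and every shell node touches the core", {
  set.seed(17)
  core <- sprintf("c%02d", 1:6)
  sim <- simulate_interactome(core, n_shell = 25, background_edge_prob = 0.05,
                              complexes = list(c(5, 1)), hub_degree = 8,
                              seed = 17)
  rec <- filter_interactions(sim$interactions)
  net <- assemble_network(core, rec)
  again <- assemble_network(core, net$edges)
  expect_identical(net$nodes, again$nodes)
  expect_identical(nrow(net$edges), nrow(again$edges))
  shell <- net$nodes$id[net$nodes$role == "shell"]
  for (s in shell) {
    partners <- c(net$edges$to[net$edges$from == s],
                  net$edges$from[net$edges$to == s])
    expect_true(any(partners %in% core), info = s)
  }
})

test_that("node removal bookkeeping: incident records plus curated extras", {
  rec <- toy_records(c("H", "H", "H", "A", "B"), c("A", "B", "C", "B", "C"))
  net <- assemble_network(c("H", "A", "B", "C"), rec)
  expect_identical(nrow(net$edges), 5L)
  out <- suppressMessages(remove_node(net, "H"))
  expect_identical(nrow(out$edges), 2L)
  expect_false("H" %in% out$nodes$id)
  out2 <- suppressMessages(remove_node(net, "H",
                                       extra_edges = data.frame(from = "B",
                                                                to = "A")))
  expect_identical(nrow(out2$edges), 1L)
  # removing an isolate leaves the edge count unchanged
  iso <- assemble_network(c("A", "B", "Z"), toy_records("A", "B"))
  expect_identical(nrow(suppressMessages(remove_node(iso, "Z"))$edges), 1L)
  expect_error(remove_node(net, "nope"), "not in network")
})

test_that("components are ordered largest-first and partition nodes and edges", {
  rec <- toy_records(c("A", "B", "C", "P", "X", "m1", "m2", "m3"),
                     c("B", "C", "D", "Q", "Y", "m2", "m3", "m4"))
  net <- assemble_network(c("A", "C", "P", "X", "m1", "m3"), rec)
  comps <- connected_components(net)
  expect_length(comps, 4)
  sizes <- vapply(comps, function(x) nrow(x$nodes), integer(1))
  expect_identical(sizes, c(4L, 4L, 2L, 2L))
  expect_identical(sum(sizes), nrow(net$nodes))
  expect_identical(sum(vapply(comps, function(x) nrow(x$edges), integer(1))),
                   nrow(net$edges))
  # tie among the two 4-node components broken by edge count then id
  expect_true(comps[[1]]$nodes$id[1] <= comps[[2]]$nodes$id[1] ||
                nrow(comps[[1]]$edges) >= nrow(comps[[2]]$edges))
})

test_that("core/shell split partitions the edge multiset", {
  rec <- toy_records(c("c1", "c2", "c1", "c2", "c3"),
                     c("c2", "c3", "s1", "s1", "s2"))
  net <- assemble_network(c("c1", "c2", "c3"), rec)
  split <- core_shell_split(net)
  expect_identical(nrow(split$core$edges), 2L)
  expect_identical(nrow(split$shell$edges), 3L)
  expect_identical(nrow(split$core$edges) + nrow(split$shell$edges),
                   nrow(net$edges))
  all_core <- core_shell_split(assemble_network(c("A", "B"),
                                                toy_records("A", "B")))
  expect_identical(nrow(all_core$shell$edges), 0L)
})

test_that("term-induced subnetworks keep isolated members", {
  rec <- toy_records(c("n1", "n2", "n3", "n4"), c("n2", "n3", "n4", "n5"))
  net <- assemble_network(c("n1", "n3", "n5"), rec)  # 5-node path
  sub <- induce_subnetwork(net, c("n1", "n5"))
  expect_setequal(sub$nodes$id, c("n1", "n5"))
  expect_identical(nrow(sub$edges), 0L)
  expect_identical(induce_subnetwork(net, net$nodes$id)$nodes, net$nodes)
  expect_warning(empty <- induce_subnetwork(net, "zz"), "intersect")
  expect_identical(nrow(empty$nodes), 0L)
})

test_that("annotation fills regulation, magnitude, DNA binding and drugs", {
  net <- assemble_network("A", toy_records("A", "B"))
  calls <- data.frame(gene = "B", final = "up", magnitude = 3.32)
  ann <- annotate_network(net, calls, dna_binding = "A",
                          drug_targets = data.frame(drug = "drugX",
                                                    target = "A"))
  expect_identical(ann$nodes$regulation[ann$nodes$id == "B"], "up")
  expect_equal(ann$nodes$magnitude[ann$nodes$id == "B"], 3.32)
  expect_identical(ann$nodes$regulation[ann$nodes$id == "A"], "none")
  expect_true(ann$nodes$dna_binding[ann$nodes$id == "A"])
  expect_identical(ann$nodes$drugs[[which(ann$nodes$id == "A")]], "drugX")
  plain <- annotate_network(net, NULL)
  expect_true(all(plain$nodes$regulation == "none"))
})

test_that("undirected simplification collapses parallel and directed records", {
  rec <- data.frame(node_a = c("A", "A", "B", "B", "C"),
                    node_b = c("B", "B", "C", "C", "A"),
                    kind = c("binding", "activation", "binding", "inhibition",
                             "binding"),
                    direction = c("none", "ab", "none", "ba", "none"),
                    score = 0.95, evidence = "experimental",
                    stringsAsFactors = FALSE)
  net <- assemble_network(c("A", "B", "C"), rec)
  g <- to_undirected_simple(net)
  expect_identical(igraph::ecount(g), 3)
  expect_lte(igraph::ecount(g), nrow(net$edges))
  expect_identical(igraph::vertex_attr(g, "role"),
                   rep("core", 3))
})

test_that("topology summary matches hand computation on small graphs", {
  k4 <- complete_graph(c("a", "b", "c", "d"))
  ts <- topology_summary(k4)
  expect_equal(ts$density, 1)
  expect_equal(ts$mean_clustering, 1)
  expect_identical(ts$n_components, 1L)

  empty <- igraph::make_empty_graph(0, directed = FALSE)
  tse <- topology_summary(empty)
  expect_identical(tse$n_nodes, 0L)
  expect_equal(tse$density, 0)

  # triangle plus pendant: by hand, local cc = (1, 1, 1/3, 0), density 4/6
  g <- edge_graph(c("a", "b", "c", "c"), c("b", "c", "a", "d"))
  tg <- topology_summary(g)
  expect_equal(tg$mean_clustering, mean(c(1, 1, 1 / 3, 0)))
  expect_equal(tg$density, 2 * 4 / (4 * 3))
  expect_identical(unname(tg$degree[order(names(tg$degree))]),
                   c(2, 2, 3, 1))
})
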