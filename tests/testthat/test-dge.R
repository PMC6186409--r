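test_that("Welch statistic, df and p match the closed form and stats::t.test", {
  w <- welch_test(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_equal(w$t, -1.732051, tolerance = 1e-6)
  expect_equal(w$df, 4.411765, tolerance = 1e-6)
  ref <- t.test(c(1, 2, 3, 4), c(2, 4, 6, 8), var.equal = FALSE)
  expect_equal(w$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(w$p, ref$p.value, tolerance = 1e-12)

  same <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)

  # antisymmetry under group swap
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(5); y <- rnorm(7)
    expect_equal(welch_test(x, y)$t, -welch_test(y, x)$t, tolerance = 1e-12)
  }

  expect_warning(wz <- welch_test(c(1, 1, 1), c(2, 2, 2)), "zero pooled")
  expect_true(wz$p > 0 && wz$p < 1e-100)
})

test_that("fold change follows the case/control orientation on both scales", {
  expect_equal(linear_fold_change(c(40, 40), c(10, 10), "linear"), 4)
  expect_equal(linear_fold_change(c(5, 5), c(5, 5), "linear"), 1)
  expect_equal(linear_fold_change(c(3, 3), c(1, 1), "log2"), 4)
  x <- c(2, 6, 4); y <- c(1, 3, 8)
  expect_equal(linear_fold_change(x, y, "linear") *
                 linear_fold_change(y, x, "linear"), 1, tolerance = 1e-12)
  expect_error(linear_fold_change(c(-1, 2), c(1, 1), "linear"), "positive")
})

test_that("present-call filter demands a P in each group", {
  vals <- matrix(2, 3, 4, dimnames = list(c("gA", "gB", "gC"),
                                          paste0("s", 1:4)))
  det <- matrix("A", 3, 4, dimnames = dimnames(vals))
  det["gA", ] <- c("P", "A", "P", "A")   # P in both groups -> retained
  det["gB", ] <- c("P", "P", "A", "A")   # P only in cases -> excluded
  ds <- expression_dataset("d", "mas5-like", vals,
                           c("case", "case", "control", "control"), det)
  expect_identical(detection_filter(ds), "gA")
  det[] <- "A"
  ds_all_absent <- expression_dataset("d", "mas5-like", vals,
                                      c("case", "case", "control", "control"),
                                      det)
  expect_length(detection_filter(ds_all_absent), 0)
})

test_that("three-state call uses inclusive thresholds in both directions", {
  expect_identical(per_gene_call(2.0, 0.05), "+")
  expect_identical(per_gene_call(0.5, 0.04), "-")
  expect_identical(per_gene_call(3.0, 0.2), "0")
  expect_identical(per_gene_call(1.99, 0.01), "0")
  expect_identical(per_gene_call(0.5, 0.05), "-")
})

test_that("within-dataset grades combine the two routes as specified", {
  expect_identical(dataset_consensus("+", "+"), "U2")
  expect_identical(dataset_consensus("0", "+"), "U1M")
  expect_identical(dataset_consensus("+", "0"), "U1R")
  expect_identical(dataset_consensus("-", "-"), "D2")
  expect_identical(dataset_consensus("0", "0"), "none")
  expect_identical(dataset_consensus("+", "-"), "conflict")
  expect_identical(dataset_consensus("-", "+"), "conflict")
  # filtered mas5 route is treated as "0": the rma route still speaks
  expect_identical(dataset_consensus("+", "filtered"), "U1R")
  expect_identical(dataset_consensus("0", "filtered"), "none")
})

test_that("cross-dataset consensus matches its quoted-rule examples", {
  expect_identical(cross_dataset_consensus(c("U2", "none", "none")), "up")
  expect_identical(cross_dataset_consensus(c("U1R", "U1M")), "up")
  expect_identical(cross_dataset_consensus(c("U2", "D1R")), "none")
  expect_identical(cross_dataset_consensus(c("U1R", "U1R")), "none")
  expect_identical(cross_dataset_consensus(c("D2", "unmeasured")), "down")
  expect_identical(cross_dataset_consensus(c("conflict", "U2")), "none")
  expect_error(cross_dataset_consensus(c("unmeasured", "unmeasured")),
               "unmeasured")
})

test_that("consensus equals the literal rule interpreter over all call-pair combinations", {
  pair_space <- c(list("unmeasured"),
                  unlist(lapply(c("+", "0", "-"), function(r)
                    lapply(c("+", "0", "-", "filtered"), function(m)
                      c(r, m))), recursive = FALSE))
  # all combinations for 2 datasets, and a subsample check for 3
  idx <- seq_along(pair_space)
  for (i in idx) for (j in idx) {
    pairs <- list(pair_space[[i]], pair_space[[j]])
    grades <- vapply(pairs, pair_to_grade, character(1))
    if (all(grades == "unmeasured")) next
    expect_identical(cross_dataset_consensus(grades), brute_consensus(pairs),
                     info = paste(unlist(pairs), collapse = "|"))
  }
  set.seed(7)
  for (rep in 1:300) {
    pairs <- pair_space[sample(idx, 3, replace = TRUE)]
    grades <- vapply(pairs, pair_to_grade, character(1))
    if (all(grades == "unmeasured")) next
    expect_identical(cross_dataset_consensus(grades), brute_consensus(pairs),
                     info = paste(unlist(pairs), collapse = "|"))
  }
})

test_that("consensus is order-invariant and diluted monotonically", {
  set.seed(3)
  grades_pool <- c("U2", "U1R", "U1M", "D2", "D1R", "D1M", "none",
                   "conflict", "unmeasured")
  for (rep in 1:50) {
    g <- sample(grades_pool, 4, replace = TRUE)
    if (all(g == "unmeasured")) next
    expect_identical(cross_dataset_consensus(g),
                     cross_dataset_consensus(sample(g)))
    expect_identical(cross_dataset_consensus(c(g, "none")),
                     cross_dataset_consensus(g))
  }
  expect_identical(cross_dataset_consensus(c("U2", "D1R")), "none")
})

test_that("probe collapse keeps any-up-no-down genes and drops unmapped probes", {
  map <- data.frame(probe = c("p1", "p2", "p3", "p4"),
                    gene = c("gA", "gA", "gB", "gB"))
  calls <- c(p1 = "+", p2 = "0", p3 = "+", p4 = "-", p5 = "+")
  out <- collapse_probes_to_gene(calls, map)
  expect_identical(out[["gA"]], "+")
  expect_identical(out[["gB"]], "0")
  expect_false("p5" %in% names(out))
  bad_map <- rbind(map, data.frame(probe = "p1", gene = "gC"))
  expect_error(collapse_probes_to_gene(calls, bad_map), "multiple")
})

test_that("planted study is recovered with high sensitivity and few false calls", {
  cfg <- study_config(n_genes = 2000, n_datasets = 3,
                      samples_per_group = list(c(5L, 5L)),
                      platform_coverage = 1.0, effect_log2 = 2,
                      base_sd_log2 = 0.5, seed = 1)
  sim <- simulate_expression_studies(cfg)
  deg <- call_degs(sim$datasets)
  up <- deg$calls$gene[deg$calls$final == "up"]
  down <- deg$calls$gene[deg$calls$final == "down"]
  expect_gte(mean(sim$truth$true_up %in% up), 0.90)
  expect_lte(mean(!(up %in% sim$truth$true_up)), 0.10)
  expect_gte(mean(sim$truth$true_down %in% down), 0.90)
})

test_that("stringency counts reduce to the consensus at k = 1 and never increase in k", {
  cfg <- study_config(n_genes = 500, n_datasets = 3, seed = 4)
  sim <- simulate_expression_studies(cfg)
  deg <- call_degs(sim$datasets)
  k1 <- stringency_counts(deg, 1)
  expect_identical(unname(k1["n_up"]), sum(deg$calls$final == "up"))
  expect_identical(unname(k1["n_down"]), sum(deg$calls$final == "down"))
  prev <- k1
  for (k in 2:3) {
    cur <- stringency_counts(deg, k)
    expect_lte(cur["n_up"], prev["n_up"])
    expect_lte(cur["n_down"], prev["n_down"])
    prev <- cur
  }
  expect_identical(stringency_counts(deg, 4), c(n_up = 0L, n_down = 0L))
  # planted genes measured everywhere with a strong effect stay selected at
  # full stringency
  k3 <- stringency_counts(deg, 3)
  expect_gt(k3["n_up"], 0)
})

test_that("swapping case/control labels maps up calls onto down calls", {
  cfg <- study_config(n_genes = 300, n_datasets = 2, seed = 6)
  sim <- simulate_expression_studies(cfg)
  flip <- function(ds) {
    g <- unname(ifelse(ds$groups == "case", "control", "case"))
    expression_dataset(ds$dataset_id, ds$view, ds$values, g, ds$detection)
  }
  flipped <- lapply(sim$datasets, function(d)
    list(rma = flip(d$rma), mas5 = flip(d$mas5)))
  a <- call_degs(sim$datasets)
  b <- call_degs(flipped)
  expect_identical(a$calls$gene[a$calls$final == "up"],
                   b$calls$gene[b$calls$final == "down"])
  expect_identical(a$calls$gene[a$calls$final == "down"],
                   b$calls$gene[b$calls$final == "up"])
})
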