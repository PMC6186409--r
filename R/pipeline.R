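#' Pipeline configuration
#'
#' Collects the thresholds and generator settings of a full synthetic run.
#' Every threshold defaults to the study values: fold change 2, p 0.05,
#' EASE 0.05, fold enrichment 1.5, minimum shared DEGs 5, minimum
#' interaction score 0.9.
#'
#' @param study A [study_config()] for the expression simulator.
#' @param fc_cut,p_cut Differential-call thresholds.
#' @param ease_cut,fe_cut Enrichment thresholds.
#' @param min_shared Overlap-edge threshold.
#' @param min_score Interaction-score threshold.
#' @param background Background convention for enrichment ("annotated" or
#'   "full-universe").
#' @param mcode An [mcode_params()] object.
#' @param catalog_sets,catalog_size Number and size range of simulated
#'   catalog sets.
#' @param n_planted_sets Number of catalog sets planted with true up-genes.
#' @param n_shell,background_edge_prob,complexes,hub_degree Interactome
#'   generator settings (see [simulate_interactome()]).
#' @param stages Character vector of stages to run, a subset of
#'   `c("dge", "enrichment", "overlap", "network", "mcode")` (each stage
#'   requires its predecessors).
#' @param seed Master seed; all stage seeds derive from it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(study = study_config(seed = seed),
                            fc_cut = 2, p_cut = 0.05, ease_cut = 0.05,
                            fe_cut = 1.5, min_shared = 5, min_score = 0.9,
                            background = "annotated",
                            mcode = mcode_params(),
                            catalog_sets = 12L, catalog_size = c(30L, 80L),
                            n_planted_sets = 3L,
                            n_shell = 60L, background_edge_prob = 0.02,
                            complexes = list(c(8, 1.0)), hub_degree = 20L,
                            stages = c("dge", "enrichment", "overlap",
                                       "network", "mcode"),
                            seed = 1L) {
  structure(list(study = study, fc_cut = fc_cut, p_cut = p_cut,
                 ease_cut = ease_cut, fe_cut = fe_cut,
                 min_shared = min_shared, min_score = min_score,
                 background = background, mcode = mcode,
                 catalog_sets = as.integer(catalog_sets),
                 catalog_size = as.integer(catalog_size),
                 n_planted_sets = as.integer(n_planted_sets),
                 n_shell = as.integer(n_shell),
                 background_edge_prob = background_edge_prob,
                 complexes = complexes, hub_degree = as.integer(hub_degree),
                 stages = stages, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; a `study` block
#' mirrors [study_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  study_args <- y$study %||% list()
  if (!is.null(y$seed) && is.null(study_args$seed))
    study_args$seed <- y$seed
  if (!is.null(study_args$samples_per_group))
    study_args$samples_per_group <- lapply(study_args$samples_per_group,
                                           as.integer)
  y$study <- do.call(study_config, study_args)
  if (!is.null(y$mcode)) y$mcode <- do.call(mcode_params, y$mcode)
  if (!is.null(y$complexes)) y$complexes <- lapply(y$complexes, unlist)
  do.call(pipeline_config, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic pipeline
#'
#' Executes the stages in order — differential expression, enrichment,
#' pathway overlap, core/shell network assembly (with hub removal and
#' component pruning), molecular-complex detection — writing every
#' intermediate table plus a JSON manifest of counts to `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created if needed).
#' @return Invisibly, a list with the manifest and the in-memory stage
#'   results.
#' @export
run_pipeline <- function(config, out_dir = tempfile("phenonet_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config_echo(config))
  results <- list()
  stages <- config$stages

  sim <- simulate_expression_studies(config$study)
  results$sim <- sim
  universe <- sort(unique(unlist(lapply(sim$datasets, function(d)
    rownames(d$rma$values)))))

  if ("dge" %in% stages) {
    deg <- call_degs(sim$datasets, config$fc_cut, config$p_cut)
    results$deg <- deg
    up <- deg$calls$gene[deg$calls$final == "up"]
    down <- deg$calls$gene[deg$calls$final == "down"]
    manifest$n_up <- length(up)
    manifest$n_down <- length(down)
    utils::write.table(cbind(deg$calls, deg$grades),
                       file.path(out_dir, "consensus_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    message(sprintf("dge: %d up, %d down of %d genes", length(up),
                    length(down), nrow(deg$calls)))
  }

  if ("enrichment" %in% stages) {
    cat_sim <- simulate_catalog(
      universe, n_sets = config$catalog_sets,
      size_range = config$catalog_size,
      n_categories_map = c("immune system" = config$catalog_sets),
      planted = sprintf("set%02d", seq_len(config$n_planted_sets)),
      truth_up = sim$truth$true_up,
      seed = config$seed + 1L)
    results$catalog <- cat_sim$catalog
    results$catalog_truth <- cat_sim$truth
    enr_up <- enrich_gene_list(up, cat_sim$catalog, universe,
                               config$ease_cut, config$fe_cut,
                               config$background)
    enr_down <- enrich_gene_list(down, cat_sim$catalog, universe,
                                 config$ease_cut, config$fe_cut,
                                 config$background)
    results$enrichment <- list(up = enr_up, down = enr_down)
    manifest$n_enriched_up <- sum(enr_up$enriched)
    manifest$n_enriched_down <- sum(enr_down$enriched)
    write_enrichment_tsv(enr_up, file.path(out_dir, "enrichment_up.tsv"))
    write_enrichment_tsv(enr_down, file.path(out_dir, "enrichment_down.tsv"))
    message(sprintf("enrichment: %d up terms, %d down terms flagged",
                    manifest$n_enriched_up, manifest$n_enriched_down))
  }

  if ("overlap" %in% stages) {
    flt_up <- filter_pathways(results$enrichment$up[
      results$enrichment$up$enriched, , drop = FALSE], results$catalog)
    keep_ids <- union(flt_up$term, character(0))
    cat_f <- results$catalog
    sel <- cat_f$meta$id %in% keep_ids
    cat_f$meta <- cat_f$meta[sel, , drop = FALSE]
    cat_f$genes <- cat_f$genes[cat_f$meta$id]
    ovl <- suppressWarnings(build_overlap_network(cat_f, up, down, universe,
                                                  config$min_shared))
    results$overlap <- ovl
    manifest$n_overlap_edges <- nrow(ovl$edges)
    write_sif(ovl, file.path(out_dir, "overlap_network.sif"))
    message(sprintf("overlap: %d edges among %d terms",
                    nrow(ovl$edges), nrow(ovl$nodes)))
  }

  if ("network" %in% stages) {
    # core = the top-ranked enriched pathway's genes present in the universe
    core_term <- if (nrow(results$enrichment$up) &&
                     any(results$enrichment$up$enriched))
      results$enrichment$up$term[results$enrichment$up$enriched][1]
    else results$catalog$meta$id[1]
    core <- intersect(results$catalog$genes[[core_term]], universe)
    int_sim <- simulate_interactome(
      core, n_shell = config$n_shell,
      background_edge_prob = config$background_edge_prob,
      complexes = config$complexes, hub_degree = config$hub_degree,
      seed = config$seed + 2L)
    results$interactome_truth <- int_sim$truth
    write_interactions_tsv(int_sim$interactions,
                           file.path(out_dir, "interactions.tsv"))
    rec <- filter_interactions(int_sim$interactions, config$min_score)
    net <- assemble_network(core, rec)
    manifest$network_nodes_initial <- nrow(net$nodes)
    manifest$network_edges_initial <- nrow(net$edges)
    if (!is.null(int_sim$truth$hub_id) &&
        int_sim$truth$hub_id %in% net$nodes$id)
      net <- suppressMessages(remove_node(net, int_sim$truth$hub_id))
    manifest$network_nodes <- nrow(net$nodes)
    manifest$network_edges <- nrow(net$edges)
    comps <- connected_components(net)
    manifest$component_sizes <- vapply(comps, function(x) nrow(x$nodes),
                                       integer(1))
    net <- comps[[1]]
    ann <- simulate_annotations(net$nodes$id, seed = config$seed + 3L)
    net <- annotate_network(net, results$deg$calls, ann$dna_binding,
                            ann$drug_targets)
    results$network <- net
    results$annotations <- ann
    manifest$largest_component_nodes <- nrow(net$nodes)
    manifest$largest_component_edges <- nrow(net$edges)
    manifest$n_dna_binding <- sum(net$nodes$dna_binding)
    split <- core_shell_split(net)
    manifest$core_nodes <- nrow(split$core$nodes)
    manifest$core_edges <- nrow(split$core$edges)
    write_sif(net, file.path(out_dir, "phenotype_network.sif"))
    write_graphml(net, file.path(out_dir, "phenotype_network.graphml"))
    message(sprintf("network: %d nodes / %d edges (largest component)",
                    nrow(net$nodes), nrow(net$edges)))
  }

  if ("mcode" %in% stages) {
    g <- to_undirected_simple(results$network)
    clusters <- find_complexes(g, config$mcode)
    results$clusters <- clusters
    manifest$n_clusters <- length(clusters)
    write_cluster_tsv(clusters, g, file.path(out_dir, "clusters.tsv"))
    message(sprintf("mcode: %d complexes", length(clusters)))
  }

  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  invisible(list(manifest = manifest, results = results,
                 out_dir = out_dir))
}

config_echo <- function(config) {
  list(seed = config$seed, fc_cut = config$fc_cut, p_cut = config$p_cut,
       ease_cut = config$ease_cut, fe_cut = config$fe_cut,
       min_shared = config$min_shared, min_score = config$min_score,
       background = config$background,
       n_genes = config$study$n_genes,
       n_datasets = config$study$n_datasets,
       stages = config$stages)
}
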