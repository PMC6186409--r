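#' Configuration for a synthetic multi-dataset expression study
#'
#' Bundles the knobs of the synthetic-study generator. The defaults emulate a
#' small multi-platform microarray compendium: several independent two-group
#' datasets, each measured on a platform covering only part of the gene
#' universe, each summarized by two imperfectly agreeing normalization routes
#' (a log2-scale "rma-like" view and a linear-scale "mas5-like" view with
#' detection calls).
#'
#' @param n_genes Size of the gene universe (shared across datasets before
#'   platform masking).
#' @param n_datasets Number of independent two-group datasets.
#' @param samples_per_group List (one element per dataset) of integer pairs
#'   `c(cases, controls)`; recycled if a single pair is given.
#' @param platform_coverage Probability, in (0, 1], that a gene is measured by
#'   a given dataset's platform (genes are masked independently).
#' @param de_fraction_up,de_fraction_down Fractions of the universe planted as
#'   up-/downregulated; their sum must be < 1. Planted counts are
#'   `floor(n_genes * fraction)` so truth sizes are deterministic.
#' @param effect_log2 Mean log2 shift added to (up) or subtracted from (down)
#'   case samples for planted genes, in every dataset measuring them.
#' @param base_sd_log2 Within-group standard deviation of log2 expression.
#' @param norm_view_noise_sd Standard deviation of the independent log2 noise
#'   separating the mas5-like view from the rma-like view; 0 makes the two
#'   normalization routes agree perfectly.
#' @param detect_present_prob Two numbers `c(midpoint, slope)` of the logistic
#'   curve giving the probability of a present ("P") detection call as a
#'   function of a gene's within-sample expression percentile in [0, 1].
#' @param attenuation Per-dataset multiplier on `effect_log2` (recycled),
#'   modelling between-study heterogeneity of the effect; defaults to 1
#'   (no attenuation) for every dataset.
#' @param seed Integer seed; equal seeds give byte-identical output.
#'
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_genes = 2000,
                         n_datasets = 3,
                         samples_per_group = list(c(5L, 5L)),
                         platform_coverage = 1.0,
                         de_fraction_up = 0.05,
                         de_fraction_down = 0.05,
                         effect_log2 = 2,
                         base_sd_log2 = 0.5,
                         norm_view_noise_sd = 0.1,
                         detect_present_prob = c(0.25, 10),
                         attenuation = 1,
                         seed = 1L) {
  if (n_genes < 1 || n_datasets < 1)
    stop("n_genes and n_datasets must be positive", call. = FALSE)
  if (length(samples_per_group) == 1L)
    samples_per_group <- rep(samples_per_group, n_datasets)
  if (length(samples_per_group) != n_datasets)
    stop("samples_per_group must have one (cases, controls) pair per dataset",
         call. = FALSE)
  for (sp in samples_per_group)
    if (length(sp) != 2L || any(sp < 2))
      stop("each group needs at least 2 samples", call. = FALSE)
  if (platform_coverage <= 0 || platform_coverage > 1)
    stop("platform_coverage must be in (0, 1]", call. = FALSE)
  if (de_fraction_up < 0 || de_fraction_down < 0 ||
      de_fraction_up + de_fraction_down >= 1)
    stop("DE fractions must be non-negative and sum to < 1", call. = FALSE)
  if (effect_log2 <= 0 || base_sd_log2 <= 0 || norm_view_noise_sd < 0)
    stop("effect_log2, base_sd_log2 must be positive; norm_view_noise_sd >= 0",
         call. = FALSE)
  attenuation <- rep_len(attenuation, n_datasets)
  structure(list(n_genes = as.integer(n_genes),
                 n_datasets = as.integer(n_datasets),
                 samples_per_group = lapply(samples_per_group, as.integer),
                 platform_coverage = platform_coverage,
                 de_fraction_up = de_fraction_up,
                 de_fraction_down = de_fraction_down,
                 effect_log2 = effect_log2,
                 base_sd_log2 = base_sd_log2,
                 norm_view_noise_sd = norm_view_noise_sd,
                 detect_present_prob = detect_present_prob,
                 attenuation = attenuation,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Construct an expression dataset view
#'
#' One dataset under one normalization route. Views are either "rma-like"
#' (log2 scale, no detection calls) or "mas5-like" (linear scale, with a
#' parallel P/A detection-call matrix).
#'
#' @param dataset_id Dataset identifier.
#' @param view `"rma-like"` or `"mas5-like"`.
#' @param values Numeric gene x sample matrix with row and column names.
#' @param groups Character vector, one of `"case"`/`"control"` per sample,
#'   named by sample.
#' @param detection Optional character gene x sample matrix of `"P"`/`"M"`/`"A"`
#'   calls; required iff `view = "mas5-like"`.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(dataset_id, view, values, groups,
                               detection = NULL) {
  view <- match.arg(view, c("rma-like", "mas5-like"))
  scale <- if (view == "rma-like") "log2" else "linear"
  if (!is.matrix(values) || is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must be a matrix with gene rownames and sample colnames",
         call. = FALSE)
  if (length(groups) != ncol(values) || !all(groups %in% c("case", "control")))
    stop("groups must label every sample as case or control", call. = FALSE)
  if (min(table(factor(groups, c("case", "control")))) < 2)
    stop("need at least 2 samples per group", call. = FALSE)
  if (scale == "linear" && any(values <= 0))
    stop("linear-scale values must be positive", call. = FALSE)
  if (view == "mas5-like") {
    if (is.null(detection)) stop("mas5-like view requires detection calls",
                                 call. = FALSE)
    stopifnot(identical(dim(detection), dim(values)))
  } else if (!is.null(detection)) {
    stop("rma-like view carries no detection calls", call. = FALSE)
  }
  names(groups) <- colnames(values)
  structure(list(dataset_id = dataset_id, view = view, values = values,
                 scale = scale, groups = groups, detection = detection),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %s [%s, %s] %d genes x %d samples (%d case / %d control)\n",
              x$dataset_id, x$view, x$scale, nrow(x$values), ncol(x$values),
              sum(x$groups == "case"), sum(x$groups == "control")))
  invisible(x)
}

#' Simulate a multi-dataset two-group expression study
#'
#' Generates `cfg$n_datasets` independent two-group datasets over a common
#' gene universe. Log2 expression is Normal(baseline_g, `base_sd_log2`) with
#' gene baselines drawn from Uniform(4, 12) per dataset (platforms differ in
#' probe affinity). A deterministic set of planted genes is shifted by
#' +/- `effect_log2` in case samples of every dataset that measures them.
#' Each dataset is reported through two views: an "rma-like" view
#' (quantile-aligned log2 values) and a "mas5-like" view (linear values with
#' independent log2 noise of sd `norm_view_noise_sd` and logistic P/A
#' detection calls), so the two normalization routes agree imperfectly.
#'
#' @param cfg A [study_config()].
#' @return A list with `datasets` (one element per dataset, each a list with
#'   members `rma` and `mas5`, both [expression_dataset()]s) and `truth`
#'   (list with `true_up`, `true_down` gene-id vectors).
#' @examples
#' sim <- simulate_expression_studies(study_config(n_genes = 200, seed = 7))
#' length(sim$truth$true_up)  # floor(200 * 0.05) = 10
#' @export
simulate_expression_studies <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  set.seed(cfg$seed)
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  n_up <- floor(cfg$n_genes * cfg$de_fraction_up)
  n_down <- floor(cfg$n_genes * cfg$de_fraction_down)
  de <- sample(genes, n_up + n_down)
  true_up <- sort(de[seq_len(n_up)])
  true_down <- sort(de[n_up + seq_len(n_down)])

  mid <- cfg$detect_present_prob[1]
  slope <- cfg$detect_present_prob[2]
  datasets <- vector("list", cfg$n_datasets)
  for (d in seq_len(cfg$n_datasets)) {
    id <- sprintf("ds%02d", d)
    measured <- genes[stats::runif(cfg$n_genes) <= cfg$platform_coverage]
    if (length(measured) < 2) measured <- genes[1:2]  # degenerate-coverage guard
    ng <- length(measured)
    nc <- cfg$samples_per_group[[d]][1]
    nh <- cfg$samples_per_group[[d]][2]
    samples <- c(sprintf("%s_case%02d", id, seq_len(nc)),
                 sprintf("%s_ctrl%02d", id, seq_len(nh)))
    groups <- c(rep("case", nc), rep("control", nh))

    baseline <- stats::runif(ng, 4, 12)
    log2m <- matrix(stats::rnorm(ng * (nc + nh), mean = baseline,
                                 sd = cfg$base_sd_log2),
                    nrow = ng, dimnames = list(measured, samples))
    eff <- cfg$effect_log2 * cfg$attenuation[d]
    up_here <- measured %in% true_up
    down_here <- measured %in% true_down
    log2m[up_here, groups == "case"] <- log2m[up_here, groups == "case"] + eff
    log2m[down_here, groups == "case"] <- log2m[down_here, groups == "case"] - eff

    rma_vals <- limma::normalizeQuantiles(log2m)
    dimnames(rma_vals) <- dimnames(log2m)

    mas5_log2 <- log2m + matrix(stats::rnorm(ng * (nc + nh), 0,
                                             cfg$norm_view_noise_sd),
                                nrow = ng)
    mas5_vals <- 2^mas5_log2
    pct <- apply(mas5_log2, 2, function(col) rank(col) / length(col))
    p_present <- stats::plogis(slope * (pct - mid))
    detection <- matrix(ifelse(stats::runif(ng * (nc + nh)) <= p_present,
                               "P", "A"),
                        nrow = ng, dimnames = list(measured, samples))

    datasets[[d]] <- list(
      rma = expression_dataset(id, "rma-like", rma_vals, groups),
      mas5 = expression_dataset(id, "mas5-like", mas5_vals, groups, detection))
  }
  list(datasets = datasets,
       truth = list(true_up = true_up, true_down = true_down))
}

#' Simulate a gene-set catalog with planted enriched sets
#'
#' Draws `n_sets` gene sets from a universe, then loads the sets named in
#' `planted` with an excess of `truth_up` genes so that over-representation
#' against a differentially expressed list is recoverable. Each set carries a
#' category tag (cycled from `n_categories_map`), a functional tag
#' (process / signaling / other) and a `has_ppi` flag.
#'
#' @param universe Character vector, the gene universe to sample from.
#' @param n_sets Number of sets to generate; ids are `set01`, `set02`, ...
#' @param size_range Integer pair, inclusive range of set sizes.
#' @param n_categories_map Named integer vector mapping category name to the
#'   number of sets tagged with it; must sum to `n_sets`.
#' @param planted Character vector of set ids to load with true up-genes.
#' @param truth_up Gene ids considered truly upregulated (the load source).
#' @param planted_load Fraction of a planted set replaced by `truth_up` genes.
#' @param prop_no_ppi Fraction of sets flagged `has_ppi = FALSE`.
#' @param seed Integer seed.
#' @return List with `catalog` (a `gene_set_catalog`: `meta` data.frame and
#'   named list `genes`) and `truth` (list with `true_enriched_sets`).
#' @export
simulate_catalog <- function(universe, n_sets, size_range,
                             n_categories_map = c("immune system" = n_sets),
                             planted = character(), truth_up = character(),
                             planted_load = 1 / 3, prop_no_ppi = 0,
                             seed = 1L) {
  if (size_range[2] > length(universe))
    stop("size_range exceeds the gene universe", call. = FALSE)
  if (sum(n_categories_map) != n_sets)
    stop("n_categories_map must sum to n_sets", call. = FALSE)
  ids <- sprintf("set%02d", seq_len(n_sets))
  if (!all(planted %in% ids))
    stop("planted ids must be among the generated set ids", call. = FALSE)
  set.seed(seed)
  categories <- rep(names(n_categories_map), n_categories_map)
  tags <- rep_len(c("process", "signaling", "other"), n_sets)
  has_ppi <- rep(TRUE, n_sets)
  if (prop_no_ppi > 0) {
    n_off <- floor(n_sets * prop_no_ppi)
    off <- setdiff(ids, planted)[seq_len(min(n_off, n_sets - length(planted)))]
    has_ppi[ids %in% off] <- FALSE
  }
  sizes <- sample(size_range[1]:size_range[2], n_sets, replace = TRUE)
  genes <- vector("list", n_sets)
  names(genes) <- ids
  for (i in seq_len(n_sets)) {
    gs <- sample(universe, sizes[i])
    if (ids[i] %in% planted && length(truth_up)) {
      k <- min(ceiling(sizes[i] * planted_load), length(truth_up))
      load <- sample(truth_up, k)
      gs <- c(load, setdiff(gs, load))[seq_len(sizes[i])]
    }
    genes[[i]] <- sort(unique(gs))
  }
  meta <- data.frame(id = ids, name = paste("pathway", ids),
                     category = categories, functional_tag = tags,
                     has_ppi = has_ppi, stringsAsFactors = FALSE)
  catalog <- structure(list(meta = meta, genes = genes),
                       class = "gene_set_catalog")
  list(catalog = catalog, truth = list(true_enriched_sets = sort(planted)))
}

#' @export
print.gene_set_catalog <- function(x, ...) {
  cat(sprintf("<gene_set_catalog> %d sets, %d distinct genes\n",
              nrow(x$meta), length(unique(unlist(x$genes)))))
  invisible(x)
}

rbeta_scores <- function(n, shape) stats::rbeta(n, shape[1], shape[2])

# Beta draw conditioned on score >= lower: planted/attachment edges must
# stay in the qualifying (>= 0.9) region so the first shell is connected
# and planted complexes remain dense after score filtering.
rbeta_scores_min <- function(n, shape, lower = 0.9) {
  p0 <- stats::pbeta(lower, shape[1], shape[2])
  stats::qbeta(stats::runif(n, p0, 1), shape[1], shape[2])
}

edge_kind_draw <- function(n) {
  kinds <- sample(c("binding", "activation", "inhibition", "ptm:phosphorylation"),
                  n, replace = TRUE, prob = c(0.55, 0.2, 0.15, 0.1))
  direction <- ifelse(kinds == "binding", "none",
                      sample(c("ab", "ba"), n, replace = TRUE))
  list(kind = kinds, direction = direction)
}

#' Simulate a scored interactome with planted complexes and a hub
#'
#' Builds a typed, scored interaction table over `core` plus `n_shell` shell
#' nodes. Every shell node gets at least one high-confidence attachment edge
#' to a random core node (so the first shell is recoverable); background
#' noise is Erdos-Renyi among shell nodes with low Beta(2, 5) scores;
#' planted complexes are dense subgraphs among shell nodes whose edges (like
#' all "true" edges) draw scores from `Beta(score_params)`, mass near 1, and
#' carry "experimental" evidence. One hub node `HUB` receives `hub_degree`
#' qualifying (score >= 0.9, experimental) edges.
#'
#' @param core Character vector of core node ids.
#' @param n_shell Number of shell nodes (`s001`, ...), excluding the hub.
#' @param background_edge_prob Erdos-Renyi edge probability among shell nodes.
#' @param complexes List of `c(size, density)` pairs to plant (density in
#'   (0, 1]).
#' @param hub_degree Number of qualifying edges of the hub (0 = no hub).
#' @param score_params Beta shape pair for true-edge scores.
#' @param seed Integer seed.
#' @return List with `interactions` (data.frame: node_a, node_b, kind,
#'   direction, score, evidence) and `truth` (list with `true_complexes`,
#'   a list of node-id vectors, and `hub_id`).
#' @export
simulate_interactome <- function(core, n_shell = 50,
                                 background_edge_prob = 0.02,
                                 complexes = list(), hub_degree = 0,
                                 score_params = c(20, 1), seed = 1L) {
  shell <- sprintf("s%03d", seq_len(n_shell))
  nodes <- c(core, shell)
  if (hub_degree > length(nodes))  # hub connects to existing nodes
    stop("hub_degree exceeds the available node count", call. = FALSE)
  for (cx in complexes) {
    if (cx[2] > 1) stop("complex density cannot exceed 1", call. = FALSE)
    if (cx[1] > n_shell) stop("complex larger than the shell", call. = FALSE)
  }
  set.seed(seed)
  ea <- character(0); eb <- character(0)
  score <- numeric(0); evid <- character(0)
  add <- function(a, b, s, ev) {
    ea <<- c(ea, a); eb <<- c(eb, b); score <<- c(score, s); evid <<- c(evid, ev)
  }
  # guaranteed core--shell attachment
  if (length(core))
    add(sample(core, n_shell, replace = TRUE), shell,
        rbeta_scores_min(n_shell, score_params), rep("experimental", n_shell))
  # ER background among shell nodes, low scores, mixed evidence
  if (n_shell >= 2 && background_edge_prob > 0) {
    pairs <- utils::combn(shell, 2)
    keep <- stats::runif(ncol(pairs)) <= background_edge_prob
    if (any(keep)) {
      np <- sum(keep)
      add(pairs[1, keep], pairs[2, keep], rbeta_scores(np, c(2, 5)),
          sample(c("experimental", "other"), np, replace = TRUE))
    }
  }
  # planted dense complexes (node-disjoint, drawn from the shell)
  true_complexes <- list()
  avail <- shell
  for (cx in complexes) {
    members <- sort(sample(avail, cx[1]))
    avail <- setdiff(avail, members)
    pairs <- utils::combn(members, 2)
    keep <- stats::runif(ncol(pairs)) <= cx[2]
    if (cx[2] >= 1) keep <- rep(TRUE, ncol(pairs))
    np <- sum(keep)
    if (np)
      add(pairs[1, keep], pairs[2, keep], rbeta_scores_min(np, score_params),
          rep("experimental", np))
    true_complexes <- c(true_complexes, list(members))
  }
  # hub with exactly hub_degree qualifying edges
  hub_id <- NULL
  if (hub_degree > 0) {
    hub_id <- "HUB"
    partners <- sample(nodes, hub_degree)
    add(rep(hub_id, hub_degree), partners,
        0.9 + 0.1 * stats::runif(hub_degree), rep("experimental", hub_degree))
  }
  kd <- edge_kind_draw(length(ea))
  interactions <- data.frame(node_a = ea, node_b = eb, kind = kd$kind,
                             direction = kd$direction, score = score,
                             evidence = evid, stringsAsFactors = FALSE)
  # drop duplicate unordered pairs (and self-loops), keeping the best score
  self <- interactions$node_a == interactions$node_b
  interactions <- interactions[!self, , drop = FALSE]
  key <- paste(pmin(interactions$node_a, interactions$node_b),
               pmax(interactions$node_a, interactions$node_b))
  ord <- order(key, -interactions$score)
  interactions <- interactions[ord, , drop = FALSE]
  interactions <- interactions[!duplicated(key[ord]), , drop = FALSE]
  rownames(interactions) <- NULL
  list(interactions = interactions,
       truth = list(true_complexes = true_complexes, hub_id = hub_id))
}

#' Simulate node annotations: GO-like terms, DNA-binding set, drug targets
#'
#' @param nodes Character vector of network node ids.
#' @param dna_binding_fraction Fraction of nodes flagged as DNA-binding.
#' @param n_terms Number of annotation term sets to draw over the nodes.
#' @param n_drugs Number of drugs; each maps to a small node subset.
#' @param seed Integer seed.
#' @return List with `terms` (named list of node-id sets), `dna_binding`
#'   (node-id vector) and `drug_targets` (data.frame: drug, target).
#' @export
simulate_annotations <- function(nodes, dna_binding_fraction = 0.2,
                                 n_terms = 5, n_drugs = 3, seed = 1L) {
  if (dna_binding_fraction < 0 || dna_binding_fraction > 1)
    stop("dna_binding_fraction must be in [0, 1]", call. = FALSE)
  set.seed(seed)
  n_dna <- round(length(nodes) * dna_binding_fraction)
  dna <- if (n_dna > 0) sort(sample(nodes, n_dna)) else character(0)
  terms <- list()
  if (n_terms > 0) {
    for (i in seq_len(n_terms)) {
      sz <- sample(2:max(2, min(10, length(nodes))), 1)
      terms[[sprintf("term%02d", i)]] <- sort(sample(nodes, min(sz, length(nodes))))
    }
  }
  drug <- character(0); target <- character(0)
  if (n_drugs > 0) {
    for (i in seq_len(n_drugs)) {
      tg <- sample(nodes, min(sample(1:3, 1), length(nodes)))
      drug <- c(drug, rep(sprintf("drug%02d", i), length(tg)))
      target <- c(target, tg)
    }
  }
  list(terms = terms, dna_binding = dna,
       drug_targets = data.frame(drug = drug, target = target,
                                 stringsAsFactors = FALSE))
}
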