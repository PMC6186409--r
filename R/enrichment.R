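check_contingency <- function(count, list_total, pop_hits, pop_total) {
  if (count < 0 || count > min(list_total, pop_hits) ||
      pop_hits > pop_total || list_total > pop_total)
    stop("invalid contingency counts", call. = FALSE)
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= count) for X ~ Hypergeometric(pop_total, pop_hits, list_total):
#' the one-tailed Fisher exact probability of drawing at least `count`
#' annotated genes in a list of `list_total` from a background of
#' `pop_total` genes of which `pop_hits` are annotated.
#'
#' @param count Observed overlap.
#' @param list_total Size of the tested list.
#' @param pop_hits Annotated genes in the background.
#' @param pop_total Background size.
#' @return Probability in (0, 1].
#' @export
hypergeom_upper_tail <- function(count, list_total, pop_hits, pop_total) {
  check_contingency(count, list_total, pop_hits, pop_total)
  if (count <= 0) return(1)
  stats::phyper(count - 1, pop_hits, pop_total - pop_hits, list_total,
                lower.tail = FALSE)
}

#' EASE score
#'
#' The EASE-modified one-tailed Fisher exact probability: the hypergeometric
#' upper tail recomputed after removing one gene from the observed overlap,
#' i.e. P(X >= count - 1). More conservative than the plain Fisher tail for
#' small counts.
#'
#' @inheritParams hypergeom_upper_tail
#' @return Probability in (0, 1].
#' @export
ease_score <- function(count, list_total, pop_hits, pop_total) {
  check_contingency(count, list_total, pop_hits, pop_total)
  hypergeom_upper_tail(max(count - 1, 0), list_total, pop_hits, pop_total)
}

#' Fold enrichment
#'
#' The proportion of Count/List Total to Population Hits/Population Total:
#' how over-represented the term is in the tested list relative to the
#' background.
#'
#' @inheritParams hypergeom_upper_tail
#' @return Non-negative real.
#' @export
fold_enrichment <- function(count, list_total, pop_hits, pop_total) {
  if (list_total <= 0 || pop_hits <= 0)
    stop("list_total and pop_hits must be positive", call. = FALSE)
  (count / list_total) / (pop_hits / pop_total)
}

#' Adjust p values (Bonferroni / Benjamini-Hochberg)
#'
#' Thin, clamped wrapper used for the report columns; selection in the
#' pipeline itself uses the raw EASE score.
#'
#' @param ps Numeric vector of p values in (0, 1].
#' @param method `"bonferroni"` or `"benjamini_hochberg"`.
#' @return Adjusted p values, clamped at 1.
#' @export
adjust_pvalues <- function(ps, method = c("bonferroni", "benjamini_hochberg")) {
  method <- match.arg(method)
  stats::p.adjust(ps, method = if (method == "bonferroni") "bonferroni" else "BH")
}

#' Gene-set over-representation with EASE scoring
#'
#' Tests a gene list against every set of a catalog. The list and every
#' term are first restricted to the background universe. Population Total
#' follows the chosen convention: `"annotated"` restricts the background to
#' genes carrying at least one catalog annotation (and List Total to list
#' genes with an annotation); `"full-universe"` uses the whole universe.
#' A term is flagged enriched iff EASE score <= `ease_cut` AND fold
#' enrichment >= `fe_cut` (both inclusive). Terms with zero overlap are
#' omitted. Rows are sorted by EASE score, ties by term id.
#'
#' @param genes Character vector, the tested gene list.
#' @param catalog A `gene_set_catalog` (see [simulate_catalog()]).
#' @param universe Character vector, the background universe.
#' @param ease_cut,fe_cut Enrichment thresholds (defaults 0.05, 1.5).
#' @param background `"annotated"` (default) or `"full-universe"`.
#' @return Data frame with columns term, count, list_total, pop_hits,
#'   pop_total, fold_enrichment, ease_p, fisher_p, bonferroni, benjamini,
#'   enriched.
#' @export
enrich_gene_list <- function(genes, catalog, universe, ease_cut = 0.05,
                             fe_cut = 1.5,
                             background = c("annotated", "full-universe")) {
  background <- match.arg(background)
  genes <- intersect(unique(genes), universe)
  if (!length(genes))
    return(empty_enrichment())
  term_genes <- lapply(catalog$genes, intersect, universe)
  annotated <- unique(unlist(term_genes))
  if (background == "annotated") {
    pop_total <- length(annotated)
    list_genes <- intersect(genes, annotated)
  } else {
    pop_total <- length(universe)
    list_genes <- genes
  }
  list_total <- length(list_genes)
  rows <- lapply(names(term_genes), function(id) {
    hits <- term_genes[[id]]
    count <- length(intersect(list_genes, hits))
    if (count == 0) return(NULL)
    pop_hits <- length(hits)
    data.frame(term = id, count = count, list_total = list_total,
               pop_hits = pop_hits, pop_total = pop_total,
               fold_enrichment = fold_enrichment(count, list_total,
                                                 pop_hits, pop_total),
               ease_p = ease_score(count, list_total, pop_hits, pop_total),
               fisher_p = hypergeom_upper_tail(count, list_total, pop_hits,
                                               pop_total),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(empty_enrichment())
  res <- res[order(res$ease_p, res$term), , drop = FALSE]
  res$bonferroni <- adjust_pvalues(res$ease_p, "bonferroni")
  res$benjamini <- adjust_pvalues(res$ease_p, "benjamini_hochberg")
  res$enriched <- res$ease_p <= ease_cut & res$fold_enrichment >= fe_cut
  rownames(res) <- NULL
  res
}

empty_enrichment <- function() {
  data.frame(term = character(), count = integer(), list_total = integer(),
             pop_hits = integer(), pop_total = integer(),
             fold_enrichment = numeric(), ease_p = numeric(),
             fisher_p = numeric(), bonferroni = numeric(),
             benjamini = numeric(), enriched = logical(),
             stringsAsFactors = FALSE)
}

#' Category filter on enrichment results
#'
#' Drops rows whose catalog category is "human diseases" or "metabolism",
#' or whose set lacks protein-protein interactions (`has_ppi = FALSE`):
#' disease maps do not reflect healthy-state interactions and metabolic
#' maps describe metabolite interconversions rather than protein signaling.
#'
#' @param rows Enrichment data frame from [enrich_gene_list()].
#' @param catalog The `gene_set_catalog` the rows were computed against.
#' @return The filtered data frame.
#' @export
filter_pathways <- function(rows, catalog) {
  idx <- match(rows$term, catalog$meta$id)
  if (anyNA(idx))
    stop("unknown term id: ", paste(rows$term[is.na(idx)], collapse = ", "),
         call. = FALSE)
  drop <- catalog$meta$category[idx] %in% c("human diseases", "metabolism") |
    !catalog$meta$has_ppi[idx]
  rows[!drop, , drop = FALSE]
}

#' Write an enrichment report TSV
#'
#' Column layout mirrors standard over-representation reports: Term, Count,
#' %, List Total, Pop Hits, Pop Total, Fold Enrichment, PValue (the EASE
#' score), Bonferroni, Benjamini (BH on EASE) and FDR (BH on the unmodified
#' Fisher tail).
#'
#' @param rows Enrichment data frame.
#' @param path Output file path.
#' @export
write_enrichment_tsv <- function(rows, path) {
  out <- data.frame(Term = rows$term, Count = rows$count,
                    `%` = round(100 * rows$count / pmax(rows$list_total, 1), 2),
                    `List Total` = rows$list_total,
                    `Pop Hits` = rows$pop_hits, `Pop Total` = rows$pop_total,
                    `Fold Enrichment` = rows$fold_enrichment,
                    PValue = rows$ease_p, Bonferroni = rows$bonferroni,
                    Benjamini = rows$benjamini,
                    FDR = adjust_pvalues(rows$fisher_p, "benjamini_hochberg"),
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
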