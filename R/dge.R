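#' Welch's two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p value. Orientation is `x` (cases) minus `y` (controls).
#' Degenerate inputs: equal means with zero pooled standard error give
#' t = 0, p = 1; unequal means with zero pooled standard error give the
#' smallest representable positive p with a warning.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`.
#' @examples
#' welch_test(c(1, 2, 3, 4), c(2, 4, 6, 8))  # t = -1.732, df = 4.412
#' @export
welch_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 observations", call. = FALSE)
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  dm <- mean(x) - mean(y)
  if (se2 == 0) {
    if (dm == 0) return(list(t = 0, df = nx + ny - 2, p = 1))
    warning("zero pooled standard error with unequal means", call. = FALSE)
    return(list(t = sign(dm) * Inf, df = nx + ny - 2,
                p = .Machine$double.xmin))
  }
  t <- dm / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Linear fold change between two groups
#'
#' Case/control orientation: ratio of group means on the linear scale, or
#' `2^(mean(x) - mean(y))` on the log2 scale.
#'
#' @param x,y Numeric vectors (cases, controls).
#' @param scale `"linear"` or `"log2"`.
#' @return Positive real fold change.
#' @export
linear_fold_change <- function(x, y, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (scale == "linear") {
    if (any(c(x, y) <= 0))
      stop("linear-scale values must be positive", call. = FALSE)
    mean(x) / mean(y)
  } else {
    2^(mean(x) - mean(y))
  }
}

#' Present-call detection filter
#'
#' Retains genes with at least one present ("P") detection call among the
#' case samples AND at least one among the control samples — the standard
#' precondition for analysing the linear-scale (mas5-like) view.
#'
#' @param ds An [expression_dataset()] with `view = "mas5-like"`.
#' @return Character vector of retained gene ids.
#' @export
detection_filter <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.null(ds$detection))
    stop("detection filter requires a detection-call matrix", call. = FALSE)
  cases <- ds$groups == "case"
  p_case <- rowSums(ds$detection[, cases, drop = FALSE] == "P") >= 1
  p_ctrl <- rowSums(ds$detection[, !cases, drop = FALSE] == "P") >= 1
  rownames(ds$values)[p_case & p_ctrl]
}

#' Three-state differential call for one gene in one view
#'
#' "+" iff linear fold change >= `fc_cut` and p <= `p_cut`; "-" iff fold
#' change <= `1/fc_cut` and p <= `p_cut`; otherwise "0". Both thresholds are
#' inclusive.
#'
#' @param fc Positive linear fold change (case/control).
#' @param p Two-sided p value.
#' @param fc_cut,p_cut Thresholds (defaults 2 and 0.05).
#' @return `"+"`, `"0"` or `"-"`.
#' @export
per_gene_call <- function(fc, p, fc_cut = 2, p_cut = 0.05) {
  if (fc <= 0) stop("fold change must be positive", call. = FALSE)
  if (p <= p_cut) {
    if (fc >= fc_cut) return("+")
    if (fc <= 1 / fc_cut) return("-")
  }
  "0"
}

# Detailed within-dataset evidence grades. The orientation of single-route
# support is kept because the cross-dataset rule distinguishes a gene called
# only by the rma route ([+,0]) from one called only by the mas5 route
# ([0,+]).
GRADE_LEVELS <- c("U2", "U1R", "U1M", "D2", "D1R", "D1M",
                  "none", "conflict", "unmeasured")

#' Within-dataset consensus of the two normalization routes
#'
#' Combines the rma-route and mas5-route calls for one gene in one dataset
#' into an evidence grade. A gene removed by the present-call filter
#' contributes `"filtered"` for the mas5 route and is treated as "0": the
#' rma route still speaks. Grades: `U2` = [+,+]; `U1R` = [+,0]; `U1M` =
#' [0,+]; `D2`/`D1R`/`D1M` mirrored; `(0,0)` = none; opposite signs =
#' conflict.
#'
#' @param call_rma `"+"`, `"0"` or `"-"`.
#' @param call_mas5 `"+"`, `"0"`, `"-"` or `"filtered"`.
#' @return One grade string.
#' @export
dataset_consensus <- function(call_rma, call_mas5) {
  stopifnot(call_rma %in% c("+", "0", "-"),
            call_mas5 %in% c("+", "0", "-", "filtered"))
  if (call_mas5 == "filtered") call_mas5 <- "0"
  if (call_rma == "+" && call_mas5 == "+") return("U2")
  if (call_rma == "-" && call_mas5 == "-") return("D2")
  if (call_rma == "+" && call_mas5 == "0") return("U1R")
  if (call_rma == "0" && call_mas5 == "+") return("U1M")
  if (call_rma == "-" && call_mas5 == "0") return("D1R")
  if (call_rma == "0" && call_mas5 == "-") return("D1M")
  if (call_rma == "0" && call_mas5 == "0") return("none")
  "conflict"
}

#' Cross-dataset consensus call for one gene
#'
#' A gene is upregulated iff it is [+,+] (`U2`) in at least one dataset, or
#' it is [+,0] (`U1R`) in at least one dataset and [0,+] (`U1M`) in at least
#' one of the remaining datasets — and in either case no dataset shows any
#' downregulation (`D2`, `D1R`, `D1M`) or a conflict. Downregulation is the
#' mirror rule. Grades `"unmeasured"` (gene absent from the platform) are
#' skipped.
#'
#' @param grades Character vector of per-dataset grades (see `GRADE_LEVELS`
#'   in the package source), one per dataset.
#' @return `"up"`, `"down"` or `"none"`.
#' @export
cross_dataset_consensus <- function(grades) {
  stopifnot(all(grades %in% GRADE_LEVELS))
  g <- grades[grades != "unmeasured"]
  if (!length(g))
    stop("gene unmeasured in every dataset", call. = FALSE)
  any_down <- any(g %in% c("D2", "D1R", "D1M", "conflict"))
  any_up <- any(g %in% c("U2", "U1R", "U1M", "conflict"))
  up <- !any_down &&
    (any(g == "U2") || (any(g == "U1R") && any(g == "U1M")))
  down <- !any_up &&
    (any(g == "D2") || (any(g == "D1R") && any(g == "D1M")))
  if (up) "up" else if (down) "down" else "none"
}

#' Collapse probe-level calls to gene-level calls
#'
#' A gene is "+" if at least one of its probes is "+" and none is "-";
#' mirrored for "-"; otherwise "0". Probes without a mapping are dropped; a
#' probe mapping to more than one gene is an error.
#'
#' @param probe_calls Named character vector of `"+"`/`"0"`/`"-"` calls,
#'   names are probe ids.
#' @param probe_map Data frame with columns `probe`, `gene`.
#' @return Named character vector of gene-level calls.
#' @export
collapse_probes_to_gene <- function(probe_calls, probe_map) {
  if (anyDuplicated(probe_map$probe))
    stop("a probe maps to multiple genes", call. = FALSE)
  idx <- match(names(probe_calls), probe_map$probe)
  keep <- !is.na(idx)
  genes <- probe_map$gene[idx[keep]]
  calls <- probe_calls[keep]
  out <- vapply(split(calls, genes), function(cs) {
    has_up <- any(cs == "+"); has_dn <- any(cs == "-")
    if (has_up && !has_dn) "+" else if (has_dn && !has_up) "-" else "0"
  }, character(1))
  out
}

# Per-view differential test table for one expression_dataset.
view_test_table <- function(ds, fc_cut = 2, p_cut = 0.05) {
  cases <- ds$groups == "case"
  genes <- rownames(ds$values)
  retained <- genes
  if (ds$view == "mas5-like") retained <- detection_filter(ds)
  res <- data.frame(gene = genes, t = NA_real_, df = NA_real_, p = NA_real_,
                    fc = NA_real_, call = "filtered", stringsAsFactors = FALSE)
  keep <- genes %in% retained
  if (any(keep)) {
    vals <- ds$values
    wt <- t(apply(vals[keep, , drop = FALSE], 1, function(v) {
      w <- welch_test(v[cases], v[!cases])
      c(w$t, w$df, w$p)
    }))
    fc <- apply(vals[keep, , drop = FALSE], 1, function(v)
      linear_fold_change(v[cases], v[!cases], scale = ds$scale))
    res$t[keep] <- wt[, 1]; res$df[keep] <- wt[, 2]; res$p[keep] <- wt[, 3]
    res$fc[keep] <- fc
    res$call[keep] <- mapply(per_gene_call, fc, wt[, 3],
                             MoreArgs = list(fc_cut = fc_cut, p_cut = p_cut))
  }
  res
}

#' Consensus differential-expression calls over a multi-dataset study
#'
#' Runs the full calling procedure: per dataset and per normalization view,
#' a Welch t test and linear fold change per gene; a three-state call at
#' `fc_cut`/`p_cut` (the mas5-like view first passes the present-call
#' filter); a within-dataset grade combining the two views; and the
#' cross-dataset consensus. The reported magnitude is the median across
#' datasets of the rma-view log2 fold change.
#'
#' @param datasets List as returned in `simulate_expression_studies()$datasets`:
#'   each element a list with `rma` and `mas5` [expression_dataset()]s.
#' @param fc_cut,p_cut Call thresholds (defaults 2, 0.05).
#' @return Object of class `deg_result`: list with `calls` (data.frame:
#'   gene, final, magnitude), `grades` (gene x dataset character matrix),
#'   `tests` (per dataset, per view test tables).
#' @export
call_degs <- function(datasets, fc_cut = 2, p_cut = 0.05) {
  genes <- sort(unique(unlist(lapply(datasets, function(d)
    rownames(d$rma$values)))))
  nd <- length(datasets)
  grades <- matrix("unmeasured", nrow = length(genes), ncol = nd,
                   dimnames = list(genes,
                                   vapply(datasets, function(d)
                                     d$rma$dataset_id, character(1))))
  tests <- vector("list", nd)
  log2fc <- matrix(NA_real_, nrow = length(genes), ncol = nd,
                   dimnames = dimnames(grades))
  for (d in seq_len(nd)) {
    rma_tab <- view_test_table(datasets[[d]]$rma, fc_cut, p_cut)
    mas_tab <- view_test_table(datasets[[d]]$mas5, fc_cut, p_cut)
    tests[[d]] <- list(rma = rma_tab, mas5 = mas_tab)
    common <- rma_tab$gene  # both views share the platform's gene rows
    g <- mapply(dataset_consensus, rma_tab$call,
                mas_tab$call[match(common, mas_tab$gene)])
    grades[common, d] <- g
    log2fc[common, d] <- log2(rma_tab$fc)
  }
  final <- apply(grades, 1, cross_dataset_consensus)
  magnitude <- apply(log2fc, 1, function(v) stats::median(v, na.rm = TRUE))
  calls <- data.frame(gene = genes, final = final, magnitude = magnitude,
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(calls = calls, grades = grades, tests = tests),
            class = "deg_result")
}

#' @export
print.deg_result <- function(x, ...) {
  cat(sprintf("<deg_result> %d genes x %d datasets: %d up, %d down\n",
              nrow(x$calls), ncol(x$grades), sum(x$calls$final == "up"),
              sum(x$calls$final == "down")))
  invisible(x)
}

#' Up/down gene counts under a stricter "at least k datasets" rule
#'
#' Counts genes that would still be selected if the selection demanded
#' support in at least `k` datasets by each normalization route: a gene
#' counts as up at stringency `k` iff at least `k` datasets give an rma "+"
#' call and at least `k` datasets give a mas5 "+" call, with no "-" call in
#' any view of any dataset. At `k = 1` this coincides with the cross-dataset
#' consensus rule. Returns `(0, 0)` when `k` exceeds the dataset count.
#'
#' @param deg A `deg_result` from [call_degs()].
#' @param k Positive integer stringency level.
#' @return Named integer vector `c(n_up, n_down)`.
#' @export
stringency_counts <- function(deg, k) {
  stopifnot(inherits(deg, "deg_result"), k >= 1)
  nd <- length(deg$tests)
  if (k > nd) return(c(n_up = 0L, n_down = 0L))
  genes <- rownames(deg$grades)
  rma_up <- mas_up <- rma_dn <- mas_dn <- matrix(
    FALSE, length(genes), nd, dimnames = list(genes, NULL))
  for (d in seq_len(nd)) {
    rt <- deg$tests[[d]]$rma; mt <- deg$tests[[d]]$mas5
    rma_up[rt$gene, d] <- rt$call == "+"
    rma_dn[rt$gene, d] <- rt$call == "-"
    mas_up[mt$gene, d] <- mt$call == "+"
    mas_dn[mt$gene, d] <- mt$call == "-"
  }
  any_dn <- rowSums(rma_dn) + rowSums(mas_dn) > 0
  any_up <- rowSums(rma_up) + rowSums(mas_up) > 0
  n_up <- sum(rowSums(rma_up) >= k & rowSums(mas_up) >= k & !any_dn)
  n_down <- sum(rowSums(rma_dn) >= k & rowSums(mas_dn) >= k & !any_up)
  c(n_up = as.integer(n_up), n_down = as.integer(n_down))
}
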