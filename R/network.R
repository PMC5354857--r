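#' Pearson product-moment correlation between two expression vectors
#'
#' Thin, argument-checked wrapper used at network edges; constant vectors
#' have no defined correlation and raise an error (the network builder
#' drops such genes up front with a warning instead).
#'
#' @param x,y numeric vectors of equal length `n >= 3`, finite values.
#' @return The correlation coefficient.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length",
                                   call. = FALSE)
  if (length(x) < 3) stop("at least 3 paired samples are required",
                          call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("correlation inputs must be finite", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  stats::cor(x, y)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the t transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2`
#' degrees of freedom; `|r| = 1` returns p = 0.
#'
#' @param pcc correlation coefficient(s), `|pcc| <= 1`.
#' @param n number of paired samples, `n >= 3`.
#' @return Two-sided p-value(s).
#' @export
correlation_pvalue <- function(pcc, n) {
  if (n < 3) stop("n must be >= 3", call. = FALSE)
  if (any(abs(pcc) > 1 + 1e-12)) stop("|pcc| must not exceed 1",
                                      call. = FALSE)
  pcc <- pmax(pmin(pcc, 1), -1)   # clamp; keeps matrix dims
  p <- ifelse(abs(pcc) == 1, 0, {
    tstat <- pcc * sqrt(n - 2) / sqrt(pmax(0, 1 - pcc^2))
    2 * stats::pt(-abs(tstat), n - 2)
  })
  p
}

#' Build a bipartite lncRNA-mRNA co-expression network
#'
#' Computes all pairwise Pearson correlations between the supplied lncRNAs
#' and mRNAs over the chosen cohort and keeps the edge (l, m) iff
#' `|pcc| >= min_abs_pcc` and `p < max_p`. The defaults implement the
#' general-network regime (|PCC| >= 0.90, no p cut); the sub-network
#' regime uses |PCC| >= 0.80 with p < 0.001. The sign of each correlation
#' is kept as an edge attribute; nodes are exactly the endpoints of
#' retained edges, so unconnected genes do not appear.
#'
#' @param expr an [expression_set()].
#' @param lnc_ids,mrna_ids gene ids (typically the significant DE genes of
#'   each biotype); all must be present in the matrix.
#' @param min_abs_pcc minimum absolute correlation (default 0.90,
#'   inclusive).
#' @param max_p strict p-value cut (default 1, i.e. no cut).
#' @param cohort `"tumor"` (default), `"normal"`, or `"all"` samples.
#' @param log2_transform correlate `log2(value + pseudocount)` instead of
#'   the raw abundances (default `TRUE`, the standard choice for
#'   co-expression on FPKM-like values, whose raw scale is dominated by
#'   the most abundant samples).
#' @param pseudocount added before the log2 transform.
#' @return An object of class `coexpression_network`: list with `edges`
#'   (`lncrna_id`, `mrna_id`, `pcc`, `p_value`, `sign`), `nodes`
#'   (`gene_id`, `biotype`, `degree`), `thresholds`, `n_samples`,
#'   `dropped` (constant genes removed before correlation).
#' @export
build_network <- function(expr, lnc_ids, mrna_ids, min_abs_pcc = 0.90,
                          max_p = 1.0, cohort = c("tumor", "normal",
                                                  "all"),
                          log2_transform = TRUE, pseudocount = 0.25) {
  stopifnot(inherits(expr, "expression_set"))
  cohort <- match.arg(cohort)
  if (length(lnc_ids) == 0 || length(mrna_ids) == 0)
    stop("both gene sets must be non-empty", call. = FALSE)
  missing <- setdiff(c(lnc_ids, mrna_ids), rownames(expr$values))
  if (length(missing))
    stop("genes absent from the expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  cols <- if (cohort == "all") rep(TRUE, ncol(expr$values)) else
    expr$group == cohort
  n <- sum(cols)
  if (n < 3) stop("cohort resolves to fewer than 3 samples", call. = FALSE)

  vals <- if (log2_transform) log2(expr$values + pseudocount) else
    expr$values
  lm_ <- t(vals[lnc_ids, cols, drop = FALSE])
  mm_ <- t(vals[mrna_ids, cols, drop = FALSE])
  const_l <- apply(lm_, 2, stats::sd) == 0
  const_m <- apply(mm_, 2, stats::sd) == 0
  dropped <- c(colnames(lm_)[const_l], colnames(mm_)[const_m])
  if (length(dropped))
    warning(length(dropped), " constant-expression gene(s) dropped ",
            "before correlation", call. = FALSE)
  lm_ <- lm_[, !const_l, drop = FALSE]
  mm_ <- mm_[, !const_m, drop = FALSE]

  edges <- data.frame(lncrna_id = character(), mrna_id = character(),
                      pcc = numeric(), p_value = numeric(),
                      sign = character(), stringsAsFactors = FALSE)
  if (ncol(lm_) > 0 && ncol(mm_) > 0) {
    r <- stats::cor(lm_, mm_)
    p <- correlation_pvalue(r, n)
    keep <- abs(r) >= min_abs_pcc & p < max_p
    ij <- which(keep, arr.ind = TRUE)
    if (nrow(ij)) {
      edges <- data.frame(
        lncrna_id = colnames(lm_)[ij[, 1]],
        mrna_id = colnames(mm_)[ij[, 2]],
        pcc = r[ij], p_value = p[ij],
        sign = ifelse(r[ij] > 0, "positive", "negative"),
        stringsAsFactors = FALSE)
      edges <- edges[order(edges$lncrna_id, edges$mrna_id), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  new_coexpression_network(edges, min_abs_pcc, max_p, n, dropped)
}

new_coexpression_network <- function(edges, min_abs_pcc, max_p, n_samples,
                                     dropped = character()) {
  node_ids <- c(unique(edges$lncrna_id), unique(edges$mrna_id))
  nodes <- data.frame(
    gene_id = node_ids,
    biotype = rep(c("lncRNA", "mRNA"),
                  c(length(unique(edges$lncrna_id)),
                    length(unique(edges$mrna_id)))),
    stringsAsFactors = FALSE)
  deg <- table(c(edges$lncrna_id, edges$mrna_id))
  nodes$degree <- as.integer(deg[nodes$gene_id])
  structure(list(edges = edges, nodes = nodes,
                 thresholds = list(min_abs_pcc = min_abs_pcc,
                                   max_p = max_p),
                 n_samples = n_samples, dropped = dropped),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf(
    "coexpression_network: %d nodes (%d lncRNA, %d mRNA), %d edges\n",
    nrow(x$nodes), sum(x$nodes$biotype == "lncRNA"),
    sum(x$nodes$biotype == "mRNA"), nrow(x$edges)))
  cat(sprintf("  thresholds: |PCC| >= %g, p < %g; %d samples\n",
              x$thresholds$min_abs_pcc, x$thresholds$max_p, x$n_samples))
  invisible(x)
}

#' @export
summary.coexpression_network <- function(object, ...) {
  list(n_nodes = nrow(object$nodes), n_edges = nrow(object$edges),
       n_lncrna = sum(object$nodes$biotype == "lncRNA"),
       n_mrna = sum(object$nodes$biotype == "mRNA"),
       thresholds = object$thresholds)
}

#' Degree table of a co-expression network, ranked
#'
#' Degree is the number of directly linked neighbours. Ranking is by
#' degree descending with ties broken lexicographically by gene id.
#'
#' @param net a `coexpression_network`.
#' @param status optional named vector (gene id -> `up`/`down`) carried
#'   into the table.
#' @param top_k optionally keep only the first `top_k` rows per biotype.
#' @return Data frame `gene_id`, `biotype`, `degree` (and `status`).
#' @export
node_degrees <- function(net, status = NULL, top_k = NULL) {
  stopifnot(inherits(net, "coexpression_network"))
  out <- net$nodes
  if (!is.null(status)) out$status <- unname(status[out$gene_id])
  out <- out[order(-out$degree, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(top_k)) {
    out <- do.call(rbind, lapply(split(out, out$biotype), utils::head,
                                 n = top_k))
    out <- out[order(-out$degree, out$gene_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Pathway-seeded co-expression sub-network
#'
#' Rebuilds the network at the sub-network thresholds (default
#' |PCC| >= 0.80, p < 0.001) keeping only edges incident to the seed
#' mRNAs — e.g. the key coding genes of one enriched pathway. Seeds with
#' no retained edge are reported but excluded from the node set.
#'
#' @param expr an [expression_set()].
#' @param lnc_ids candidate lncRNA ids (typically all DE lncRNAs).
#' @param seed_mrnas seed mRNA ids.
#' @param min_abs_pcc,max_p sub-network thresholds.
#' @param cohort,log2_transform,pseudocount passed to [build_network()].
#' @return A `coexpression_network` with an extra `unconnected_seeds`
#'   element.
#' @export
extract_subnetwork <- function(expr, lnc_ids, seed_mrnas,
                               min_abs_pcc = 0.80, max_p = 0.001,
                               cohort = "tumor", log2_transform = TRUE,
                               pseudocount = 0.25) {
  if (length(seed_mrnas) == 0) stop("seed mRNA set is empty",
                                    call. = FALSE)
  net <- build_network(expr, lnc_ids, seed_mrnas,
                       min_abs_pcc = min_abs_pcc, max_p = max_p,
                       cohort = cohort, log2_transform = log2_transform,
                       pseudocount = pseudocount)
  net$unconnected_seeds <- setdiff(seed_mrnas, net$nodes$gene_id)
  net
}

#' Convert a co-expression network to an igraph graph
#'
#' @param net a `coexpression_network`.
#' @return An undirected [igraph::igraph] with node attributes `biotype`,
#'   `degree` and edge attributes `pcc`, `p_value`, `sign`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "coexpression_network"))
  igraph::graph_from_data_frame(
    net$edges[, c("lncrna_id", "mrna_id", "pcc", "p_value", "sign")],
    directed = FALSE,
    vertices = net$nodes)
}

#' Export a network as an edge-list TSV and GraphML
#'
#' The edge list carries `lncrna_id`, `mrna_id`, `pcc`, `p_value`, `sign`;
#' the GraphML file carries node `biotype`/`degree` attributes. Both are
#' formats network viewers such as Cytoscape consume, and both round-trip
#' through [read_network_edges()] / [igraph::read_graph()].
#'
#' @param net a `coexpression_network`.
#' @param edge_path,graphml_path output paths (`NULL` skips that file).
#' @return Invisibly, the written paths.
#' @export
export_graph <- function(net, edge_path = NULL, graphml_path = NULL) {
  stopifnot(inherits(net, "coexpression_network"))
  written <- character()
  if (!is.null(edge_path)) {
    utils::write.table(net$edges, edge_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, edge_path)
  }
  if (!is.null(graphml_path)) {
    igraph::write_graph(as_igraph(net), graphml_path, format = "graphml")
    written <- c(written, graphml_path)
  }
  invisible(written)
}

#' Read a network edge list written by [export_graph()]
#'
#' @param path edge-list TSV path.
#' @param min_abs_pcc,max_p thresholds to record on the rebuilt object.
#' @param n_samples sample count to record.
#' @return A `coexpression_network`.
#' @export
read_network_edges <- function(path, min_abs_pcc = NA, max_p = NA,
                               n_samples = NA) {
  edges <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = c(lncrna_id = "character",
                                            mrna_id = "character"))
  need <- c("lncrna_id", "mrna_id", "pcc", "p_value", "sign")
  if (!all(need %in% names(edges)))
    stop("edge list must have columns ", paste(need, collapse = ", "),
         ": ", path, call. = FALSE)
  new_coexpression_network(edges, min_abs_pcc, max_p, n_samples)
}
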