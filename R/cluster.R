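#' Deterministic average-linkage clustering for heat-map ordering
#'
#' Orders significant genes (and samples) by agglomerative clustering on
#' the correlation distance `1 - PCC`, the conventional overview of a
#' differential-expression heat map. Merge ties are broken by the
#' lexicographically smallest member id of the candidate cluster pairs, so
#' the leaf order is reproducible across platforms; at each merge the
#' cluster containing the smaller id is placed on the left.
#'
#' Constant (zero-variance) rows have no defined correlation; they are
#' assigned the maximal distance 2 to every other item and a warning is
#' issued.
#'
#' @param expr an [expression_set()].
#' @param records a `de_result`; clustering uses the significant genes.
#' @return List of class `cluster_order` with `genes` and `samples` (leaf
#'   orders) and `gene_heights` / `sample_heights` (merge heights).
#' @export
cluster_order <- function(expr, records) {
  stopifnot(inherits(expr, "expression_set"))
  sig <- records$gene_id[records$significant]
  if (length(sig) < 2)
    stop("clustering needs at least two significant genes", call. = FALSE)
  m <- expr$values[sig, , drop = FALSE]
  g <- agglomerate(correlation_distance(m))
  s <- agglomerate(correlation_distance(t(m)))
  structure(list(genes = g$order, samples = s$order,
                 gene_heights = g$heights, sample_heights = s$heights),
            class = "cluster_order")
}

#' @export
print.cluster_order <- function(x, ...) {
  cat(sprintf("cluster_order: %d genes, %d samples\n",
              length(x$genes), length(x$samples)))
  invisible(x)
}

## 1 - Pearson correlation between rows; constant rows get distance 2.
correlation_distance <- function(m) {
  sds <- apply(m, 1, stats::sd)
  d <- matrix(2, nrow(m), nrow(m), dimnames = list(rownames(m),
                                                   rownames(m)))
  ok <- sds > 0
  if (any(!ok))
    warning(sum(!ok), " constant row(s) assigned maximal distance in ",
            "clustering", call. = FALSE)
  if (sum(ok) >= 2)
    d[ok, ok] <- 1 - stats::cor(t(m[ok, , drop = FALSE]))
  diag(d) <- 0
  d
}

## Average-linkage agglomeration with deterministic tie-breaking.
## Ties in merge distance are broken by comparing the sorted pair of
## smallest member ids of the two candidate clusters.
agglomerate <- function(d) {
  labels <- rownames(d)
  n <- length(labels)
  if (n == 1) return(list(order = labels, heights = numeric(0)))
  members <- as.list(labels)          # ordered members per active cluster
  min_id <- labels                    # smallest member id per cluster
  size <- rep(1, n)
  active <- rep(TRUE, n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    best <- NULL
    for (ai in seq_along(idx)) {
      for (bi in seq_len(ai - 1L)) {
        a <- idx[ai]; b <- idx[bi]
        key <- sort(c(min_id[a], min_id[b]))
        cand <- list(a = a, b = b, h = d[a, b], key = key)
        if (is.null(best) || cand$h < best$h ||
            (cand$h == best$h &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2]))))
          best <- cand
      }
    }
    a <- best$a; b <- best$b
    if (min_id[b] < min_id[a]) { tmp <- a; a <- b; b <- tmp }
    heights[step] <- best$h
    ## Lance-Williams update for average linkage
    upd <- (size[a] * d[a, ] + size[b] * d[b, ]) / (size[a] + size[b])
    d[a, ] <- upd; d[, a] <- upd; d[a, a] <- 0
    members[[a]] <- c(members[[a]], members[[b]])
    min_id[a] <- min(min_id[a], min_id[b])
    size[a] <- size[a] + size[b]
    active[b] <- FALSE
  }
  list(order = members[[which(active)]], heights = heights)
}
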