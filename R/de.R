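#' Significance thresholds for differential expression
#'
#' Defaults follow the common filtering rule for this kind of study:
#' linear fold change above 2 or below 0.5, raw p below 0.05 and
#' Benjamini-Hochberg FDR below 0.1, all strict inequalities. The
#' pseudocount keeps fold changes finite for zero-expression genes and is
#' also added inside the log2 transform before testing.
#'
#' @param fc_up,fc_down linear fold-change cut-offs (up / down).
#' @param p_max raw p-value cut-off.
#' @param fdr_max BH-FDR cut-off.
#' @param pseudocount value added to group means and inside log2.
#' @return A list of class `de_thresholds`.
#' @export
de_thresholds <- function(fc_up = 2.0, fc_down = 0.5, p_max = 0.05,
                          fdr_max = 0.1, pseudocount = 0.25) {
  if (!(fc_up > 1)) stop("fc_up must exceed 1", call. = FALSE)
  if (!(fc_down > 0 && fc_down < 1))
    stop("fc_down must lie in (0, 1)", call. = FALSE)
  if (!(p_max > 0 && p_max <= 1)) stop("p_max must lie in (0, 1]",
                                       call. = FALSE)
  if (!(fdr_max > 0 && fdr_max <= 1)) stop("fdr_max must lie in (0, 1]",
                                           call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  structure(list(fc_up = fc_up, fc_down = fc_down, p_max = p_max,
                 fdr_max = fdr_max, pseudocount = pseudocount),
            class = "de_thresholds")
}

group_means <- function(expr) {
  tumor <- expr$values[, expr$group == "tumor", drop = FALSE]
  normal <- expr$values[, expr$group == "normal", drop = FALSE]
  if (ncol(tumor) == 0 || ncol(normal) == 0)
    stop("both tumor and normal samples are required", call. = FALSE)
  list(tumor = rowMeans(tumor), normal = rowMeans(normal))
}

#' Per-gene fold change between tumor and normal means
#'
#' `fc = (mean_tumor + pseudocount) / (mean_normal + pseudocount)`, defined
#' for every gene including those with zero expression in one group.
#'
#' @param expr an [expression_set()].
#' @param thresholds a [de_thresholds()] (supplies the pseudocount).
#' @return Data frame with `gene_id`, `biotype`, `mean_tumor`,
#'   `mean_normal`, `fc`, `log2fc`.
#' @export
compute_fold_change <- function(expr, thresholds = de_thresholds()) {
  stopifnot(inherits(expr, "expression_set"))
  m <- group_means(expr)
  fc <- (m$tumor + thresholds$pseudocount) /
    (m$normal + thresholds$pseudocount)
  data.frame(gene_id = rownames(expr$values),
             biotype = unname(expr$biotype),
             mean_tumor = unname(m$tumor), mean_normal = unname(m$normal),
             fc = unname(fc), log2fc = unname(log2(fc)),
             stringsAsFactors = FALSE)
}

#' Per-gene two-sided Welch t-test on log2 expression
#'
#' Tests tumor vs normal on `log2(value + pseudocount)` with
#' Welch-Satterthwaite degrees of freedom, vectorized over genes.
#' Degenerate genes (zero variance in both groups) return p = 1 when the
#' group means agree and the smallest representable positive double when
#' they differ.
#'
#' @param expr an [expression_set()] with at least two samples per group.
#' @param pseudocount added inside the log2 transform.
#' @return Named numeric vector of two-sided p-values.
#' @export
welch_t_test <- function(expr, pseudocount = 0.25) {
  stopifnot(inherits(expr, "expression_set"))
  x <- log2(expr$values + pseudocount)
  g1 <- x[, expr$group == "tumor", drop = FALSE]
  g2 <- x[, expr$group == "normal", drop = FALSE]
  n1 <- ncol(g1); n2 <- ncol(g2)
  if (n1 < 2 || n2 < 2)
    stop("each group needs at least two samples for the Welch test",
         call. = FALSE)
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  v1 <- rowSums((g1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((g2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  p <- rep(NA_real_, nrow(x))
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1,
                          .Machine$double.xmin)
  ok <- !degenerate
  tstat <- (m1[ok] - m2[ok]) / sqrt(se2[ok])
  df <- se2[ok]^2 / (v1[ok]^2 / (n1^2 * (n1 - 1)) +
                     v2[ok]^2 / (n2^2 * (n2 - 1)))
  p[ok] <- 2 * stats::pt(-abs(tstat), df)
  stats::setNames(p, rownames(x))
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_{j >= i} m * p_(j) / j`, clipped to at most 1, returned in
#' the input order. Written out explicitly so it can be cross-checked
#' against [stats::p.adjust()] as an independent reference.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  o <- order(p)
  vals <- m * p[o] / seq_len(m)
  q_sorted <- pmin(1, rev(cummin(rev(vals))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Apply significance calls to a DE record table
#'
#' A gene is significant iff (`fc > fc_up` or `fc < fc_down`) and
#' `p < p_max` and `fdr < fdr_max`, all strict. `direction` reflects the
#' fold-change side (`up`/`down`) and is `none` for genes inside the
#' fold-change band. Idempotent: depends only on `fc`, `p_value`, `fdr`.
#'
#' @param records data frame with columns `fc`, `p_value`, `fdr`.
#' @param thresholds a [de_thresholds()].
#' @return `records` with `significant` (logical) and `direction` columns.
#' @export
filter_significant <- function(records, thresholds = de_thresholds()) {
  stopifnot(all(c("fc", "p_value", "fdr") %in% names(records)))
  direction <- ifelse(records$fc > thresholds$fc_up, "up",
                      ifelse(records$fc < thresholds$fc_down, "down",
                             "none"))
  records$significant <- direction != "none" &
    records$p_value < thresholds$p_max & records$fdr < thresholds$fdr_max
  records$direction <- ifelse(records$significant, direction, "none")
  records
}

#' Run the full differential-expression stage
#'
#' Fold change, per-gene Welch test on log2 values, BH-FDR (by default
#' within each biotype separately, since lncRNAs and mRNAs are reported as
#' separate populations), and threshold-based significance calls.
#'
#' @param expr an [expression_set()].
#' @param thresholds a [de_thresholds()].
#' @param fdr_by `"biotype"` (default) or `"pooled"`.
#' @return Data frame of class `de_result` with one row per gene and
#'   columns `gene_id`, `biotype`, `mean_tumor`, `mean_normal`, `fc`,
#'   `log2fc`, `p_value`, `fdr`, `significant`, `direction`.
#' @export
de_analysis <- function(expr, thresholds = de_thresholds(),
                        fdr_by = c("biotype", "pooled")) {
  fdr_by <- match.arg(fdr_by)
  records <- compute_fold_change(expr, thresholds)
  records$p_value <- unname(welch_t_test(expr, thresholds$pseudocount))
  if (fdr_by == "biotype") {
    records$fdr <- NA_real_
    for (b in unique(records$biotype)) {
      idx <- records$biotype == b
      records$fdr[idx] <- bh_fdr(records$p_value[idx])
    }
  } else {
    records$fdr <- bh_fdr(records$p_value)
  }
  records <- filter_significant(records, thresholds)
  structure(records, thresholds = thresholds,
            class = c("de_result", "data.frame"))
}

#' @export
print.de_result <- function(x, ...) {
  s <- summarize_counts(x)
  cat(sprintf("de_result: %d genes tested\n", nrow(x)))
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s: %d significant (%d up, %d down)\n",
                s$biotype[i], s$n_total[i], s$n_up[i], s$n_down[i]))
  invisible(x)
}

#' @export
summary.de_result <- function(object, ...) summarize_counts(object)

#' Count significant genes per biotype and direction
#'
#' Also counts genes beyond an extra fold-change cut (default 10), i.e.
#' significant genes with `fc > extra_fc_cut` or `fc < 1/extra_fc_cut`.
#'
#' @param records DE record table with significance calls.
#' @param extra_fc_cut secondary linear fold-change cut (default 10).
#' @return Data frame with one row per biotype: `n_up`, `n_down`,
#'   `n_total` (= up + down), `n_extreme_up`, `n_extreme_down`,
#'   `n_extreme`.
#' @export
summarize_counts <- function(records, extra_fc_cut = 10) {
  bio <- factor(records$biotype, levels = c("mRNA", "lncRNA"))
  sig <- records$significant
  count <- function(cond) as.integer(
    table(bio[cond & sig], useNA = "no")[c("mRNA", "lncRNA")])
  zero_na <- function(v) ifelse(is.na(v), 0L, v)
  out <- data.frame(
    biotype = c("mRNA", "lncRNA"),
    n_up = zero_na(count(records$direction == "up")),
    n_down = zero_na(count(records$direction == "down")),
    stringsAsFactors = FALSE)
  out$n_total <- out$n_up + out$n_down
  out$n_extreme_up <- zero_na(count(records$direction == "up" &
                                      records$fc > extra_fc_cut))
  out$n_extreme_down <- zero_na(count(records$direction == "down" &
                                        records$fc < 1 / extra_fc_cut))
  out$n_extreme <- out$n_extreme_up + out$n_extreme_down
  out
}

#' Export volcano and scatter plot tables
#'
#' The volcano table plots `-log10(fdr)` against `log2fc`, classing genes
#' `up`/`down`/`ns` consistently with [filter_significant()]; an FDR of
#' exactly zero is capped at 320 on the y-axis. The scatter table carries
#' per-group log2 mean expression (`log2(mean + pseudocount)`).
#'
#' @param records a `de_result` (or DE record table with calls).
#' @param pseudocount used for the scatter log2 transform.
#' @return List with data frames `volcano` and `scatter`.
#' @export
export_plot_tables <- function(records, pseudocount = 0.25) {
  stopifnot(all(c("fdr", "log2fc", "significant", "direction") %in%
                  names(records)))
  neg_log10_fdr <- ifelse(records$fdr == 0, 320, -log10(records$fdr))
  class_ <- ifelse(records$significant, records$direction, "ns")
  volcano <- data.frame(gene_id = records$gene_id,
                        log2fc = records$log2fc,
                        neg_log10_fdr = neg_log10_fdr,
                        class = class_, stringsAsFactors = FALSE)
  scatter <- data.frame(
    gene_id = records$gene_id,
    log2_mean_tumor = log2(records$mean_tumor + pseudocount),
    log2_mean_normal = log2(records$mean_normal + pseudocount),
    class = class_, stringsAsFactors = FALSE)
  list(volcano = volcano, scatter = scatter)
}
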