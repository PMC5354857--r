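#' Per-sample relative expression by the 2^-ddCt method
#'
#' Replicate wells are averaged (arithmetic mean of Ct), then
#' `dCt = mean Ct(target) - mean Ct(reference)` per sample and
#' `ddCt = dCt - calibrator`, where the calibrator is the mean
#' normal-group dCt (default; equivalent to calibrating on the geometric
#' mean of the control group, whose mean relative expression is then 1 by
#' construction) or the dCt of a named calibrator sample. Relative
#' expression is `2^-ddCt`.
#'
#' @param ct Ct table (`sample_id`, `group`, `gene_id`, `replicate`,
#'   `ct`).
#' @param target target gene id.
#' @param reference reference (housekeeping) gene id; samples lacking it
#'   are excluded with a warning.
#' @param calibrator `"normal_mean"` (default) or a sample id.
#' @return Data frame: `sample_id`, `group`, `delta_ct`,
#'   `delta_delta_ct`, `rel_expr`.
#' @export
relative_expression <- function(ct, target, reference,
                                calibrator = "normal_mean") {
  need <- c("sample_id", "group", "gene_id", "replicate", "ct")
  stopifnot(all(need %in% names(ct)))
  if (any(ct$ct <= 0)) stop("Ct values must be positive", call. = FALSE)
  mean_ct <- function(gene) {
    sub <- ct[ct$gene_id == gene, , drop = FALSE]
    tapply(sub$ct, sub$sample_id, mean)
  }
  tgt <- mean_ct(target)
  ref <- mean_ct(reference)
  if (length(tgt) == 0) stop("target gene ", target,
                             " absent from Ct table", call. = FALSE)
  samples <- names(tgt)
  no_ref <- setdiff(samples, names(ref))
  if (length(no_ref)) {
    warning("sample(s) lacking the reference gene excluded: ",
            paste(no_ref, collapse = ", "), call. = FALSE)
    samples <- setdiff(samples, no_ref)
  }
  group <- ct$group[match(samples, ct$sample_id)]
  d_ct <- tgt[samples] - ref[samples]
  cal <- if (identical(calibrator, "normal_mean")) {
    if (!any(group == "normal"))
      stop("no normal samples available as calibrator", call. = FALSE)
    mean(d_ct[group == "normal"])
  } else {
    if (!calibrator %in% samples)
      stop("calibrator sample ", calibrator, " not measured for ",
           target, call. = FALSE)
    d_ct[calibrator]
  }
  dd_ct <- d_ct - cal
  data.frame(sample_id = samples, group = group,
             delta_ct = unname(d_ct), delta_delta_ct = unname(dd_ct),
             rel_expr = unname(2^(-dd_ct)),
             stringsAsFactors = FALSE, row.names = NULL)
}

## Two-sample t on a numeric vector split by group; Welch by default.
## Degenerate data (zero variance in both groups) gets p = 1 for equal
## means and the smallest positive double otherwise.
two_sample_t <- function(x, group, var_equal = FALSE) {
  a <- x[group == "tumor"]; b <- x[group == "normal"]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least two samples", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  if (var_equal) {
    sp2 <- ((length(a) - 1) * va + (length(b) - 1) * vb) /
      (length(a) + length(b) - 2)
    se2 <- sp2 * (1 / length(a) + 1 / length(b))
    df <- length(a) + length(b) - 2
  } else {
    se2 <- va / length(a) + vb / length(b)
    df <- se2^2 / (va^2 / (length(a)^2 * (length(a) - 1)) +
                   vb^2 / (length(b)^2 * (length(b) - 1)))
  }
  if (se2 == 0)
    return(if (mean(a) == mean(b)) 1 else .Machine$double.xmin)
  2 * stats::pt(-abs((mean(a) - mean(b)) / sqrt(se2)), df)
}

#' Compare relative expression between groups
#'
#' Mean and SD of `2^-ddCt` per group plus a two-sided two-sample t-test
#' (Welch by default, reflecting the unequal group sizes; set
#' `var_equal = TRUE` for the pooled-variance Student variant).
#'
#' @param rel data frame from [relative_expression()].
#' @param var_equal pooled-variance test instead of Welch.
#' @param p_max significance cut (default 0.05).
#' @return List: `mean_tumor`, `sd_tumor`, `mean_normal`, `sd_normal`,
#'   `p_value`, `significant`.
#' @export
group_compare <- function(rel, var_equal = FALSE, p_max = 0.05) {
  stopifnot(all(c("group", "rel_expr") %in% names(rel)))
  p <- two_sample_t(rel$rel_expr, rel$group, var_equal)
  list(mean_tumor = mean(rel$rel_expr[rel$group == "tumor"]),
       sd_tumor = stats::sd(rel$rel_expr[rel$group == "tumor"]),
       mean_normal = mean(rel$rel_expr[rel$group == "normal"]),
       sd_normal = stats::sd(rel$rel_expr[rel$group == "normal"]),
       p_value = p, significant = p < p_max)
}

#' Quantify every target gene in a Ct table
#'
#' Runs [relative_expression()] and [group_compare()] for each non-reference
#' gene. The estimated fold change is the geometric mean of tumor-sample
#' relative expression (exactly the planted fold change at zero noise).
#'
#' @param ct Ct table.
#' @param reference reference gene id.
#' @param targets target gene ids (default: every other gene in the
#'   table).
#' @param var_equal passed to [group_compare()].
#' @return Data frame of class `qpcr_result`: one row per target with
#'   group means/SDs, `fold_change`, `p_value`, `significant`.
#' @export
qpcr_analysis <- function(ct, reference, targets = NULL,
                          var_equal = FALSE) {
  if (is.null(targets)) targets <- setdiff(unique(ct$gene_id), reference)
  rows <- lapply(targets, function(g) {
    rel <- relative_expression(ct, g, reference)
    cmp <- group_compare(rel, var_equal)
    fc <- 2^mean(-rel$delta_delta_ct[rel$group == "tumor"])
    data.frame(gene_id = g, mean_tumor = cmp$mean_tumor,
               sd_tumor = cmp$sd_tumor, mean_normal = cmp$mean_normal,
               sd_normal = cmp$sd_normal, fold_change = fc,
               p_value = cmp$p_value, significant = cmp$significant,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("qpcr_result", "data.frame"))
}

#' @export
print.qpcr_result <- function(x, ...) {
  cat(sprintf("qpcr_result: %d targets, %d significant at p < 0.05\n",
              nrow(x), sum(x$significant)))
  print.data.frame(as.data.frame(x), digits = 4)
  invisible(x)
}
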