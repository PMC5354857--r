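#' Gene-by-sample expression container
#'
#' Bundles a non-negative genes x samples matrix of normalized expression
#' values (FPKM-like) with a per-gene biotype (`"mRNA"` or `"lncRNA"`) and a
#' per-sample group label (`"tumor"` or `"normal"`).
#'
#' @param values numeric matrix, genes in rows (rownames are gene ids),
#'   samples in columns (colnames are sample ids). All values must be
#'   non-negative and finite.
#' @param biotype character vector, one of `"mRNA"`/`"lncRNA"` per gene.
#' @param group character vector, one of `"tumor"`/`"normal"` per sample.
#' @return An object of class `expression_set`: a list with elements
#'   `values`, `biotype`, `group`.
#' @export
expression_set <- function(values, biotype, group) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in expression matrix", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in expression matrix", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and non-negative", call. = FALSE)
  biotype <- as.character(biotype)
  group <- as.character(group)
  if (length(biotype) != nrow(values))
    stop("`biotype` must have one entry per gene", call. = FALSE)
  if (!all(biotype %in% c("mRNA", "lncRNA")))
    stop("`biotype` entries must be 'mRNA' or 'lncRNA'", call. = FALSE)
  if (length(group) != ncol(values))
    stop("`group` must have one entry per sample", call. = FALSE)
  if (!all(group %in% c("tumor", "normal")))
    stop("`group` entries must be 'tumor' or 'normal'", call. = FALSE)
  structure(
    list(values = values,
         biotype = stats::setNames(biotype, rownames(values)),
         group = stats::setNames(group, colnames(values))),
    class = "expression_set"
  )
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("expression_set: %d genes (%d mRNA, %d lncRNA) x %d samples (%d tumor, %d normal)\n",
              nrow(x$values),
              sum(x$biotype == "mRNA"), sum(x$biotype == "lncRNA"),
              ncol(x$values),
              sum(x$group == "tumor"), sum(x$group == "normal")))
  invisible(x)
}

#' @export
dim.expression_set <- function(x) dim(x$values)

#' Subset an expression set by gene and/or sample
#'
#' @param x an `expression_set`.
#' @param genes,samples character or logical index vectors; `NULL` keeps all.
#' @return An `expression_set` restricted to the requested rows/columns.
#' @export
subset_expression <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "expression_set"))
  if (is.null(genes)) genes <- rownames(x$values)
  if (is.null(samples)) samples <- colnames(x$values)
  expression_set(x$values[genes, samples, drop = FALSE],
                 x$biotype[genes], x$group[samples])
}

#' Write / read expression matrix and sample sheet TSVs
#'
#' The matrix TSV has a `gene_id` first column, an optional `biotype`
#' second column, then one column per sample. The sample sheet has columns
#' `sample_id` and `group`.
#'
#' @param x an `expression_set`.
#' @param matrix_path,sheet_path file paths for the matrix and sample sheet.
#' @return `write_expression_set` returns the paths invisibly;
#'   `read_expression_set` returns an `expression_set`.
#' @export
write_expression_set <- function(x, matrix_path, sheet_path) {
  stopifnot(inherits(x, "expression_set"))
  df <- data.frame(gene_id = rownames(x$values),
                   biotype = unname(x$biotype),
                   x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sheet <- data.frame(sample_id = colnames(x$values),
                      group = unname(x$group), stringsAsFactors = FALSE)
  utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, sheet_path))
}

#' @rdname write_expression_set
#' @export
read_expression_set <- function(matrix_path, sheet_path) {
  df <- utils::read.delim(matrix_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id")
    stop("matrix TSV must start with a gene_id column: ", matrix_path,
         call. = FALSE)
  sheet <- utils::read.delim(sheet_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(sheet)))
    stop("sample sheet must have sample_id and group columns: ", sheet_path,
         call. = FALSE)
  biotype <- if ("biotype" %in% names(df)) df$biotype else
    rep("mRNA", nrow(df))
  value_cols <- setdiff(names(df), c("gene_id", "biotype"))
  missing <- setdiff(value_cols, sheet$sample_id)
  if (length(missing))
    stop("samples in matrix missing from sample sheet: ",
         paste(missing, collapse = ", "), call. = FALSE)
  m <- as.matrix(df[, value_cols, drop = FALSE])
  rownames(m) <- df$gene_id
  group <- sheet$group[match(value_cols, sheet$sample_id)]
  expression_set(m, biotype, group)
}
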