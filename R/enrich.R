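#' Construct a gene-set collection
#'
#' @param members named list: set id -> character vector of member gene
#'   ids (non-empty, duplicates removed).
#' @param description optional named character vector of set descriptions.
#' @param expected_direction optional named vector (gene id -> `up`/`down`)
#'   of the direction each member is expected to move when the pathway is
#'   active; used by [activation_zscore()].
#' @return An object of class `gene_sets`.
#' @export
gene_sets <- function(members, description = NULL,
                      expected_direction = NULL) {
  if (!is.list(members) || is.null(names(members)) ||
      any(names(members) == ""))
    stop("`members` must be a named list of gene id vectors",
         call. = FALSE)
  if (anyDuplicated(names(members)))
    stop("duplicate set ids", call. = FALSE)
  members <- lapply(members, function(m) unique(as.character(m)))
  if (any(lengths(members) == 0))
    stop("every gene set must be non-empty", call. = FALSE)
  if (is.null(description))
    description <- stats::setNames(names(members), names(members))
  if (!is.null(expected_direction) &&
      !all(expected_direction %in% c("up", "down")))
    stop("expected_direction entries must be 'up' or 'down'",
         call. = FALSE)
  structure(list(members = members,
                 description = description[names(members)],
                 expected_direction = expected_direction),
            class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("gene_sets: %d sets, %d-%d members\n", length(x$members),
              min(lengths(x$members)), max(lengths(x$members))))
  invisible(x)
}

#' Write / read gene sets in GMT format
#'
#' One set per line: set id, description, then tab-separated member ids.
#' Reading uses [fgsea::gmtPathways()]; the description column is not
#' preserved by that reader and is reset to the set id.
#'
#' @param sets a [gene_sets()] collection.
#' @param path GMT file path.
#' @return The path (write) or a `gene_sets` collection (read).
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_sets"))
  lines <- vapply(names(sets$members), function(id)
    paste(c(id, sets$description[[id]], sets$members[[id]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  gene_sets(fgsea::gmtPathways(path))
}

#' Write / read per-gene expected-direction annotations
#'
#' Two-column TSV (`gene_id`, `direction`) giving the direction each gene
#' is expected to move when its pathway is active.
#'
#' @param direction named vector (gene id -> `up`/`down`).
#' @param path TSV path.
#' @return The path (write) or the named vector (read).
#' @export
write_directions <- function(direction, path) {
  utils::write.table(
    data.frame(gene_id = names(direction), direction = unname(direction)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_directions
#' @export
read_directions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$direction, df$gene_id)
}

#' Fisher exact gene-set enrichment
#'
#' One-sided (enrichment) Fisher exact test per set from the 2x2 table of
#' overlap / DE-only / set-only / neither, i.e. the hypergeometric upper
#' tail. Set members are intersected with the universe before testing;
#' sets with empty intersection are skipped with a warning.
#'
#' @param de_genes character vector of differentially expressed gene ids
#'   (must be a subset of `universe`).
#' @param sets a [gene_sets()] collection.
#' @param universe background gene ids (typically every detected gene).
#' @param alternative `"greater"` (default, enrichment) or `"two.sided"`.
#' @return Data frame of class `enrichment_result`, sorted by p-value:
#'   `set_id`, `n_universe`, `n_set`, `n_de`, `n_overlap`, `p_value`,
#'   `neg_log10_p`.
#' @export
fisher_enrichment <- function(de_genes, sets, universe,
                              alternative = c("greater", "two.sided")) {
  stopifnot(inherits(sets, "gene_sets"))
  alternative <- match.arg(alternative)
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty gene universe", call. = FALSE)
  de_genes <- unique(as.character(de_genes))
  if (!all(de_genes %in% universe))
    stop("de_genes must be a subset of the universe", call. = FALSE)
  n_u <- length(universe)
  n_de <- length(de_genes)
  rows <- lapply(names(sets$members), function(id) {
    mem <- intersect(sets$members[[id]], universe)
    if (length(mem) == 0) {
      warning("set ", id, " shares no genes with the universe; skipped",
              call. = FALSE)
      return(NULL)
    }
    k <- length(intersect(mem, de_genes))
    if (alternative == "greater") {
      p <- stats::phyper(k - 1, n_de, n_u - n_de, length(mem),
                         lower.tail = FALSE)
    } else {
      tab <- matrix(c(k, n_de - k, length(mem) - k,
                      n_u - n_de - length(mem) + k), 2)
      p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    }
    data.frame(set_id = id, n_universe = n_u, n_set = length(mem),
               n_de = n_de, n_overlap = k, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no gene set overlaps the universe", call. = FALSE)
  out$neg_log10_p <- -log10(out$p_value)
  out <- out[order(out$p_value, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: %d sets tested, %d with -log10(p) > 1.3\n",
              nrow(x), sum(x$neg_log10_p > 1.3)))
  print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Filter enrichment results at a -log10(p) cut-off
#'
#' Keeps sets with `-log10(p) > neg_log10_cut` (strictly), the
#' conventional `-log(P) > 1.3` rule, i.e. p below about 0.05.
#'
#' @param results an `enrichment_result`.
#' @param neg_log10_cut cut-off on `-log10(p)` (default 1.3).
#' @return The filtered `enrichment_result`.
#' @export
significance_filter <- function(results, neg_log10_cut = 1.3) {
  out <- results[results$neg_log10_p > neg_log10_cut, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sign-consistency activation score for one gene set
#'
#' Compares each DE member's observed direction with the direction it is
#' expected to move when the pathway is active:
#' `z = (n_consistent - n_inconsistent) / sqrt(n)` over the annotated DE
#' members. `z >= 2` labels the pathway activated, `z <= -2` suppressed,
#' anything else (including no annotated DE member) unpredicted. This is
#' an openly specified stand-in for proprietary pathway-direction
#' analytics and is labelled as such in pipeline output metadata.
#'
#' @param members gene ids of the set.
#' @param expected_direction named vector (gene id -> `up`/`down`).
#' @param de_records a `de_result` (or DE record table with calls).
#' @return List with `z_score` (`NA` when undefined) and `status`.
#' @export
activation_zscore <- function(members, expected_direction, de_records) {
  obs <- de_records$direction[de_records$significant]
  names(obs) <- de_records$gene_id[de_records$significant]
  ann <- intersect(members,
                   intersect(names(obs), names(expected_direction)))
  if (length(ann) == 0)
    return(list(z_score = NA_real_, status = "unpredicted"))
  consistent <- sum(obs[ann] == expected_direction[ann])
  z <- (2 * consistent - length(ann)) / sqrt(length(ann))
  status <- if (z >= 2) "activated" else if (z <= -2) "suppressed" else
    "unpredicted"
  list(z_score = z, status = status)
}

#' Score every enriched set for activation status
#'
#' @param results an `enrichment_result`.
#' @param sets the [gene_sets()] used for testing (with
#'   `expected_direction` annotations).
#' @param de_records a `de_result`.
#' @return `results` with `z_score` and `status` columns appended.
#' @export
score_activation <- function(results, sets, de_records) {
  sc <- lapply(results$set_id, function(id)
    activation_zscore(sets$members[[id]], sets$expected_direction,
                      de_records))
  results$z_score <- vapply(sc, `[[`, numeric(1), "z_score")
  results$status <- vapply(sc, `[[`, character(1), "status")
  results
}

#' Pathway-act network over the top enriched sets
#'
#' Among the `top_k` most significant sets, joins every pair of pathways
#' sharing strictly more than `min_shared` differentially expressed genes.
#'
#' @param results an `enrichment_result` (sorted by p, as returned by
#'   [fisher_enrichment()]).
#' @param sets the [gene_sets()] collection.
#' @param de_genes DE gene ids used for the shared counts.
#' @param top_k number of top sets considered (default 20).
#' @param min_shared edge rule: shared DE genes must exceed this
#'   (default 5, strict).
#' @return List with `edges` (`set_id_a`, `set_id_b`, `n_shared_de`) and
#'   `nodes` (the top-k results, with status when present).
#' @export
pathway_act_network <- function(results, sets, de_genes, top_k = 20,
                                min_shared = 5) {
  top <- utils::head(results, top_k)
  ids <- top$set_id
  edges <- list()
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1L)) {
      shared <- length(intersect(
        intersect(sets$members[[ids[i]]], sets$members[[ids[j]]]),
        de_genes))
      if (shared > min_shared)
        edges[[length(edges) + 1]] <- data.frame(
          set_id_a = ids[j], set_id_b = ids[i], n_shared_de = shared,
          stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(set_id_a = character(), set_id_b = character(),
               n_shared_de = integer(), stringsAsFactors = FALSE)
  list(edges = edges, nodes = as.data.frame(top))
}

#' Simulate pathway gene sets with controlled DE overlap
#'
#' Builds GMT-serializable sets over the simulated mRNA universe with an
#' exact number of DE members per set and exact pairwise shared-DE-gene
#' counts; all remaining members are set-exclusive, so overlaps not listed
#' in `shared_de` are zero. Construction is deterministic (genes are taken
#' from the pools in id order). DE members carry their planted direction
#' as the expected activation direction, so packed sets score as
#' activated/suppressed downstream.
#'
#' @param config a [sim_config()].
#' @param truth the planted-truth list of [simulate_expression()].
#' @param n_pathways number of sets (default 8, sized for the
#'   desk-scale simulated universe).
#' @param set_size members per set (scalar or vector).
#' @param de_overlap DE members per set; default packs the first three
#'   sets (10, 6, 4) and leaves the rest at zero.
#' @param shared_de data frame (`set_a`, `set_b`, `n_shared`) of exact
#'   pairwise shared-DE counts; the default plants one pair sharing 6.
#' @return A [gene_sets()] collection.
#' @export
simulate_pathways <- function(config, truth, n_pathways = 8,
                              set_size = 15, de_overlap = NULL,
                              shared_de = NULL) {
  validate_sim_config(config)
  de_pool <- truth$de_genes$gene_id[truth$de_genes$biotype == "mRNA"]
  dir_pool <- stats::setNames(truth$de_genes$direction,
                              truth$de_genes$gene_id)
  nonde_pool <- setdiff(mrna_ids(config$n_mrna), de_pool)
  if (is.null(de_overlap))
    de_overlap <- c(10, 6, 4, rep(0, max(0, n_pathways - 3)))[
      seq_len(n_pathways)]
  if (is.null(shared_de))
    shared_de <- if (n_pathways >= 2 && de_overlap[1] >= 6 &&
                     de_overlap[2] >= 6)
      data.frame(set_a = 1, set_b = 2, n_shared = 6) else
      data.frame(set_a = integer(), set_b = integer(),
                 n_shared = integer())
  set_size <- rep_len(set_size, n_pathways)
  if (length(de_overlap) != n_pathways)
    stop("de_overlap must have one entry per pathway", call. = FALSE)
  if (any(de_overlap > set_size))
    stop("requested DE overlap exceeds set size", call. = FALSE)

  ids <- sprintf("PATH%02d", seq_len(n_pathways))
  members <- stats::setNames(rep(list(character()), n_pathways), ids)
  quota <- de_overlap
  take <- function(pool, k, what) {
    if (k > length(pool))
      stop("requested ", what, " exceeds available genes", call. = FALSE)
    pool[seq_len(k)]
  }
  for (r in seq_len(nrow(shared_de))) {
    a <- shared_de$set_a[r]; b <- shared_de$set_b[r]
    k <- shared_de$n_shared[r]
    if (k > quota[a] || k > quota[b])
      stop("requested shared-DE count exceeds a set's DE overlap",
           call. = FALSE)
    g <- take(de_pool, k, "shared DE overlap")
    de_pool <- setdiff(de_pool, g)
    members[[a]] <- c(members[[a]], g)
    members[[b]] <- c(members[[b]], g)
    quota[a] <- quota[a] - k; quota[b] <- quota[b] - k
  }
  for (i in seq_len(n_pathways)) {
    g <- take(de_pool, quota[i], "DE overlap")
    de_pool <- setdiff(de_pool, g)
    members[[i]] <- c(members[[i]], g)
    fill <- take(nonde_pool, set_size[i] - length(members[[i]]),
                 "set size")
    nonde_pool <- setdiff(nonde_pool, fill)
    members[[i]] <- c(members[[i]], fill)
  }
  gene_sets(members, expected_direction = dir_pool)
}
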