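#' Simulation configuration for the synthetic study
#'
#' Describes a synthetic two-group expression study patterned on an
#' 11-tumor vs 5-normal design, with planted differential expression,
#' planted lncRNA-mRNA correlation modules, positional lncRNA categories
#' and qPCR validation targets. All generators are deterministic given the
#' configuration (which carries a mandatory seed).
#'
#' @param seed integer seed; every generator derives its stream from it.
#' @param n_tumor,n_normal samples per group (defaults 11 and 5).
#' @param n_mrna,n_lncrna genes per biotype.
#' @param n_de_up_mrna,n_de_down_mrna,n_de_up_lnc,n_de_down_lnc planted
#'   differentially expressed genes per biotype and direction.
#' @param planted_log2fc absolute log2 fold change planted in DE genes.
#' @param noise_sd residual SD on the log2 scale.
#' @param planted_edges `NULL` or a data frame with columns `lncrna_id`,
#'   `mrna_id`, `target_pcc`; pairs sharing a gene form one latent-factor
#'   module (modules must be stars).
#' @param factor_amplitude amplitude (log2 units) of the shared latent
#'   factor used to plant correlations; default 2.5.
#' @param baseline_range range of per-gene baseline log2 means.
#' @param category_props named proportions over the six positional lncRNA
#'   categories used by [simulate_annotation()].
#' @param chroms chromosomes over which simulated genes are laid out.
#' @param qpcr_targets named vector of true tumor/normal fold changes for
#'   qPCR validation genes.
#' @param qpcr_reference reference (housekeeping) gene id.
#' @param qpcr_noise_sd per-well Ct noise SD (cycles).
#' @param qpcr_replicates wells per sample-gene combination (default 3).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_tumor = 11, n_normal = 5,
                       n_mrna = 150, n_lncrna = 60,
                       n_de_up_mrna = 5, n_de_down_mrna = 20,
                       n_de_up_lnc = 3, n_de_down_lnc = 18,
                       planted_log2fc = 4, noise_sd = 0.3,
                       planted_edges = NULL,
                       factor_amplitude = 2.5,
                       baseline_range = c(2, 8),
                       category_props = c(exonic_sense = 0.129,
                                          intronic_sense = 0.082,
                                          exonic_antisense = 0.203,
                                          intronic_antisense = 0.151,
                                          bidirectional = 0.013,
                                          intergenic = 0.422),
                       chroms = c("chr1", "chr2", "chr3", "chrX", "chrY"),
                       qpcr_targets = c(LNC0001 = 4, LNC0002 = 0.25,
                                        MRNA0001 = 2, MRNA0002 = 0.5),
                       qpcr_reference = "GAPDH",
                       qpcr_noise_sd = 0.1,
                       qpcr_replicates = 3) {
  cfg <- list(seed = seed, n_tumor = n_tumor, n_normal = n_normal,
              n_mrna = n_mrna, n_lncrna = n_lncrna,
              n_de_up_mrna = n_de_up_mrna, n_de_down_mrna = n_de_down_mrna,
              n_de_up_lnc = n_de_up_lnc, n_de_down_lnc = n_de_down_lnc,
              planted_log2fc = planted_log2fc, noise_sd = noise_sd,
              planted_edges = planted_edges,
              factor_amplitude = factor_amplitude,
              baseline_range = baseline_range,
              category_props = category_props / sum(category_props),
              chroms = chroms,
              qpcr_targets = qpcr_targets,
              qpcr_reference = qpcr_reference,
              qpcr_noise_sd = qpcr_noise_sd,
              qpcr_replicates = qpcr_replicates)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fail <- function(field, msg)
    stop(sprintf("invalid simulation config: field `%s` %s", field, msg),
         call. = FALSE)
  num1 <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      fail(field, "must be a single finite number")
    v
  }
  seed <- num1("seed")
  if (seed != round(seed) || abs(seed) >= 2^31 - 16)
    fail("seed", "must be an integer below 2^31")
  for (f in c("n_tumor", "n_normal", "n_mrna", "n_lncrna",
              "n_de_up_mrna", "n_de_down_mrna",
              "n_de_up_lnc", "n_de_down_lnc", "qpcr_replicates")) {
    v <- num1(f)
    if (v < 0 || v != round(v)) fail(f, "must be a non-negative integer")
  }
  if (cfg$qpcr_replicates < 1) fail("qpcr_replicates", "must be >= 1")
  if (num1("noise_sd") < 0) fail("noise_sd", "must be >= 0")
  if (num1("qpcr_noise_sd") < 0) fail("qpcr_noise_sd", "must be >= 0")
  if (num1("factor_amplitude") <= 0) fail("factor_amplitude", "must be > 0")
  num1("planted_log2fc")
  if (cfg$n_de_up_mrna + cfg$n_de_down_mrna > cfg$n_mrna)
    fail("n_de_up_mrna", "+ n_de_down_mrna exceeds n_mrna")
  if (cfg$n_de_up_lnc + cfg$n_de_down_lnc > cfg$n_lncrna)
    fail("n_de_up_lnc", "+ n_de_down_lnc exceeds n_lncrna")
  if (length(cfg$baseline_range) != 2 || diff(cfg$baseline_range) < 0)
    fail("baseline_range", "must be an increasing length-2 range")
  p <- cfg$category_props
  if (length(p) != 6 || is.null(names(p)) ||
      !setequal(names(p), lncrna_categories()) || any(p < 0))
    fail("category_props",
         "must be non-negative and named by the six positional categories")
  pe <- cfg$planted_edges
  if (!is.null(pe)) {
    if (!is.data.frame(pe) ||
        !all(c("lncrna_id", "mrna_id", "target_pcc") %in% names(pe)))
      fail("planted_edges",
           "must have columns lncrna_id, mrna_id, target_pcc")
    if (any(abs(pe$target_pcc) > 1))
      fail("planted_edges", "has target_pcc outside [-1, 1]")
    if (anyDuplicated(pe[c("lncrna_id", "mrna_id")]))
      fail("planted_edges", "contains duplicate pairs")
  }
  invisible(cfg)
}

mrna_ids <- function(n) sprintf("MRNA%04d", seq_len(n))
lnc_ids <- function(n) sprintf("LNC%04d", seq_len(n))

## Planted DE genes are assigned deterministically: the first up-count ids
## of each biotype go up, the next down-count go down.
planted_de_table <- function(cfg) {
  block <- function(ids, biotype, direction, lfc)
    data.frame(gene_id = ids, biotype = rep(biotype, length(ids)),
               direction = rep(direction, length(ids)),
               planted_log2fc = rep(lfc, length(ids)),
               stringsAsFactors = FALSE)
  rbind(
    block(mrna_ids(cfg$n_mrna)[seq_len(cfg$n_de_up_mrna)],
          "mRNA", "up", cfg$planted_log2fc),
    block(mrna_ids(cfg$n_mrna)[cfg$n_de_up_mrna +
                                 seq_len(cfg$n_de_down_mrna)],
          "mRNA", "down", -cfg$planted_log2fc),
    block(lnc_ids(cfg$n_lncrna)[seq_len(cfg$n_de_up_lnc)],
          "lncRNA", "up", cfg$planted_log2fc),
    block(lnc_ids(cfg$n_lncrna)[cfg$n_de_up_lnc +
                                  seq_len(cfg$n_de_down_lnc)],
          "lncRNA", "down", -cfg$planted_log2fc)
  )
}

## Decompose planted edges into star modules: each connected component must
## contain one gene shared by all of its pairs (the hub).
planted_edge_modules <- function(pe) {
  g <- igraph::graph_from_data_frame(pe[, c("lncrna_id", "mrna_id")],
                                     directed = FALSE)
  comp <- igraph::components(g)$membership
  lapply(split(names(comp), comp), function(members) {
    rows <- pe[pe$lncrna_id %in% members | pe$mrna_id %in% members, ,
               drop = FALSE]
    hub <- intersect(Reduce(intersect, Map(c, rows$lncrna_id, rows$mrna_id)),
                     members)
    if (length(hub) != 1 && nrow(rows) > 1)
      stop("planted_edges: each correlation module must be a star ",
           "(all pairs of a module share one gene)", call. = FALSE)
    hub <- if (length(hub)) hub[1] else rows$lncrna_id[1]
    leaves <- ifelse(rows$lncrna_id == hub, rows$mrna_id, rows$lncrna_id)
    list(hub = hub, leaves = leaves, target_pcc = rows$target_pcc)
  })
}

## Standardize to zero mean, unit SD; error on degenerate input.
standardize <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    stop("degenerate latent draw (constant vector)", call. = FALSE)
  (v - mean(v)) / s
}

#' Simulate a tumor/normal expression matrix with planted truth
#'
#' Non-DE genes share a log-normal baseline (log2 values Normal around a
#' per-gene mean drawn uniformly from `baseline_range`). Planted DE genes
#' receive a tumor-group log2 shift equal to their planted log2FC, so the
#' group-mean difference equals the planted value exactly when
#' `noise_sd = 0`. Planted lncRNA-mRNA pairs are driven by a shared latent
#' factor over the tumor samples: the module hub carries the standardized
#' factor and each leaf a combination whose within-tumor sample Pearson
#' correlation with the hub equals `target_pcc` exactly before noise.
#'
#' @param config a [sim_config()].
#' @return A list with elements `expr` (an [expression_set()]) and `truth`
#'   (planted DE table, planted correlated pairs, and the configuration).
#' @export
simulate_expression <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  n_genes <- config$n_mrna + config$n_lncrna
  n_samp <- config$n_tumor + config$n_normal
  gene_id <- c(mrna_ids(config$n_mrna), lnc_ids(config$n_lncrna))
  biotype <- rep(c("mRNA", "lncRNA"), c(config$n_mrna, config$n_lncrna))
  sample_id <- c(sprintf("T%02d", seq_len(config$n_tumor)),
                 sprintf("N%02d", seq_len(config$n_normal)))
  group <- rep(c("tumor", "normal"), c(config$n_tumor, config$n_normal))
  is_tumor <- group == "tumor"

  mu <- stats::runif(n_genes, config$baseline_range[1],
                     config$baseline_range[2])
  log2v <- matrix(mu, n_genes, n_samp) +
    matrix(stats::rnorm(n_genes * n_samp, 0, config$noise_sd),
           n_genes, n_samp)
  dimnames(log2v) <- list(gene_id, sample_id)

  de <- planted_de_table(config)
  if (nrow(de))
    log2v[de$gene_id, is_tumor] <-
      log2v[de$gene_id, is_tumor] + de$planted_log2fc

  pe <- config$planted_edges
  if (!is.null(pe) && nrow(pe)) {
    bad <- setdiff(c(pe$lncrna_id, pe$mrna_id), gene_id)
    if (length(bad))
      stop("invalid simulation config: field `planted_edges` names genes ",
           "not in the simulated matrix: ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (config$n_tumor < 3)
      stop("invalid simulation config: field `n_tumor` must be >= 3 ",
           "when planted_edges are requested", call. = FALSE)
    a <- config$factor_amplitude
    for (mod in planted_edge_modules(pe)) {
      z <- standardize(stats::rnorm(config$n_tumor))
      log2v[mod$hub, is_tumor] <- log2v[mod$hub, is_tumor] + a * z
      for (k in seq_along(mod$leaves)) {
        lam <- mod$target_pcc[k]
        if (abs(lam) == 1) {
          y <- lam * z
        } else {
          e <- stats::rnorm(config$n_tumor)
          e <- standardize(e - z * sum(e * z) / sum(z * z))
          y <- lam * z + sqrt(1 - lam^2) * e
        }
        log2v[mod$leaves[k], is_tumor] <-
          log2v[mod$leaves[k], is_tumor] + a * y
      }
    }
  }

  truth <- list(de_genes = de,
                correlated_pairs = if (is.null(pe))
                  data.frame(lncrna_id = character(), mrna_id = character(),
                             target_pcc = numeric()) else pe,
                config = config)
  list(expr = expression_set(2^log2v, biotype, group), truth = truth)
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Emits per-well threshold-cycle values for the configured target genes
#' and the reference gene, three wells per sample-gene by default. The
#' reference gene has a common baseline Ct in both groups; each target's
#' tumor-group Ct is shifted by `-log2(fold change)` so that downstream
#' 2^-ddCt quantification recovers the configured fold change exactly at
#' zero noise.
#'
#' @param config a [sim_config()]; fields `qpcr_targets`,
#'   `qpcr_reference`, `qpcr_noise_sd`, `qpcr_replicates` drive the table.
#' @return A data frame with columns `sample_id`, `group`, `gene_id`,
#'   `replicate`, `ct`.
#' @export
simulate_qpcr <- function(config) {
  validate_sim_config(config)
  if (length(config$qpcr_targets) < 1 ||
      is.null(names(config$qpcr_targets)))
    stop("invalid simulation config: field `qpcr_targets` must be a named ",
         "vector of fold changes", call. = FALSE)
  if (any(config$qpcr_targets <= 0))
    stop("invalid simulation config: field `qpcr_targets` must be positive",
         call. = FALSE)
  set.seed(config$seed + 4L)
  sample_id <- c(sprintf("T%02d", seq_len(config$n_tumor)),
                 sprintf("N%02d", seq_len(config$n_normal)))
  group <- rep(c("tumor", "normal"), c(config$n_tumor, config$n_normal))
  genes <- c(config$qpcr_reference, names(config$qpcr_targets))
  ## baseline Ct: reference at 18 cycles, targets spread above it
  base_ct <- stats::setNames(
    c(18, 22 + 2 * (seq_along(config$qpcr_targets) - 1) %% 6), genes)
  rows <- expand.grid(replicate = seq_len(config$qpcr_replicates),
                      gene_id = genes, sample_id = sample_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$group <- group[match(rows$sample_id, sample_id)]
  shift <- stats::setNames(c(0, -log2(config$qpcr_targets)), genes)
  rows$ct <- base_ct[rows$gene_id] +
    ifelse(rows$group == "tumor", shift[rows$gene_id], 0) +
    stats::rnorm(nrow(rows), 0, config$qpcr_noise_sd)
  rows[, c("sample_id", "group", "gene_id", "replicate", "ct")]
}

#' Write / read a Ct table TSV
#' @param ct data frame as returned by [simulate_qpcr()].
#' @param path file path.
#' @return The path (write) or the Ct data frame (read).
#' @export
write_ct_table <- function(ct, path) {
  utils::write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(path) {
  ct <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "gene_id", "replicate", "ct")
  if (!all(need %in% names(ct)))
    stop("Ct table must have columns ", paste(need, collapse = ", "),
         ": ", path, call. = FALSE)
  ct
}

#' Serialize planted truth to JSON
#' @param truth truth list from the generators.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  out <- truth
  out$config <- unclass(out$config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}
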