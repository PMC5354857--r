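#' Configuration for an end-to-end pipeline run
#'
#' Either a simulation block (a [sim_config()]) or a set of input paths
#' must be supplied. Stage parameters default to the standard regimes:
#' DE thresholds FC > 2 / < 0.5, p < 0.05, FDR < 0.1; general network
#' |PCC| >= 0.90; sub-network |PCC| >= 0.80 with p < 0.001; enrichment
#' kept at -log10(p) > 1.3 with a pathway-act edge rule of more than 5
#' shared DE genes among the top 20 sets.
#'
#' @param simulation a [sim_config()], or `NULL` when reading inputs.
#' @param inputs `NULL`, or a named list of paths: `matrix`,
#'   `sample_sheet`, `gtf`, `gmt`, `ct_table`, optionally `directions`.
#' @param de a [de_thresholds()].
#' @param network_general,network_sub lists with `min_abs_pcc`, `max_p`.
#' @param cohort correlation cohort for networks (default `"tumor"`).
#' @param enrichment list with `top_k`, `min_shared`, `neg_log10_cut`.
#' @param qpcr_reference reference gene id for the qPCR stage.
#' @param promoter_window bidirectional-rule window for classification.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, inputs = NULL,
                            de = de_thresholds(),
                            network_general = list(min_abs_pcc = 0.90,
                                                   max_p = 1.0),
                            network_sub = list(min_abs_pcc = 0.80,
                                               max_p = 0.001),
                            cohort = "tumor",
                            enrichment = list(top_k = 20, min_shared = 5,
                                              neg_log10_cut = 1.3),
                            qpcr_reference = "GAPDH",
                            promoter_window = 1000) {
  if (is.null(simulation) && is.null(inputs))
    stop("either a simulation block or input paths must be supplied",
         call. = FALSE)
  if (!is.null(simulation)) validate_sim_config(simulation)
  if (!is.null(inputs)) {
    need <- c("matrix", "sample_sheet", "gtf", "gmt", "ct_table")
    if (!all(need %in% names(inputs)))
      stop("inputs must name paths: ", paste(need, collapse = ", "),
           call. = FALSE)
  }
  stopifnot(inherits(de, "de_thresholds"))
  structure(list(simulation = simulation, inputs = inputs, de = de,
                 network_general = network_general,
                 network_sub = network_sub, cohort = cohort,
                 enrichment = enrichment,
                 qpcr_reference = qpcr_reference,
                 promoter_window = promoter_window),
            class = "pipeline_config")
}

#' Demo configuration: the default synthetic study
#'
#' An 11 tumor vs 5 normal simulation with planted DE genes, two planted
#' correlation stars (an mRNA hub with five lncRNA partners and a lncRNA
#' hub with three mRNA partners, one negatively correlated), pathway sets
#' with a planted enriched pair sharing six DE genes, and qPCR targets.
#'
#' @param seed integer seed.
#' @return A [pipeline_config()].
#' @export
demo_config <- function(seed = 42) {
  edges <- rbind(
    data.frame(lncrna_id = sprintf("LNC%04d", 4:8),
               mrna_id = "MRNA0006", target_pcc = 0.95,
               stringsAsFactors = FALSE),
    data.frame(lncrna_id = "LNC0001",
               mrna_id = c("MRNA0001", "MRNA0007", "MRNA0008"),
               target_pcc = c(0.95, 0.92, -0.90),
               stringsAsFactors = FALSE))
  pipeline_config(simulation = sim_config(seed = seed,
                                          planted_edges = edges))
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the
#' `simulation` block holds [sim_config()] arguments and the `de` block
#' holds [de_thresholds()] arguments.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$simulation)) {
    sim <- y$simulation
    if (!is.null(sim$planted_edges))
      sim$planted_edges <- do.call(rbind, lapply(sim$planted_edges,
                                                 as.data.frame))
    args$simulation <- do.call(sim_config, sim)
  }
  if (!is.null(y$inputs)) args$inputs <- y$inputs
  if (!is.null(y$de)) args$de <- do.call(de_thresholds, y$de)
  for (k in c("network_general", "network_sub", "cohort", "enrichment",
              "qpcr_reference", "promoter_window"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(pipeline_config, args)
}

#' Validate pipeline inputs without running anything
#'
#' Checks matrix / sample-sheet consistency, GTF and GMT parseability,
#' GMT-to-matrix gene overlap (warns below 50%), and Ct-table
#' completeness. All problems are reported together.
#'
#' @param config a [pipeline_config()].
#' @return Data frame with `severity` (`fatal` / `warning`) and
#'   `message`; zero rows when everything is consistent.
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  issues <- list()
  note <- function(severity, msg)
    issues[[length(issues) + 1]] <<- data.frame(
      severity = severity, message = msg, stringsAsFactors = FALSE)
  if (is.null(config$inputs)) {
    ok <- tryCatch({ validate_sim_config(config$simulation); TRUE },
                   error = function(e) { note("fatal", conditionMessage(e))
                     FALSE })
  } else {
    inp <- config$inputs
    for (f in c("matrix", "sample_sheet", "gtf", "gmt", "ct_table"))
      if (!file.exists(inp[[f]]))
        note("fatal", paste0("missing input file (", f, "): ", inp[[f]]))
    expr <- tryCatch(read_expression_set(inp$matrix, inp$sample_sheet),
                     error = function(e) { note("fatal",
                       conditionMessage(e)); NULL })
    tryCatch(read_gtf(inp$gtf),
             error = function(e) note("fatal",
               paste0("GTF unreadable: ", conditionMessage(e))))
    sets <- tryCatch(read_gmt(inp$gmt),
                     error = function(e) { note("fatal",
                       paste0("GMT unreadable: ", conditionMessage(e)))
                       NULL })
    if (!is.null(expr) && !is.null(sets)) {
      genes <- unique(unlist(sets$members))
      frac <- mean(genes %in% rownames(expr$values))
      if (frac == 0)
        note("fatal", "no GMT gene overlaps the expression matrix")
      else if (frac < 0.5)
        note("warning", sprintf(
          "only %.0f%% of GMT genes are in the expression matrix",
          100 * frac))
    }
    ct <- tryCatch(read_ct_table(inp$ct_table),
                   error = function(e) { note("fatal",
                     conditionMessage(e)); NULL })
    if (!is.null(ct) &&
        !all(unique(ct$sample_id) %in%
               ct$sample_id[ct$gene_id == config$qpcr_reference]))
      note("fatal", paste0("reference gene ", config$qpcr_reference,
                           " missing for some qPCR samples"))
  }
  if (length(issues)) do.call(rbind, issues) else
    data.frame(severity = character(), message = character(),
               stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Stage order mirrors the study design: input acquisition (simulation or
#' file reading), differential expression, positional classification,
#' pathway enrichment with the pathway-act network, general and
#' pathway-seeded co-expression networks, and qPCR quantification. Every
#' stage writes its tables under `outdir`; a JSON manifest records the
#' seed, parameters, per-stage row counts and MD5 checksums of every
#' written file, so two runs with the same configuration produce
#' identical manifests.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if absent).
#' @return The manifest, invisibly (also written to
#'   `outdir/manifest.json`).
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  issues <- validate_inputs(config)
  if (any(issues$severity == "fatal"))
    stop("input validation failed:\n  ",
         paste(issues$message[issues$severity == "fatal"],
               collapse = "\n  "), call. = FALSE)
  manifest <- list(package = "lncnet",
                   seed = if (!is.null(config$simulation))
                     config$simulation$seed else NA,
                   parameters = list(
                     de = unclass(config$de),
                     network_general = config$network_general,
                     network_sub = config$network_sub,
                     cohort = config$cohort,
                     enrichment = config$enrichment,
                     promoter_window = config$promoter_window,
                     activation_score =
                       "sign-consistency z (open stand-in statistic)"),
                   stages = list(), files = character())
  files <- character()
  stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- res$counts
    files <<- c(files, res$files)
    res$value
  }

  inputs <- stage("inputs", function() {
    if (!is.null(config$simulation)) {
      idir <- file.path(outdir, "inputs")
      dir.create(idir, showWarnings = FALSE)
      sim <- simulate_expression(config$simulation)
      ann <- simulate_annotation(config$simulation,
                                 config$promoter_window)
      sets <- simulate_pathways(config$simulation, sim$truth)
      ct <- simulate_qpcr(config$simulation)
      truth <- sim$truth
      truth$category_labels <- as.list(ann$labels)
      truth$pathway_memberships <- sets$members
      write_expression_set(sim$expr, file.path(idir, "matrix.tsv"),
                           file.path(idir, "samples.tsv"))
      write_gtf(ann$models, file.path(idir, "annotation.gtf"))
      write_gmt(sets, file.path(idir, "pathways.gmt"))
      write_directions(sets$expected_direction,
                       file.path(idir, "directions.tsv"))
      write_ct_table(ct, file.path(idir, "ct_table.tsv"))
      write_truth_json(truth, file.path(idir, "truth.json"))
      list(value = list(expr = sim$expr, models = ann$models,
                        sets = sets, ct = ct, truth = truth),
           counts = list(genes = nrow(sim$expr$values),
                         samples = ncol(sim$expr$values),
                         gene_models = nrow(ann$models),
                         pathways = length(sets$members),
                         ct_rows = nrow(ct)),
           files = file.path(idir, c("matrix.tsv", "samples.tsv",
                                     "annotation.gtf", "pathways.gmt",
                                     "directions.tsv", "ct_table.tsv",
                                     "truth.json")))
    } else {
      inp <- config$inputs
      expr <- read_expression_set(inp$matrix, inp$sample_sheet)
      sets <- read_gmt(inp$gmt)
      if (!is.null(inp$directions))
        sets$expected_direction <- read_directions(inp$directions)
      list(value = list(expr = expr, models = read_gtf(inp$gtf),
                        sets = sets, ct = read_ct_table(inp$ct_table),
                        truth = NULL),
           counts = list(genes = nrow(expr$values),
                         samples = ncol(expr$values)),
           files = character())
    }
  })

  de <- stage("differential_expression", function() {
    res <- de_analysis(inputs$expr, config$de)
    plots <- export_plot_tables(res, config$de$pseudocount)
    f <- c(write_tsv(as.data.frame(res), file.path(outdir, "de_table.tsv")),
           write_tsv(summarize_counts(res),
                     file.path(outdir, "de_summary.tsv")),
           write_tsv(plots$volcano, file.path(outdir, "volcano.tsv")),
           write_tsv(plots$scatter, file.path(outdir, "scatter.tsv")))
    if (sum(res$significant) >= 2) {
      ord <- cluster_order(inputs$expr, res)
      f <- c(f, write_tsv(data.frame(gene_id = ord$genes),
                          file.path(outdir, "cluster_gene_order.tsv")),
             write_tsv(data.frame(sample_id = ord$samples),
                       file.path(outdir, "cluster_sample_order.tsv")))
    }
    list(value = res,
         counts = list(tested = nrow(res),
                       significant = sum(res$significant)),
         files = f)
  })
  de_lnc <- de$gene_id[de$significant & de$biotype == "lncRNA"]
  de_mrna <- de$gene_id[de$significant & de$biotype == "mRNA"]
  status <- stats::setNames(de$direction, de$gene_id)

  stage("classification", function() {
    labels <- classify_lncrnas(inputs$models, config$promoter_window)
    de_labels <- labels[names(labels) %in% de_lnc]
    tab <- tabulate_categories(labels)
    f <- c(write_tsv(tab, file.path(outdir, "lncrna_categories.tsv")),
           write_tsv(chromosome_distribution(inputs$models,
                                             status[de_lnc]),
                     file.path(outdir, "chromosome_distribution.tsv")))
    if (length(de_labels))
      f <- c(f, write_tsv(
        tabulate_categories(de_labels, status[names(de_labels)]),
        file.path(outdir, "lncrna_categories_by_direction.tsv")))
    list(value = labels,
         counts = list(classified = length(labels)), files = f)
  })

  enr <- stage("enrichment", function() {
    universe <- de$gene_id[de$biotype == "mRNA"]
    res <- fisher_enrichment(de_mrna, inputs$sets, universe)
    res <- score_activation(res, inputs$sets, de)
    kept <- significance_filter(res, config$enrichment$neg_log10_cut)
    act <- pathway_act_network(res, inputs$sets, de_mrna,
                               config$enrichment$top_k,
                               config$enrichment$min_shared)
    f <- c(write_tsv(as.data.frame(res),
                     file.path(outdir, "enrichment.tsv")),
           write_tsv(as.data.frame(kept),
                     file.path(outdir, "enrichment_significant.tsv")),
           write_tsv(act$edges, file.path(outdir, "pathway_act_edges.tsv")))
    list(value = res,
         counts = list(tested = nrow(res), significant = nrow(kept),
                       act_edges = nrow(act$edges)),
         files = f)
  })

  stage("networks", function() {
    general <- build_network(inputs$expr, de_lnc, de_mrna,
                             config$network_general$min_abs_pcc,
                             config$network_general$max_p,
                             config$cohort)
    seeds <- intersect(inputs$sets$members[[enr$set_id[1]]], de_mrna)
    f <- c(export_graph(general, file.path(outdir, "network_edges.tsv"),
                        file.path(outdir, "network.graphml")),
           write_tsv(node_degrees(general, status),
                     file.path(outdir, "network_degrees.tsv")))
    counts <- list(general_nodes = nrow(general$nodes),
                   general_edges = nrow(general$edges))
    if (length(seeds)) {
      sub <- extract_subnetwork(inputs$expr, de_lnc, seeds,
                                config$network_sub$min_abs_pcc,
                                config$network_sub$max_p,
                                config$cohort)
      f <- c(f, export_graph(sub,
                             file.path(outdir, "subnetwork_edges.tsv"),
                             file.path(outdir, "subnetwork.graphml")),
             write_tsv(node_degrees(sub, status),
                       file.path(outdir, "subnetwork_degrees.tsv")))
      counts$sub_nodes <- nrow(sub$nodes)
      counts$sub_edges <- nrow(sub$edges)
    }
    list(value = general, counts = counts, files = f)
  })

  stage("qpcr", function() {
    res <- qpcr_analysis(inputs$ct, config$qpcr_reference)
    list(value = res,
         counts = list(targets = nrow(res),
                       significant = sum(res$significant)),
         files = write_tsv(as.data.frame(res),
                           file.path(outdir, "qpcr_summary.tsv")))
  })

  manifest$files <- lapply(files, function(f) unname(tools::md5sum(f)))
  names(manifest$files) <- sub(paste0("^", outdir, "/?"), "", files)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
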