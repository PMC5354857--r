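test_that("generators are deterministic given (config, seed)", {
  cfg <- sim_config(seed = 7,
                    planted_edges = data.frame(
                      lncrna_id = "LNC0004", mrna_id = "MRNA0006",
                      target_pcc = 0.9))
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(simulate_qpcr(cfg), simulate_qpcr(cfg))
  expect_identical(simulate_annotation(cfg)$models,
                   simulate_annotation(cfg)$models)
  t1 <- simulate_pathways(cfg, a$truth)
  t2 <- simulate_pathways(cfg, b$truth)
  expect_identical(t1$members, t2$members)
  # changing the seed changes the values
  expect_false(identical(
    simulate_expression(sim_config(seed = 8))$expr$values,
    simulate_expression(sim_config(seed = 9))$expr$values))
})

test_that("config validation names the offending field", {
  expect_error(sim_config(seed = 1, noise_sd = -1), "noise_sd")
  expect_error(sim_config(seed = 1, n_de_up_mrna = 200, n_mrna = 100),
               "n_de_up_mrna")
  expect_error(sim_config(seed = 2^40), "seed")
  expect_error(sim_config(seed = 1, planted_edges = data.frame(
    lncrna_id = "LNC0001", mrna_id = "MRNA0001", target_pcc = 1.5)),
    "planted_edges")
  expect_error(
    simulate_expression(sim_config(
      seed = 1, planted_edges = data.frame(
        lncrna_id = "LNC9999", mrna_id = "MRNA0001", target_pcc = 0.5))),
    "planted_edges")
})

test_that("zero noise gives exact planted log2FC and exact planted PCC", {
  edges <- data.frame(lncrna_id = c("LNC0004", "LNC0005", "LNC0006"),
                      mrna_id = "MRNA0006",
                      target_pcc = c(1, 0.8, -0.6))
  cfg <- sim_config(seed = 11, noise_sd = 0, planted_edges = edges)
  sim <- simulate_expression(cfg)
  lv <- log2(sim$expr$values)
  tumor <- sim$expr$group == "tumor"
  for (i in seq_len(nrow(sim$truth$de_genes))) {
    g <- sim$truth$de_genes$gene_id[i]
    expect_equal(mean(lv[g, tumor]) - mean(lv[g, !tumor]),
                 sim$truth$de_genes$planted_log2fc[i], tolerance = 1e-10)
  }
  for (i in seq_len(nrow(edges))) {
    r <- cor(lv[edges$lncrna_id[i], tumor], lv[edges$mrna_id[i], tumor])
    expect_equal(r, edges$target_pcc[i], tolerance = 1e-12)
  }
  # expression values themselves stay non-negative
  expect_true(all(sim$expr$values >= 0))
})

test_that("with noise, mean realized PCC stays within 0.05 of target", {
  targets <- c(0.5, 0.9, 0.95)
  edges <- data.frame(lncrna_id = sprintf("LNC%04d", 4:6),
                      mrna_id = sprintf("MRNA%04d", 6:8),
                      target_pcc = targets)
  realized <- sapply(1:40, function(s) {
    sim <- simulate_expression(sim_config(seed = 100 + s,
                                          planted_edges = edges))
    lv <- log2(sim$expr$values)
    tumor <- sim$expr$group == "tumor"
    sapply(seq_len(nrow(edges)), function(i)
      cor(lv[edges$lncrna_id[i], tumor], lv[edges$mrna_id[i], tumor]))
  })
  expect_true(all(abs(rowMeans(realized) - targets) < 0.05))
})

test_that("simulated annotation is classifier-consistent and recovers requested proportions", {
  props <- c(exonic_sense = 0.13, intronic_sense = 0.08,
             exonic_antisense = 0.20, intronic_antisense = 0.15,
             bidirectional = 0.02, intergenic = 0.42)
  cfg <- sim_config(seed = 3, n_lncrna = 100, category_props = props)
  ann <- simulate_annotation(cfg)
  labels <- classify_lncrnas(ann$models)
  expect_identical(labels[names(ann$labels)], ann$labels)
  tab <- tabulate_categories(labels)
  expect_equal(
    tab$proportion[match(names(props), tab$category)],
    unname(props), tolerance = 1e-12)
})

test_that("annotation round-trips through GTF with labels preserved", {
  cfg <- sim_config(seed = 5, n_lncrna = 12, n_de_up_lnc = 2,
                    n_de_down_lnc = 4)
  ann <- simulate_annotation(cfg)
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann$models, path)
  back <- read_gtf(path)
  ord <- match(ann$models$gene_id, back$gene_id)
  expect_identical(back$gene_id[ord], ann$models$gene_id)
  expect_equal(back$start[ord], ann$models$start)
  expect_equal(back$end[ord], ann$models$end)
  expect_identical(back$strand[ord], ann$models$strand)
  expect_identical(back$biotype[ord], ann$models$biotype)
  expect_identical(classify_lncrnas(back), classify_lncrnas(ann$models))
})

test_that("simulated pathways control DE overlap and pairwise sharing", {
  cfg <- sim_config(seed = 13)
  sim <- simulate_expression(cfg)
  sets <- simulate_pathways(cfg, sim$truth, n_pathways = 6, set_size = 15,
                            de_overlap = c(10, 11, 5, 6, 0, 0),
                            shared_de = data.frame(set_a = c(1, 2),
                                                   set_b = c(2, 4),
                                                   n_shared = c(6, 5)))
  de <- sim$truth$de_genes$gene_id
  n_de <- sapply(sets$members, function(m) length(intersect(m, de)))
  expect_equal(unname(n_de), c(10, 11, 5, 6, 0, 0))
  shared <- function(a, b) length(intersect(
    intersect(sets$members[[a]], sets$members[[b]]), de))
  expect_equal(shared(1, 2), 6)
  expect_equal(shared(2, 4), 5)
  expect_equal(shared(1, 3), 0)
  expect_equal(shared(1, 4), 0)
  # full member overlap outside the planted sharing is zero
  expect_equal(length(intersect(sets$members[[5]], sets$members[[6]])), 0)
  # infeasible requests error out
  expect_error(simulate_pathways(cfg, sim$truth, n_pathways = 2,
                                 set_size = 10,
                                 de_overlap = c(30, 30)),
               "exceeds")
})

test_that("zero-noise qPCR tables encode the configured fold changes", {
  cfg <- sim_config(seed = 9, qpcr_noise_sd = 0,
                    qpcr_targets = c(GENEA = 1, GENEB = 0.25))
  ct <- simulate_qpcr(cfg)
  relA <- relative_expression(ct, "GENEA", "GAPDH")
  expect_true(all(relA$rel_expr == 1))
  relB <- relative_expression(ct, "GENEB", "GAPDH")
  expect_equal(unique(relB$delta_delta_ct[relB$group == "tumor"]), 2)
  expect_true(all(relB$rel_expr[relB$group == "tumor"] == 0.25))
})
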