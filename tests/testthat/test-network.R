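test_that("pearson correlation and its p-value match the textbook values", {
  expect_equal(pearson_correlation(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(6, 4, 2)), -1)
  expect_equal(pearson_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_correlation(c(1, 2), c(1, 2)), "3")

  expect_equal(correlation_pvalue(0, 10), 1)
  expect_equal(correlation_pvalue(1, 10), 0)
  expect_equal(correlation_pvalue(0.8, 4), 0.2, tolerance = 0.01)
  # cross-check against cor.test over a grid
  set.seed(4)
  for (i in 1:10) {
    n <- sample(4:16, 1)
    x <- rnorm(n); y <- rnorm(n)
    ct <- cor.test(x, y)
    expect_equal(correlation_pvalue(cor(x, y), n), unname(ct$p.value),
                 tolerance = 1e-10)
  }
})

test_that("network construction equals a brute-force all-pairs oracle", {
  set.seed(5)
  v <- matrix(2^rnorm(20 * 8, 5), 20, 8,
              dimnames = list(c(sprintf("L%02d", 1:10),
                                sprintf("M%02d", 1:10)),
                              sprintf("S%d", 1:8)))
  expr <- expression_set(v, rep(c("lncRNA", "mRNA"), each = 10),
                         rep(c("tumor", "normal"), each = 4))
  lncs <- sprintf("L%02d", 1:10); mrnas <- sprintf("M%02d", 1:10)
  for (th in list(c(0.3, 1), c(0.6, 0.5), c(0, 0.2))) {
    net <- build_network(expr, lncs, mrnas, th[1], th[2], cohort = "all",
                         log2_transform = FALSE)
    oracle <- list()
    for (l in lncs) for (m in mrnas) {
      r <- cor(v[l, ], v[m, ])
      p <- 2 * pt(-abs(r * sqrt(6) / sqrt(1 - r^2)), 6)
      if (abs(r) >= th[1] && p < th[2])
        oracle[[paste(l, m)]] <- c(r = r, p = p)
    }
    expect_equal(nrow(net$edges), length(oracle))
    key <- paste(net$edges$lncrna_id, net$edges$mrna_id)
    expect_setequal(key, names(oracle))
    expect_equal(net$edges$pcc,
                 unname(sapply(oracle[key], `[[`, "r")), tolerance = 1e-12)
    # degrees equal a brute-force incidence recount and igraph's count
    deg <- node_degrees(net)
    recount <- sapply(deg$gene_id, function(g)
      sum(net$edges$lncrna_id == g | net$edges$mrna_id == g))
    expect_equal(deg$degree, unname(recount))
    ig <- as_igraph(net)
    expect_equal(deg$degree,
                 unname(igraph::degree(ig)[deg$gene_id]))
  }
})

test_that("edge thresholds are monotone and the bipartite handshake holds", {
  set.seed(6)
  v <- matrix(2^rnorm(30 * 11, 5), 30, 11,
              dimnames = list(c(sprintf("L%02d", 1:15),
                                sprintf("M%02d", 1:15)),
                              sprintf("T%02d", 1:11)))
  expr <- expression_set(v, rep(c("lncRNA", "mRNA"), each = 15),
                         rep("tumor", 11))
  lncs <- sprintf("L%02d", 1:15); mrnas <- sprintf("M%02d", 1:15)
  n80 <- build_network(expr, lncs, mrnas, 0.80)
  n90 <- build_network(expr, lncs, mrnas, 0.90)
  k80 <- paste(n80$edges$lncrna_id, n80$edges$mrna_id)
  k90 <- paste(n90$edges$lncrna_id, n90$edges$mrna_id)
  expect_true(all(k90 %in% k80))
  for (net in list(n80, n90)) {
    expect_equal(sum(net$nodes$degree[net$nodes$biotype == "lncRNA"]),
                 nrow(net$edges))
    expect_equal(sum(net$nodes$degree[net$nodes$biotype == "mRNA"]),
                 nrow(net$edges))
    expect_true(all((net$edges$pcc > 0) ==
                      (net$edges$sign == "positive")))
  }
  # unattainable threshold gives an empty network
  empty <- build_network(expr, lncs, mrnas, 1.01)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(nrow(empty$nodes), 0)
})

test_that("planted star modules are recovered as stars", {
  edges <- data.frame(lncrna_id = sprintf("LNC%04d", 4:8),
                      mrna_id = "MRNA0006", target_pcc = 0.95)
  cfg <- sim_config(seed = 23, noise_sd = 0, planted_edges = edges)
  sim <- simulate_expression(cfg)
  # all unplanted genes are constant at zero noise and must be dropped
  expect_warning(
    net <- build_network(sim$expr, sprintf("LNC%04d", 1:20),
                         sprintf("MRNA%04d", 1:20), 0.90),
    "constant")
  deg <- node_degrees(net)
  expect_equal(deg$degree[deg$gene_id == "MRNA0006"], 5)
  expect_setequal(net$edges$lncrna_id, sprintf("LNC%04d", 4:8))
})

test_that("seeded sub-networks restrict the same-threshold full network", {
  cfg <- demo_config(seed = 31)
  sim <- simulate_expression(cfg$simulation)
  de <- de_analysis(sim$expr)
  lncs <- de$gene_id[de$significant & de$biotype == "lncRNA"]
  mrnas <- de$gene_id[de$significant & de$biotype == "mRNA"]
  seeds <- c("MRNA0006", "MRNA0001", "MRNA0003")
  sub <- extract_subnetwork(sim$expr, lncs, seeds, 0.80, 0.001)
  full <- build_network(sim$expr, lncs, mrnas, 0.80, 0.001)
  fk <- paste(full$edges$lncrna_id, full$edges$mrna_id)
  sk <- paste(sub$edges$lncrna_id, sub$edges$mrna_id)
  expect_setequal(sk, fk[full$edges$mrna_id %in% seeds])
  expect_true(all(sub$edges$mrna_id %in% seeds))
  expect_setequal(c(sub$nodes$gene_id[sub$nodes$biotype == "mRNA"],
                    sub$unconnected_seeds), seeds)
  expect_error(extract_subnetwork(sim$expr, lncs, character(0)), "empty")
})

test_that("graph export round-trips through TSV and GraphML", {
  set.seed(7)
  v <- matrix(2^rnorm(12 * 6, 5), 12, 6,
              dimnames = list(c(sprintf("L%d", 1:6), sprintf("M%d", 1:6)),
                              sprintf("T%d", 1:6)))
  expr <- expression_set(v, rep(c("lncRNA", "mRNA"), each = 6),
                         rep("tumor", 6))
  net <- build_network(expr, sprintf("L%d", 1:6), sprintf("M%d", 1:6),
                       0.5)
  edge_path <- withr::local_tempfile(fileext = ".tsv")
  graphml_path <- withr::local_tempfile(fileext = ".graphml")
  export_graph(net, edge_path, graphml_path)
  expect_equal(length(readLines(edge_path)), nrow(net$edges) + 1)
  back <- read_network_edges(edge_path)
  expect_equal(back$edges$pcc, net$edges$pcc)
  expect_identical(back$nodes$gene_id, net$nodes$gene_id)
  ig <- igraph::read_graph(graphml_path, format = "graphml")
  expect_setequal(igraph::V(ig)$name, net$nodes$gene_id)
  expect_equal(igraph::ecount(ig), nrow(net$edges))
  # empty network still exports a valid header-only TSV and graphml
  empty <- build_network(expr, sprintf("L%d", 1:6), sprintf("M%d", 1:6),
                         1.01)
  export_graph(empty, edge_path, graphml_path)
  expect_equal(length(readLines(edge_path)), 1)
  ig0 <- igraph::read_graph(graphml_path, format = "graphml")
  expect_equal(igraph::vcount(ig0), 0)
})

test_that("constant genes are dropped with a warning, errors are informative", {
  v <- rbind(L1 = c(1, 2, 3, 4), L2 = rep(5, 4),
             M1 = c(2, 4, 6, 8), M2 = c(5, 6, 7, 9))
  colnames(v) <- sprintf("T%d", 1:4)
  expr <- expression_set(v, c("lncRNA", "lncRNA", "mRNA", "mRNA"),
                         rep("tumor", 4))
  expect_warning(net <- build_network(expr, c("L1", "L2"), c("M1", "M2"),
                                      0.5), "constant")
  expect_false("L2" %in% net$nodes$gene_id)
  expect_error(build_network(expr, character(0), "M1"), "non-empty")
  expect_error(build_network(expr, "L1", "MX"), "absent")
  expect_error(build_network(expr, "L1", "M1", cohort = "normal"),
               "fewer than 3")
})
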