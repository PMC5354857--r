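test_that("fold change follows the pseudocount formula", {
  v <- rbind(A = c(4, 4, 4, 2, 2, 2),
             B = c(5, 5, 5, 5, 5, 5),
             C = c(0.75, 0.75, 0.75, 0, 0, 0))
  colnames(v) <- sprintf("S%d", 1:6)
  expr <- tiny_expression(v)
  fc0 <- compute_fold_change(expr, de_thresholds(pseudocount = 0))
  expect_equal(fc0$fc[fc0$gene_id == "A"], 2)
  expect_equal(fc0$log2fc[fc0$gene_id == "A"], 1)
  expect_equal(fc0$fc[fc0$gene_id == "B"], 1)
  fc <- compute_fold_change(expr, de_thresholds(pseudocount = 0.25))
  expect_equal(fc$fc[fc$gene_id == "B"], 1)      # symmetry at any pseudocount
  expect_equal(fc$fc[fc$gene_id == "C"], 4)      # (0.75+0.25)/(0+0.25)
  expect_equal(fc$log2fc[fc$gene_id == "C"], 2)
  expect_equal(fc$log2fc, log2(fc$fc))
})

test_that("Welch test matches stats::t.test and handles degenerate genes", {
  set.seed(42)
  v <- matrix(2^rnorm(50 * 8, 5), 50, 8,
              dimnames = list(sprintf("G%02d", 1:50), sprintf("S%d", 1:8)))
  expr <- tiny_expression(v)
  p <- welch_t_test(expr, pseudocount = 0.25)
  x <- log2(v + 0.25)
  ref <- apply(x, 1, function(row)
    stats::t.test(row[1:4], row[5:8])$p.value)
  expect_equal(unname(p), unname(ref), tolerance = 1e-10)

  vd <- rbind(EQ = rep(3, 6), NE = rep(c(2, 8), each = 3),
              ID = rep(c(1, 2, 3), 2))
  colnames(vd) <- sprintf("S%d", 1:6)
  pd <- welch_t_test(tiny_expression(vd))
  expect_equal(unname(pd["EQ"]), 1)
  expect_lt(pd["NE"], 1e-300)
  expect_equal(unname(pd["ID"]), 1)  # identical samples in both groups
})

test_that("BH step-up q-values match the hand formula and p.adjust", {
  p <- c(0.01, 0.04, 0.03, 0.005)
  expect_equal(bh_fdr(p), c(0.02, 0.04, 0.04, 0.02))
  expect_equal(bh_fdr(rep(0.07, 5)), rep(0.07, 5))
  expect_equal(bh_fdr(0.3), 0.3)
  set.seed(1)
  for (i in 1:20) {
    pp <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(pp), stats::p.adjust(pp, "BH"), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("BH q-values are permutation-invariant and monotone in p", {
  set.seed(2)
  p <- runif(30)
  q <- bh_fdr(p)
  perm <- sample(30)
  expect_equal(bh_fdr(p[perm]), q[perm])
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
})

test_that("significance calls use strict thresholds in all three criteria", {
  rec <- data.frame(
    gene_id = sprintf("G%d", 1:6), biotype = "mRNA",
    fc = c(2.0, 3, 0.4, 3, 3, 0.5),
    p_value = c(0.001, 0.01, 0.04, 0.05, 0.01, 0.01),
    fdr = c(0.001, 0.05, 0.09, 0.01, 0.1, 0.01))
  out <- filter_significant(rec)
  expect_equal(out$significant, c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$direction[2:3], c("up", "down"))
  # idempotent and dependent only on (fc, p, fdr)
  expect_identical(filter_significant(out), out)
})

test_that("count summaries add up and plot tables mirror the calls", {
  rec <- data.frame(
    gene_id = sprintf("G%d", 1:5),
    biotype = c("lncRNA", "lncRNA", "mRNA", "mRNA", "lncRNA"),
    mean_tumor = c(40, 1, 12, 5, 5), mean_normal = c(2, 30, 4, 5, 5),
    fc = c(20, 1 / 30, 3, 1, 1), log2fc = log2(c(20, 1 / 30, 3, 1, 1)),
    p_value = c(0.001, 0.001, 0.01, 0.5, 0.5),
    fdr = c(0.01, 0.01, 0.05, 0.9, 0.9))
  rec <- filter_significant(rec)
  s <- summarize_counts(rec)
  expect_equal(s$n_total, s$n_up + s$n_down)
  expect_equal(s$n_up[s$biotype == "lncRNA"], 1)
  expect_equal(s$n_down[s$biotype == "lncRNA"], 1)
  expect_equal(s$n_extreme[s$biotype == "lncRNA"], 2)  # fc 20 and 1/30
  expect_equal(s$n_extreme[s$biotype == "mRNA"], 0)
  empty <- summarize_counts(rec[0, ])
  expect_true(all(empty[, -1] == 0))

  tabs <- export_plot_tables(rec)
  expect_equal(tabs$volcano$class, c("up", "down", "up", "ns", "ns"))
  expect_equal(tabs$volcano$neg_log10_fdr[1], 2)  # fdr 0.01
  cap <- export_plot_tables(transform(rec, fdr = 0))
  expect_true(all(cap$volcano$neg_log10_fdr == 320))
  one <- export_plot_tables(transform(rec, fdr = 1))
  expect_true(all(one$volcano$neg_log10_fdr == 0))
})

test_that("de_analysis recovers planted genes and controls the null", {
  cfg <- sim_config(seed = 21, n_mrna = 100, n_lncrna = 100,
                    n_de_up_mrna = 5, n_de_down_mrna = 5,
                    n_de_up_lnc = 5, n_de_down_lnc = 5)
  sim <- simulate_expression(cfg)
  de <- de_analysis(sim$expr)
  truth <- sim$truth$de_genes
  hits <- de$gene_id[de$significant]
  expect_gte(length(intersect(hits, truth$gene_id)), 18)
  found <- de[match(truth$gene_id, de$gene_id), ]
  expect_true(all(found$direction[found$significant] ==
                    truth$direction[found$significant]))

  null_cfg <- sim_config(seed = 22, n_mrna = 500, n_lncrna = 0,
                         n_de_up_mrna = 0, n_de_down_mrna = 0,
                         n_de_up_lnc = 0, n_de_down_lnc = 0)
  null_de <- de_analysis(simulate_expression(null_cfg)$expr)
  expect_lte(mean(null_de$significant), 0.1)
})

test_that("hierarchical ordering is deterministic and matches a brute-force oracle", {
  set.seed(3)
  for (rep in 1:5) {
    n <- sample(4:6, 1)
    v <- matrix(2^rnorm(n * 6, 5), n, 6,
                dimnames = list(sprintf("G%d", seq_len(n)),
                                sprintf("S%d", 1:6)))
    d <- 1 - cor(t(log2(v)))
    heights <- lncnet:::agglomerate(d)$heights
    expect_equal(heights, oracle_average_linkage_heights(d),
                 tolerance = 1e-12)
  }

  # identical genes sit adjacent; an anti-correlated gene joins last
  v <- rbind(G1 = c(1, 2, 3, 4, 5, 6), G2 = c(2, 4, 6, 8, 10, 12),
             G3 = c(6, 5, 4, 3, 2, 1), G4 = c(1, 3, 2, 6, 4, 8))
  colnames(v) <- sprintf("S%d", 1:6)
  expr <- tiny_expression(v)
  rec <- data.frame(gene_id = rownames(v), fc = 3, p_value = 0.001,
                    fdr = 0.001, significant = TRUE, direction = "up")
  ord <- cluster_order(expr, rec)
  g <- ord$genes
  expect_equal(abs(diff(match(c("G1", "G2"), g))), 1)
  expect_equal(g[length(g)] == "G3" || g[1] == "G3", TRUE)
  expect_length(ord$samples, 6)

  # constant gene handled with a warning
  v2 <- rbind(v, G5 = rep(4, 6))
  rec2 <- rbind(rec, data.frame(gene_id = "G5", fc = 3, p_value = 0.001,
                                fdr = 0.001, significant = TRUE,
                                direction = "up"))
  expect_warning(cluster_order(tiny_expression(v2), rec2), "constant")
})
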