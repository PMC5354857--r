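# Small fixtures shared across test files; everything is built in code.

# Minimal expression set: explicit values, 3 tumor vs 3 normal samples.
tiny_expression <- function(values, biotype = NULL) {
  if (is.null(biotype))
    biotype <- rep("mRNA", nrow(values))
  group <- rep(c("tumor", "normal"), each = ncol(values) / 2)
  expression_set(values, biotype, group)
}

# One coding gene on chr1 '+' with three exons, plus helpers to place
# lncRNAs around it. Internal coordinates are 0-based half-open.
fixture_coding_gene <- function() {
  gene_models(gene_id = "CODA", chrom = "chr1", strand = "+",
              start = 1000, end = 5000, biotype = "coding",
              exons = list(data.frame(start = c(1000, 3000, 4500),
                                      end = c(2000, 4000, 5000))))
}

fixture_lnc <- function(id, strand, start, end, exons = NULL,
                        chrom = "chr1") {
  if (is.null(exons)) exons <- data.frame(start = start, end = end)
  gene_models(gene_id = id, chrom = chrom, strand = strand,
              start = start, end = end, biotype = "lncRNA",
              exons = list(exons))
}

rbind_models <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("gene_models", "data.frame")
  out
}

# Brute-force average-linkage agglomeration: recompute the mean pairwise
# distance between cluster members at every step (no Lance-Williams).
oracle_average_linkage_heights <- function(d0) {
  clusters <- as.list(seq_len(nrow(d0)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- mean(d0[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(j, i) }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Exhaustive hypergeometric tail: P(overlap >= k) by enumerating all
# possible overlap counts for a universe of size n with n_de DE genes and
# a set of size n_set.
oracle_hyper_tail <- function(k, n_de, n_u, n_set) {
  kk <- max(0, n_set + n_de - n_u):min(n_set, n_de)
  probs <- choose(n_de, kk) * choose(n_u - n_de, n_set - kk) /
    choose(n_u, n_set)
  sum(probs[kk >= k])
}
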