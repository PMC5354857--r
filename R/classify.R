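#' The six positional lncRNA categories
#'
#' Closed vocabulary describing a lncRNA's relationship to protein-coding
#' genes: exon overlap on the same or opposite strand, containment within
#' a coding gene on either strand, divergent transcription from a nearby
#' opposite-strand coding promoter, or none of these (intergenic).
#'
#' @return Character vector of the six category names.
#' @export
lncrna_categories <- function() {
  c("exonic_sense", "intronic_sense", "exonic_antisense",
    "intronic_antisense", "bidirectional", "intergenic")
}

#' Build a table of stranded, exon-resolved gene models
#'
#' Internal coordinates are 0-based half-open; a GTF interval `[s, e]`
#' (1-based inclusive) corresponds to internal `(s - 1, e)`.
#'
#' @param gene_id,chrom,strand,start,end,biotype per-gene vectors; `strand`
#'   in `+`/`-`, `biotype` in `coding`/`lncRNA`. Chromosome names are
#'   normalized to the `chr` prefix.
#' @param exons list of per-gene exon tables (`start`, `end`), sorted and
#'   non-overlapping, all within the gene span.
#' @return A data frame of class `gene_models` with an `exons` list-column.
#' @export
gene_models <- function(gene_id, chrom, strand, start, end, biotype, exons) {
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = norm_chrom(chrom),
                   strand = as.character(strand),
                   start = as.numeric(start), end = as.numeric(end),
                   biotype = as.character(biotype),
                   stringsAsFactors = FALSE)
  df$exons <- lapply(exons, function(e)
    data.frame(start = as.numeric(e$start), end = as.numeric(e$end)))
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids", call. = FALSE)
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-' for every gene", call. = FALSE)
  if (!all(df$biotype %in% c("coding", "lncRNA")))
    stop("biotype must be 'coding' or 'lncRNA'", call. = FALSE)
  if (any(df$start >= df$end)) stop("gene span must have start < end",
                                    call. = FALSE)
  for (i in seq_len(nrow(df))) {
    e <- df$exons[[i]]
    if (nrow(e) == 0) stop("gene ", df$gene_id[i], " has no exons",
                           call. = FALSE)
    if (any(e$start >= e$end) || is.unsorted(e$start, strictly = TRUE) ||
        any(e$start[-1] < e$end[-nrow(e)]))
      stop("exons of gene ", df$gene_id[i],
           " must be sorted, non-overlapping intervals", call. = FALSE)
    if (e$start[1] < df$start[i] || e$end[nrow(e)] > df$end[i])
      stop("exons of gene ", df$gene_id[i], " exceed the gene span",
           call. = FALSE)
  }
  class(df) <- c("gene_models", "data.frame")
  df
}

norm_chrom <- function(x) {
  x <- as.character(x)
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}

## half-open interval overlap width; 0 when disjoint
overlap_width <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

## transcription start coordinate of a stranded span
tss_of <- function(strand, start, end) ifelse(strand == "+", start, end)

#' Classify a lncRNA against a collection of coding gene models
#'
#' Assigns exactly one of the six positional categories using a fixed
#' precedence: (1) `exonic_sense` if any lncRNA exon overlaps a same-strand
#' coding exon by at least 1 bp; (2) `intronic_sense` if the lncRNA span
#' lies within a same-strand coding gene span without exonic overlap;
#' (3) `exonic_antisense` and (4) `intronic_antisense` are the
#' opposite-strand analogues; (5) `bidirectional` if the lncRNA overlaps no
#' coding span and its transcription start lies within `promoter_window` bp
#' of an opposite-strand coding transcription start; (6) `intergenic`
#' otherwise. The precedence makes the label independent of the order in
#' which coding genes are scanned.
#'
#' @param lnc a single-row `gene_models` table (biotype `lncRNA`).
#' @param coding a `gene_models` table of coding genes.
#' @param promoter_window distance in bp for the bidirectional rule
#'   (default 1000).
#' @return A single category label.
#' @export
classify_lncrna <- function(lnc, coding, promoter_window = 1000) {
  stopifnot(inherits(lnc, "gene_models"), nrow(lnc) == 1)
  if (lnc$biotype != "lncRNA")
    stop("classify_lncrna expects a lncRNA gene model", call. = FALSE)
  coding <- coding[coding$biotype == "coding", , drop = FALSE]
  same_chrom <- coding[coding$chrom == lnc$chrom, , drop = FALSE]
  if (nrow(coding) > 0 && nrow(same_chrom) == 0)
    message("lncRNA ", lnc$gene_id, " lies on chromosome ", lnc$chrom,
            " with no coding genes; labelled intergenic")
  if (nrow(same_chrom) == 0) return("intergenic")

  le <- lnc$exons[[1]]
  exon_hit <- function(g) {
    ce <- g$exons[[1]]
    for (i in seq_len(nrow(le)))
      if (any(overlap_width(le$start[i], le$end[i], ce$start, ce$end) > 0))
        return(TRUE)
    FALSE
  }
  span_contains <- function(g) g$start <= lnc$start && lnc$end <= g$end
  span_overlaps <- overlap_width(lnc$start, lnc$end,
                                 same_chrom$start, same_chrom$end) > 0
  sense <- same_chrom$strand == lnc$strand

  for (i in which(span_overlaps & sense))
    if (exon_hit(same_chrom[i, ])) return("exonic_sense")
  for (i in which(span_overlaps & sense))
    if (span_contains(same_chrom[i, ])) return("intronic_sense")
  for (i in which(span_overlaps & !sense))
    if (exon_hit(same_chrom[i, ])) return("exonic_antisense")
  for (i in which(span_overlaps & !sense))
    if (span_contains(same_chrom[i, ])) return("intronic_antisense")
  if (!any(span_overlaps)) {
    lnc_tss <- tss_of(lnc$strand, lnc$start, lnc$end)
    anti <- same_chrom[!sense, , drop = FALSE]
    if (nrow(anti)) {
      d <- abs(tss_of(anti$strand, anti$start, anti$end) - lnc_tss)
      if (any(d <= promoter_window)) return("bidirectional")
    }
  }
  "intergenic"
}

#' Classify every lncRNA in an annotation
#'
#' @param models a `gene_models` table mixing coding genes and lncRNAs.
#' @param promoter_window passed to [classify_lncrna()].
#' @return Named character vector: lncRNA gene id -> category.
#' @export
classify_lncrnas <- function(models, promoter_window = 1000) {
  stopifnot(inherits(models, "gene_models"))
  coding <- models[models$biotype == "coding", , drop = FALSE]
  lncs <- models[models$biotype == "lncRNA", , drop = FALSE]
  out <- vapply(seq_len(nrow(lncs)), function(i)
    classify_lncrna(lncs[i, ], coding, promoter_window), character(1))
  stats::setNames(out, lncs$gene_id)
}

#' Tabulate positional category proportions
#'
#' @param labels character vector of category labels (names are gene ids).
#' @param direction optional named vector (`up`/`down`) to split the table
#'   by differential-expression direction.
#' @return Data frame with `category`, `n`, `proportion` (and `direction`
#'   when a split is requested). Proportions sum to 1 within each split.
#' @export
tabulate_categories <- function(labels, direction = NULL) {
  if (length(labels) == 0) stop("no category labels supplied", call. = FALSE)
  bad <- setdiff(unique(labels), lncrna_categories())
  if (length(bad)) stop("unknown category labels: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  tab_one <- function(lab, extra = NULL) {
    n <- table(factor(lab, levels = lncrna_categories()))
    out <- data.frame(category = names(n), n = as.integer(n),
                      proportion = as.integer(n) / length(lab),
                      stringsAsFactors = FALSE)
    if (!is.null(extra)) out <- cbind(direction = extra, out)
    out
  }
  if (is.null(direction)) return(tab_one(labels))
  direction <- direction[names(labels)]
  do.call(rbind, lapply(c("up", "down"), function(d)
    tab_one(labels[!is.na(direction) & direction == d], d)))
}

#' Per-chromosome distribution of differentially expressed lncRNAs
#'
#' @param models `gene_models` table providing chromosome placement.
#' @param status named vector (gene id -> `up`/`down`) of significant
#'   DE lncRNAs.
#' @return Data frame with `chrom`, `n_up`, `n_down`, `n_total`, one row
#'   per chromosome carrying at least one listed gene; suitable as a
#'   Circos track table.
#' @export
chromosome_distribution <- function(models, status) {
  stopifnot(inherits(models, "gene_models"))
  status <- status[names(status) %in% models$gene_id]
  chrom <- models$chrom[match(names(status), models$gene_id)]
  chroms <- sort(unique(chrom))
  out <- data.frame(
    chrom = chroms,
    n_up = vapply(chroms, function(cc)
      sum(chrom == cc & status == "up"), integer(1)),
    n_down = vapply(chroms, function(cc)
      sum(chrom == cc & status == "down"), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$n_total <- out$n_up + out$n_down
  out
}

#' Write / read gene models as GTF
#'
#' Emits one `gene` row and one `exon` row per exon, 1-based inclusive
#' coordinates, with `gene_id` and `gene_biotype` attributes
#' (`protein_coding` / `lncRNA`). Reading inverts the mapping and restores
#' internal 0-based half-open coordinates.
#'
#' @param models a `gene_models` table.
#' @param path GTF file path.
#' @return The path (write) or a `gene_models` table (read).
#' @export
write_gtf <- function(models, path) {
  stopifnot(inherits(models, "gene_models"))
  rows <- lapply(seq_len(nrow(models)), function(i) {
    g <- models[i, ]
    ex <- g$exons[[1]]
    data.frame(
      chrom = g$chrom,
      type = c("gene", rep("exon", nrow(ex))),
      start = c(g$start, ex$start) + 1,   # to 1-based inclusive
      end = c(g$end, ex$end),
      strand = g$strand,
      gene_id = g$gene_id,
      biotype = if (g$biotype == "coding") "protein_coding" else "lncRNA",
      stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = rows$chrom,
    ranges = IRanges::IRanges(start = rows$start, end = rows$end),
    strand = rows$strand)
  S4Vectors::mcols(gr)$type <- rows$type
  S4Vectors::mcols(gr)$source <- "lncnet"
  S4Vectors::mcols(gr)$gene_id <- rows$gene_id
  S4Vectors::mcols(gr)$gene_biotype <- rows$biotype
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' @rdname write_gtf
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  genes <- df[df$type == "gene", , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  gene_models(
    gene_id = genes$gene_id,
    chrom = genes$seqnames,
    strand = genes$strand,
    start = genes$start - 1,              # to 0-based half-open
    end = genes$end,
    biotype = ifelse(genes$gene_biotype == "lncRNA", "lncRNA", "coding"),
    exons = lapply(genes$gene_id, function(id) {
      e <- exons[exons$gene_id == id, , drop = FALSE]
      e <- e[order(e$start), , drop = FALSE]
      data.frame(start = e$start - 1, end = e$end)
    })
  )
}

## Largest-remainder apportionment of n items over proportions p.
apportion <- function(n, p) {
  raw <- n * p / sum(p)
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    extra <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
    k[extra] <- k[extra] + 1
  }
  stats::setNames(as.integer(k), names(p))
}

#' Simulate a gene annotation with known positional categories
#'
#' Lays each lncRNA out in its own genomic neighbourhood (100 kb apart)
#' together with a partner coding gene where the category requires one,
#' constructed so the classification of [classify_lncrnas()] is
#' unambiguous. Category counts follow `config$category_props` by
#' largest-remainder apportionment; lncRNA ids match those of
#' [simulate_expression()].
#'
#' @param config a [sim_config()].
#' @param promoter_window bidirectional-rule window used for geometry
#'   (default 1000 bp; must allow a positive promoter gap).
#' @return List with `models` (a `gene_models` table of coding genes and
#'   lncRNAs) and `labels` (named vector lncRNA id -> true category).
#' @export
simulate_annotation <- function(config, promoter_window = 1000) {
  validate_sim_config(config)
  gap <- floor(promoter_window / 2)
  if (gap < 1)
    stop("impossible geometry: promoter_window too small for a ",
         "bidirectional promoter gap", call. = FALSE)
  n <- config$n_lncrna
  counts <- apportion(n, config$category_props)
  cats <- rep(names(counts), counts)
  ids <- lnc_ids(n)
  chroms <- config$chroms[((seq_len(n) - 1) %% length(config$chroms)) + 1]

  rows <- list()
  for (i in seq_len(n)) {
    o <- 1e5 * i
    cat_i <- cats[i]
    needs_partner <- cat_i != "intergenic"
    if (needs_partner)
      rows[[length(rows) + 1]] <- list(
        gene_id = sprintf("CODG%04d", i), chrom = chroms[i], strand = "+",
        start = o + 1000, end = o + 5000, biotype = "coding",
        exons = data.frame(start = o + c(1000, 3000, 4500),
                           end = o + c(2000, 4000, 5000)))
    lnc <- switch(cat_i,
      exonic_sense = list(strand = "+", start = o + 1500, end = o + 2500,
                          exons = data.frame(start = o + 1500,
                                             end = o + 2100)),
      intronic_sense = list(strand = "+", start = o + 2100, end = o + 2900,
                            exons = data.frame(start = o + 2100,
                                               end = o + 2900)),
      exonic_antisense = list(strand = "-", start = o + 1500, end = o + 2500,
                              exons = data.frame(start = o + 1500,
                                                 end = o + 2100)),
      intronic_antisense = list(strand = "-", start = o + 2100,
                                end = o + 2900,
                                exons = data.frame(start = o + 2100,
                                                   end = o + 2900)),
      bidirectional = list(strand = "-", start = o + 1000 - gap - 600,
                           end = o + 1000 - gap,
                           exons = data.frame(start = o + 1000 - gap - 600,
                                              end = o + 1000 - gap)),
      intergenic = list(strand = "+", start = o + 1000, end = o + 2000,
                        exons = data.frame(start = o + 1000,
                                           end = o + 2000)))
    rows[[length(rows) + 1]] <- c(list(gene_id = ids[i], chrom = chroms[i],
                                       biotype = "lncRNA"), lnc)
  }
  models <- gene_models(
    gene_id = vapply(rows, `[[`, character(1), "gene_id"),
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    start = vapply(rows, `[[`, numeric(1), "start"),
    end = vapply(rows, `[[`, numeric(1), "end"),
    biotype = vapply(rows, `[[`, character(1), "biotype"),
    exons = lapply(rows, `[[`, "exons"))
  list(models = models, labels = stats::setNames(cats, ids))
}
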