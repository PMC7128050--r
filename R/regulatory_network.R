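#' Pearson correlation with a two-sided t p-value
#'
#' Sample Pearson r and the two-sided p-value from the t transform
#' `t = r sqrt((n - 2) / (1 - r^2))`. Constant vectors are a defined error
#' (class `ncmod_degenerate_correlation`) rather than a silent `NaN`.
#'
#' @param x,y numeric vectors of equal length (>= 3, finite).
#' @return list with `r` and `p`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stopf("need two vectors of equal length >= 3")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) stopf("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("constant vector: correlation undefined",
          class = "ncmod_degenerate_correlation")
  }
  r <- stats::cor(x, y)
  n <- length(x)
  if (abs(r) >= 1) return(list(r = r, p = 0))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), df = n - 2))
}

# vectorized Pearson r and p for aligned row pairs of two matrices
row_pair_cor <- function(xm, ym) {
  n <- ncol(xm)
  xc <- xm - rowMeans(xm)
  yc <- ym - rowMeans(ym)
  sx <- sqrt(rowSums(xc^2))
  sy <- sqrt(rowSums(yc^2))
  r <- rowSums(xc * yc) / (sx * sy)
  r[sx == 0 | sy == 0] <- NA_real_
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(r) >= 1] <- 0
  list(r = r, p = p)
}

#' Expression-active miRNA-target edges
#'
#' Tests every catalog pair of one target class for negative expression
#' coupling: the Pearson correlation between the miRNA and its candidate
#' target across the shared samples. Benjamini-Hochberg adjustment is
#' applied across all tested pairs of the class, and retained edges satisfy
#' `r < 0` and adjusted p below `fdr`. Catalog pairs whose ids do not
#' resolve in the matrices are dropped with a logged count; pairs with a
#' constant expression vector are skipped the same way.
#'
#' @param catalog `data.frame` with `regulator_id`, `target_id` (one target
#'   class).
#' @param mirna_expr,target_expr log2 expression matrices with aligned
#'   sample columns.
#' @param fdr BH-adjusted significance threshold.
#' @param edge_class label stored on the result rows.
#' @return `data.frame` of retained edges with `regulator_id`, `target_id`,
#'   `edge_class`, `pearson_r`, `p_raw`, `p_adjusted`; all tested pairs are
#'   available as attribute `tested`.
#' @export
active_mirna_edges <- function(catalog, mirna_expr, target_expr, fdr = 0.05,
                               edge_class = "miRNA->mRNA") {
  if (nrow(catalog) == 0L) {
    warnf("empty interaction catalog")
    return(empty_edges(edge_class))
  }
  ok <- catalog$regulator_id %in% rownames(mirna_expr) &
    catalog$target_id %in% rownames(target_expr)
  if (any(!ok)) {
    message(sum(!ok), " catalog pair(s) dropped: ids not in expression matrices")
  }
  cat2 <- catalog[ok, , drop = FALSE]
  if (nrow(cat2) == 0L) return(empty_edges(edge_class))
  cp <- row_pair_cor(mirna_expr[cat2$regulator_id, , drop = FALSE],
                     target_expr[cat2$target_id, , drop = FALSE])
  degen <- is.na(cp$r)
  if (any(degen)) {
    message(sum(degen), " pair(s) skipped: constant expression vector")
  }
  cat2 <- cat2[!degen, , drop = FALSE]
  r <- cp$r[!degen]; p <- cp$p[!degen]
  padj <- stats::p.adjust(p, method = "BH")
  tested <- data.frame(regulator_id = cat2$regulator_id,
                       target_id = cat2$target_id,
                       edge_class = edge_class, pearson_r = r,
                       p_raw = p, p_adjusted = padj,
                       stringsAsFactors = FALSE)
  out <- tested[tested$pearson_r < 0 & tested$p_adjusted < fdr, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tested") <- tested
  out
}

empty_edges <- function(edge_class) {
  data.frame(regulator_id = character(0), target_id = character(0),
             edge_class = character(0), pearson_r = numeric(0),
             p_raw = numeric(0), p_adjusted = numeric(0),
             stringsAsFactors = FALSE)
}

#' Significance of shared miRNAs for a lncRNA-gene pair
#'
#' Upper-tail hypergeometric probability of observing at least the actual
#' number of shared miRNAs when `|gene_mirnas|` draws are made from a
#' universe of `universe_size` miRNAs of which `|lnc_mirnas|` regulate the
#' lncRNA.
#'
#' @param lnc_mirnas,gene_mirnas character sets of miRNA ids.
#' @param universe_size size of the miRNA sampling frame (at least the size
#'   of either set).
#' @return list with `k_shared` and `p`.
#' @export
shared_mirna_hypergeom <- function(lnc_mirnas, gene_mirnas, universe_size) {
  lnc_mirnas <- unique(lnc_mirnas)
  gene_mirnas <- unique(gene_mirnas)
  k <- length(intersect(lnc_mirnas, gene_mirnas))
  list(k_shared = k,
       p = hyper_upper_p(k, length(lnc_mirnas), length(gene_mirnas), universe_size))
}

#' Two-stage lncRNA-gene regulatory inference
#'
#' Stage 1 keeps lncRNA-gene pairs that share at least one miRNA and whose
#' shared-miRNA overlap is hypergeometrically significant
#' (`p < hyper_alpha`); the gene side miRNA sets come from the active
#' (expression-filtered) miRNA-mRNA edges, the lncRNA side from the
#' miRNA-lncRNA edges supplied (raw catalog by default). Stage 2 computes
#' the Pearson correlation of every stage-1 candidate and keeps pairs with
#' `r > 0` and BH-adjusted p below `adj_alpha` across all candidates. The
#' hypergeometric universe is the set of miRNAs with at least one edge in
#' either supplied edge set.
#'
#' @param mirna_lnc_edges `data.frame` with `regulator_id` (miRNA),
#'   `target_id` (lncRNA).
#' @param mirna_gene_edges active miRNA-mRNA edges ([active_mirna_edges()]).
#' @param lnc_expr,gene_expr log2 expression matrices, aligned samples.
#' @param hyper_alpha stage-1 shared-miRNA significance threshold.
#' @param adj_alpha stage-2 BH-adjusted correlation threshold.
#' @return `data.frame` of retained edges with correlation and
#'   hypergeometric columns (`n_shared_mirnas`, `hyper_p`); stage-1
#'   candidates as attribute `candidates`, and every pair sharing at least
#'   one miRNA (with its hypergeometric p) as attribute `evaluated`.
#' @export
lncrna_gene_edges <- function(mirna_lnc_edges, mirna_gene_edges,
                              lnc_expr, gene_expr,
                              hyper_alpha = 0.05, adj_alpha = 0.05) {
  lnc_sets <- split(mirna_lnc_edges$regulator_id, mirna_lnc_edges$target_id)
  gene_sets <- split(mirna_gene_edges$regulator_id, mirna_gene_edges$target_id)
  universe <- union(unique(mirna_lnc_edges$regulator_id),
                    unique(mirna_gene_edges$regulator_id))
  if (length(lnc_sets) == 0L || length(gene_sets) == 0L) {
    return(empty_lnc_edges())
  }
  evaluated <- NULL
  for (lnc in names(lnc_sets)) {
    lm <- unique(lnc_sets[[lnc]])
    shared_genes <- unique(mirna_gene_edges$target_id[
      mirna_gene_edges$regulator_id %in% lm])
    if (!length(shared_genes)) next
    for (gene in shared_genes) {
      gm <- unique(gene_sets[[gene]])
      hp <- shared_mirna_hypergeom(lm, gm, length(universe))
      evaluated <- rbind(evaluated, data.frame(
        regulator_id = lnc, target_id = gene,
        n_shared_mirnas = hp$k_shared, hyper_p = hp$p,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(evaluated)) return(empty_lnc_edges())
  cand <- evaluated[evaluated$hyper_p < hyper_alpha, , drop = FALSE]
  if (nrow(cand) == 0L) {
    out <- empty_lnc_edges()
    attr(out, "evaluated") <- evaluated
    return(out)
  }
  ok <- cand$regulator_id %in% rownames(lnc_expr) &
    cand$target_id %in% rownames(gene_expr)
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty_lnc_edges())
  cp <- row_pair_cor(lnc_expr[cand$regulator_id, , drop = FALSE],
                     gene_expr[cand$target_id, , drop = FALSE])
  keep_finite <- !is.na(cp$r)
  cand <- cand[keep_finite, , drop = FALSE]
  cand$pearson_r <- cp$r[keep_finite]
  cand$p_raw <- cp$p[keep_finite]
  cand$p_adjusted <- stats::p.adjust(cand$p_raw, method = "BH")
  cand$edge_class <- "lncRNA->gene"
  out <- cand[cand$pearson_r > 0 & cand$p_adjusted < adj_alpha, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "candidates") <- cand
  attr(out, "evaluated") <- evaluated
  out
}

empty_lnc_edges <- function() {
  data.frame(regulator_id = character(0), target_id = character(0),
             n_shared_mirnas = integer(0), hyper_p = numeric(0),
             pearson_r = numeric(0), p_raw = numeric(0),
             p_adjusted = numeric(0), edge_class = character(0),
             stringsAsFactors = FALSE)
}

#' Assemble the heterogeneous posttranscriptional regulatory network
#'
#' Combines the PPI, active miRNA edges (mRNA and optionally lncRNA
#' targets) and lncRNA-gene edges into one igraph whose vertices carry a
#' `node_class` attribute (`mRNA`, `miRNA`, `lncRNA`) and whose edges carry
#' an `edge_class`. Feature ids must be unique across classes.
#'
#' @param ppi igraph PPI network (mRNA nodes).
#' @param mirna_edges active miRNA edge `data.frame`s (rbind of classes).
#' @param lncrna_edges lncRNA-gene edge `data.frame`.
#' @return igraph with `node_class` vertex attribute and `edge_class` edge
#'   attribute.
#' @export
assemble_network <- function(ppi, mirna_edges, lncrna_edges) {
  mrna_nodes <- igraph::V(ppi)$name
  mirna_nodes <- unique(mirna_edges$regulator_id)
  lnc_nodes <- unique(c(lncrna_edges$regulator_id,
                        mirna_edges$target_id[mirna_edges$edge_class == "miRNA->lncRNA"]))
  if (length(intersect(mrna_nodes, mirna_nodes)) ||
      length(intersect(mrna_nodes, lnc_nodes)) ||
      length(intersect(mirna_nodes, lnc_nodes))) {
    stopf("feature id collisions across node classes")
  }
  ppi_el <- igraph::as_edgelist(ppi)
  edges <- rbind(
    data.frame(from = ppi_el[, 1L], to = ppi_el[, 2L], edge_class = "PPI",
               stringsAsFactors = FALSE),
    if (nrow(mirna_edges)) data.frame(from = mirna_edges$regulator_id,
                                      to = mirna_edges$target_id,
                                      edge_class = mirna_edges$edge_class,
                                      stringsAsFactors = FALSE),
    if (nrow(lncrna_edges)) data.frame(from = lncrna_edges$regulator_id,
                                       to = lncrna_edges$target_id,
                                       edge_class = "lncRNA->gene",
                                       stringsAsFactors = FALSE)
  )
  nodes <- data.frame(
    name = c(mrna_nodes, mirna_nodes, setdiff(lnc_nodes, character(0))),
    node_class = c(rep("mRNA", length(mrna_nodes)),
                   rep("miRNA", length(mirna_nodes)),
                   rep("lncRNA", length(lnc_nodes))),
    stringsAsFactors = FALSE
  )
  extra <- setdiff(unique(c(edges$from, edges$to)), nodes$name)
  if (length(extra)) {
    nodes <- rbind(nodes, data.frame(name = extra, node_class = "mRNA",
                                     stringsAsFactors = FALSE))
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}
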