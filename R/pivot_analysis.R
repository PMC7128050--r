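#' Find pivot ncRNA regulators of a significant crosstalk module pair
#'
#' A pivot is a miRNA or lncRNA whose network targets are sufficiently and
#' significantly present in *both* modules of a crosstalk pair: at least
#' `min_targets_per_module` targets in each module, and an upper-tail
#' hypergeometric enrichment p-value below `alpha` in each module. The
#' enrichment universe for each regulator class is the set of mRNA nodes
#' that are a target of at least one regulator of that class (the regulable
#' frame); module gene sets are intersected with it. No multiple-testing
#' correction is applied across regulators (raw p-values, matching the
#' pipeline's other raw thresholds); `adjust = "BH"` switches it on.
#'
#' @param mirna_gene_edges active miRNA-mRNA edges.
#' @param lncrna_edges lncRNA-gene edges.
#' @param module_a,module_b character vectors of the pair's gene ids.
#' @param min_targets_per_module minimum targets required in each module
#'   (`>= 2` by default; set 3 for a strict "more than two" reading).
#' @param alpha per-module enrichment threshold.
#' @param adjust `"none"` (default) or `"BH"` across regulators.
#' @return `data.frame` of pivots: `regulator_id`, `regulator_class`,
#'   `targets_in_A`, `targets_in_B`, `hyper_p_A`, `hyper_p_B`; all
#'   evaluated regulators as attribute `tested`.
#' @export
find_pivots <- function(mirna_gene_edges, lncrna_edges, module_a, module_b,
                        min_targets_per_module = 2, alpha = 0.05,
                        adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  class_edges <- list(
    miRNA = mirna_gene_edges[mirna_gene_edges$edge_class %in%
                               c("miRNA->mRNA", "miRNA-mRNA"), , drop = FALSE],
    lncRNA = lncrna_edges
  )
  rows <- NULL
  for (cls in names(class_edges)) {
    ed <- class_edges[[cls]]
    if (is.null(ed) || nrow(ed) == 0L) next
    universe <- unique(ed$target_id)
    a_u <- intersect(module_a, universe)
    b_u <- intersect(module_b, universe)
    targets <- split(ed$target_id, ed$regulator_id)
    for (reg in names(targets)) {
      tg <- unique(targets[[reg]])
      if (length(tg) == 0L) next
      ka <- length(intersect(tg, a_u))
      kb <- length(intersect(tg, b_u))
      pa <- hyper_upper_p(ka, length(a_u), length(tg), length(universe))
      pb <- hyper_upper_p(kb, length(b_u), length(tg), length(universe))
      rows <- rbind(rows, data.frame(
        regulator_id = reg, regulator_class = cls,
        targets_in_A = ka, targets_in_B = kb,
        hyper_p_A = pa, hyper_p_B = pb, stringsAsFactors = FALSE))
    }
  }
  if (is.null(rows)) {
    rows <- data.frame(regulator_id = character(0),
                       regulator_class = character(0),
                       targets_in_A = integer(0), targets_in_B = integer(0),
                       hyper_p_A = numeric(0), hyper_p_B = numeric(0),
                       stringsAsFactors = FALSE)
  }
  pa <- rows$hyper_p_A
  pb <- rows$hyper_p_B
  if (adjust == "BH" && nrow(rows)) {
    pa <- stats::p.adjust(pa, "BH")
    pb <- stats::p.adjust(pb, "BH")
  }
  keep <- rows$targets_in_A >= min_targets_per_module &
    rows$targets_in_B >= min_targets_per_module &
    pa < alpha & pb < alpha
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tested") <- rows
  out
}

#' Build ncRNA-regulated modules from significant crosstalk pairs
#'
#' One NcModule per significant crosstalk pair with at least one pivot: the
#' merged (deduplicated) gene content of the pair plus its pivot regulator
#' set. Pairs without pivots are dropped.
#'
#' @param pairs `data.frame` from [crosstalk_test()] (significant rows are
#'   used).
#' @param modules_iii,modules_iv the module lists the pairs refer to.
#' @param pivots_per_pair list of [find_pivots()] results indexed like the
#'   significant rows of `pairs` (names `"<III id>|<IV id>"`).
#' @return list of NcModules: `id`, `source_pair`, `gene_ids`, `pivot_ids`,
#'   `pivot_classes`.
#' @export
build_nc_modules <- function(pairs, modules_iii, modules_iv, pivots_per_pair) {
  sig <- pairs[pairs$significant, , drop = FALSE]
  by_id_iii <- stats::setNames(modules_iii, vapply(modules_iii, `[[`, "", "id"))
  by_id_iv <- stats::setNames(modules_iv, vapply(modules_iv, `[[`, "", "id"))
  out <- list()
  for (i in seq_len(nrow(sig))) {
    key <- paste(sig$module_III_id[i], sig$module_IV_id[i], sep = "|")
    piv <- pivots_per_pair[[key]]
    if (is.null(piv) || nrow(piv) == 0L) next
    a <- by_id_iii[[sig$module_III_id[i]]]$node_ids
    b <- by_id_iv[[sig$module_IV_id[i]]]$node_ids
    out[[length(out) + 1L]] <- list(
      id = sprintf("NC%02d", length(out) + 1L),
      source_pair = c(sig$module_III_id[i], sig$module_IV_id[i]),
      gene_ids = sort(union(a, b)),
      pivot_ids = piv$regulator_id,
      pivot_classes = piv$regulator_class
    )
  }
  out
}
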