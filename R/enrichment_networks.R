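#' Hypergeometric gene-set enrichment of a module
#'
#' Upper-tail hypergeometric test of the overlap between the module's genes
#' and each gene set, against a fixed gene universe. Module genes outside
#' the universe are dropped with a message; set members outside the
#' universe are ignored.
#'
#' @param module_genes character vector of module gene ids.
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe character vector of all eligible genes.
#' @param alpha significance threshold (`significant` when `p < alpha`).
#' @param module_id optional id recorded on the rows.
#' @return `data.frame` with `module_id`, `set_name`, `overlap_k`,
#'   `set_size`, `module_size`, `universe_size`, `p`, `significant`.
#' @export
enrich_module <- function(module_genes, gene_sets, universe, alpha = 0.05,
                          module_id = NA_character_) {
  if (length(universe) == 0L) stopf("empty enrichment universe")
  universe <- unique(universe)
  outside <- setdiff(module_genes, universe)
  if (length(outside)) {
    message(length(outside), " module gene(s) outside the universe dropped")
  }
  mod <- intersect(module_genes, universe)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    k <- length(intersect(mod, set))
    p <- hyper_upper_p(k, length(set), length(mod), length(universe))
    data.frame(module_id = module_id, set_name = nm, overlap_k = k,
               set_size = length(set), module_size = length(mod),
               universe_size = length(universe), p = p,
               significant = p < alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pathway co-enrichment network
#'
#' Builds a network over pathways from per-module enrichment results: two
#' pathways are linked when the overlap of the module sets they are
#' significantly enriched in is itself hypergeometrically significant
#' (population = number of modules, successes = modules enriching pathway
#' 1, draws = modules enriching pathway 2), at `p < edge_alpha`.
#'
#' @param enrichments `data.frame` of stacked [enrich_module()] results
#'   over the module collection.
#' @param n_modules number of modules in the collection.
#' @param edge_alpha edge significance threshold (default 0.01).
#' @param group optional group tag (`"A"`/`"B"`) stored on the result.
#' @return list with `nodes` (pathways significant in >= 1 module, with
#'   their module counts), `edges` (`pathway1`, `pathway2`, `overlap`,
#'   `p`), and `group`.
#' @export
pathway_coenrichment_network <- function(enrichments, n_modules,
                                         edge_alpha = 0.01, group = NA) {
  sig <- enrichments[enrichments$significant, , drop = FALSE]
  mod_sets <- split(sig$module_id, sig$set_name)
  mod_sets <- lapply(mod_sets, unique)
  pathways <- names(mod_sets)
  nodes <- data.frame(pathway = pathways,
                      n_modules_enriched = lengths(mod_sets),
                      stringsAsFactors = FALSE)
  edges <- NULL
  if (length(pathways) >= 2L) {
    idx <- utils::combn(length(pathways), 2L)
    for (c_i in seq_len(ncol(idx))) {
      i <- idx[1L, c_i]; j <- idx[2L, c_i]
      k <- length(intersect(mod_sets[[i]], mod_sets[[j]]))
      p <- hyper_upper_p(k, length(mod_sets[[i]]), length(mod_sets[[j]]),
                         n_modules)
      if (p < edge_alpha) {
        edges <- rbind(edges, data.frame(pathway1 = pathways[i],
                                         pathway2 = pathways[j],
                                         overlap = k, p = p,
                                         stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(edges)) {
    edges <- data.frame(pathway1 = character(0), pathway2 = character(0),
                        overlap = integer(0), p = numeric(0),
                        stringsAsFactors = FALSE)
  }
  list(nodes = nodes, edges = edges, group = group, n_modules = n_modules)
}

#' Core hallmark pathways of a co-enrichment network
#'
#' Pathways enriched in at least `min_modules` modules and with network
#' degree at least `min_degree`, ranked by (modules enriched, degree)
#' descending. `min_degree = NULL` uses the upper quartile of the degree
#' distribution.
#'
#' @param network list from [pathway_coenrichment_network()].
#' @param min_modules minimum modules a core pathway must enrich.
#' @param min_degree minimum co-enrichment degree (`NULL` for the upper
#'   quartile).
#' @return `data.frame` with `pathway`, `n_modules_enriched`, `degree`.
#' @export
core_pathways <- function(network, min_modules = 3, min_degree = NULL) {
  nodes <- network$nodes
  deg <- table(c(network$edges$pathway1, network$edges$pathway2))
  nodes$degree <- as.integer(deg[nodes$pathway])
  nodes$degree[is.na(nodes$degree)] <- 0L
  if (is.null(min_degree)) {
    min_degree <- stats::quantile(nodes$degree, 0.75, names = FALSE)
  }
  out <- nodes[nodes$n_modules_enriched >= min_modules &
                 nodes$degree >= min_degree, , drop = FALSE]
  out <- out[order(-out$n_modules_enriched, -out$degree, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}
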