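#' Pipeline configuration
#'
#' All thresholds of the analysis chain in one list, at the study's
#' defaults: 5% SAM FDR, PPI confidence cutoff 900 (STRING 0.9), 1000
#' degree-preserving random networks at alpha 0.05 for crosstalk, 5%
#' BH-FDR for active miRNA edges, 0.05/0.05 for the two-stage lncRNA-gene
#' filters, pivot minimum of 2 targets per module at p < 0.05, enrichment
#' alpha 0.05 and co-enrichment edge alpha 0.01.
#'
#' @param ... overrides of the defaults.
#' @return named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    zero_floor = 0.05, merge_low_stages = TRUE,
    deg_fdr = 0.05, n_perm = 1000,
    ppi_cutoff = 900,
    n_random = 1000, crosstalk_alpha = 0.05,
    mirna_fdr = 0.05, filter_mirna_lnc = FALSE,
    lnc_hyper_alpha = 0.05, lnc_adj_alpha = 0.05,
    pivot_min_targets = 2, pivot_alpha = 0.05,
    enrich_alpha = 0.05, edge_alpha = 0.01,
    multivariable = FALSE,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

#' Run the full analysis chain on a study directory
#'
#' Executes preprocessing, SAM differential expression for both stage
#' contrasts, module discovery per stage, the crosstalk permutation test,
#' regulatory network inference, pivot analysis, NcModule survival
#' comparison, and hallmark enrichment with co-enrichment networks for the
#' improved (group A) and non-improved (group B) NcModules as well as for
#' the full stage-module collection. All stage artifacts are written to
#' `output_dir` (TSV/GraphML/JSON) when given, along with a JSON manifest
#' of counts and settings; a rerun with the same inputs, config and seed
#' reproduces every statistic exactly.
#'
#' @param input_dir directory holding the study files as written by
#'   [write_study()].
#' @param output_dir optional directory for per-stage artifacts and the
#'   manifest.
#' @param config list from [pipeline_config()].
#' @return the manifest list (invisibly carries the full `results` as an
#'   attribute).
#' @export
run_all <- function(input_dir, output_dir = NULL, config = pipeline_config()) {
  t0 <- Sys.time()
  seed <- as.integer(config$seed)

  # preprocessing
  gene <- load_and_transform(file.path(input_dir, "expression_gene.tsv"),
                             "mRNA", config$zero_floor)
  mirna <- load_and_transform(file.path(input_dir, "expression_mirna.tsv"),
                              "miRNA", config$zero_floor)
  lnc <- load_and_transform(file.path(input_dir, "expression_lncrna.tsv"),
                            "lncRNA", config$zero_floor)
  clinical <- load_clinical(file.path(input_dir, "clinical.tsv"),
                            config$merge_low_stages)
  h <- harmonize_samples(list(gene = gene, mirna = mirna, lnc = lnc), clinical)
  gene <- h$matrices$gene; mirna <- h$matrices$mirna; lnc <- h$matrices$lnc
  clinical <- h$clinical

  # differential expression, both contrasts
  deg <- list()
  for (ct in c("III", "IV")) {
    sel <- clinical$stage %in% c("low", ct)
    labels <- factor(as.character(clinical$stage[sel]), levels = c("low", ct))
    deg[[ct]] <- permutation_fdr(gene[, sel, drop = FALSE], labels,
                                 n_perm = config$n_perm,
                                 fdr_threshold = config$deg_fdr,
                                 seed = child_seed(seed, 101L),
                                 contrast = paste0(ct, "_vs_low"))
  }

  # module discovery per stage
  ppi <- load_ppi(file.path(input_dir, "ppi_edges.tsv"), config$ppi_cutoff)
  modules <- list()
  for (ct in c("III", "IV")) {
    ids <- intersect(deg[[ct]]$deg_ids, igraph::V(ppi)$name)
    modules[[ct]] <- if (length(ids)) discover_modules(ppi, ids, contrast = ct) else list()
  }

  # crosstalk between stage III and stage IV modules
  if (length(modules$III) && length(modules$IV)) {
    pairs <- crosstalk_test(ppi, modules$III, modules$IV,
                            n_random = config$n_random,
                            alpha = config$crosstalk_alpha,
                            seed = child_seed(seed, 211L))
  } else {
    pairs <- data.frame(module_III_id = character(0), module_IV_id = character(0),
                        real_edges = integer(0), p_value = numeric(0),
                        significant = logical(0), stringsAsFactors = FALSE)
  }

  # regulatory network
  catalog <- read_tsv(file.path(input_dir, "interactions.tsv"))
  cat_mrna <- catalog[catalog$target_class == "mRNA", , drop = FALSE]
  cat_lnc <- catalog[catalog$target_class == "lncRNA", , drop = FALSE]
  mirna_gene <- active_mirna_edges(cat_mrna, mirna, gene, config$mirna_fdr,
                                   edge_class = "miRNA->mRNA")
  if (config$filter_mirna_lnc) {
    mirna_lnc <- active_mirna_edges(cat_lnc, mirna, lnc, config$mirna_fdr,
                                    edge_class = "miRNA->lncRNA")
  } else {
    mirna_lnc <- data.frame(regulator_id = cat_lnc$regulator_id,
                            target_id = cat_lnc$target_id,
                            edge_class = "miRNA->lncRNA",
                            pearson_r = NA_real_, p_raw = NA_real_,
                            p_adjusted = NA_real_, stringsAsFactors = FALSE)
  }
  lnc_gene <- lncrna_gene_edges(mirna_lnc, mirna_gene, lnc, gene,
                                config$lnc_hyper_alpha, config$lnc_adj_alpha)
  regnet <- assemble_network(ppi, rbind(mirna_gene, mirna_lnc), lnc_gene)

  # pivot analysis on significant pairs
  by_id <- function(mods) stats::setNames(mods, vapply(mods, `[[`, "", "id"))
  m3 <- by_id(modules$III); m4 <- by_id(modules$IV)
  pivots <- list()
  sig <- pairs[pairs$significant, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    key <- paste(sig$module_III_id[i], sig$module_IV_id[i], sep = "|")
    pivots[[key]] <- find_pivots(
      mirna_gene, lnc_gene,
      m3[[sig$module_III_id[i]]]$node_ids, m4[[sig$module_IV_id[i]]]$node_ids,
      min_targets_per_module = config$pivot_min_targets,
      alpha = config$pivot_alpha)
  }
  nc_modules <- build_nc_modules(pairs, modules$III, modules$IV, pivots)

  # survival comparison per NcModule
  surv <- lapply(nc_modules, function(nc) {
    module_survival_comparison(nc, gene, mirna, lnc, clinical,
                               multivariable = config$multivariable)
  })
  improved <- vapply(surv, `[[`, TRUE, "improved")
  sig_surv <- vapply(surv, function(s) s$genes_plus_ncrna$logrank_p < 0.05, TRUE)

  # enrichment: NcModules split into group A (improved) / group B, plus the
  # full stage-module collection
  gene_sets <- read_gmt(file.path(input_dir, "gene_sets.gmt"))
  universe <- igraph::V(ppi)$name
  empty_enrich <- data.frame(module_id = character(0), set_name = character(0),
                             overlap_k = integer(0), set_size = integer(0),
                             module_size = integer(0), universe_size = integer(0),
                             p = numeric(0), significant = logical(0),
                             stringsAsFactors = FALSE)
  enrich_nc <- do.call(rbind, lapply(nc_modules, function(nc) {
    suppressMessages(enrich_module(nc$gene_ids, gene_sets, universe,
                                   config$enrich_alpha, nc$id))
  })) %||% empty_enrich
  group_nets <- list()
  for (grp in c("A", "B")) {
    idx <- if (grp == "A") which(improved) else which(!improved)
    ids <- vapply(nc_modules[idx], `[[`, "", "id")
    en <- enrich_nc[enrich_nc$module_id %in% ids, , drop = FALSE]
    group_nets[[grp]] <- pathway_coenrichment_network(
      en, length(idx), config$edge_alpha, group = grp)
  }
  all_mods <- c(modules$III, modules$IV)
  enrich_stage <- do.call(rbind, lapply(all_mods, function(m) {
    suppressMessages(enrich_module(m$node_ids, gene_sets, universe,
                                   config$enrich_alpha, m$id))
  })) %||% empty_enrich
  stage_net <- pathway_coenrichment_network(
    enrich_stage, length(all_mods), config$edge_alpha, group = "stage_modules")

  manifest <- list(
    config = config,
    n_samples = nrow(clinical),
    n_genes = nrow(gene), n_mirnas = nrow(mirna), n_lncrnas = nrow(lnc),
    n_deg_III = length(deg$III$deg_ids), n_deg_IV = length(deg$IV$deg_ids),
    n_modules_III = length(modules$III), n_modules_IV = length(modules$IV),
    n_pairs_tested = nrow(pairs),
    n_crosstalk_significant = sum(pairs$significant),
    n_mirna_gene_edges = nrow(mirna_gene),
    n_lncrna_gene_edges = nrow(lnc_gene),
    regnet_nodes = igraph::vcount(regnet),
    regnet_edges = igraph::ecount(regnet),
    n_pivots_total = sum(vapply(pivots, nrow, 0L)),
    n_nc_modules = length(nc_modules),
    n_survival_significant = sum(sig_surv),
    n_improved = sum(improved),
    pathway_edges_group_A = nrow(group_nets$A$edges),
    pathway_edges_group_B = nrow(group_nets$B$edges),
    pathway_edges_stage_modules = nrow(stage_net$edges),
    crosstalk_p_values = stats::setNames(pairs$p_value,
                                         paste(pairs$module_III_id,
                                               pairs$module_IV_id, sep = "|")),
    survival = lapply(surv, function(s) list(
      nc_module_id = s$nc_module_id,
      logrank_p_genes_only = s$genes_only$logrank_p,
      logrank_p_genes_plus_ncrna = s$genes_plus_ncrna$logrank_p,
      improved = s$improved)),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  results <- list(deg = deg, ppi = ppi, modules = modules, pairs = pairs,
                  mirna_gene = mirna_gene, mirna_lnc = mirna_lnc,
                  lnc_gene = lnc_gene, regnet = regnet, pivots = pivots,
                  nc_modules = nc_modules, survival = surv,
                  enrich_nc = enrich_nc, enrich_stage = enrich_stage,
                  group_nets = group_nets, stage_net = stage_net,
                  clinical = clinical,
                  expr = list(gene = gene, mirna = mirna, lnc = lnc))

  if (!is.null(output_dir)) write_run_outputs(results, manifest, output_dir)
  attr(manifest, "results") <- results
  invisible(manifest)
}

# per-stage artifacts + manifest JSON
write_run_outputs <- function(results, manifest, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  for (ct in c("III", "IV")) {
    d <- results$deg[[ct]]
    write_tsv(data.frame(feature_id = names(d$d), contrast = d$contrast,
                         d = d$d, q = d$q, is_deg = names(d$d) %in% d$deg_ids,
                         stringsAsFactors = FALSE),
              file.path(output_dir, sprintf("deg_%s.tsv", ct)))
    mods <- results$modules[[ct]]
    if (length(mods)) {
      write_tsv(do.call(rbind, lapply(mods, function(m) {
        data.frame(module_id = m$id, contrast = ct, node_id = m$node_ids,
                   mcode_score = m$mcode_score, stringsAsFactors = FALSE)
      })), file.path(output_dir, sprintf("modules_%s.tsv", ct)))
    }
  }
  write_tsv(results$pairs, file.path(output_dir, "crosstalk_pairs.tsv"))
  write_tsv(rbind(results$mirna_gene,
                  results$lnc_gene[c("regulator_id", "target_id", "edge_class",
                                     "pearson_r", "p_raw", "p_adjusted")]),
            file.path(output_dir, "regulatory_edges.tsv"))
  write_graphml(results$regnet, file.path(output_dir, "regulatory_network.graphml"))
  if (length(results$pivots)) {
    write_tsv(do.call(rbind, lapply(names(results$pivots), function(k) {
      p <- attr(results$pivots[[k]], "tested")
      if (is.null(p) || nrow(p) == 0L) return(NULL)
      p$pair <- k
      p$is_pivot <- p$regulator_id %in% results$pivots[[k]]$regulator_id
      p
    })), file.path(output_dir, "pivots.tsv"))
  }
  jsonlite::write_json(lapply(results$nc_modules, function(nc) {
    nc[c("id", "source_pair", "gene_ids", "pivot_ids")]
  }), file.path(output_dir, "nc_modules.json"), auto_unbox = FALSE, pretty = TRUE)
  if (length(results$survival)) {
    write_tsv(do.call(rbind, lapply(results$survival, function(s) {
      data.frame(nc_module_id = s$nc_module_id,
                 logrank_p_genes_only = s$genes_only$logrank_p,
                 logrank_p_genes_plus_ncrna = s$genes_plus_ncrna$logrank_p,
                 predictive_ability_genes_only = s$genes_only$predictive_ability,
                 predictive_ability_genes_plus_ncrna = s$genes_plus_ncrna$predictive_ability,
                 improved = s$improved, stringsAsFactors = FALSE)
    })), file.path(output_dir, "survival_comparison.tsv"))
  }
  if (!is.null(results$enrich_nc)) {
    write_tsv(results$enrich_nc, file.path(output_dir, "enrichment_nc_modules.tsv"))
  }
  if (!is.null(results$enrich_stage)) {
    write_tsv(results$enrich_stage, file.path(output_dir, "enrichment_stage_modules.tsv"))
  }
  for (grp in names(results$group_nets)) {
    net <- results$group_nets[[grp]]
    if (nrow(net$edges)) {
      write_tsv(net$edges, file.path(output_dir, sprintf("pathway_network_group_%s.tsv", grp)))
    }
  }
  if (nrow(results$stage_net$edges)) {
    write_tsv(results$stage_net$edges,
              file.path(output_dir, "pathway_network_stage_modules.tsv"))
  }
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}
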