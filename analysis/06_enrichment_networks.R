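#!/usr/bin/env Rscript
# Stage 6 - hallmark enrichment and pathway co-enrichment networks.
#
# Hypergeometric enrichment of every stage module and NcModule against the
# gene-set collection, then pathway co-enrichment networks (edges where
# two pathways are enriched in overlapping module sets at P < 0.01), built
# for group A, group B, and the full stage-module collection, with the
# core pathways of each network reported.

suppressPackageStartupMessages(library(ncmod))

state3 <- readRDS("results/state_03.rds")
state5 <- readRDS("results/state_05.rds")
gene_sets <- read_gmt("results/synthetic_study/gene_sets.gmt")
universe <- igraph::V(state3$ppi)$name

all_mods <- c(state3$modules$III, state3$modules$IV)
enr_stage <- do.call(rbind, lapply(all_mods, function(m) {
  enrich_module(m$node_ids, gene_sets, universe, module_id = m$id)
}))
write.table(enr_stage, "results/tables/enrichment_stage_modules.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("stage modules: %d significant enrichments across %d modules\n",
            sum(enr_stage$significant), length(all_mods)))

net_stage <- pathway_coenrichment_network(enr_stage, length(all_mods),
                                          edge_alpha = 0.01,
                                          group = "stage_modules")
cat(sprintf("stage-module pathway network: %d pathways, %d edges (P < 0.01)\n",
            nrow(net_stage$nodes), nrow(net_stage$edges)))

improved <- vapply(state5$survival, `[[`, TRUE, "improved")
enr_nc <- do.call(rbind, lapply(state5$nc_modules, function(nc) {
  enrich_module(nc$gene_ids, gene_sets, universe, module_id = nc$id)
}))
for (grp in c("A", "B")) {
  ids <- vapply(state5$nc_modules[if (grp == "A") which(improved) else which(!improved)],
                `[[`, "", "id")
  en <- enr_nc[enr_nc$module_id %in% ids, ]
  net <- pathway_coenrichment_network(en, length(ids), edge_alpha = 0.01,
                                      group = grp)
  cat(sprintf("group %s (%d modules): %d enriched pathways, %d network edges\n",
              grp, length(ids), nrow(net$nodes), nrow(net$edges)))
  if (nrow(net$edges)) {
    write.table(net$edges,
                sprintf("results/tables/pathway_network_group_%s.tsv", grp),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  core <- core_pathways(net, min_modules = 1, min_degree = NULL)
  if (nrow(core)) {
    cat(sprintf("  core pathways: %s\n", paste(core$pathway, collapse = ", ")))
  }
}
cat("Enrichment tables written to results/tables/\n")
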