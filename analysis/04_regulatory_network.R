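#!/usr/bin/env Rscript
# Stage 4 - ncRNA posttranscriptional regulatory network.
#
# Filters the CLIP-style catalog to expression-active miRNA-target edges
# (negative correlation, BH-FDR < 0.05), infers lncRNA-gene regulation by
# the two-stage shared-miRNA + positive-correlation analysis, and
# assembles the heterogeneous network with the PPI.

suppressPackageStartupMessages(library(ncmod))

state2 <- readRDS("results/state_02.rds")
state3 <- readRDS("results/state_03.rds")
catalog <- read.delim("results/synthetic_study/interactions.tsv")

cat_m <- catalog[catalog$target_class == "mRNA", ]
cat_l <- catalog[catalog$target_class == "lncRNA", ]
mirna_gene <- active_mirna_edges(cat_m, state2$expr$mirna, state2$expr$gene,
                                 fdr = 0.05, edge_class = "miRNA->mRNA")
cat(sprintf("%d of %d catalog miRNA-mRNA pairs are expression-active (r < 0, FDR < 0.05)\n",
            nrow(mirna_gene), nrow(cat_m)))

mirna_lnc <- data.frame(regulator_id = cat_l$regulator_id,
                        target_id = cat_l$target_id,
                        edge_class = "miRNA->lncRNA",
                        pearson_r = NA_real_, p_raw = NA_real_,
                        p_adjusted = NA_real_)
lnc_gene <- lncrna_gene_edges(mirna_lnc, mirna_gene,
                              state2$expr$lnc, state2$expr$gene)
cat(sprintf("%d lncRNA-gene edges pass the two-stage filter (of %d stage-1 candidates)\n",
            nrow(lnc_gene), nrow(attr(lnc_gene, "candidates"))))

regnet <- assemble_network(state3$ppi, rbind(mirna_gene, mirna_lnc), lnc_gene)
cat(sprintf("assembled network: %d nodes (%s), %d edges\n",
            igraph::vcount(regnet),
            paste(names(table(igraph::V(regnet)$node_class)),
                  table(igraph::V(regnet)$node_class),
                  sep = "=", collapse = ", "),
            igraph::ecount(regnet)))

write.table(rbind(mirna_gene,
                  lnc_gene[c("regulator_id", "target_id", "edge_class",
                             "pearson_r", "p_raw", "p_adjusted")]),
            "results/tables/regulatory_edges.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write_graphml(regnet, "results/tables/regulatory_network.graphml")
saveRDS(list(mirna_gene = mirna_gene, mirna_lnc = mirna_lnc,
             lnc_gene = lnc_gene, regnet = regnet),
        "results/state_04.rds")
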