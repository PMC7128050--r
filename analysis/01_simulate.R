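#!/usr/bin/env Rscript
# Stage 1 - simulate the synthetic study.
#
# Generates the full synthetic cohort with planted structure: a PPI with ten
# near-clique modules (five per stage contrast), four bridged stage-III/IV
# crosstalk pairs, planted stage DEGs, miRNA-target and lncRNA-gene
# couplings with pivot regulators on every bridged pair, hazard
# coefficients on the first pair's genes and ncRNAs, and hallmark-style
# gene sets. Everything downstream reads the files written here.

suppressPackageStartupMessages(library(ncmod))

seed <- 1L
out <- "results/synthetic_study"
st <- simulate_study(seed = seed, dir = out)

cat("Synthetic study written to", out, "\n")
cat(sprintf("  %d genes x %d patients, %d miRNAs, %d lncRNAs\n",
            nrow(st$expr$gene), ncol(st$expr$gene),
            nrow(st$expr$mirna), nrow(st$expr$lnc)))
cat(sprintf("  PPI: %d nodes, %d edges; %d planted modules, %d bridged pairs\n",
            igraph::vcount(st$graph), igraph::ecount(st$graph),
            length(st$truth$planted_modules),
            nrow(st$truth$planted_crosstalk_pairs)))
cat(sprintf("  planted DEGs: %d (III), %d (IV); planted regulatory pairs: %d miRNA-target, %d lncRNA-gene\n",
            length(st$truth$planted_deg_ids_per_contrast$III_vs_low),
            length(st$truth$planted_deg_ids_per_contrast$IV_vs_low),
            nrow(st$truth$regulation$mirna_target),
            nrow(st$truth$regulation$lncrna_gene)))
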