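#!/usr/bin/env Rscript
# Stage 2 - preprocessing and SAM differential expression.
#
# Applies the zero-handling/log2 transform, harmonizes samples with the
# clinical table, and calls stage III and stage IV DEGs against the
# low-stage group with the SAM permutation statistic at 5% FDR.

suppressPackageStartupMessages(library(ncmod))

study <- "results/synthetic_study"
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

gene <- load_and_transform(file.path(study, "expression_gene.tsv"), "mRNA")
mirna <- load_and_transform(file.path(study, "expression_mirna.tsv"), "miRNA")
lnc <- load_and_transform(file.path(study, "expression_lncrna.tsv"), "lncRNA")
clinical <- load_clinical(file.path(study, "clinical.tsv"))
h <- harmonize_samples(list(gene = gene, mirna = mirna, lnc = lnc), clinical)

cat(sprintf("%d patients (low/III/IV = %s) after harmonization\n",
            nrow(h$clinical), paste(table(h$clinical$stage), collapse = "/")))

deg <- list()
for (ct in c("III", "IV")) {
  sel <- h$clinical$stage %in% c("low", ct)
  labels <- factor(as.character(h$clinical$stage[sel]), levels = c("low", ct))
  deg[[ct]] <- permutation_fdr(h$matrices$gene[, sel], labels,
                               n_perm = 1000, seed = 102L,
                               contrast = paste0(ct, "_vs_low"))
  print(deg[[ct]])
  write.table(
    data.frame(feature_id = names(deg[[ct]]$d), contrast = deg[[ct]]$contrast,
               d = deg[[ct]]$d, q = deg[[ct]]$q,
               is_deg = names(deg[[ct]]$d) %in% deg[[ct]]$deg_ids),
    sprintf("results/tables/deg_%s.tsv", ct),
    sep = "\t", quote = FALSE, row.names = FALSE)
}

saveRDS(list(expr = h$matrices, clinical = h$clinical, deg = deg),
        "results/state_02.rds")
cat("DEG tables written to results/tables/\n")
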