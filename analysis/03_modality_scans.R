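#!/usr/bin/env Rscript
# Run the parallel age-association scans on gene expression, transcript
# expression and within-gene transcript ratios, then compare the four
# modalities' age-associated gene sets.

library(spliceage)

dat <- file.path("results", "data")
pheno <- read_phenotypes(file.path(dat, "phenotypes.tsv"))
tx2gene_df <- read.delim(file.path(dat, "tx2gene.tsv"))
mats <- list(
  psi = read_psi_table(file.path(dat, "psi_tissue1.tsv")),
  gene = read_expression_table(file.path(dat, "gene_tpm.tsv")),
  transcript = read_expression_table(file.path(dat, "transcript_tpm.tsv")),
  tx2gene = setNames(tx2gene_df$gene_id, tx2gene_df$tx_id)
)

psi_res <- read.delim(file.path("results", "scan_psi_tissue1.tsv"))
scans <- list(splicing = psi_res)
for (mod in c("gene", "transcript", "ratio")) {
  scans[[mod]] <- run_modality_scan(mod, mats, pheno, n_factors = 20,
                                    n_perm = 1000, seed = 12)
  write.table(scans[[mod]], file.path("results", sprintf("scan_%s.tsv", mod)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%-10s scan: %d tested, %d significant\n", mod,
              sum(scans[[mod]]$tested), sum(scans[[mod]]$significant)))
}

fmap <- c(event_to_gene(rownames(mats$psi)), mats$tx2gene)
ov <- modality_overlap(scans, fmap)
write.table(ov$membership, file.path("results", "modality_overlap.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\ngenes with any age-associated signal:", nrow(ov$membership), "\n")
for (nm in names(ov$unique_genes)) {
  cat(sprintf("unique to %s: %d genes\n", nm, length(ov$unique_genes[[nm]])))
}
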