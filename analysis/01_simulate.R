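#!/usr/bin/env Rscript
# Build the default synthetic tissue cohort and write every pipeline input:
# phenotypes, per-tissue PSI matrices, gene/transcript expression,
# cassette-exon region sequences, splicing-factor expression, disease
# labels and the ground-truth event table. All later analysis scripts read
# from results/data/.

library(spliceage)

out <- file.path("results", "data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 2026)   # 150 donors, 500 events, 10% age-associated
cohort <- simulate_cohort(cfg)

# two tissues share the cohort (one sample per donor per tissue, as in
# population expression atlases); tissue 1 carries the full annotation
tissues <- lapply(1:2, function(t) {
  simulate_psi(cohort, cfg, seed = 5000 + t)
})
expr <- simulate_expression(cohort, cfg)
regsf <- simulate_regions_and_sf(tissues[[1]]$truth, cohort, cfg)
disease <- simulate_disease(cohort, tissues[[1]]$psi, expr$gene, cfg)

pheno <- data.frame(cohort[, c("sample_id", "donor_id", "age", "gender")],
                    disease = as.integer(disease))
write_phenotypes(pheno, file.path(out, "phenotypes.tsv"))
for (t in 1:2) {
  write_psi_table(tissues[[t]]$psi, file.path(out, sprintf("psi_tissue%d.tsv", t)))
}
write_psi_table(expr$gene, file.path(out, "gene_tpm.tsv"))
write_psi_table(expr$transcript, file.path(out, "transcript_tpm.tsv"))
write.table(data.frame(tx_id = names(expr$tx2gene), gene_id = expr$tx2gene),
            file.path(out, "tx2gene.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write_regions_fasta(regsf$regions, file.path(out, "regions_tissue1.fa"))
write_psi_table(regsf$sf_expr, file.path(out, "sf_expression.tsv"))
write.table(cfg$motif_set, file.path(out, "motifs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_json_result(tissues[[1]]$truth$events,
                  file.path(out, "ground_truth_tissue1.json"))

cat(sprintf("cohort: %d donors, ages %.0f-%.0f\n", nrow(cohort),
            min(cohort$age), max(cohort$age)))
cat(sprintf("tissue 1: %d events (%d truly age-associated), %.1f%% sentinel cells\n",
            nrow(tissues[[1]]$psi),
            sum(tissues[[1]]$truth$events$is_age_assoc),
            100 * mean(tissues[[1]]$psi == -1)))
cat(sprintf("expression: %d genes / %d transcripts; disease prevalence %.2f\n",
            nrow(expr$gene), nrow(expr$transcript), mean(disease)))
cat("inputs written to", out, "\n")
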