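#!/usr/bin/env Rscript
# Independent contribution of age-associated splicing to disease: nested
# logistic models of disease status on age + gender + gene-expression
# components, with and without PSI components of the significant
# age-associated events; chi-square likelihood-ratio test on the added
# components.

library(spliceage)

dat <- file.path("results", "data")
pheno <- read_phenotypes(file.path(dat, "phenotypes.tsv"))
psi <- read_psi_table(file.path(dat, "psi_tissue1.tsv"))
gene <- read_expression_table(file.path(dat, "gene_tpm.tsv"))
res <- read.delim(file.path("results", "scan_psi_tissue1.tsv"))

sig_events <- res$event_id[res$significant]
cat(sprintf("PSI feature block built from %d significant events\n",
            length(sig_events)))

# 20 + 20 components keep the sample-to-parameter ratio healthy at this
# cohort size (the full-scale analysis uses 100 + 100)
llr <- disease_llr(pheno$disease, pheno, gene, psi, sig_events,
                   n_ge_components = 20, n_psi_components = 20)
write_json_result(llr[c("ll_null", "ll_alt", "llr", "df", "p_value",
                        "family", "separation")],
                  file.path("results", "disease_llr.json"))
cat(sprintf("null log-likelihood: %.2f\nsplicing log-likelihood: %.2f\n",
            llr$ll_null, llr$ll_alt))
cat(sprintf("LLR = %.2f on %d df, chi-square p = %.3g\n",
            llr$llr, llr$df, llr$p_value))
cat(if (llr$p_value <= 0.05) {
  "splicing adds significant disease information beyond age, gender and expression\n"
} else {
  "no significant added information from splicing in this cohort\n"
})
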