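#!/usr/bin/env Rscript
# Stage 6: metabolite-by-protein multiple-regression matrix restricted to
# food-derived metabolites (age + sex adjusted, standardized betas, FDR
# over the whole pair matrix), with chemical-class summaries.

suppressPackageStartupMessages(library(npxcc))

a <- read_npx_long("results/qc/npx_cohort_a_clean.csv", "TZ")
meta <- read_metadata("results/data/metadata.csv")
mv <- read.csv("results/data/metabolites.csv", check.names = FALSE)
values <- as.matrix(mv[, -1]); rownames(values) <- mv$sample_id
ann <- read.csv("results/data/metabolite_annotation.csv")
food <- select_food_metabolites(metabolite_table(values, ann))

sc <- metabolite_protein_scan(food, a, meta)
dir.create("results/metab", recursive = TRUE, showWarnings = FALSE)
write.table(as.data.frame(sc), "results/metab/metabolite_protein_scan.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

cs <- class_summary(sc)
write.table(cs, "results/metab/class_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("scanned %d pairs; %d significant at FDR < 0.05\n",
            nrow(sc), sum(sc$fdr < 0.05)))
cat("\nchemical-class summary:\n")
print(cs)

top <- as.data.frame(sc[order(sc$fdr), ])[1:15,
        c("metabolite", "chem_class", "protein", "beta", "fdr", "stars")]
cat("\nstrongest metabolite-protein associations:\n")
print(top, row.names = FALSE)
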