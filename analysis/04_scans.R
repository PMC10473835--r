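#!/usr/bin/env Rscript
# Stage 4: host-factor regression scans (age, sex, BMI, season, residency)
# per cohort, and the matrix pQTL scan on cohort A.

suppressPackageStartupMessages(library(npxcc))

a <- read_npx_long("results/qc/npx_cohort_a_clean.csv", "TZ")
b <- read_npx_long("results/qc/npx_cohort_b_clean.csv", "NL")
meta <- read_metadata("results/data/metadata.csv")

dir.create("results/scans", recursive = TRUE, showWarnings = FALSE)
scans <- list()
for (co in list(a, b)) {
  m <- meta[meta$sample_id %in% npx_samples(co, "study"), ]
  for (f in c("age", "sex", "bmi", "season", "residency")) {
    vals <- m[[f]][!is.na(m[[f]])]
    if (length(unique(vals)) < 2) next
    scans[[paste(co$cohort, f)]] <- factor_scan(co, m, f)
  }
}
long <- do.call(rbind, lapply(scans, as.data.frame))
write.table(long, "results/scans/factor_scans.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
sig <- long[long$fdr < 0.05, ]
cat(sprintf("factor scans: %d (factor, protein) associations at FDR < 0.05 across %d scans\n",
            nrow(sig), length(scans)))
for (k in names(scans)) {
  s <- scans[[k]]
  cat(sprintf("  %-14s %3d significant of %d proteins\n", k,
              sum(s$fdr < 0.05), nrow(s)))
}

g <- read.csv("results/data/genotypes.csv", check.names = FALSE)
gm <- as.matrix(g[, -1]); rownames(gm) <- g$sample_id
pq <- pqtl_scan(gm, a, meta)
write.table(as.data.frame(pq), "results/scans/pqtl_scan.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("pQTL scan: %d pairs tested; %d crossed the suggestive (5e-6) line, %d genome-wide (5e-8); min p = %.2g\n",
            nrow(pq), sum(pq$flag != ""), sum(pq$flag == "genomewide"),
            min(pq$p)))
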