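#!/usr/bin/env Rscript
# Stage 2: ingest the exported tables and run the pre-analytical chain --
# bridging normalization from the pooled controls, the >25% below-LOD
# exclusion rule, and 3-sd PCA outlier screening per cohort.

suppressPackageStartupMessages(library(npxcc))

a <- read_npx_long("results/data/npx_cohort_a.csv", "TZ")
b <- read_npx_long("results/data/npx_cohort_b.csv", "NL")
meta <- read_metadata("results/data/metadata.csv")

pp <- preprocess_pipeline(a, b)
print(pp$qc)

dir.create("results/qc", recursive = TRUE, showWarnings = FALSE)
write.table(pp$qc$lod_filter, "results/qc/lod_filter.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(pp$qc$bridge_offsets, "results/qc/bridge_offsets.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(rbind(pp$qc$outlier_samples_a, pp$qc$outlier_samples_b),
            "results/qc/outliers.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
write_npx_long(pp$a, "results/qc/npx_cohort_a_clean.csv")
write_npx_long(pp$b, "results/qc/npx_cohort_b_clean.csv")

off <- pp$qc$bridge_offsets
cat(sprintf("bridge offsets: median %.2f log2 (range %.2f..%.2f), defined for %d/%d proteins\n",
            median(off$offset, na.rm = TRUE), min(off$offset, na.rm = TRUE),
            max(off$offset, na.rm = TRUE), sum(off$defined), nrow(off)))
cat(sprintf("retained %d (A) and %d (B) proteins; excluded %d outlier samples in total\n",
            ncol(pp$a$values), ncol(pp$b$values),
            nrow(pp$qc$outlier_samples_a) + nrow(pp$qc$outlier_samples_b)))
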