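#!/usr/bin/env Rscript
# Stage 5: two-layer unsupervised clustering -- food-derived metabolome
# first (Ward/Euclidean), then the inflammatory proteome (k-means, 100
# restarts) -- and enrichment of annotations across the proteome clusters.

suppressPackageStartupMessages(library(npxcc))

seed <- as.integer(Sys.getenv("NPXCC_SEED", "1"))
a <- read_npx_long("results/qc/npx_cohort_a_clean.csv", "TZ")
meta <- read_metadata("results/data/metadata.csv")

mv <- read.csv("results/data/metabolites.csv", check.names = FALSE)
values <- as.matrix(mv[, -1]); rownames(values) <- mv$sample_id
ann <- read.csv("results/data/metabolite_annotation.csv")
metab <- metabolite_table(values, ann)
food <- select_food_metabolites(metab)

ids <- intersect(rownames(food$values), npx_samples(a, "study"))
mc <- cluster_metabolome(food$values[ids, , drop = FALSE])
pc <- cluster_proteome(npx_values(a, "study")[ids, , drop = FALSE],
                       seed = seed)
print(mc); print(pc)

sample_ann <- meta[match(ids, meta$sample_id),
                   c("sample_id", "age", "sex", "bmi", "season", "residency")]
sample_ann$metabolome_cluster <- as.character(mc$labels[ids])
enr <- cluster_enrichment(pc, sample_ann)

dir.create("results/clusters", recursive = TRUE, showWarnings = FALSE)
write.table(data.frame(sample_id = ids,
                       metabolome_cluster = unname(mc$labels[ids]),
                       proteome_cluster = unname(pc$labels[ids])),
            "results/clusters/assignments.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(as.data.frame(enr), "results/clusters/enrichment.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("annotation enrichment across proteome clusters:\n")
print(as.data.frame(enr)[, c("annotation", "test", "p", "fdr", "effect")])
hit <- enr[enr$annotation == "metabolome_cluster", ]
cat(sprintf("\nmetabolome-cluster x proteome-cluster association: %s p = %.3g (OR %.2f)\n",
            hit$test, hit$p, hit$effect))

if (requireNamespace("pheatmap", quietly = TRUE)) {
  z <- scale(npx_values(a, "study")[ids, , drop = FALSE])
  ord <- order(pc$labels[ids])
  dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)
  pheatmap::pheatmap(
    t(z[ord, ]), cluster_cols = FALSE, show_colnames = FALSE,
    annotation_col = data.frame(
      proteome = factor(pc$labels[ids][ord]),
      metabolome = factor(mc$labels[ids][ord]),
      row.names = ids[ord]),
    filename = "results/figures/proteome_clusters.png", width = 9, height = 7)
  cat("wrote results/figures/proteome_clusters.png\n")
}
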