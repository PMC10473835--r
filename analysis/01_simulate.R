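#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-cohort study and export it in the
# standard exchange formats (long NPX CSV per cohort, metadata CSV,
# metabolite matrix + annotation CSV, genotype CSV, ground-truth JSON).
# Everything downstream works from these files alone.

suppressPackageStartupMessages(library(npxcc))

seed <- as.integer(Sys.getenv("NPXCC_SEED", "1"))
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
sim <- simulate_cohorts(cfg)
sm <- simulate_metabolome(cfg, sim$a, sim$metadata, sim$truth)
gt <- simulate_genotypes(cfg, sim$metadata, npx = sm$npx)

write_npx_long(sm$npx, file.path(out, "npx_cohort_a.csv"))
write_npx_long(sim$b, file.path(out, "npx_cohort_b.csv"))
write.csv(sim$metadata, file.path(out, "metadata.csv"), row.names = FALSE)
write.csv(data.frame(sample_id = rownames(sm$metab$values),
                     sm$metab$values, check.names = FALSE),
          file.path(out, "metabolites.csv"), row.names = FALSE)
write.csv(sm$metab$annotation, file.path(out, "metabolite_annotation.csv"),
          row.names = FALSE)
write.csv(data.frame(sample_id = rownames(gt$genotypes), gt$genotypes),
          file.path(out, "genotypes.csv"), row.names = FALSE)
# named vectors are serialized as JSON objects so names survive round-trip
truth <- sm$truth
for (k in c("cohort_effects", "technical_offset", "sigma2", "baseline",
            "lod_quantile", "diet_cluster"))
  truth[[k]] <- as.list(truth[[k]])
jsonlite::write_json(truth, file.path(out, "truth.json"),
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("simulated %d + %d study samples, %d proteins, %d metabolites (%d food-derived), %d SNPs (seed %d)\n",
            cfg$n_a, cfg$n_b, cfg$n_proteins, ncol(sm$metab$values),
            sum(sm$metab$annotation$food_derived), cfg$n_snps, seed))
cat(sprintf("injected: %d up / %d down cohort effects (%.1f..%.1f log2), %d heavily censored proteins, %d + %d outliers\n",
            sum(sim$truth$cohort_effects > 0), sum(sim$truth$cohort_effects < 0),
            min(sim$truth$cohort_effects), max(sim$truth$cohort_effects),
            sum(cfg$lod_quantile > 0.25),
            length(sim$truth$outliers_a), length(sim$truth$outliers_b)))
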