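# Full-pipeline orchestration: config validation, staged execution,
# machine-readable run report.

.default_config <- function() {
  list(
    lod_max_frac = 0.25,
    lod_mode = "per_cohort",
    fdr_cut = 0.05,
    fc_cut = 0.5,
    outlier_sd = 3,
    outlier_components = 2,
    outlier_scale = TRUE,
    outlier_scope = "per_cohort",
    pqtl_genomewide = 5e-8,
    pqtl_suggestive = 5e-6,
    star_bins = c(0.05, 0.005, 0.0001),
    moderated = TRUE,
    covariates = c("age", "sex", "bmi"),
    cluster_k = 2,
    cluster_restarts = 100,
    seed = 1
  )
}

#' Validate and normalize a run configuration
#'
#' Accepts a partial configuration (a list, or the path of a YAML file),
#' injects defaults for every missing key, and checks ranges. Normalization
#' is idempotent: `validate_config(validate_config(cfg))` equals
#' `validate_config(cfg)`.
#'
#' @param cfg named list of overrides, or a YAML file path, or `NULL` for
#'   all defaults.
#' @return normalized configuration list of class `run_config`.
#' @export
validate_config <- function(cfg = NULL) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  if (is.null(cfg)) cfg <- list()
  stopifnot(is.list(cfg))
  unknown <- setdiff(names(cfg), names(.default_config()))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(.default_config(), cfg)
  chk <- function(key, lo, hi) {
    v <- out[[key]]
    if (!is.numeric(v) || any(v <= lo | v >= hi))
      stop(sprintf("config '%s' out of range: must lie in (%g, %g)", key, lo, hi))
  }
  chk("lod_max_frac", 0, 1)
  chk("fdr_cut", 0, 1)
  chk("pqtl_genomewide", 0, 1)
  chk("pqtl_suggestive", 0, 1)
  if (out$outlier_sd <= 0) stop("config 'outlier_sd' out of range: must be > 0")
  if (!out$lod_mode %in% c("per_cohort", "both", "either"))
    stop("config 'lod_mode' must be per_cohort, both or either")
  if (length(out$star_bins) != 3 || any(diff(out$star_bins) >= 0))
    stop("config 'star_bins' must be 3 strictly decreasing bounds")
  out$seed <- as.integer(out$seed)
  class(out) <- c("run_config", "list")
  out
}

#' Run the full cross-cohort analysis
#'
#' Executes the stages in fixed order: preprocessing (bridging, LOD filter,
#' outlier removal), cross-cohort differential expression, host-factor
#' scans, two-layer clustering with annotation enrichment (when a metabolome
#' is supplied), the metabolite-protein scan, and the SNP-protein scan (when
#' genotypes are supplied). Returns a run report whose counts are internally
#' consistent (samples in = samples out + excluded, likewise proteins) and
#' fully reproducible from inputs + config.
#'
#' @param a,b `npx_matrix` cohort objects (A receives the bridge offsets).
#' @param meta metadata data.frame covering both cohorts.
#' @param metab optional `metabolite_table` over cohort-A samples.
#' @param genotypes optional dosage matrix over cohort-A samples.
#' @param config configuration accepted by [validate_config()].
#' @param out_dir optional directory; when given, result tables are written
#'   as TSV and the report as JSON.
#' @return list of class `run_report`: `config`, `qc` (QC report), `de`
#'   (`de_result`), `de_counts`, `factor_scans` (list per factor),
#'   `clusters` (`metabolome`, `proteome`, `enrichment`), `metab_scan`,
#'   `pqtl`, `stage_counts`.
#' @export
run_full <- function(a, b, meta, metab = NULL, genotypes = NULL,
                     config = NULL, out_dir = NULL) {
  cfg <- validate_config(config)

  pp <- preprocess_pipeline(a, b, config = cfg)
  clean_a <- pp$a; clean_b <- pp$b

  de <- run_de(clean_a, clean_b, meta, covariates = cfg$covariates,
               moderated = cfg$moderated, fdr_cut = cfg$fdr_cut,
               fc_cut = cfg$fc_cut)

  scan_factors <- c("age", "sex", "bmi", "season", "residency")
  factor_scans <- list()
  for (co in list(clean_a, clean_b)) {
    meta_co <- meta[meta$sample_id %in% npx_samples(co, "study"), , drop = FALSE]
    for (f in scan_factors) {
      if (!f %in% names(meta_co)) next
      vals <- meta_co[[f]][!is.na(meta_co[[f]])]
      if (length(unique(vals)) < 2) next
      key <- paste(co$cohort, f, sep = ".")
      factor_scans[[key]] <- factor_scan(co, meta_co, f, cohort = co$cohort)
    }
  }

  clusters <- NULL
  if (!is.null(metab)) {
    food <- select_food_metabolites(metab)
    shared <- intersect(rownames(food$values), npx_samples(clean_a, "study"))
    mc <- cluster_metabolome(food$values[shared, , drop = FALSE],
                             k = cfg$cluster_k)
    pc <- cluster_proteome(npx_values(clean_a, "study")[shared, , drop = FALSE],
                           k = cfg$cluster_k,
                           restarts = cfg$cluster_restarts, seed = cfg$seed)
    ann <- meta[match(shared, meta$sample_id),
                intersect(c("sample_id", "age", "sex", "bmi", "season",
                            "residency"), names(meta)), drop = FALSE]
    ann$metabolome_cluster <- as.character(mc$labels[shared])
    enr <- cluster_enrichment(pc, ann)
    clusters <- list(metabolome = mc, proteome = pc, enrichment = enr)
  }

  mp <- NULL
  if (!is.null(metab)) {
    food <- select_food_metabolites(metab)
    mp <- metabolite_protein_scan(food, clean_a, meta)
  }

  pq <- NULL
  if (!is.null(genotypes))
    pq <- pqtl_scan(genotypes, clean_a, meta,
                    genomewide = cfg$pqtl_genomewide,
                    suggestive = cfg$pqtl_suggestive)

  r <- pp$qc$retained
  stage_counts <- list(
    samples_in = c(a = r$samples_in_a, b = r$samples_in_b),
    samples_out = c(a = r$samples_a, b = r$samples_b),
    samples_excluded = c(a = r$samples_excluded_a, b = r$samples_excluded_b),
    proteins_in = r$proteins_in,
    proteins_out = c(a = r$proteins_a, b = r$proteins_b),
    proteins_excluded = c(a = r$proteins_excluded_a, b = r$proteins_excluded_b)
  )

  report <- structure(list(
    config = cfg, qc = pp$qc, de = de, de_counts = attr(de, "counts"),
    factor_scans = factor_scans, clusters = clusters, metab_scan = mp,
    pqtl = pq, stage_counts = stage_counts, a = clean_a, b = clean_b
  ), class = "run_report")

  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  print(x$qc)
  cnt <- x$de_counts
  cat(sprintf("  DE: %d up / %d down / %d ns at FDR < %g\n",
              cnt["up"], cnt["down"], cnt["ns"], x$config$fdr_cut))
  if (!is.null(x$clusters))
    cat(sprintf("  clusters: metabolome %s | proteome %s\n",
                paste(tabulate(x$clusters$metabolome$labels, 2), collapse = "/"),
                paste(tabulate(x$clusters$proteome$labels, 2), collapse = "/")))
  invisible(x)
}

#' Write a run report's tables and JSON summary to a directory
#'
#' Emits TSVs for the DE table, the factor scans, the QC exclusion tables,
#' the metabolite-protein scan and the pQTL scan, plus a `report.json` with
#' stage counts, DE counts and the normalized config. Deterministic:
#' identical reports serialize to identical bytes.
#'
#' @param report a `run_report`.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  wt(as.data.frame(report$de), "de_result.tsv")
  wt(report$qc$lod_filter, "lod_filter.tsv")
  wt(report$qc$bridge_offsets, "bridge_offsets.tsv")
  if (nrow(report$qc$outlier_samples_a))
    wt(report$qc$outlier_samples_a, "outliers_a.tsv")
  if (nrow(report$qc$outlier_samples_b))
    wt(report$qc$outlier_samples_b, "outliers_b.tsv")
  if (length(report$factor_scans))
    wt(do.call(rbind, lapply(report$factor_scans, as.data.frame)),
       "factor_scans.tsv")
  if (!is.null(report$metab_scan))
    wt(as.data.frame(report$metab_scan), "metabolite_protein_scan.tsv")
  if (!is.null(report$pqtl)) wt(as.data.frame(report$pqtl), "pqtl_scan.tsv")
  if (!is.null(report$clusters)) {
    cl <- data.frame(
      sample_id = names(report$clusters$proteome$labels),
      proteome_cluster = unname(report$clusters$proteome$labels),
      stringsAsFactors = FALSE)
    mcl <- report$clusters$metabolome$labels
    cl$metabolome_cluster <- unname(mcl[cl$sample_id])
    wt(cl, "cluster_assignments.tsv")
    wt(as.data.frame(report$clusters$enrichment), "cluster_enrichment.tsv")
  }
  summary <- list(
    config = unclass(report$config),
    stage_counts = report$stage_counts,
    de_counts = as.list(report$de_counts),
    moderation = unclass(attr(report$de, "moderation"))
  )
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
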