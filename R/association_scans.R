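# Factor-by-protein regression scans and the matrix-style SNP-protein scan.

#' Significance stars for FDR-adjusted p-values
#'
#' Binning used throughout the heatmap outputs: `***` below 0.0001, `**`
#' below 0.005, `*` below 0.05 (all strict), blank otherwise.
#'
#' @param fdr numeric vector of adjusted p-values in (0, 1].
#' @param bins numeric length-3 vector of (strict) upper bounds for
#'   one, two and three stars.
#' @return character vector of star labels.
#' @export
fdr_stars <- function(fdr, bins = c(0.05, 0.005, 0.0001)) {
  stopifnot(length(bins) == 3, all(diff(bins) < 0))
  out <- character(length(fdr))
  out[fdr < bins[1]] <- "*"
  out[fdr < bins[2]] <- "**"
  out[fdr < bins[3]] <- "***"
  out[is.na(fdr)] <- NA_character_
  out
}

#' Scan one host/environment factor against every analyte
#'
#' Per analyte (protein or absolute-concentration marker), ordinary least
#' squares of the analyte on the factor plus covariates; the factor's
#' coefficient, its p-value and the BH FDR across analytes (the family is
#' the factor-by-cohort scan) are reported. The factor may be numeric or a
#' two-level categorical (coded 0/1 against its reference level). With
#' `standardized = TRUE` the analyte (and a numeric factor) are scaled to
#' unit variance, so the coefficient is scale-free.
#'
#' @param m analyte matrix (samples x analytes) or `npx_matrix`.
#' @param meta metadata data.frame with `sample_id`, the factor and the
#'   covariates.
#' @param factor_name metadata column to scan.
#' @param covariates metadata columns to adjust for (default: the other two
#'   of age/sex/bmi that are present and differ from the factor).
#' @param standardized logical; report standardized coefficients.
#' @param cohort optional cohort label stored on the result.
#' @return data.frame of class `factor_scan`: `factor`, `protein`, `beta`,
#'   `se`, `p`, `fdr`, `stars`, `n_used`, `cohort`.
#' @export
factor_scan <- function(m, meta, factor_name, covariates = NULL,
                        standardized = FALSE, cohort = NA_character_) {
  if (inherits(m, "npx_matrix")) {
    if (is.na(cohort)) cohort <- m$cohort
    m <- npx_values(m, "study")
  }
  stopifnot(is.matrix(m))
  if (!factor_name %in% names(meta)) stop("factor not in metadata: ", factor_name)
  if (is.null(covariates))
    covariates <- setdiff(intersect(c("age", "sex", "bmi"), names(meta)),
                          factor_name)
  if (factor_name %in% covariates)
    stop("factor may not appear among its own covariates")
  mm <- meta[match(rownames(m), meta$sample_id), , drop = FALSE]
  f <- mm[[factor_name]]
  if (is.character(f) || is.factor(f)) {
    f <- as.character(f)
    levs <- sort(unique(f[!is.na(f)]))
    if (factor_name == "sex") levs <- intersect(c("male", "female"), levs)
    if (factor_name == "season") levs <- intersect(c("dry", "rainy"), levs)
    if (length(levs) < 2) stop("no variance: factor '", factor_name,
                               "' is constant")
    if (length(levs) > 2)
      stop("factor '", factor_name,
           "' has >2 levels; recode to a binary contrast first")
    f <- as.numeric(f == levs[2])
  }
  if (length(unique(f[!is.na(f)])) < 2)
    stop("no variance: factor '", factor_name, "' is constant")
  if (standardized && stats::sd(f, na.rm = TRUE) > 0 &&
      length(unique(f[!is.na(f)])) > 2)
    f <- as.numeric(scale(f))
  df <- data.frame(.factor = f, mm[, covariates, drop = FALSE])
  design <- build_design(df, contrast = ".factor")
  keep <- stats::complete.cases(design)
  ym <- m[keep, , drop = FALSE]
  if (standardized) {
    sds <- apply(ym, 2, stats::sd, na.rm = TRUE)
    sds[sds == 0] <- 1
    ym <- sweep(ym, 2, sds, "/")
  }
  fits <- fit_linear_models(ym, design[keep, , drop = FALSE])
  tab <- moderate(fits, list(d0 = 0, s0_sq = 1), coef = ".factor")
  fdr <- bh_fdr(tab$p)
  out <- data.frame(factor = factor_name, protein = tab$protein,
                    beta = tab$beta, se = tab$se, p = tab$p, fdr = fdr,
                    stars = fdr_stars(fdr), n_used = fits$n_used[tab$protein],
                    cohort = cohort, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("factor_scan", "data.frame")
  out
}

#' Matrix-style pQTL scan: SNP dosages against protein levels
#'
#' Per (SNP, protein) pair, an additive-dosage linear model of the protein
#' on the SNP dosage plus covariates. P-values are reported unadjusted; each
#' pair is flagged when it crosses the genome-wide (5e-8) or suggestive
#' (5e-6) threshold. Monomorphic SNPs (zero dosage variance in the analysed
#' samples) are skipped with a reason.
#'
#' @param g genotype dosage matrix (samples x SNPs, values in `[0, 2]`).
#' @param m `npx_matrix` or protein matrix.
#' @param meta metadata with `sample_id` and the covariates.
#' @param covariates metadata columns to adjust for (default age + sex).
#' @param genomewide,suggestive significance thresholds for flagging.
#' @return data.frame of class `pqtl_scan`: `snp`, `protein`, `beta`, `se`,
#'   `p`, `n_used`, `flag` (`""`, `"suggestive"`, `"genomewide"`);
#'   attribute `skipped_snps`.
#' @export
pqtl_scan <- function(g, m, meta, covariates = c("age", "sex"),
                      genomewide = 5e-8, suggestive = 5e-6) {
  if (inherits(m, "npx_matrix")) m <- npx_values(m, "study")
  stopifnot(is.matrix(g) || is.data.frame(g))
  g <- as.matrix(g)
  if (any(g < 0 | g > 2, na.rm = TRUE)) stop("dosages must lie in [0, 2]")
  shared <- intersect(rownames(g), rownames(m))
  if (length(shared) < 30)
    stop("need at least 30 overlapping samples (have ", length(shared), ")")
  g <- g[shared, , drop = FALSE]
  m <- m[shared, , drop = FALSE]
  mm <- meta[match(shared, meta$sample_id), , drop = FALSE]

  skipped <- character(0)
  res <- list()
  for (s in colnames(g)) {
    dose <- g[, s]
    if (stats::sd(dose, na.rm = TRUE) == 0) {
      skipped <- c(skipped, s)
      next
    }
    df <- data.frame(.dose = dose, mm[, covariates, drop = FALSE])
    design <- build_design(df, contrast = ".dose")
    keep <- stats::complete.cases(design)
    fits <- fit_linear_models(m[keep, , drop = FALSE],
                              design[keep, , drop = FALSE])
    tab <- moderate(fits, list(d0 = 0, s0_sq = 1), coef = ".dose")
    res[[s]] <- data.frame(snp = s, protein = tab$protein, beta = tab$beta,
                           se = tab$se, p = tab$p,
                           n_used = unname(fits$n_used[tab$protein]),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(snp = character(0), protein = character(0),
                      beta = numeric(0), se = numeric(0), p = numeric(0),
                      n_used = integer(0), stringsAsFactors = FALSE)
  out$flag <- ifelse(out$p < genomewide, "genomewide",
                     ifelse(out$p < suggestive, "suggestive", ""))
  rownames(out) <- NULL
  attr(out, "skipped_snps") <- data.frame(
    snp = skipped, reason = rep("monomorphic", length(skipped)),
    stringsAsFactors = FALSE)
  class(out) <- c("pqtl_scan", "data.frame")
  out
}
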