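# Metabolite-by-protein multiple-regression association matrix, restricted
# to food-derived metabolites, with chemical-class summaries.

#' Construct a metabolite table
#'
#' Pairs a samples x metabolites log-intensity matrix with its per-metabolite
#' annotation (chemical formula, putative name, chemical class, and the
#' food-derived flag, which is consumed as input — ontology curation is
#' upstream of this package).
#'
#' @param values numeric matrix, samples x metabolites (log-transformed
#'   intensities); finite or `NA`.
#' @param annotation data.frame with columns `metabolite`, `formula`,
#'   `putative_name`, `chem_class`, `food_derived` (logical), one row per
#'   matrix column.
#' @return object of class `metabolite_table`.
#' @export
metabolite_table <- function(values, annotation) {
  stopifnot(is.matrix(values), is.data.frame(annotation))
  req <- c("metabolite", "formula", "putative_name", "chem_class", "food_derived")
  missing <- setdiff(req, names(annotation))
  if (length(missing))
    stop("annotation missing column(s): ", paste(missing, collapse = ", "))
  if (!setequal(colnames(values), annotation$metabolite))
    stop("annotation rows must match value columns")
  annotation <- annotation[match(colnames(values), annotation$metabolite), ]
  if (any(is.na(annotation$food_derived)))
    stop("food_derived flag must be present for every metabolite")
  structure(list(values = values, annotation = annotation),
            class = "metabolite_table")
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat(sprintf("<metabolite_table> %d samples x %d metabolites (%d food-derived)\n",
              nrow(x$values), ncol(x$values), sum(x$annotation$food_derived)))
  invisible(x)
}

#' Restrict a metabolite table to food-derived metabolites
#'
#' @param t a `metabolite_table` with the `food_derived` flag populated.
#' @return the food-derived subset, same class; errors when none is flagged.
#' @export
select_food_metabolites <- function(t) {
  stopifnot(inherits(t, "metabolite_table"))
  keep <- t$annotation$metabolite[t$annotation$food_derived]
  if (length(keep) == 0) stop("no metabolites carry the food-derived flag")
  message(length(keep), " of ", ncol(t$values),
          " metabolites flagged food-derived")
  metabolite_table(t$values[, keep, drop = FALSE],
                   t$annotation[t$annotation$food_derived, , drop = FALSE])
}

#' Metabolite-protein association matrix
#'
#' For every (metabolite, protein) pair, a multiple linear regression of the
#' protein on the metabolite with age and sex as covariates (by default).
#' Both analyte and metabolite are standardized to unit variance, so the
#' coefficient is a standardized beta, invariant to measurement scale. FDR
#' is adjusted across the full pair matrix by default (`fdr_family =
#' "per_protein"` adjusts within each protein instead). Zero-variance
#' metabolites are skipped with a reason.
#'
#' Computation uses the Frisch-Waugh decomposition: covariates are
#' residualized out of proteins and metabolites once, and each pair's OLS
#' slope, standard error and t-test are recovered exactly from the residual
#' cross-products (per-pair complete-case refits handle missing values).
#'
#' @param metab a `metabolite_table` (typically after
#'   [select_food_metabolites()]).
#' @param npx `npx_matrix` or protein matrix.
#' @param meta metadata with `sample_id` and the covariates.
#' @param covariates metadata columns to adjust for (default age + sex).
#' @param fdr_family `"matrix"` (default) or `"per_protein"`.
#' @return data.frame of class `metab_scan`: `metabolite`, `formula`,
#'   `chem_class`, `protein`, `beta`, `se`, `p`, `fdr`, `stars`, `n_used`;
#'   attribute `skipped_metabolites`.
#' @export
metabolite_protein_scan <- function(metab, npx, meta,
                                    covariates = c("age", "sex"),
                                    fdr_family = c("matrix", "per_protein")) {
  fdr_family <- match.arg(fdr_family)
  stopifnot(inherits(metab, "metabolite_table"))
  if (inherits(npx, "npx_matrix")) npx <- npx_values(npx, "study")
  shared <- intersect(rownames(metab$values), rownames(npx))
  if (length(shared) < 50)
    stop("need at least 50 overlapping samples (have ", length(shared), ")")
  X <- metab$values[shared, , drop = FALSE]
  Y <- npx[shared, , drop = FALSE]
  mm <- meta[match(shared, meta$sample_id), , drop = FALSE]
  Z <- build_design(data.frame(mm[, covariates, drop = FALSE]),
                    contrast = covariates[1])
  keep <- stats::complete.cases(Z)
  X <- X[keep, , drop = FALSE]; Y <- Y[keep, , drop = FALSE]
  Z <- Z[keep, , drop = FALSE]

  sdx <- apply(X, 2, stats::sd, na.rm = TRUE)
  skipped <- colnames(X)[sdx == 0 | !is.finite(sdx)]
  usable <- setdiff(colnames(X), skipped)
  X <- X[, usable, drop = FALSE]
  X <- sweep(X, 2, sdx[usable], "/")
  sdy <- apply(Y, 2, stats::sd, na.rm = TRUE)
  sdy[sdy == 0] <- 1
  Y <- sweep(Y, 2, sdy, "/")

  n <- nrow(Z)
  pz <- ncol(Z)
  df <- n - pz - 1
  if (df < 1) stop("insufficient residual degrees of freedom")

  if (!anyNA(X) && !anyNA(Y)) {
    qz <- qr(Z)
    Xr <- qr.resid(qz, X)
    Yr <- qr.resid(qz, Y)
    xx <- colSums(Xr^2)
    cross <- crossprod(Xr, Yr)           # metabolites x proteins
    beta <- cross / xx
    yy <- colSums(Yr^2)
    rss <- sweep(-beta * cross, 2, yy, "+")
    rss[rss < 0] <- 0
    sigma2 <- rss / df
    se <- sqrt(sigma2 / xx)
    tt <- beta / se
    p <- 2 * stats::pt(-abs(tt), df = df)
    long <- data.frame(
      metabolite = rep(rownames(beta), times = ncol(beta)),
      protein = rep(colnames(beta), each = nrow(beta)),
      beta = as.vector(beta), se = as.vector(se), p = as.vector(p),
      n_used = n, stringsAsFactors = FALSE)
  } else {
    rows <- vector("list", length(usable) * ncol(Y))
    idx <- 1L
    for (mcol in usable) for (pcol in colnames(Y)) {
      ok <- !is.na(X[, mcol]) & !is.na(Y[, pcol])
      nn <- sum(ok)
      dfp <- nn - pz - 1
      if (dfp < 1) next
      f <- stats::lm.fit(cbind(Z[ok, , drop = FALSE], X[ok, mcol]), Y[ok, pcol])
      b <- f$coefficients[pz + 1]
      R <- qr.R(f$qr)
      sedf <- sqrt(diag(chol2inv(R)) * sum(f$residuals^2) / dfp)
      pv <- 2 * stats::pt(-abs(b / sedf[pz + 1]), df = dfp)
      rows[[idx]] <- data.frame(metabolite = mcol, protein = pcol,
                                beta = unname(b), se = unname(sedf[pz + 1]),
                                p = unname(pv), n_used = nn,
                                stringsAsFactors = FALSE)
      idx <- idx + 1L
    }
    long <- do.call(rbind, rows)
  }

  if (fdr_family == "matrix") {
    long$fdr <- bh_fdr(long$p)
  } else {
    long$fdr <- NA_real_
    for (pcol in unique(long$protein)) {
      sel <- long$protein == pcol
      long$fdr[sel] <- bh_fdr(long$p[sel])
    }
  }
  long$stars <- fdr_stars(long$fdr)
  ann <- metab$annotation[match(long$metabolite, metab$annotation$metabolite), ]
  long$formula <- ann$formula
  long$chem_class <- ann$chem_class
  long <- long[, c("metabolite", "formula", "chem_class", "protein",
                   "beta", "se", "p", "fdr", "stars", "n_used")]
  rownames(long) <- NULL
  attr(long, "skipped_metabolites") <- data.frame(
    metabolite = skipped, reason = rep("zero variance", length(skipped)),
    stringsAsFactors = FALSE)
  attr(long, "fdr_family") <- fdr_family
  class(long) <- c("metab_scan", "data.frame")
  long
}

#' Chemical-class summary of a metabolite-protein scan
#'
#' Aggregates the scan by chemical class: median standardized beta and the
#' fraction of pairs passing the FDR gate. Purely descriptive; no new
#' inference is performed.
#'
#' @param scan a `metab_scan` result.
#' @param fdr_cut FDR gate for the significant-pair fraction (default 0.05).
#' @return data.frame: `chem_class`, `n_pairs`, `median_beta`,
#'   `frac_significant`.
#' @export
class_summary <- function(scan, fdr_cut = 0.05) {
  stopifnot(inherits(scan, "metab_scan"))
  sp <- split(scan, scan$chem_class)
  out <- do.call(rbind, lapply(names(sp), function(cls) {
    s <- sp[[cls]]
    data.frame(chem_class = cls, n_pairs = nrow(s),
               median_beta = stats::median(s$beta),
               frac_significant = mean(s$fdr < fdr_cut),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
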