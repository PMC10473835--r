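# Pre-analytical chain: bridging normalization from pooled plasma controls,
# below-LOD exclusion rules, PCA-based sample outlier screening.

#' Per-protein bridging offsets from pooled plasma controls
#'
#' Both cohorts measure aliquots of the same pooled plasma on every plate
#' (the bridge samples). For each protein the offset X is the difference of
#' the bridge-sample medians, cohort A minus cohort B; subtracting X from
#' cohort A removes the between-cohort technical shift while leaving
#' biological contrasts untouched. The median uses the usual midpoint
#' convention for even counts (relevant with 8 bridge samples per cohort).
#'
#' @param a,b `npx_matrix` objects, each containing bridge samples.
#' @return object of class `bridge_offsets`: a data.frame with columns
#'   `protein`, `offset` (log2 units), `n_bridge_a`, `n_bridge_b`, `defined`.
#'   Proteins with fewer than 2 bridge values in either cohort get an
#'   undefined (`NA`) offset and `defined = FALSE`.
#' @export
compute_bridge_offsets <- function(a, b) {
  stopifnot(inherits(a, "npx_matrix"), inherits(b, "npx_matrix"))
  proteins <- sort(intersect(colnames(a$values), colnames(b$values)))
  if (length(proteins) == 0) stop("no shared proteins")
  ba <- npx_values(a, "bridge")[, proteins, drop = FALSE]
  bb <- npx_values(b, "bridge")[, proteins, drop = FALSE]
  na <- colSums(!is.na(ba))
  nb <- colSums(!is.na(bb))
  med_a <- apply(ba, 2, stats::median, na.rm = TRUE)
  med_b <- apply(bb, 2, stats::median, na.rm = TRUE)
  defined <- na >= 2 & nb >= 2
  offset <- ifelse(defined, med_a - med_b, NA_real_)
  out <- data.frame(protein = proteins, offset = unname(offset),
                    n_bridge_a = unname(na), n_bridge_b = unname(nb),
                    defined = unname(defined), stringsAsFactors = FALSE)
  class(out) <- c("bridge_offsets", "data.frame")
  out
}

#' Subtract bridging offsets from a cohort
#'
#' Applies the per-protein offset X to every value of the cohort (study and
#' bridge samples alike) and shifts the LOD by the same amount, so that
#' below-LOD status is invariant under bridging. Proteins without a defined
#' offset pass through unadjusted with a warning.
#'
#' @param a the offset-receiving `npx_matrix`.
#' @param offsets a `bridge_offsets` object from [compute_bridge_offsets()].
#' @return the adjusted `npx_matrix`.
#' @export
apply_bridge <- function(a, offsets) {
  stopifnot(inherits(a, "npx_matrix"), inherits(offsets, "bridge_offsets"))
  proteins <- colnames(a$values)
  x <- stats::setNames(offsets$offset, offsets$protein)[proteins]
  undef <- is.na(x)
  if (any(undef)) {
    warning(sum(undef), " protein(s) without defined bridge offset passed through unadjusted: ",
            paste(utils::head(proteins[undef], 5), collapse = ", "))
    x[undef] <- 0
  }
  a$values <- sweep(a$values, 2, x, "-")
  a$lod <- a$lod - x
  a
}

#' Fraction of study samples below the limit of detection, per protein
#'
#' Values below the LOD are retained as measured (never imputed); this
#' function only counts them. A value exactly equal to the LOD counts as
#' detected (strict `<`). Bridge samples are excluded from the denominator.
#'
#' @param m an `npx_matrix`
#' @return named numeric vector of fractions in `[0, 1]` per protein
#' @export
below_lod_fraction <- function(m) {
  stopifnot(inherits(m, "npx_matrix"))
  v <- npx_values(m, "study")
  below <- sweep(v, 2, m$lod, "<")
  colMeans(below, na.rm = TRUE)
}

#' Exclude proteins by below-LOD fraction
#'
#' A protein is excluded when its below-LOD fraction exceeds the threshold
#' (strictly more than, default 25%). Three rules are supported:
#' `both` excludes a protein from both cohorts only when its fraction exceeds
#' the threshold in both; `either` when it exceeds it in at least one;
#' `per_cohort` excludes independently per cohort, which can leave the two
#' cohorts with different retained panels.
#'
#' @param frac_a,frac_b named fractions per protein (see
#'   [below_lod_fraction()]); must cover the same protein universe.
#' @param threshold exclusion threshold in (0, 1), default 0.25.
#' @param mode `"per_cohort"` (default), `"both"` or `"either"`.
#' @return data.frame (`lod_filter_report`) with columns `protein`, `frac_a`,
#'   `frac_b`, `excluded_a`, `excluded_b`, `reason`.
#' @export
lod_filter <- function(frac_a, frac_b, threshold = 0.25,
                       mode = c("per_cohort", "both", "either")) {
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  proteins <- sort(union(names(frac_a), names(frac_b)))
  if (!setequal(names(frac_a), names(frac_b)))
    stop("frac_a and frac_b must cover the same protein universe")
  fa <- frac_a[proteins]; fb <- frac_b[proteins]
  over_a <- fa > threshold
  over_b <- fb > threshold
  if (mode == "both") {
    ex_a <- ex_b <- over_a & over_b
  } else if (mode == "either") {
    ex_a <- ex_b <- over_a | over_b
  } else {
    ex_a <- over_a; ex_b <- over_b
  }
  reason <- ifelse(ex_a | ex_b,
                   sprintf("below-LOD fraction > %g (mode=%s): A=%.3f, B=%.3f",
                           threshold, mode, fa, fb), "")
  out <- data.frame(protein = proteins, frac_a = unname(fa), frac_b = unname(fb),
                    excluded_a = unname(ex_a), excluded_b = unname(ex_b),
                    reason = reason, stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "mode") <- mode
  class(out) <- c("lod_filter_report", "data.frame")
  out
}

#' Principal-component scores for sample screening and ordination
#'
#' Thin wrapper around the singular value decomposition (via
#' [stats::prcomp()]) with a fixed sign convention: each component is flipped
#' if necessary so its largest-magnitude loading is positive, making scores
#' reproducible across platforms. Zero-variance features are dropped with a
#' warning when unit-variance scaling is requested; missing cells are filled
#' with the feature mean (recorded in the result).
#'
#' @param m numeric matrix, samples x features.
#' @param center,scale logical; centre and unit-variance scale features
#'   (both default `TRUE`).
#' @return list of class `pc_scores`: `scores` (samples x components),
#'   `explained_variance` (fractions, non-increasing), `rotation`, `center`,
#'   `scale`, `n_mean_filled`, `dropped_features`.
#' @export
pca_scores <- function(m, center = TRUE, scale = TRUE) {
  stopifnot(is.matrix(m), nrow(m) >= 3, ncol(m) >= 2)
  n_filled <- 0L
  if (anyNA(m)) {
    mu <- colMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- mu[idx[, 2]]
    n_filled <- nrow(idx)
  }
  dropped <- character(0)
  if (scale) {
    sds <- apply(m, 2, stats::sd)
    zv <- sds == 0 | !is.finite(sds)
    if (any(zv)) {
      warning(sum(zv), " zero-variance feature(s) dropped before scaled PCA")
      dropped <- colnames(m)[zv]
      m <- m[, !zv, drop = FALSE]
    }
  }
  p <- stats::prcomp(m, center = center, scale. = scale)
  # sign convention: largest-magnitude loading of each PC is positive
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  p$rotation <- sweep(p$rotation, 2, flip, "*")
  p$x <- sweep(p$x, 2, flip, "*")
  ev <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = p$x, explained_variance = ev,
                 rotation = p$rotation, center = center, scale = scale,
                 n_mean_filled = n_filled, dropped_features = dropped),
            class = "pc_scores")
}

#' Flag multivariate outlier samples on leading principal components
#'
#' A sample is flagged when its score on any of the first `components`
#' principal components lies more than `k_sd` standard deviations from that
#' component's mean (single pass; the rule is not re-applied after removal).
#' A component with zero score variance contributes no flags.
#'
#' @param scores a `pc_scores` object.
#' @param k_sd flag threshold in standard deviations (default 3).
#' @param components number of leading components screened (default 2).
#' @return data.frame of flagged samples: `sample_id`, `pc<i>_score` and
#'   `z<i>` columns for each screened component.
#' @export
flag_outliers <- function(scores, k_sd = 3, components = 2) {
  stopifnot(inherits(scores, "pc_scores"))
  components <- min(components, ncol(scores$scores))
  s <- scores$scores[, seq_len(components), drop = FALSE]
  mu <- colMeans(s)
  sd <- apply(s, 2, stats::sd)
  z <- sweep(sweep(s, 2, mu, "-"), 2, ifelse(sd > 0, sd, Inf), "/")
  flagged <- rowSums(abs(z) > k_sd) > 0
  out <- data.frame(sample_id = rownames(s)[flagged], stringsAsFactors = FALSE)
  for (i in seq_len(components)) {
    out[[sprintf("pc%d_score", i)]] <- s[flagged, i]
    out[[sprintf("z%d", i)]] <- z[flagged, i]
  }
  rownames(out) <- NULL
  out
}

#' Run the full pre-analytical chain on a cohort pair
#'
#' Ordered stages: (1) bridging normalization — offsets estimated from the
#' pooled-control bridge samples and subtracted from cohort A; (2) below-LOD
#' protein exclusion; (3) PCA outlier screening of study samples, run per
#' cohort by default (`outlier_scope = "combined"` screens the pooled
#' matrix). Every exclusion decision is recorded in the returned QC report.
#'
#' @param a,b `npx_matrix` objects (cohort A receives the bridge offsets).
#' @param config optional list overriding thresholds: `lod_max_frac` (0.25),
#'   `lod_mode` ("per_cohort"), `outlier_sd` (3), `outlier_components` (2),
#'   `outlier_scale` (TRUE), `outlier_scope` ("per_cohort").
#' @return list with the cleaned matrices `a` and `b` (excluded proteins and
#'   flagged samples removed) and `qc`, a `qc_report` list carrying the
#'   bridge offsets, below-LOD fractions, the LOD filter table, flagged
#'   outliers per cohort, and retained counts.
#' @export
preprocess_pipeline <- function(a, b, config = list()) {
  cfg <- utils::modifyList(list(lod_max_frac = 0.25, lod_mode = "per_cohort",
                                outlier_sd = 3, outlier_components = 2,
                                outlier_scale = TRUE,
                                outlier_scope = "per_cohort"), config)
  n_in_a <- length(npx_samples(a, "study"))
  n_in_b <- length(npx_samples(b, "study"))

  offsets <- compute_bridge_offsets(a, b)
  common <- sort(intersect(colnames(a$values), colnames(b$values)))
  a <- npx_subset(a, proteins = common)
  b <- npx_subset(b, proteins = common)
  a <- apply_bridge(a, offsets)

  frac_a <- below_lod_fraction(a)
  frac_b <- below_lod_fraction(b)
  lf <- lod_filter(frac_a, frac_b, threshold = cfg$lod_max_frac,
                   mode = cfg$lod_mode)
  keep_a <- lf$protein[!lf$excluded_a]
  keep_b <- lf$protein[!lf$excluded_b]
  a <- npx_subset(a, proteins = intersect(colnames(a$values), keep_a))
  b <- npx_subset(b, proteins = intersect(colnames(b$values), keep_b))

  screen <- function(x) {
    v <- npx_values(x, "study")
    sc <- pca_scores(v, center = TRUE, scale = cfg$outlier_scale)
    flag_outliers(sc, k_sd = cfg$outlier_sd,
                  components = cfg$outlier_components)
  }
  if (identical(cfg$outlier_scope, "combined")) {
    shared <- sort(intersect(colnames(a$values), colnames(b$values)))
    v <- rbind(npx_values(a, "study")[, shared, drop = FALSE],
               npx_values(b, "study")[, shared, drop = FALSE])
    fl <- flag_outliers(pca_scores(v, center = TRUE, scale = cfg$outlier_scale),
                        k_sd = cfg$outlier_sd,
                        components = cfg$outlier_components)
    out_a <- fl[fl$sample_id %in% rownames(a$values), , drop = FALSE]
    out_b <- fl[fl$sample_id %in% rownames(b$values), , drop = FALSE]
  } else {
    out_a <- screen(a)
    out_b <- screen(b)
  }
  a <- npx_subset(a, samples = setdiff(rownames(a$values), out_a$sample_id))
  b <- npx_subset(b, samples = setdiff(rownames(b$values), out_b$sample_id))

  qc <- structure(list(
    bridge_offsets = offsets,
    below_lod_fraction = data.frame(protein = lf$protein, frac_a = lf$frac_a,
                                    frac_b = lf$frac_b),
    lod_filter = lf,
    excluded_proteins = lf[lf$excluded_a | lf$excluded_b, , drop = FALSE],
    outlier_samples_a = out_a,
    outlier_samples_b = out_b,
    retained = list(
      samples_a = length(npx_samples(a, "study")),
      samples_b = length(npx_samples(b, "study")),
      samples_excluded_a = nrow(out_a),
      samples_excluded_b = nrow(out_b),
      samples_in_a = n_in_a, samples_in_b = n_in_b,
      proteins_a = ncol(a$values), proteins_b = ncol(b$values),
      proteins_in = length(common),
      proteins_excluded_a = sum(lf$excluded_a),
      proteins_excluded_b = sum(lf$excluded_b)
    ),
    config = cfg
  ), class = "qc_report")
  list(a = a, b = b, qc = qc)
}

#' @export
print.qc_report <- function(x, ...) {
  r <- x$retained
  cat("<qc_report>\n")
  cat(sprintf("  proteins: %d shared in; excluded A=%d, B=%d; retained A=%d, B=%d (mode=%s)\n",
              r$proteins_in, r$proteins_excluded_a, r$proteins_excluded_b,
              r$proteins_a, r$proteins_b, attr(x$lod_filter, "mode")))
  cat(sprintf("  samples: A %d -> %d (%d outliers), B %d -> %d (%d outliers)\n",
              r$samples_in_a, r$samples_a, r$samples_excluded_a,
              r$samples_in_b, r$samples_b, r$samples_excluded_b))
  invisible(x)
}
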