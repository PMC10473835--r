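# Per-protein covariate-adjusted linear models with empirical-Bayes variance
# moderation, BH FDR, and a paired pre/post contrast.

#' Fit per-protein ordinary least squares models
#'
#' Fits the same design to every protein column. With complete data a single
#' QR decomposition is shared across proteins; proteins with missing values
#' are refit on their complete cases. Samples with missing design rows are
#' dropped for all proteins. Proteins left with fewer residual degrees of
#' freedom than 1 are skipped with a reason.
#'
#' @param y numeric matrix (samples x proteins) or an `npx_matrix` (study
#'   samples are used).
#' @param design numeric design matrix (samples x coefficients) with column
#'   names; must be full column rank.
#' @return object of class `protein_fits`: list with `coefficients` and
#'   `stdev_unscaled` (proteins x coefficients; the latter is the unit-sigma
#'   standard error, `sqrt(diag((X'X)^-1))`), `sigma2`, `df_resid`, `n_used`
#'   (per protein), `design_cols`, and `skipped` (data.frame of reasons).
#' @export
fit_linear_models <- function(y, design) {
  if (inherits(y, "npx_matrix")) y <- npx_values(y, "study")
  stopifnot(is.matrix(y), is.matrix(design), nrow(y) == nrow(design))
  if (is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  ok_row <- stats::complete.cases(design)
  if (!all(ok_row)) {
    y <- y[ok_row, , drop = FALSE]
    design <- design[ok_row, , drop = FALSE]
  }
  p <- ncol(design)
  if (qr(design)$rank < p) stop("design matrix is not full column rank")

  proteins <- colnames(y)
  coef <- matrix(NA_real_, length(proteins), p,
                 dimnames = list(proteins, colnames(design)))
  sdu <- coef
  sigma2 <- stats::setNames(rep(NA_real_, length(proteins)), proteins)
  df_resid <- stats::setNames(rep(NA_integer_, length(proteins)), proteins)
  n_used <- df_resid
  skipped <- character(0)

  complete <- !colSums(is.na(y))
  if (any(complete)) {
    qrx <- qr(design)
    yc <- y[, complete, drop = FALSE]
    cf <- qr.coef(qrx, yc)
    res <- qr.resid(qrx, yc)
    xtx_inv <- chol2inv(qr.R(qrx))
    df <- nrow(design) - p
    coef[complete, ] <- t(cf)
    sdu[complete, ] <- matrix(sqrt(diag(xtx_inv)), sum(complete), p, byrow = TRUE)
    sigma2[complete] <- colSums(res^2) / df
    df_resid[complete] <- df
    n_used[complete] <- nrow(design)
  }
  for (j in which(!complete)) {
    ok <- !is.na(y[, j])
    Xj <- design[ok, , drop = FALSE]
    if (sum(ok) - p < 1 || qr(Xj)$rank < p) {
      skipped <- c(skipped, proteins[j])
      next
    }
    f <- stats::lm.fit(Xj, y[ok, j])
    coef[j, ] <- f$coefficients
    R <- qr.R(f$qr)
    sdu[j, ] <- sqrt(diag(chol2inv(R)))
    sigma2[j] <- sum(f$residuals^2) / f$df.residual
    df_resid[j] <- f$df.residual
    n_used[j] <- sum(ok)
  }
  keep <- !(proteins %in% skipped)
  structure(list(
    coefficients = coef[keep, , drop = FALSE],
    stdev_unscaled = sdu[keep, , drop = FALSE],
    sigma2 = sigma2[keep], df_resid = df_resid[keep], n_used = n_used[keep],
    design_cols = colnames(design),
    skipped = data.frame(protein = skipped,
                         reason = rep("insufficient residual df", length(skipped)),
                         stringsAsFactors = FALSE)
  ), class = "protein_fits")
}

# Newton inversion of the trigamma function (used for the prior df estimate).
trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif) < 1e-8 * y) break
  }
  y
}

#' Estimate the variance-moderation prior by moment matching
#'
#' Models the per-protein residual variances as draws from a scaled inverse
#' chi-square prior with `d0` degrees of freedom and scale `s0_sq`, and
#' estimates both by matching the first two moments of the log residual
#' variances: the excess of `var(log s^2)` over the sampling component
#' `trigamma(df/2)` identifies `d0` through a trigamma inversion, and the
#' mean identifies `s0_sq`. When the observed spread does not exceed the
#' sampling expectation, `d0 = Inf` (all variances treated as equal).
#'
#' @param fits a `protein_fits` object.
#' @return list of class `moderation_params`: `d0`, `s0_sq`,
#'   `low_confidence` (TRUE when fewer than 10 usable proteins), `n_proteins`.
#' @export
estimate_moderation <- function(fits) {
  stopifnot(inherits(fits, "protein_fits"))
  ok <- is.finite(fits$sigma2) & fits$sigma2 > 0 & fits$df_resid >= 1
  s2 <- fits$sigma2[ok]
  df <- fits$df_resid[ok]
  n <- length(s2)
  if (n < 2) stop("need at least 2 proteins with positive residual variance")
  low_conf <- n < 10
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess spread over the sampling expectation: all true variances
    # equal; pool with df weights (exactly the common value when identical)
    d0 <- Inf
    s0_sq <- sum(df * s2) / sum(df)
  }
  structure(list(d0 = d0, s0_sq = s0_sq, low_confidence = low_conf,
                 n_proteins = n), class = "moderation_params")
}

#' Moderated t-statistics by posterior variance shrinkage
#'
#' Shrinks each protein's residual variance toward the prior:
#' `s2_post = (d0 * s0_sq + df * s2) / (d0 + df)`, then forms
#' `t = beta / (stdev_unscaled * sqrt(s2_post))` with `d0 + df` degrees of
#' freedom and a two-sided p-value. `d0 = 0` reproduces classical OLS
#' inference exactly; `d0 = Inf` uses the common prior variance for every
#' protein.
#'
#' @param fits a `protein_fits` object.
#' @param params a `moderation_params` object (or a list with `d0`, `s0_sq`).
#' @param coef coefficient to test: name or column index (default 2, the
#'   first non-intercept column).
#' @return data.frame: `protein`, `beta`, `se`, `t_mod`, `df_total`, `p`,
#'   `s2_post`.
#' @export
moderate <- function(fits, params, coef = 2L) {
  stopifnot(inherits(fits, "protein_fits"))
  d0 <- params$d0; s0 <- params$s0_sq
  stopifnot(is.numeric(d0), d0 >= 0, is.numeric(s0), s0 > 0)
  if (is.character(coef)) coef <- match(coef, fits$design_cols)
  beta <- fits$coefficients[, coef]
  sdu <- fits$stdev_unscaled[, coef]
  df <- fits$df_resid
  s2 <- fits$sigma2
  s2_post <- if (is.infinite(d0)) rep(s0, length(s2))
             else (d0 * s0 + df * s2) / (d0 + df)
  se <- sdu * sqrt(s2_post)
  t_mod <- beta / se
  df_total <- df + d0
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  data.frame(protein = rownames(fits$coefficients), beta = unname(beta),
             se = unname(se), t_mod = unname(t_mod),
             df_total = unname(df_total), p = unname(p),
             s2_post = unname(s2_post), stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (`q_(i) = min_{j>=i} m p_(j) / j`, mapped back to
#' input order). `NA` p-values propagate as `NA` without entering the family
#' size.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return numeric vector of adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Cross-cohort differential expression
#'
#' Stacks the study samples of both cohorts on their common proteins and fits
#' per-protein linear models with a cohort indicator (cohort A = 1, so a
#' positive coefficient means higher in cohort A) plus the requested
#' covariates. The cohort coefficient is reported as the log2 fold change.
#' Empirical-Bayes variance moderation is applied by default; `moderated =
#' FALSE` gives classical OLS inference. Direction is `up`/`down` for
#' proteins passing the FDR gate, `ns` otherwise; `fc_cut` is a display
#' threshold carried alongside, not a significance gate.
#'
#' @param a,b `npx_matrix` objects after preprocessing.
#' @param meta metadata data.frame with `sample_id` and covariate columns.
#' @param covariates character vector of metadata columns to adjust for
#'   (default `c("age", "sex", "bmi")`); categorical covariates are
#'   reference-coded (sex reference = male).
#' @param moderated logical, apply variance moderation (default TRUE).
#' @param fdr_cut FDR significance gate (default 0.05).
#' @param fc_cut display threshold for the volcano annotation (default 0.5).
#' @return data.frame of class `de_result`: `protein`, `log2_fc`, `t_mod`,
#'   `p`, `fdr`, `direction`, `neg_log10_fdr`; attributes `counts`
#'   (up/down/ns), `moderation`, `excluded_proteins` (present in only one
#'   cohort), `fdr_cut`, `fc_cut`.
#' @export
run_de <- function(a, b, meta, covariates = c("age", "sex", "bmi"),
                   moderated = TRUE, fdr_cut = 0.05, fc_cut = 0.5) {
  mg <- merge_cohorts(a, b)
  va <- npx_values(a, "study")[, mg$common, drop = FALSE]
  vb <- npx_values(b, "study")[, mg$common, drop = FALSE]
  y <- rbind(va, vb)
  ids <- rownames(y)
  m <- meta[match(ids, meta$sample_id), , drop = FALSE]
  if (any(is.na(m$sample_id)))
    stop("metadata missing for ", sum(is.na(m$sample_id)), " sample(s)")
  cohort_a <- c(rep(1, nrow(va)), rep(0, nrow(vb)))
  for (cv in covariates) {
    if (!cv %in% names(m)) stop("covariate not in metadata: ", cv)
    miss_a <- all(is.na(m[[cv]][cohort_a == 1]))
    miss_b <- all(is.na(m[[cv]][cohort_a == 0]))
    if (miss_a || miss_b)
      stop("covariate entirely missing in one cohort: ", cv)
  }
  design <- build_design(data.frame(cohort_a = cohort_a,
                                    m[, covariates, drop = FALSE]),
                         contrast = "cohort_a")
  keep <- stats::complete.cases(design)
  fits <- fit_linear_models(y[keep, , drop = FALSE],
                            design[keep, , drop = FALSE])
  if (moderated) {
    params <- estimate_moderation(fits)
    tab <- moderate(fits, params, coef = "cohort_a")
  } else {
    params <- list(d0 = 0, s0_sq = 1)
    tab <- moderate(fits, params, coef = "cohort_a")
  }
  fdr <- bh_fdr(tab$p)
  direction <- ifelse(fdr < fdr_cut, ifelse(tab$beta > 0, "up", "down"), "ns")
  out <- data.frame(protein = tab$protein, log2_fc = tab$beta,
                    t_mod = tab$t_mod, p = tab$p, fdr = fdr,
                    direction = direction,
                    neg_log10_fdr = -log10(fdr), stringsAsFactors = FALSE)
  out <- out[order(out$fdr, out$p), ]
  rownames(out) <- NULL
  attr(out, "counts") <- c(up = sum(direction == "up"),
                           down = sum(direction == "down"),
                           ns = sum(direction == "ns"))
  attr(out, "moderation") <- params
  attr(out, "excluded_proteins") <- c(mg$only_a, mg$only_b)
  attr(out, "fdr_cut") <- fdr_cut
  attr(out, "fc_cut") <- fc_cut
  class(out) <- c("de_result", "data.frame")
  out
}

#' @export
print.de_result <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat(sprintf("<de_result> %d proteins: %d up, %d down, %d ns (FDR < %g)\n",
              nrow(x), cnt["up"], cnt["down"], cnt["ns"], attr(x, "fdr_cut")))
  print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

# Build a design matrix: contrast column first after the intercept, then
# covariates; character/factor covariates reference-coded (sex ref = male).
build_design <- function(df, contrast) {
  for (nm in names(df)) {
    if (is.character(df[[nm]])) {
      levs <- sort(unique(df[[nm]][!is.na(df[[nm]])]))
      if (nm == "sex") levs <- intersect(c("male", "female", levs), levs)
      df[[nm]] <- factor(df[[nm]], levels = unique(levs))
    }
  }
  form <- stats::as.formula(paste("~", paste(c(contrast,
                                               setdiff(names(df), contrast)),
                                             collapse = " + ")))
  stats::model.matrix(form, stats::model.frame(form, df, na.action = stats::na.pass))
}

#' Paired pre/post contrast per protein
#'
#' For a paired design (the same subjects measured before and after an
#' intervention), reports per protein the mean within-subject difference
#' (post minus pre, so a negative coefficient is a reduction after the
#' switch) and the paired t-test p-value. Proteins with all-zero differences
#' get `p = NA` and are flagged degenerate.
#'
#' @param pre,post `npx_matrix` objects (or plain matrices) with common
#'   proteins.
#' @param pairing data.frame with columns `pre` and `post` giving the sample
#'   ids of each pair, or a named character vector (names = post ids,
#'   values = pre ids).
#' @return data.frame: `protein`, `beta`, `se`, `t`, `p`, `n_pairs`,
#'   `degenerate`.
#' @export
paired_de <- function(pre, post, pairing) {
  vp <- if (inherits(pre, "npx_matrix")) npx_values(pre, "study") else pre
  vq <- if (inherits(post, "npx_matrix")) npx_values(post, "study") else post
  if (!is.data.frame(pairing))
    pairing <- data.frame(post = names(pairing), pre = unname(pairing),
                          stringsAsFactors = FALSE)
  miss_pre <- setdiff(pairing$pre, rownames(vp))
  miss_post <- setdiff(pairing$post, rownames(vq))
  if (length(miss_pre) || length(miss_post))
    stop("unpaired sample id(s): ",
         paste(c(miss_pre, miss_post), collapse = ", "))
  proteins <- sort(intersect(colnames(vp), colnames(vq)))
  d <- vq[pairing$post, proteins, drop = FALSE] -
       vp[pairing$pre, proteins, drop = FALSE]
  n <- colSums(!is.na(d))
  beta <- colMeans(d, na.rm = TRUE)
  sdd <- apply(d, 2, stats::sd, na.rm = TRUE)
  se <- sdd / sqrt(n)
  tt <- beta / se
  p <- 2 * stats::pt(-abs(tt), df = n - 1)
  degen <- sdd == 0
  p[degen] <- NA_real_
  data.frame(protein = proteins, beta = unname(beta), se = unname(se),
             t = unname(tt), p = unname(p), n_pairs = unname(n),
             degenerate = unname(degen), stringsAsFactors = FALSE)
}
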