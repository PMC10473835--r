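# Two-layer unsupervised clustering (food metabolome, then proteome) and
# annotation enrichment across the resulting sample clusters.

# Canonical relabelling: cluster 1 = largest cluster; ties broken by lower
# mean feature value, then by smallest original label.
.relabel_canonical <- function(labels, values) {
  k <- length(unique(labels))
  sizes <- tabulate(labels, k)
  means <- vapply(seq_len(k), function(cl)
    mean(values[labels == cl, , drop = FALSE]), numeric(1))
  ord <- order(-sizes, means, seq_len(k))
  new <- match(labels, ord)
  stats::setNames(new, names(labels))
}

new_cluster_assignment <- function(labels, k, method, seed = NA_integer_,
                                   inertia = NA_real_, restarts = NA_integer_) {
  structure(list(labels = labels, k = k, method = method,
                 distance = "euclidean", seed = seed, inertia = inertia,
                 restarts = restarts),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %s, k=%d: sizes %s\n", x$method, x$k,
              paste(tabulate(x$labels, x$k), collapse = "/")))
  invisible(x)
}

#' Cluster samples by their food-derived metabolite profiles
#'
#' Ward-linkage hierarchical clustering on Euclidean distances of the
#' per-feature standardized (z-scored) log-intensity matrix, with the tree
#' cut at `k`. Deterministic. Cluster labels are canonical: cluster 1 is the
#' larger cluster (ties broken by lower mean intensity), so repeated runs
#' compare equal.
#'
#' @param metab numeric matrix (samples x metabolites, log scale) or a
#'   `metabolite_table`.
#' @param k number of clusters (default 2).
#' @param standardize z-score each feature before distances (default TRUE).
#' @return a `cluster_assignment` (method `"hierarchical_ward"`).
#' @export
cluster_metabolome <- function(metab, k = 2, standardize = TRUE) {
  if (inherits(metab, "metabolite_table")) metab <- metab$values
  stopifnot(is.matrix(metab))
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(metab) / 2) stop("k larger than n/2")
  z <- if (standardize) .zscore_cols(metab) else metab
  if (k == 1) {
    labels <- stats::setNames(rep(1L, nrow(metab)), rownames(metab))
    return(new_cluster_assignment(labels, 1L, "hierarchical_ward"))
  }
  hc <- stats::hclust(stats::dist(z, method = "euclidean"), method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  labels <- .relabel_canonical(raw, metab)
  new_cluster_assignment(labels, as.integer(k), "hierarchical_ward")
}

.zscore_cols <- function(m) {
  mu <- colMeans(m, na.rm = TRUE)
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  sds[sds == 0 | !is.finite(sds)] <- 1
  sweep(sweep(m, 2, mu, "-"), 2, sds, "/")
}

#' Cluster samples by their inflammatory-protein profiles
#'
#' k-means on the per-protein standardized NPX matrix with `restarts` random
#' initializations, keeping the solution with minimal within-cluster sum of
#' squares. Seed-reproducible: the same seed gives an identical assignment.
#' Cluster labels are canonical by mean NPX: cluster 1 is the
#' lower-expressed cluster, cluster `k` the highest.
#'
#' @param npx `npx_matrix` (study samples used) or numeric matrix.
#' @param k number of clusters (default 2).
#' @param restarts number of random initializations (default 100).
#' @param seed integer seed for the initializations.
#' @param standardize z-score each protein before clustering (default TRUE).
#' @return a `cluster_assignment` (method `"kmeans"`) with `inertia` (total
#'   within-cluster sum of squares) and the seed recorded.
#' @export
cluster_proteome <- function(npx, k = 2, restarts = 100, seed = 1,
                             standardize = TRUE) {
  if (inherits(npx, "npx_matrix")) npx <- npx_values(npx, "study")
  stopifnot(is.matrix(npx))
  if (k > nrow(npx) / 2) stop("k larger than n/2")
  z <- if (standardize) .zscore_cols(npx) else npx
  km <- withr::with_seed(seed,
    stats::kmeans(z, centers = k, nstart = restarts, iter.max = 100))
  if (km$ifault != 0)
    warning("k-means did not fully converge; best solution so far returned")
  raw <- km$cluster
  # canonical: order clusters by increasing mean NPX (lower-expressed first)
  means <- vapply(seq_len(k), function(cl)
    mean(npx[raw == cl, , drop = FALSE]), numeric(1))
  ord <- order(means)
  labels <- stats::setNames(match(raw, ord), names(raw))
  new_cluster_assignment(labels, as.integer(k), "kmeans", seed = seed,
                         inertia = km$tot.withinss,
                         restarts = as.integer(restarts))
}

#' Test annotations for enrichment across sample clusters
#'
#' For each annotation column: categorical variables are tested with the
#' Pearson chi-square test (uncorrected; Fisher's exact test when any
#' expected cell is below 5), continuous variables with the Mann-Whitney U
#' test (Kruskal-Wallis for k > 2). Effect sizes: the odds ratio for a 2x2
#' table (flagged infinite for perfect association) and the rank-biserial
#' correlation for continuous two-cluster comparisons. FDR is adjusted
#' across annotations (BH).
#'
#' @param assign a `cluster_assignment`.
#' @param annotations data.frame with a `sample_id` column and one column
#'   per annotation; must cover at least 90% of clustered samples.
#' @return data.frame of class `enrichment_table`: `annotation`, `test`,
#'   `statistic`, `p`, `fdr`, `effect`, `effect_type`, `n`; attribute
#'   `contingency` holds the per-annotation tables.
#' @export
cluster_enrichment <- function(assign, annotations) {
  stopifnot(inherits(assign, "cluster_assignment"))
  ids <- names(assign$labels)
  hit <- ids %in% annotations$sample_id
  if (mean(hit) < 0.9)
    stop("annotations join to only ", round(100 * mean(hit)),
         "% of clustered samples (need >= 90%)")
  ids <- ids[hit]
  cl <- assign$labels[ids]
  ann <- annotations[match(ids, annotations$sample_id), , drop = FALSE]
  cols <- setdiff(names(ann), "sample_id")

  rows <- list()
  tables <- list()
  for (v in cols) {
    x <- ann[[v]]
    ok <- !is.na(x)
    if (!any(ok)) next
    xi <- x[ok]; ci <- cl[ok]
    if (is.numeric(xi) && length(unique(xi)) > 5) {
      if (assign$k == 2) {
        w <- stats::wilcox.test(xi[ci == 1], xi[ci == 2], exact = FALSE)
        n1 <- sum(ci == 1); n2 <- sum(ci == 2)
        effect <- 2 * w$statistic / (n1 * n2) - 1   # rank-biserial
        rows[[v]] <- data.frame(annotation = v, test = "mann_whitney",
                                statistic = unname(w$statistic),
                                p = w$p.value, effect = unname(effect),
                                effect_type = "rank_biserial",
                                n = length(xi), stringsAsFactors = FALSE)
      } else {
        kw <- stats::kruskal.test(xi, factor(ci))
        rows[[v]] <- data.frame(annotation = v, test = "kruskal_wallis",
                                statistic = unname(kw$statistic),
                                p = kw$p.value, effect = NA_real_,
                                effect_type = NA_character_,
                                n = length(xi), stringsAsFactors = FALSE)
      }
    } else {
      xi <- as.character(xi)
      if (length(unique(xi)) < 2) next  # single level: nothing to test
      tab <- table(cluster = ci, level = xi)
      tables[[v]] <- tab
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      use_fisher <- any(expected < 5)
      if (use_fisher) {
        ft <- stats::fisher.test(tab)
        p <- ft$p.value; statistic <- NA_real_; test <- "fisher"
      } else {
        ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        p <- ct$p.value; statistic <- unname(ct$statistic); test <- "chi_square"
      }
      effect <- NA_real_; effect_type <- NA_character_
      if (all(dim(tab) == c(2, 2))) {
        effect <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
        effect_type <- "odds_ratio"
      }
      rows[[v]] <- data.frame(annotation = v, test = test,
                              statistic = statistic, p = p, effect = effect,
                              effect_type = effect_type, n = sum(tab),
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no testable annotations (all single-level or missing)")
  out$fdr <- bh_fdr(out$p)
  rownames(out) <- NULL
  attr(out, "contingency") <- tables
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same samples;
#' 1 for identical partitions, about 0 for independent ones. Used to score
#' cluster recovery against simulated ground truth.
#'
#' @param a,b integer/factor label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
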