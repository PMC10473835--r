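# Fixture builders shared across the suite. Everything is generated in code;
# no fixture files.

# Minimal npx_matrix: values is a samples x proteins matrix (or coercible);
# all samples on one plate unless a plate map is given.
make_npx <- function(values, lod = NULL, cohort = "A", sample_type = NULL,
                     plate = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("s%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("P%02d", seq_len(ncol(values)))
  if (is.null(lod))
    lod <- stats::setNames(rep(-100, ncol(values)), colnames(values))
  if (is.null(names(lod))) names(lod) <- colnames(values)
  if (is.null(plate))
    plate <- stats::setNames(rep("plate1", nrow(values)), rownames(values))
  if (is.null(sample_type))
    sample_type <- stats::setNames(rep("study", nrow(values)), rownames(values))
  npx_matrix(values, lod, plate, sample_type, cohort)
}

# Two-cohort pair with explicit bridge rows appended to each matrix.
make_pair <- function(study_a, study_b, bridge_a, bridge_b, lod_a = NULL,
                      lod_b = NULL) {
  build <- function(study, bridge, cohort, lod) {
    study <- as.matrix(study); bridge <- as.matrix(bridge)
    colnames(bridge) <- colnames(study) <-
      if (!is.null(colnames(study))) colnames(study)
      else sprintf("P%02d", seq_len(ncol(study)))
    rownames(study) <- sprintf("%s_s%02d", cohort, seq_len(nrow(study)))
    rownames(bridge) <- sprintf("%s_br%02d", cohort, seq_len(nrow(bridge)))
    v <- rbind(study, bridge)
    st <- stats::setNames(c(rep("study", nrow(study)),
                            rep("bridge", nrow(bridge))), rownames(v))
    make_npx_full(v, cohort, st, lod)
  }
  list(a = build(study_a, bridge_a, "A", lod_a),
       b = build(study_b, bridge_b, "B", lod_b))
}

make_npx_full <- function(v, cohort, sample_type, lod = NULL) {
  if (is.null(lod)) lod <- stats::setNames(rep(-100, ncol(v)), colnames(v))
  npx_matrix(v, lod, stats::setNames(rep("plate1", nrow(v)), rownames(v)),
             sample_type, cohort)
}

# Brute-force BH step-up by its definition: q_(i) = min_{j >= i} m p_(j)/j.
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m))
    q_sorted[i] <- min(1, min(m * p[ord][i:m] / (i:m)))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Closed-form Pearson chi-square statistic.
pearson_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Small fully-crossed metadata for synthetic matrices.
make_meta <- function(ids, seed = 1) {
  withr::with_seed(seed, data.frame(
    sample_id = ids,
    age = sample(20:60, length(ids), TRUE),
    sex = sample(c("male", "female"), length(ids), TRUE),
    bmi = round(runif(length(ids), 18, 32), 1),
    stringsAsFactors = FALSE))
}
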