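# Synthetic two-cohort generator with known ground truth: NPX panels with
# plate structure, bridge samples, LOD censoring, covariate effects and
# outliers; a food-metabolome with two latent diet clusters; SNP dosages.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study conditions of a two-cohort inflammatory-panel
#' comparison: 318 + 416 participants, 92 proteins on the log2 NPX scale,
#' 4 plates per cohort with 2 pooled bridge samples each (8 per cohort),
#' per-protein technical offsets between cohorts, sparse cohort effects
#' spanning -0.8 to +1.9 log2 units, age/sex/BMI covariate effects, 18
#' proteins heavily censored by the limit of detection in both cohorts, a
#' small fraction of multivariate outliers, and a food-derived metabolome
#' with two latent diet clusters coupled to a subset of proteins.
#'
#' @param n_a,n_b study sample counts per cohort (defaults 318 and 416).
#' @param n_proteins panel size (default 92).
#' @param plates_per_cohort,bridge_per_plate plate layout (4 and 2).
#' @param cohort_effects named numeric vector of injected log2 fold changes
#'   (cohort A relative to B); `NULL` uses the default sparse pattern: 35
#'   up-regulated proteins spanning 0.2..1.9 and 20 down-regulated spanning
#'   -0.8..-0.2.
#' @param covariate_effects list of lists with `factor` (`age`, `sex_female`
#'   or `bmi`), `proteins` (indices) and `slope`; `NULL` uses modest
#'   defaults.
#' @param technical_offset named per-protein shift applied to every cohort-A
#'   measurement (the quantity bridging removes); `NULL` draws one from
#'   N(0, 0.5^2) per protein.
#' @param plate_sd standard deviation of residual per-(plate, protein)
#'   offsets (default 0.05; the emulated exports are already inter-plate
#'   normalized upstream, so only small residual plate structure remains).
#' @param bridge_sd technical replication noise of the pooled bridge
#'   controls (default 0.1 log2 units, an intra-assay CV of roughly 7%;
#'   pooled aliquots carry no biological variance).
#' @param lod_quantile per-protein censoring quantile; `NULL` uses 0.35 for
#'   the last 18 proteins and 0.02 elsewhere.
#' @param outlier_frac fraction of study samples turned into multivariate
#'   outliers (default 0.016, i.e. about 12 of 734).
#' @param d0,s0_sq scaled-inverse-chi-square parameters for the per-protein
#'   noise variances (defaults 4 and 0.25).
#' @param metabolome list: `n_metab` total features, `n_food` food-derived,
#'   `n_shifted` features shifted between the two diet clusters,
#'   `cluster_shift` (log2 shift, default 0.5), `noise_sd` (default 0.8),
#'   `protein_targets` (indices of proteins shifted by diet-cluster
#'   membership), `protein_shift` (default 0.5), `couplings` data.frame
#'   (`metabolite`, `protein`, `beta`).
#' @param n_snps,maf genotype block: number of SNPs (6) and their minor
#'   allele frequencies.
#' @param label_a,label_b cohort labels.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_a = 318, n_b = 416, n_proteins = 92,
                       plates_per_cohort = 4, bridge_per_plate = 2,
                       cohort_effects = NULL, covariate_effects = NULL,
                       technical_offset = NULL, plate_sd = 0.05,
                       bridge_sd = 0.1,
                       lod_quantile = NULL, outlier_frac = 0.016,
                       d0 = 4, s0_sq = 0.25, metabolome = list(),
                       n_snps = 6, maf = c(0.1, 0.15, 0.2, 0.3, 0.4, 0.5),
                       label_a = "TZ", label_b = "NL", seed = 1) {
  stopifnot(n_a > 0, n_b > 0, n_proteins > 0, plates_per_cohort > 0,
            bridge_per_plate > 0, outlier_frac >= 0, outlier_frac < 1,
            d0 > 0, s0_sq > 0, plate_sd >= 0, bridge_sd >= 0)
  proteins <- sprintf("P%03d", seq_len(n_proteins))
  if (is.null(cohort_effects)) {
    eff <- numeric(n_proteins)
    n_up <- min(35, n_proteins)
    n_dn <- min(20, max(0, n_proteins - n_up))
    if (n_up > 0) eff[seq_len(n_up)] <- seq(0.2, 1.9, length.out = n_up)
    if (n_dn > 0) eff[n_up + seq_len(n_dn)] <- seq(-0.8, -0.2, length.out = n_dn)
    cohort_effects <- stats::setNames(eff, proteins)
  }
  if (is.null(names(cohort_effects)))
    names(cohort_effects) <- proteins[seq_along(cohort_effects)]
  if (!all(is.finite(cohort_effects))) stop("cohort effects must be finite")
  if (is.null(covariate_effects)) {
    covariate_effects <- list(
      list(factor = "age", proteins = 56:60, slope = 0.02),
      list(factor = "sex_female", proteins = 61:65, slope = -0.3),
      list(factor = "bmi", proteins = 66:70, slope = 0.05))
    covariate_effects <- Filter(function(e) all(e$proteins <= n_proteins),
                                covariate_effects)
  }
  if (is.null(lod_quantile)) {
    lq <- rep(0.02, n_proteins)
    n_cens <- min(18, n_proteins)
    lq[n_proteins - seq_len(n_cens) + 1] <- 0.35
    lod_quantile <- stats::setNames(lq, proteins)
  }
  if (any(lod_quantile < 0 | lod_quantile >= 1))
    stop("lod_quantile must lie in [0, 1)")
  mb <- utils::modifyList(list(
    n_metab = 350, n_food = 288, n_shifted = 120, cluster_shift = 0.5,
    noise_sd = 0.8,
    protein_targets = if (n_proteins >= 60) 31:60 else seq_len(n_proteins),
    protein_shift = 0.5, couplings = NULL), metabolome)
  if (is.null(mb$couplings)) {
    if (n_proteins >= 78) {
      neg <- expand.grid(metabolite = sprintf("M%03d", 1:2),
                         protein = proteins[71:75],
                         stringsAsFactors = FALSE)
      neg$beta <- -0.3
      pos <- expand.grid(metabolite = "M150", protein = proteins[76:78],
                         stringsAsFactors = FALSE)
      pos$beta <- 0.3
      mb$couplings <- rbind(neg, pos)
    } else {
      mb$couplings <- data.frame(metabolite = character(0),
                                 protein = character(0), beta = numeric(0))
    }
  }
  if (any(maf <= 0 | maf > 0.5)) stop("MAF must lie in (0, 0.5]")
  if (length(maf) != n_snps) maf <- rep_len(maf, n_snps)
  structure(list(n_a = n_a, n_b = n_b, n_proteins = n_proteins,
                 proteins = proteins, plates_per_cohort = plates_per_cohort,
                 bridge_per_plate = bridge_per_plate,
                 cohort_effects = cohort_effects,
                 covariate_effects = covariate_effects,
                 technical_offset = technical_offset, plate_sd = plate_sd,
                 bridge_sd = bridge_sd,
                 lod_quantile = lod_quantile, outlier_frac = outlier_frac,
                 d0 = d0, s0_sq = s0_sq, metabolome = mb, n_snps = n_snps,
                 maf = maf, label_a = label_a, label_b = label_b,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Metadata for one cohort, loosely matching the descriptive tables of the
# two studies being emulated (ages, sex balance, BMI distributions, season,
# residency and categorical exposures for the Tanzanian-style cohort).
.sim_metadata <- function(cfg) {
  ids_a <- sprintf("%s%04d", cfg$label_a, seq_len(cfg$n_a))
  ids_b <- sprintf("%s%04d", cfg$label_b, seq_len(cfg$n_b))
  age_a <- pmin(65, pmax(18, round(stats::rlnorm(cfg$n_a, log(30), 0.30))))
  age_b <- pmin(75, pmax(18, round(stats::rlnorm(cfg$n_b, log(23), 0.18))))
  sex_a <- sample(c("female", "male"), cfg$n_a, TRUE, prob = c(0.513, 0.487))
  sex_b <- sample(c("female", "male"), cfg$n_b, TRUE, prob = c(0.514, 0.486))
  bmi_a <- round(stats::rlnorm(cfg$n_a, log(23.8), 0.18), 1)
  bmi_b <- round(stats::rlnorm(cfg$n_b, log(22.3), 0.10), 1)
  meta_a <- data.frame(
    sample_id = ids_a, cohort = cfg$label_a, age = age_a, sex = sex_a,
    bmi = bmi_a,
    season = sample(c("rainy", "dry"), cfg$n_a, TRUE),
    residency = sample(c("urban", "rural"), cfg$n_a, TRUE, prob = c(0.786, 0.214)),
    toilet = sample(c("water_closet", "pit_latrine"), cfg$n_a, TRUE,
                    prob = c(0.764, 0.236)),
    cooking_fuel = sample(c("non_smoky", "smoky"), cfg$n_a, TRUE,
                          prob = c(0.645, 0.355)),
    animal_exposure = sample(c("yes", "no"), cfg$n_a, TRUE, prob = c(0.434, 0.566)),
    antibiotics_past_year = sample(c("none", "1-3", ">3"), cfg$n_a, TRUE,
                                   prob = c(0.406, 0.508, 0.087)),
    water_source = sample(c("tap", "other"), cfg$n_a, TRUE, prob = c(0.972, 0.028)),
    stringsAsFactors = FALSE)
  meta_b <- data.frame(
    sample_id = ids_b, cohort = cfg$label_b, age = age_b, sex = sex_b,
    bmi = bmi_b,
    season = sample(c("rainy", "dry"), cfg$n_b, TRUE),
    residency = NA_character_, toilet = NA_character_,
    cooking_fuel = NA_character_, animal_exposure = NA_character_,
    antibiotics_past_year = NA_character_, water_source = NA_character_,
    stringsAsFactors = FALSE)
  rbind(meta_a, meta_b)
}

.sim_cohort_matrix <- function(cfg, meta, baseline, sigma, tech, eff, label,
                               prefix) {
  n <- nrow(meta)
  p <- cfg$n_proteins
  plates <- sprintf("%s_plate%d", label, seq_len(cfg$plates_per_cohort))
  plate_of_study <- rep(plates, length.out = n)
  plate_offsets <- matrix(stats::rnorm(cfg$plates_per_cohort * p,
                                       sd = cfg$plate_sd),
                          cfg$plates_per_cohort, p,
                          dimnames = list(plates, cfg$proteins))
  covars <- matrix(0, n, p)
  for (ce in cfg$covariate_effects) {
    x <- switch(ce$factor,
                age = meta$age - 30,
                sex_female = as.numeric(meta$sex == "female"),
                bmi = meta$bmi - 23,
                stop("unknown covariate effect factor: ", ce$factor))
    covars[, ce$proteins] <- covars[, ce$proteins] + outer(x, rep(ce$slope, length(ce$proteins)))
  }
  noise <- matrix(stats::rnorm(n * p), n, p) %*% diag(sigma)
  values <- matrix(baseline, n, p, byrow = TRUE) +
    matrix(eff, n, p, byrow = TRUE) +
    matrix(tech, n, p, byrow = TRUE) +
    plate_offsets[plate_of_study, , drop = FALSE] +
    covars + noise
  dimnames(values) <- list(meta$sample_id, cfg$proteins)

  n_bridge <- cfg$plates_per_cohort * cfg$bridge_per_plate
  bridge_ids <- sprintf("%s_BR%02d", prefix, seq_len(n_bridge))
  bridge_plates <- rep(plates, each = cfg$bridge_per_plate)
  # pooled aliquots: technical replication noise only, no biological term
  bvalues <- matrix(baseline, n_bridge, p, byrow = TRUE) +
    matrix(tech, n_bridge, p, byrow = TRUE) +
    plate_offsets[bridge_plates, , drop = FALSE] +
    matrix(stats::rnorm(n_bridge * p, sd = cfg$bridge_sd), n_bridge, p)
  dimnames(bvalues) <- list(bridge_ids, cfg$proteins)

  all_values <- rbind(values, bvalues)
  plate <- stats::setNames(c(plate_of_study, bridge_plates),
                           rownames(all_values))
  stype <- stats::setNames(c(rep("study", n), rep("bridge", n_bridge)),
                           rownames(all_values))

  # outliers: 6 residual sd along one random sign direction shared within
  # the cohort (a common technical artifact, e.g. hemolysis), each sample
  # on a random side of it -- so the leading PCs align with the artifact
  n_out <- round(cfg$outlier_frac * n)
  out_ids <- character(0)
  if (n_out > 0) {
    out_idx <- sample(n, n_out)
    out_ids <- meta$sample_id[out_idx]
    direction <- sample(c(-1, 1), p, TRUE)
    side <- sample(c(-1, 1), n_out, TRUE)
    for (k in seq_along(out_idx))
      all_values[out_idx[k], ] <- all_values[out_idx[k], ] +
        6 * sigma * direction * side[k]
  }

  # LOD at the configured per-protein quantile of the study values
  lq <- cfg$lod_quantile
  lod <- vapply(seq_len(p), function(j) {
    if (lq[j] <= 0) min(all_values[seq_len(n), j]) - 1
    else stats::quantile(all_values[seq_len(n), j], probs = lq[j], names = FALSE)
  }, numeric(1))
  names(lod) <- cfg$proteins

  list(mat = npx_matrix(all_values, lod, plate, stype, label),
       plate_offsets = plate_offsets, outliers = out_ids)
}

#' Simulate a two-cohort NPX panel with known ground truth
#'
#' Generates study and bridge samples for both cohorts under the additive
#' model: baseline + cohort effect (cohort A only) + technical offset
#' (cohort A only) + plate offset + covariate terms + protein-specific
#' Gaussian noise with variances drawn from a scaled inverse chi-square.
#' Bridge samples share the pooled-control expectation (baseline + technical
#' offset + plate offset), so the bridging offsets recover the technical
#' offset. Limits of detection sit at the configured per-protein quantile of
#' the study values; values below the LOD are retained as measured. A small
#' fraction of study samples are turned into multivariate outliers by a
#' 6-residual-sd shift with a random sign per protein. Fully
#' seed-deterministic.
#'
#' @param cfg a [sim_config()].
#' @return list: `a`, `b` (`npx_matrix` per cohort), `metadata` (both
#'   cohorts), `truth` (list of every injected quantity: `cohort_effects`,
#'   `technical_offset`, `plate_offsets`, `covariate_effects`, `sigma2`,
#'   `baseline`, `lod_quantile`, `outliers_a`, `outliers_b`).
#' @export
simulate_cohorts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    meta <- .sim_metadata(cfg)
    meta_a <- meta[meta$cohort == cfg$label_a, , drop = FALSE]
    meta_b <- meta[meta$cohort == cfg$label_b, , drop = FALSE]
    p <- cfg$n_proteins
    baseline <- stats::runif(p, 2, 8)
    sigma2 <- cfg$d0 * cfg$s0_sq / stats::rchisq(p, df = cfg$d0)
    tech <- cfg$technical_offset
    if (is.null(tech))
      tech <- stats::setNames(stats::rnorm(p, 0, 0.5), cfg$proteins)
    eff <- stats::setNames(rep(0, p), cfg$proteins)
    eff[names(cfg$cohort_effects)] <- cfg$cohort_effects

    a <- .sim_cohort_matrix(cfg, meta_a, baseline, sqrt(sigma2),
                            tech[cfg$proteins], eff, cfg$label_a, "A")
    b <- .sim_cohort_matrix(cfg, meta_b, baseline, sqrt(sigma2),
                            rep(0, p), rep(0, p), cfg$label_b, "B")

    truth <- list(cohort_effects = eff, technical_offset = tech,
                  plate_offsets = list(a = a$plate_offsets, b = b$plate_offsets),
                  covariate_effects = cfg$covariate_effects,
                  sigma2 = stats::setNames(sigma2, cfg$proteins),
                  baseline = stats::setNames(baseline, cfg$proteins),
                  lod_quantile = cfg$lod_quantile,
                  outliers_a = a$outliers, outliers_b = b$outliers)
    list(a = a$mat, b = b$mat, metadata = meta, truth = truth)
  })
}

#' Simulate a food-derived metabolome with two latent diet clusters
#'
#' Assigns every cohort-A study sample to one of two latent diet clusters,
#' shifts a configured subset of food-derived metabolites by the cluster
#' shift, shifts a configured subset of proteins in the NPX matrix by the
#' diet-cluster protein shift (the diet-to-inflammation signal), and adds
#' the configured direct (metabolite, protein) couplings. Ground truth is
#' recorded alongside.
#'
#' @param cfg a [sim_config()].
#' @param npx the cohort-A `npx_matrix` from [simulate_cohorts()].
#' @param metadata the metadata from [simulate_cohorts()].
#' @param truth the truth list from [simulate_cohorts()] (extended in the
#'   return value).
#' @return list: `metab` (a [metabolite_table] over cohort-A study samples),
#'   `npx` (the coupled cohort-A matrix), `truth` (with `diet_cluster`,
#'   `shifted_metabolites`, `diet_protein_targets`, `couplings` added).
#' @export
simulate_metabolome <- function(cfg, npx, metadata, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(npx, "npx_matrix"))
  mb <- cfg$metabolome
  ids <- npx_samples(npx, "study")
  if (length(ids) == 0) stop("cohort A has no study samples")
  withr::with_seed(cfg$seed + 1L, {
    n <- length(ids)
    cluster <- sample(1:2, n, TRUE)
    mets <- sprintf("M%03d", seq_len(mb$n_metab))
    base_m <- stats::runif(mb$n_metab, 8, 14)
    values <- matrix(base_m, n, mb$n_metab, byrow = TRUE) +
      matrix(stats::rnorm(n * mb$n_metab, sd = mb$noise_sd), n, mb$n_metab)
    dimnames(values) <- list(ids, mets)
    shifted <- mets[seq_len(min(mb$n_shifted, mb$n_food))]
    values[, shifted] <- values[, shifted] +
      mb$cluster_shift * (cluster == 2)

    # diet-cluster shift on a protein subset (diet -> inflammation signal)
    tgt <- cfg$proteins[mb$protein_targets]
    npx$values[ids, tgt] <- npx$values[ids, tgt] +
      mb$protein_shift * (cluster == 2)

    # direct metabolite-protein couplings
    cpl <- mb$couplings
    bad <- setdiff(cpl$protein, colnames(npx$values))
    if (length(bad))
      stop("coupling references unknown protein(s): ",
           paste(bad, collapse = ", "))
    for (i in seq_len(nrow(cpl))) {
      mz <- as.numeric(scale(values[, cpl$metabolite[i]]))
      npx$values[ids, cpl$protein[i]] <-
        npx$values[ids, cpl$protein[i]] + cpl$beta[i] * mz
    }

    classes <- c("polyphenols", "carboxylic_acids", "organooxygen",
                 "prenol_lipids", "other")
    ann <- data.frame(
      metabolite = mets,
      formula = sprintf("C%dH%dO%d", 6 + seq_len(mb$n_metab) %% 15,
                        8 + seq_len(mb$n_metab) %% 20,
                        2 + seq_len(mb$n_metab) %% 7),
      putative_name = paste0("synthetic_metabolite_", seq_len(mb$n_metab)),
      chem_class = classes[1 + (seq_len(mb$n_metab) - 1) %% length(classes)],
      food_derived = seq_len(mb$n_metab) <= mb$n_food,
      stringsAsFactors = FALSE)

    truth$diet_cluster <- stats::setNames(cluster, ids)
    truth$shifted_metabolites <- shifted
    truth$diet_protein_targets <- tgt
    truth$diet_protein_shift <- mb$protein_shift
    truth$diet_cluster_shift <- mb$cluster_shift
    truth$couplings <- cpl
    list(metab = metabolite_table(values, ann), npx = npx, truth = truth)
  })
}

#' Simulate SNP dosages under Hardy-Weinberg equilibrium
#'
#' Draws biallelic dosages (0/1/2) for the cohort-A study samples at the
#' configured minor allele frequencies, optionally adding additive effects
#' to named proteins in the NPX matrix.
#'
#' @param cfg a [sim_config()].
#' @param metadata metadata from [simulate_cohorts()].
#' @param npx optional cohort-A `npx_matrix` to receive SNP effects.
#' @param effects optional data.frame (`snp`, `protein`, `beta`).
#' @return list: `genotypes` (samples x SNPs matrix), `npx` (possibly
#'   modified), `truth_effects` (the effects applied, possibly empty).
#' @export
simulate_genotypes <- function(cfg, metadata, npx = NULL, effects = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  ids <- metadata$sample_id[metadata$cohort == cfg$label_a]
  if (!is.null(npx)) ids <- intersect(ids, npx_samples(npx, "study"))
  withr::with_seed(cfg$seed + 2L, {
    g <- vapply(cfg$maf, function(f) stats::rbinom(length(ids), 2, f),
                numeric(length(ids)))
    dimnames(g) <- list(ids, sprintf("rs%04d", seq_len(cfg$n_snps)))
    if (!is.null(effects) && nrow(effects) > 0) {
      if (is.null(npx)) stop("effects require an npx matrix to act on")
      for (i in seq_len(nrow(effects)))
        npx$values[ids, effects$protein[i]] <-
          npx$values[ids, effects$protein[i]] +
          effects$beta[i] * g[, effects$snp[i]]
    }
    list(genotypes = g, npx = npx,
         truth_effects = if (is.null(effects))
           data.frame(snp = character(0), protein = character(0),
                      beta = numeric(0)) else effects)
  })
}
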