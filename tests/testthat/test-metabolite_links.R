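make_metab <- function(values, food = NULL, classes = NULL) {
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("M%03d", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("s%03d", seq_len(nrow(values)))
  if (is.null(food)) food <- rep(TRUE, ncol(values))
  if (is.null(classes)) classes <- rep("other", ncol(values))
  metabolite_table(values, data.frame(
    metabolite = colnames(values), formula = "C6H12O6",
    putative_name = colnames(values), chem_class = classes,
    food_derived = food, stringsAsFactors = FALSE))
}

test_that("food-derived selection subsets by the flag and errors when empty", {
  withr::with_seed(71, v <- matrix(rnorm(10 * 1000), 10, 1000))
  t_all <- make_metab(v, food = c(rep(TRUE, 288), rep(FALSE, 712)))
  expect_message(sub <- select_food_metabolites(t_all), "288")
  expect_equal(ncol(sub$values), 288)
  t_full <- make_metab(v[, 1:5])
  expect_equal(dim(suppressMessages(select_food_metabolites(t_full))$values),
               dim(t_full$values))
  t_none <- make_metab(v[, 1:5], food = rep(FALSE, 5))
  expect_error(select_food_metabolites(t_none), "food-derived")
})

test_that("the scan matches per-pair lm() and is scale invariant", {
  withr::with_seed(72, {
    n <- 80
    ids <- paste0("s", 1:n)
    meta <- make_meta(ids)
    metab_v <- matrix(rnorm(n * 3, 10), n, 3,
                      dimnames = list(ids, sprintf("M%03d", 1:3)))
    y <- matrix(rnorm(n * 2, 5), n, 2, dimnames = list(ids, c("P1", "P2")))
  })
  mt <- make_metab(metab_v)
  sc <- metabolite_protein_scan(mt, y, meta)
  # oracle: full lm on sd-standardized variables, pair by pair
  for (i in seq_len(nrow(sc))) {
    d <- data.frame(y = y[, sc$protein[i]] / sd(y[, sc$protein[i]]),
                    x = metab_v[, sc$metabolite[i]] /
                      sd(metab_v[, sc$metabolite[i]]),
                    age = meta$age, sex = meta$sex)
    ref <- summary(lm(y ~ x + age + sex, data = d))$coefficients
    expect_equal(sc$beta[i], ref["x", "Estimate"], tolerance = 1e-10)
    expect_equal(sc$p[i], ref["x", "Pr(>|t|)"], tolerance = 1e-10)
  }
  # scaling a metabolite by 100 leaves its standardized beta unchanged
  metab_v2 <- metab_v; metab_v2[, 1] <- metab_v2[, 1] * 100
  sc2 <- metabolite_protein_scan(make_metab(metab_v2), y, meta)
  expect_equal(sc2$beta, sc$beta, tolerance = 1e-12)
})

test_that("regressing either way preserves the association sign", {
  withr::with_seed(73, {
    n <- 100
    ids <- paste0("s", 1:n)
    meta <- make_meta(ids)
    x <- rnorm(n)
    y <- matrix(-0.5 * x + rnorm(n, sd = 0.5), n, 1,
                dimnames = list(ids, "P1"))
    metab_v <- matrix(x + 10, n, 1, dimnames = list(ids, "M001"))
  })
  fwd <- metabolite_protein_scan(make_metab(metab_v), y, meta)
  rev <- metabolite_protein_scan(make_metab(y + 10), metab_v, meta)
  expect_equal(sign(fwd$beta), sign(rev$beta))
  expect_lt(fwd$beta, 0)
})

test_that("growing the pair family can only weaken a fixed pair's FDR", {
  withr::with_seed(74, {
    n <- 90
    ids <- paste0("s", 1:n)
    meta <- make_meta(ids)
    metab_v <- matrix(rnorm(n * 20, 10), n, 20, dimnames = list(ids, NULL))
    y <- matrix(rnorm(n * 4), n, 4, dimnames = list(ids, paste0("P", 1:4)))
    y[, 1] <- y[, 1] + 0.4 * scale(metab_v[, 1])
  })
  small <- metabolite_protein_scan(make_metab(metab_v[, 1:5, drop = FALSE]),
                                   y, meta)
  big <- metabolite_protein_scan(make_metab(metab_v), y, meta)
  key <- small$metabolite == "M001" & small$protein == "P1"
  keyb <- big$metabolite == "M001" & big$protein == "P1"
  expect_gte(big$fdr[keyb], small$fdr[key])
})

test_that("planted polyphenol-chemokine couplings are recovered", {
  hits <- vapply(1:5, function(s) {
    cfg <- sim_config(seed = 700 + s)
    sim <- simulate_cohorts(cfg)
    sm <- simulate_metabolome(cfg, sim$a, sim$metadata, sim$truth)
    food <- suppressMessages(select_food_metabolites(sm$metab))
    sc <- metabolite_protein_scan(food, sm$npx, sim$metadata)
    cpl <- sm$truth$couplings
    neg <- cpl[cpl$beta < 0, ]
    key <- paste(sc$metabolite, sc$protein) %in% paste(neg$metabolite, neg$protein)
    sum(sc$fdr[key] < 0.05 & sc$beta[key] < 0) / nrow(neg)
  }, numeric(1))
  expect_gte(mean(hits >= 0.8), 0.8)
})

test_that("zero-variance metabolites are skipped with a reason", {
  withr::with_seed(75, {
    n <- 60
    ids <- paste0("s", 1:n)
    meta <- make_meta(ids)
    metab_v <- matrix(rnorm(n * 3, 10), n, 3, dimnames = list(ids, NULL))
    metab_v[, 2] <- 4
    y <- matrix(rnorm(n), n, 1, dimnames = list(ids, "P1"))
  })
  sc <- metabolite_protein_scan(make_metab(metab_v), y, meta)
  expect_false("M002" %in% sc$metabolite)
  expect_equal(attr(sc, "skipped_metabolites")$metabolite, "M002")
})

test_that("class summaries aggregate medians and significant fractions", {
  withr::with_seed(76, {
    n <- 150
    ids <- paste0("s", 1:n)
    meta <- make_meta(ids)
    metab_v <- matrix(rnorm(n * 4, 10), n, 4, dimnames = list(ids, NULL))
    y <- matrix(rnorm(n * 2, sd = 0.5), n, 2, dimnames = list(ids, c("P1", "P2")))
    # classes with opposite injected signs
    y[, 1] <- y[, 1] - 0.6 * scale(metab_v[, 1]) - 0.6 * scale(metab_v[, 2])
    y[, 2] <- y[, 2] + 0.6 * scale(metab_v[, 3]) + 0.6 * scale(metab_v[, 4])
  })
  mt <- make_metab(metab_v, classes = c("polyphenols", "polyphenols",
                                        "organooxygen", "organooxygen"))
  sc <- metabolite_protein_scan(mt, y, meta)
  cs <- class_summary(sc)
  expect_lt(cs$median_beta[cs$chem_class == "polyphenols"], 0)
  expect_gt(cs$median_beta[cs$chem_class == "organooxygen"], 0)
  expect_equal(cs$n_pairs, c(4, 4))

  one <- class_summary(sc[sc$metabolite == "M001" & sc$protein == "P1", ])
  expect_equal(one$median_beta, sc$beta[sc$metabolite == "M001" &
                                          sc$protein == "P1"])
  # a class with only null pairs has significant fraction 0
  null_pairs <- sc[sc$metabolite %in% c("M001", "M002") & sc$protein == "P2", ]
  expect_equal(class_summary(null_pairs)$frac_significant, 0)
})
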