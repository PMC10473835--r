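test_that("per-protein OLS matches closed forms and lm()", {
  # constant response: all non-intercept betas 0, sigma2 = 0
  y <- matrix(3, 20, 2, dimnames = list(paste0("s", 1:20), c("P1", "P2")))
  X <- cbind(intercept = 1, g = rep(0:1, each = 10))
  rownames(X) <- rownames(y)
  f <- fit_linear_models(y, X)
  expect_equal(unname(f$coefficients[, "g"]), c(0, 0))
  expect_equal(unname(f$sigma2), c(0, 0))

  # two-group design: contrast beta equals difference of group means
  withr::with_seed(31, y2 <- matrix(rnorm(40), 20, 2,
                                    dimnames = dimnames(y)))
  f2 <- fit_linear_models(y2, X)
  expect_equal(unname(f2$coefficients[, "g"]),
               unname(colMeans(y2[11:20, ]) - colMeans(y2[1:10, ])))

  # full agreement with lm(): coefficients, se, sigma2, df
  withr::with_seed(32, {
    X3 <- cbind(intercept = 1, age = rnorm(50), sex = rbinom(50, 1, 0.5))
    y3 <- matrix(rnorm(100), 50, 2,
                 dimnames = list(paste0("s", 1:50), c("P1", "P2")))
  })
  rownames(X3) <- rownames(y3)
  f3 <- fit_linear_models(y3, X3)
  ref <- lm(y3[, 1] ~ X3[, -1])
  expect_equal(unname(f3$coefficients[1, ]), unname(coef(ref)))
  expect_equal(unname(f3$stdev_unscaled[1, ] * sqrt(f3$sigma2[1])),
               unname(summary(ref)$coefficients[, "Std. Error"]))
  expect_equal(unname(f3$df_resid[1]), df.residual(ref))
})

test_that("a strong covariate effect is recovered within 3 standard errors", {
  withr::with_seed(33, {
    age <- runif(200, 20, 60)
    y <- matrix(0.5 * age + rnorm(200, sd = 0.01), 200, 1,
                dimnames = list(paste0("s", 1:200), "P1"))
  })
  X <- cbind(intercept = 1, age = age)
  rownames(X) <- rownames(y)
  f <- fit_linear_models(y, X)
  se <- f$stdev_unscaled[1, "age"] * sqrt(f$sigma2[1])
  expect_lt(abs(f$coefficients[1, "age"] - 0.5), 3 * se)
})

test_that("proteins with missing values are refit on complete cases", {
  withr::with_seed(34, {
    y <- matrix(rnorm(60), 30, 2,
                dimnames = list(paste0("s", 1:30), c("P1", "P2")))
    X <- cbind(intercept = 1, x = rnorm(30))
  })
  rownames(X) <- rownames(y)
  y[1:5, 2] <- NA
  f <- fit_linear_models(y, X)
  ref <- lm(y[6:30, 2] ~ X[6:30, "x"])
  expect_equal(unname(f$coefficients["P2", ]), unname(coef(ref)))
  expect_equal(unname(f$n_used["P2"]), 25L)
  expect_equal(unname(f$n_used["P1"]), 30L)
})

test_that("moment-matching estimates the variance prior", {
  # identical variances: no between-protein spread, d0 = Inf
  y <- matrix(3, 20, 12, dimnames = list(paste0("s", 1:20), paste0("P", 1:12)))
  X <- cbind(intercept = 1, g = rep(0:1, 10))
  rownames(X) <- rownames(y)
  withr::with_seed(35, e <- rnorm(20))
  yv <- y + e   # same residual vector for every protein
  fv <- fit_linear_models(yv, X)
  mp <- estimate_moderation(fv)
  expect_equal(mp$d0, Inf)
  expect_equal(mp$s0_sq, fv$sigma2[[1]], tolerance = 1e-10)

  # scaled-inverse-chi-square truth is recovered and matches limma
  skip_if_not_installed("limma")
  withr::with_seed(36, {
    sigma2 <- 4 * 0.25 / rchisq(500, 4)
    n <- 104
    ys <- vapply(sigma2, function(s2) rnorm(n, sd = sqrt(s2)), numeric(n))
  })
  dimnames(ys) <- list(paste0("s", 1:104), paste0("P", 1:500))
  Xs <- cbind(intercept = 1, x = rnorm(104), z = rnorm(104), w = rnorm(104))
  rownames(Xs) <- rownames(ys)
  fs <- fit_linear_models(ys, Xs)
  mps <- estimate_moderation(fs)
  expect_gt(mps$d0, 2.5); expect_lt(mps$d0, 6.5)
  expect_lt(abs(mps$s0_sq - 0.25) / 0.25, 0.15)
  sv <- limma::squeezeVar(fs$sigma2, fs$df_resid)
  expect_equal(mps$d0, sv$df.prior, tolerance = 0.05)
  expect_equal(mps$s0_sq, sv$var.prior, tolerance = 0.01)

  # tiny panels are flagged low-confidence
  f2 <- fit_linear_models(ys[, 1:2], Xs)
  expect_true(estimate_moderation(f2)$low_confidence)
})

test_that("moderated t has the right limits and matches the direct formula", {
  withr::with_seed(37, {
    n <- 30
    X <- cbind(intercept = 1, g = rbinom(n, 1, 0.5))
    y <- matrix(rnorm(n * 20), n, 20,
                dimnames = list(paste0("s", 1:n), paste0("P", 1:20)))
  })
  rownames(X) <- rownames(y)
  fits <- fit_linear_models(y, X)

  # d0 = 0: classical OLS t and p, to 1e-10 relative error
  tab0 <- moderate(fits, list(d0 = 0, s0_sq = 1), coef = "g")
  for (j in 1:20) {
    ref <- summary(lm(y[, j] ~ X[, "g"]))$coefficients
    expect_equal(tab0$t_mod[j], ref["X[, \"g\"]", "t value"], tolerance = 1e-10)
    expect_equal(tab0$p[j], ref["X[, \"g\"]", "Pr(>|t|)"], tolerance = 1e-10)
  }

  # d0 = Inf: posterior variance collapses to the prior for every protein
  tabInf <- moderate(fits, list(d0 = Inf, s0_sq = 0.3), coef = "g")
  expect_equal(tabInf$s2_post, rep(0.3, 20))

  # finite d0: matches an independently coded per-protein shrinkage formula
  mp <- estimate_moderation(fits)
  tab <- moderate(fits, mp, coef = "g")
  for (j in 1:20) {
    s2p <- (mp$d0 * mp$s0_sq + fits$df_resid[j] * fits$sigma2[j]) /
      (mp$d0 + fits$df_resid[j])
    tstat <- fits$coefficients[j, "g"] / (fits$stdev_unscaled[j, "g"] * sqrt(s2p))
    expect_equal(tab$t_mod[j], unname(tstat), tolerance = 1e-12)
    expect_equal(tab$p[j],
                 2 * pt(-abs(tstat), df = mp$d0 + fits$df_resid[j])[[1]],
                 tolerance = 1e-12)
  }
})

test_that("moderated inference agrees with limma on a fixture", {
  skip_if_not_installed("limma")
  withr::with_seed(38, {
    n <- 40
    X <- cbind(intercept = 1, g = rbinom(n, 1, 0.5), age = rnorm(n))
    sigma2 <- 4 * 0.25 / rchisq(60, 4)
    y <- vapply(sigma2, function(s2) rnorm(n, sd = sqrt(s2)), numeric(n))
  })
  dimnames(y) <- list(paste0("s", 1:40), paste0("P", 1:60))
  rownames(X) <- rownames(y)
  fits <- fit_linear_models(y, X)
  tab <- moderate(fits, estimate_moderation(fits), coef = "g")
  lf <- limma::eBayes(limma::lmFit(t(y), X))
  expect_equal(tab$t_mod, unname(lf$t[, "g"]), tolerance = 1e-6)
  expect_equal(tab$p, unname(lf$p.value[, "g"]), tolerance = 1e-6)
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  withr::with_seed(39, {
    for (i in 1:10) {
      p <- runif(25)^2
      expect_equal(bh_fdr(p), bh_bruteforce(p))
    }
  })
  # permutation equivariance and monotonicity
  withr::with_seed(40, p <- runif(30))
  perm <- sample(30)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  expect_true(all(diff(bh_fdr(sort(p))) >= 0))
})

test_that("swapping cohort labels flips every log2 fold change exactly", {
  sim <- simulate_cohorts(sim_config(seed = 41, n_a = 60, n_b = 80,
                                     n_proteins = 20, outlier_frac = 0))
  de_ab <- run_de(sim$a, sim$b, sim$metadata)
  de_ba <- run_de(sim$b, sim$a, sim$metadata)
  ord <- match(de_ab$protein, de_ba$protein)
  expect_equal(de_ab$log2_fc, -de_ba$log2_fc[ord], tolerance = 1e-12)
  expect_equal(de_ab$p, de_ba$p[ord], tolerance = 1e-12)
})

test_that("run_de reports direction against the FDR gate and names missing covariates", {
  sim <- simulate_cohorts(sim_config(seed = 42, n_a = 60, n_b = 60,
                                     n_proteins = 15, outlier_frac = 0))
  de <- run_de(sim$a, sim$b, sim$metadata)
  expect_true(all(de$direction[de$fdr >= 0.05] == "ns"))
  expect_true(all(de$direction[de$fdr < 0.05 & de$log2_fc > 0] == "up"))
  cnt <- attr(de, "counts")
  expect_equal(sum(cnt), nrow(de))

  meta_bad <- sim$metadata
  meta_bad$bmi[meta_bad$cohort == "TZ"] <- NA
  expect_error(run_de(sim$a, sim$b, meta_bad), "bmi")
})

test_that("the paired contrast recovers a planted dietary-switch effect", {
  # post = pre exactly: beta 0, degenerate flag
  pre <- make_npx(matrix(rnorm(23 * 2), 23, 2), cohort = "pre")
  post <- pre
  pairing <- data.frame(pre = rownames(pre$values), post = rownames(post$values))
  pd <- paired_de(pre, post, pairing)
  expect_equal(pd$beta, c(0, 0))
  expect_true(all(pd$degenerate))
  expect_true(all(is.na(pd$p)))

  # planted -1.87 shift, n = 23, noise sd 0.3: recovered within 0.2
  withr::with_seed(43, {
    base <- matrix(rnorm(23 * 3, mean = 5), 23, 3)
    noise <- matrix(rnorm(23 * 3, sd = 0.3), 23, 3)
  })
  pre2 <- make_npx(base, cohort = "pre")
  post_v <- base + noise
  post_v[, 1] <- post_v[, 1] - 1.87
  post2 <- make_npx(post_v, cohort = "post")
  pd2 <- paired_de(pre2, post2, pairing)
  expect_lt(abs(pd2$beta[1] + 1.87), 0.2)
  expect_lt(pd2$p[1], 0.01)

  # reversing roles negates beta exactly (shared ids, so the map is valid)
  pd3 <- paired_de(post2, pre2, pairing)
  expect_equal(pd3$beta, -pd2$beta, tolerance = 1e-12)

  # unpaired ids are an error
  bad <- rbind(pairing, data.frame(pre = "ghost", post = "s01"))
  expect_error(paired_de(pre2, post2, bad), "ghost")
})
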