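test_that("per-time-point ANOVA baseline matches aov and handles ties", {
  set.seed(61)
  g <- make_geno(matrix(c("A", "A", "A", "B", "B", "B"), ncol = 1))
  vals <- matrix(rnorm(6 * 3), 6, 3)
  e <- make_expr(vals, g$strain)
  # dual route: vectorised F against stats::aov at each time point
  for (tm in 1:3) {
    p_fast <- dyver:::two_group_anova_p(vals[, tm],
                                        dyver:::geno_matrix(g))
    df <- data.frame(y = vals[, tm], grp = factor(g$v01))
    p_aov <- summary(stats::aov(y ~ grp, df))[[1]][["Pr(>F)"]][1]
    expect_equal(unname(p_fast), p_aov, tolerance = 1e-10)
  }
  sc <- scan_naive(e, g)
  expect_equal(names(sc)[1:4], c("gene", "variant", "p", "bonf_p"))

  # identical group means: F = 0, p = 1
  e2 <- make_expr(matrix(c(1, 2, 3, 1, 2, 3), ncol = 1), g$strain)
  expect_equal(scan_naive(e2, g)$p, 1)
})

test_that("naive baseline recovers a strong constant effect", {
  set.seed(62)
  sim <- sim_collection("sustained", n_time = 6, effect_size = 2,
                        n_genes = 6, n_assoc = 6, n_strains = 40,
                        n_variants = 20)
  sc <- scan_naive(sim$expr, sim$geno)
  expect_gte(mean(sc$variant == sim$truth$variant), 0.8)
})

test_that("PCA baseline is rank-1 exact and sign-invariant", {
  set.seed(63)
  amp <- rnorm(12)
  prof <- c(1, 2, 3, 2.5)
  vals <- outer(amp, prof)  # rank-1 strains x times
  g <- make_geno(matrix(rep(c("A", "B"), 6), ncol = 1))
  G <- dyver:::geno_matrix(g)
  pc1 <- prcomp(vals, center = TRUE)$x[, 1]
  # PC1 scores are an affine map of the amplitudes: same ANOVA p
  expect_equal(unname(dyver:::two_group_anova_p(pc1, G)),
               unname(dyver:::two_group_anova_p(amp, G)), tolerance = 1e-8)
  expect_equal(unname(dyver:::two_group_anova_p(-pc1, G)),
               unname(dyver:::two_group_anova_p(pc1, G)), tolerance = 1e-12)

  e <- make_expr(vals, g$strain, times = 1:4)
  sc <- scan_pca(e, g)
  expect_equal(nrow(sc), 1)

  # strains with missing time points are excluded from the projection
  vals2 <- vals
  vals2[1, 2] <- NA
  sc2 <- scan_pca(make_expr(vals2, g$strain, times = 1:4), g)
  expect_false(identical(sc2$p, sc$p))
})

test_that("expression-dynamics F test matches the lm RSS oracle", {
  set.seed(64)
  g <- make_geno(cbind(c(rep("A", 4), rep("B", 4)),
                       rep(c("A", "B"), 4)))
  vals <- matrix(rnorm(8 * 4), 8, 4)
  e <- make_expr(vals, g$strain, times = c(0, 10, 20, 30))
  sc <- scan_expression_dynamics(e, g)
  long <- as.data.frame(e)
  long$grp <- factor(g$v01[match(long$strain, g$strain)])
  m0 <- stats::lm(value ~ time, long)
  m1 <- stats::lm(value ~ grp * time, long)
  p_lm <- stats::anova(m0, m1)[["Pr(>F)"]][2]
  G <- dyver:::geno_matrix(g)
  p_all <- purrr::map_dbl(c("v01", "v02"), function(v) {
    lg <- long
    lg$grp <- factor(g[[v]][match(lg$strain, g$strain)])
    stats::anova(stats::lm(value ~ time, lg),
                 stats::lm(value ~ grp * time, lg))[["Pr(>F)"]][2]
  })
  expect_equal(sc$p, min(p_all), tolerance = 1e-8)

  # mirror-identical groups: the genotype terms add nothing, p = 1
  g1 <- make_geno(matrix(c(rep("A", 4), rep("B", 4)), ncol = 1))
  sym <- rbind(vals[1:4, ], vals[1:4, ])
  e2 <- make_expr(sym, g1$strain, times = c(0, 10, 20, 30))
  sc2 <- scan_expression_dynamics(e2, g1)
  expect_gt(sc2$p, 0.999)
})

test_that("expression-dynamics detects linearly diverging alleles", {
  set.seed(65)
  sim <- sim_collection("linear", n_time = 9, effect_size = 1,
                        n_genes = 5, n_assoc = 5, n_strains = 40,
                        n_variants = 20)
  sc <- scan_expression_dynamics(sim$expr, sim$geno)
  expect_gte(mean(sc$variant == sim$truth$variant), 0.8)
  expect_lt(max(sc$bonf_p), 0.01)
})

test_that("outcome classification follows the variant-aware definitions", {
  truth <- tibble::tibble(gene = paste0("g", 1:5),
                          is_associated = c(TRUE, TRUE, TRUE, FALSE, FALSE),
                          variant = c("v1", "v2", "v3", NA, NA))
  perfect <- tibble::tibble(gene = paste0("g", 1:5),
                            variant = c("v1", "v2", "v3", "v9", "v9"),
                            bonf_p = c(1e-5, 1e-5, 1e-5, 1, 1))
  calls <- classify_outcomes(perfect, truth, alpha = 0.05)
  expect_equal(calls$call, c("TP", "TP", "TP", "TN", "TN"))

  # associated gene with a significant *wrong* variant is FP, not TP
  wrongv <- perfect
  wrongv$variant[1] <- "v7"
  expect_equal(classify_outcomes(wrongv, truth, 0.05)$call[1], "FP")

  # all-null predictor: associated genes become FN
  nullp <- perfect
  nullp$bonf_p <- 1
  expect_equal(classify_outcomes(nullp, truth, 0.05)$call,
               c("FN", "FN", "FN", "TN", "TN"))

  stranger <- rbind(perfect, tibble::tibble(gene = "gX", variant = "v1",
                                            bonf_p = 0.01))
  expect_error(classify_outcomes(stranger, truth, 0.05), "absent")

  conf <- eval_confusion(perfect, truth, 0.05)
  expect_equal(conf$sensitivity, 1)
  expect_equal(conf$specificity, 1)
})

test_that("random predictions have near-zero variant-aware sensitivity", {
  set.seed(66)
  truth <- tibble::tibble(gene = sprintf("g%03d", 1:200),
                          is_associated = rep(c(TRUE, FALSE), 100),
                          variant = ifelse(rep(c(TRUE, FALSE), 100),
                                           sprintf("v%03d",
                                                   sample(100, 200, TRUE)),
                                           NA))
  geno <- sim_genotypes(10, 100)
  rnd <- tibble::tibble(gene = truth$gene,
                        variant = sample(names(geno)[-1], 200, TRUE),
                        p = runif(200), bonf_p = runif(200))
  conf <- eval_confusion(rnd, truth, alpha = 1)
  expect_lte(conf$sensitivity, 0.05)
})

test_that("accuracy spans 0 for random to 1 for perfect predictions", {
  set.seed(67)
  truth <- tibble::tibble(gene = sprintf("g%03d", 1:100),
                          is_associated = c(rep(TRUE, 60), rep(FALSE, 40)),
                          variant = c(sprintf("v%03d", sample(50, 60, TRUE)),
                                      rep(NA, 40)))
  perfect <- tibble::tibble(gene = truth$gene, variant = truth$variant,
                            bonf_p = ifelse(truth$is_associated, 1e-8, 1))
  perfect$variant[!truth$is_associated] <- "v001"
  expect_equal(as.numeric(accuracy_auc(perfect, truth)), 1)

  rnd <- tibble::tibble(gene = truth$gene,
                        variant = sprintf("v%03d", sample(50, 100, TRUE)),
                        bonf_p = runif(100))
  expect_lte(as.numeric(accuracy_auc(rnd, truth)), 0.15)
  expect_error(accuracy_auc(perfect, truth, grid = 0.5), "2 points")
})

test_that("trapezoidal accuracy agrees with a dense-grid oracle", {
  set.seed(68)
  truth <- tibble::tibble(gene = sprintf("g%03d", 1:150),
                          is_associated = rep(c(TRUE, FALSE), 75),
                          variant = ifelse(rep(c(TRUE, FALSE), 75),
                                           sprintf("v%03d",
                                                   sample(20, 150, TRUE)),
                                           NA))
  noisy <- tibble::tibble(
    gene = truth$gene,
    variant = ifelse(!is.na(truth$variant) & runif(150) < 0.7,
                     truth$variant, sprintf("v%03d", sample(20, 150, TRUE))),
    bonf_p = ifelse(truth$is_associated, rbeta(150, 0.5, 5), runif(150)))
  a200 <- as.numeric(accuracy_auc(noisy, truth))
  a2k <- as.numeric(accuracy_auc(noisy, truth,
                                 grid = 10^seq(-6, 0, length.out = 2000)))
  expect_equal(a200, a2k, tolerance = 1e-3)
})

test_that("pattern error rates implement stringent and flexible matching", {
  scan <- tibble::tibble(gene = c("g1", "g2", "g3"),
                         variant = c("v1", "v2", "v3"),
                         pattern = c("LHHH", "LLHH", "LLHL"),
                         perm_p = c(0.001, 0.001, 0.5))
  truth <- tibble::tibble(gene = c("g1", "g2", "g3"),
                          variant = c("v1", "v2", "v3"),
                          pattern = c("LLHH", "LLHH", "LLHH"))
  # g3 is not significant: denominator is {g1, g2}
  strict <- two_state_error_rate(scan, truth, alpha = 0.01, "stringent")
  flex <- two_state_error_rate(scan, truth, alpha = 0.01, "flexible")
  expect_equal(as.numeric(strict), 0.5)  # g1 wrong timing, g2 exact
  expect_equal(as.numeric(flex), 0)      # LHHH collapses to LH, matches
  expect_equal(attr(strict, "n"), 2L)

  same <- scan
  same$pattern <- truth$pattern
  expect_equal(as.numeric(two_state_error_rate(same, truth, 0.01,
                                               "stringent")), 0)

  # flexible error can never exceed stringent error
  set.seed(69)
  for (i in 1:20) {
    pats <- sample_state_paths(30, 6)
    fits <- sample_state_paths(30, 6)
    sc <- tibble::tibble(gene = paste0("g", 1:30), variant = "v1",
                         pattern = fits, perm_p = 0.001)
    tr <- tibble::tibble(gene = paste0("g", 1:30), variant = "v1",
                         pattern = pats)
    expect_lte(as.numeric(two_state_error_rate(sc, tr, 0.01, "flexible")),
               as.numeric(two_state_error_rate(sc, tr, 0.01, "stringent")))
  }

  expect_warning(empty <- two_state_error_rate(scan, truth, 1e-9),
                 "undefined")
  expect_true(is.na(empty))
})
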