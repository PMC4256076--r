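test_that("self-comparison score reduces to the sequence-prior term", {
  set.seed(31)
  d <- make_effects(lapply(1:4, function(t) rnorm(20)))
  s <- dyver_score(d, d)
  # identical samples: emission terms cancel exactly, leaving one sequence
  # prior (bounded by T log 2); far below any real separation signal
  expect_lt(abs(s$score), 4 * log(2) + 0.5)
  expect_gt(s$score, -(4 * log(2) + 0.5))
})

test_that("a shifted observed-effect sample produces a dominant score", {
  set.seed(32)
  d <- make_effects(lapply(1:6, function(t)
    rnorm(30, ifelse(t > 3, 3, 0), 1)))
  b <- make_effects(lapply(1:6, function(t) rnorm(30)))
  s_alt <- dyver_score(d, b)$score
  s_null <- dyver_score(make_effects(lapply(1:6, function(t) rnorm(30))),
                        b)$score
  expect_gt(s_alt, s_null + 50)
  expect_error(dyver_score(d, d[0, ]), "panel")
})

test_that("permutation p-values use add-one smoothing and R's RNG", {
  set.seed(33)
  sim <- sim_collection("sustained", n_time = 6, effect_size = 3,
                        n_genes = 1, n_assoc = 1, n_strains = 20,
                        n_variants = 1)
  set.seed(133)
  p <- permutation_pvalue(sim$expr, sim$geno, "g0001",
                          sim$truth$variant[1], n_perm = 99)
  expect_equal(as.numeric(p), 1 / 100)  # observed beats all 99 permutations
  set.seed(133)
  p2 <- permutation_pvalue(sim$expr, sim$geno, "g0001",
                           sim$truth$variant[1], n_perm = 99)
  expect_identical(as.numeric(p), as.numeric(p2))

  # null gene: p is bounded away from 0 and at most 1
  set.seed(34)
  nullsim <- sim_collection("sustained", n_time = 6, effect_size = 0,
                            n_genes = 1, n_assoc = 0, n_strains = 20,
                            n_variants = 1)
  pn <- permutation_pvalue(nullsim$expr, nullsim$geno, "g0001", "v001",
                           n_perm = 49)
  expect_gte(as.numeric(pn), 1 / 50)
  expect_lte(as.numeric(pn), 1)
})

test_that("the scan reports the true variant with Bonferroni arithmetic", {
  set.seed(35)
  sim <- sim_collection("sustained", n_time = 9, effect_size = 1,
                        n_genes = 12, n_assoc = 12, n_strains = 50,
                        n_variants = 25)
  sc <- dyver_scan(sim$expr, sim$geno, n_perm = 99)
  expect_s3_class(sc, "dyver_scan")
  hits <- mean(sc$variant == sim$truth$variant)
  expect_gte(hits, 0.8)
  expect_equal(sc$bonf_p, pmin(1, sc$perm_p * sc$n_variants))
  expect_true(all(sc$perm_p >= 1 / 100 & sc$perm_p <= 1))
  expect_equal(nchar(sc$pattern[1]), 9L)
})

test_that("monomorphic variants are excluded from the tested count", {
  set.seed(36)
  geno <- sim_genotypes(20, 10)
  tbl <- tibble::as_tibble(geno)
  tbl$v003 <- "A"  # force monomorphic
  geno2 <- dyver:::new_dyver_geno(tbl, variant_positions(geno),
                                  attr(geno, "allele_codes"))
  sim <- sim_collection("sustained", n_time = 6, effect_size = 1,
                        n_genes = 2, n_assoc = 0, geno = geno2)
  sc <- dyver_scan(sim$expr, geno2, n_perm = 9)
  expect_equal(unique(sc$n_variants), 9L)
})

test_that("scores are invariant to per-time-point additive shifts", {
  set.seed(37)
  geno <- sim_genotypes(20, 5)
  vals <- matrix(rnorm(20 * 4), 20, 4)
  G <- dyver:::geno_matrix(geno)
  y0 <- dyver:::expr_matrix(make_expr(vals, geno$strain), "g1", geno$strain)
  y1 <- dyver:::expr_matrix(make_expr(vals + rep(rnorm(4, sd = 5),
                                                 each = 20),
                                      geno$strain), "g1", geno$strain)
  r0 <- dyver:::cpp_scan_gene(y0, G, 0.5, 0.5, 0L, 0L, 1e-8, 500L, 1e-6, 2L)
  r1 <- dyver:::cpp_scan_gene(y1, G, 0.5, 0.5, 0L, 0L, 1e-8, 500L, 1e-6, 2L)
  expect_equal(r0$score, r1$score, tolerance = 1e-6)
})

test_that("gene-level FDR follows Benjamini-Hochberg step-up", {
  sc <- tibble::tibble(gene = sprintf("g%03d", 1:100),
                       bonf_p = c(rep(0.001, 30), rep(1, 70)),
                       dynamic_p = runif(100))
  out <- gene_level_fdr(sc, q = 0.06)
  expect_equal(sum(out$fdr_pass), 30)
  expect_true(all(out$fdr_pass[1:30]))

  none <- gene_level_fdr(tibble::tibble(gene = "g", bonf_p = 1,
                                        dynamic_p = NA_real_), q = 0.06)
  expect_false(any(none$fdr_pass))

  # discoveries are monotone non-increasing as q decreases
  set.seed(38)
  ps <- tibble::tibble(gene = sprintf("g%03d", 1:200),
                       bonf_p = rbeta(200, 0.3, 3), dynamic_p = NA_real_)
  counts <- vapply(c(0.2, 0.1, 0.06, 0.01),
                   function(q) sum(gene_level_fdr(ps, q)$fdr_pass),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))

  # agreement with p.adjust as the independent route
  expect_equal(gene_level_fdr(ps, 0.1)$fdr_pass,
               p.adjust(ps$bonf_p, "BH") <= 0.1)
})

test_that("dynamic association score is a Welch t-test over state pools", {
  d_eq <- make_effects(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(dynamic_association_score(d_eq, "HL"), 1, tolerance = 1e-12)

  set.seed(39)
  h <- rnorm(50, 5, 0.5)
  l <- rnorm(50, 0, 0.5)
  d <- make_effects(list(l, h))
  p <- dynamic_association_score(d, "LH")
  expect_lt(p, 1e-10)
  # closed-form Welch statistic
  tstat <- (mean(h) - mean(l)) / sqrt(var(h) / 50 + var(l) / 50)
  df <- (var(h) / 50 + var(l) / 50)^2 /
    ((var(h) / 50)^2 / 49 + (var(l) / 50)^2 / 49)
  expect_equal(p, 2 * pt(abs(tstat), df, lower.tail = FALSE),
               tolerance = 1e-12)

  expect_true(is.na(dynamic_association_score(d, "HH")))
  expect_error(dynamic_association_score(d, "HLL"), "length")
})

test_that("pattern refits at a stronger penalty smooth the state path", {
  set.seed(40)
  sim <- sim_markov_collection(n_time = 9, n_genes = 6, n_strains = 50,
                               n_variants = 10)
  sc <- dyver_scan(sim$expr, sim$geno, n_perm = 19)
  re <- refit_patterns(sc, sim$expr, sim$geno, lambda = 0.01)
  n_trans <- function(p) sum(diff(utf8ToInt(p)) != 0)
  expect_true(all(vapply(re$pattern, n_trans, 1) <=
                    vapply(sc$pattern, n_trans, 1)))
  expect_equal(re$gene, sc$gene)
})

test_that("familywise permutation mode yields a calibrated gene p-value", {
  set.seed(41)
  sim <- sim_collection("sustained", n_time = 6, effect_size = 0,
                        n_genes = 3, n_assoc = 0, n_strains = 20,
                        n_variants = 8)
  sc <- dyver_scan(sim$expr, sim$geno, n_perm = 49, perm_variants = "all")
  expect_true(all(sc$fw_p >= sc$perm_p - 1e-12))
  expect_true(all(sc$fw_p <= 1))
})
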