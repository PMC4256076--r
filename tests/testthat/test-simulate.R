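test_that("genotype simulation is seed-reproducible with fair alleles", {
  set.seed(51)
  g1 <- sim_genotypes(50, 100)
  set.seed(51)
  g2 <- sim_genotypes(50, 100)
  expect_identical(as.data.frame(g1), as.data.frame(g2))

  frac <- vapply(names(g1)[-1], function(v) mean(g1[[v]] == "A"),
                 numeric(1))
  # Binomial(50, 0.5): P(fraction in [0.4, 0.6]) = 0.881, so the count out
  # of 100 variants exceeds qbinom(0.001, 100, 0.881) = 77
  expect_gte(sum(frac >= 0.4 & frac <= 0.6), 77)

  set.seed(52)
  tiny <- sim_genotypes(2, 200)
  poly <- mean(vapply(names(tiny)[-1],
                      function(v) length(unique(tiny[[v]])) == 2,
                      logical(1)))
  expect_gt(poly, 0.35)  # both alleles present at about half the variants
  expect_lt(poly, 0.65)
  expect_error(sim_genotypes(1, 5), "at least 2")
})

test_that("waveforms hit their anchors and threshold patterns", {
  ws <- waveform("sustained", n_time = 9, effect_size = 0.8)
  expect_equal(attr(ws, "pattern"), "LLLLHHHHH")
  expect_equal(ws$mu, 0.8 * plogis(0.5 * (1:9 - 4.5)))

  wl <- waveform("linear", n_time = 6, effect_size = 1)
  expect_equal(wl$mu[1], 0)
  expect_equal(wl$mu[6], 1)
  expect_equal(attr(wl, "pattern"), "LLLHHH")

  # short impulse: exactly l grid points above h/2
  wi <- waveform("impulse", n_time = 27, effect_size = 0.625,
                 impulse_length = 5)
  expect_equal(sum(wi$state == "H"), 5)
  expect_equal(max(wi$mu), 0.625)
  wi15 <- waveform("impulse", n_time = 27, effect_size = 0.625,
                   impulse_length = 15)
  expect_equal(sum(wi15$state == "H"), 15)
  expect_error(waveform("impulse", n_time = 9, effect_size = 1,
                        impulse_length = 9), "shorter")

  wc <- waveform("complex", n_time = 12, effect_size = 1)
  expect_equal(nrow(wc), 12)
  expect_gte(sum(rle(wc$state)$values == "H"), 2)  # two pulses

  # zero effect size: everything low
  w0 <- waveform("sustained", n_time = 6, effect_size = 0)
  expect_equal(attr(w0, "pattern"), "LLLLLL")
})

test_that("collections carry the declared truth composition", {
  set.seed(53)
  sim <- sim_collection("sustained", n_time = 3, effect_size = 0.5)
  expect_equal(nrow(sim$truth), 500)
  expect_equal(sum(sim$truth$is_associated), 300)
  expect_true(all(is.na(sim$truth$variant[!sim$truth$is_associated])))
  expect_equal(nrow(sim$geno), 50)
  expect_equal(ncol(sim$geno) - 1, 100)
  expect_equal(nrow(sim$expr), 500 * 50 * 3)
  expect_error(sim_collection("sustained", 3, 1, n_genes = 5, n_assoc = 6),
               "exceed")
})

test_that("mean observed effects trace the waveform within 3 SE", {
  set.seed(54)
  sim <- sim_collection("sustained", n_time = 6, effect_size = 1,
                        n_genes = 2, n_assoc = 2, n_strains = 100,
                        n_variants = 4)
  for (i in 1:2) {
    d <- observed_effects(sim$expr, sim$geno, sim$truth$variant[i],
                          sim$truth$gene[i])
    sp <- split_by_allele(sim$geno, sim$truth$variant[i])
    n_a <- sum(sp$allele == "A")
    n_b <- sum(sp$allele == "B")
    se <- sqrt(1 / n_a + 1 / n_b)
    m <- tapply(d$effect, d$time, mean)
    expect_true(all(abs(m - sim$curve$mu) < 3 * se))
  }
})

test_that("Markov-prior paths have the right transition statistics", {
  set.seed(55)
  paths <- sample_state_paths(10000, 9, lambda = 0.3)
  trans <- vapply(strsplit(paths, ""),
                  function(s) sum(s[-1] != s[-9]), numeric(1))
  freq <- mean(trans) / 8
  expect_lt(abs(freq - 0.3), 3 * sqrt(0.3 * 0.7 / (8 * 10000)))

  half <- sample_state_paths(5000, 9, lambda = 0.5)
  t2 <- vapply(strsplit(half, ""), function(s) sum(s[-1] != s[-9]),
               numeric(1))
  expect_equal(mean(t2), 4, tolerance = 0.1)  # (T - 1) / 2

  frozen <- sample_state_paths(2000, 9, lambda = 0.01)
  expect_gte(mean(!grepl("HL|LH", frozen)), 0.88)  # (1 - .01)^8 = 0.92
})

test_that("the Markov collection embeds its sampled paths as truth", {
  set.seed(56)
  sim <- sim_markov_collection(n_time = 5, n_genes = 4, mu_H = 2,
                               n_strains = 40, n_variants = 5)
  expect_true(all(nchar(sim$truth$pattern) == 5))
  i <- which(grepl("H", sim$truth$pattern) &
               grepl("L", sim$truth$pattern))[1]
  d <- observed_effects(sim$expr, sim$geno, sim$truth$variant[i],
                        sim$truth$gene[i])
  m <- tapply(d$effect, d$time, mean)
  s <- strsplit(sim$truth$pattern[i], "")[[1]]
  expect_gt(mean(m[s == "H"]), mean(m[s == "L"]))
})

test_that("missingness drops the stated share of strains per time point", {
  set.seed(57)
  sim <- sim_collection("sustained", n_time = 4, effect_size = 1,
                        n_genes = 2, n_assoc = 1, n_strains = 50,
                        n_variants = 5)
  expect_identical(apply_missingness(sim, 0), sim)
  miss <- apply_missingness(sim, 60)
  per_tp <- table(miss$expr$time[miss$expr$gene == "g0001"])
  expect_true(all(per_tp == 20))  # 60% of 50 omitted -> 20 observed
  sets <- lapply(split(miss$expr$strain[miss$expr$gene == "g0001"],
                       miss$expr$time[miss$expr$gene == "g0001"]), sort)
  expect_gt(length(unique(sets)), 1)  # different strains missing per time
  expect_error(apply_missingness(sim, 100), "k_percent")

  # the scan still runs on incomplete data
  sc <- dyver_scan(miss$expr, miss$geno, genes = "g0001", n_perm = 9)
  expect_equal(nrow(sc), 1)
})

test_that("collections round-trip through their TSV dumps", {
  set.seed(58)
  sim <- sim_collection("linear", n_time = 3, effect_size = 0.5,
                        n_genes = 4, n_assoc = 2, n_strains = 10,
                        n_variants = 5)
  dir <- withr::local_tempdir()
  write_collection(sim, dir)
  g <- read_genotype_table(file.path(dir, "genotypes.tsv"),
                           positions = file.path(dir, "positions.tsv"))
  expect_equal(as.data.frame(g), as.data.frame(sim$geno))
  e <- read_expression_table(file.path(dir, "expression.tsv"))
  expect_equal(nrow(e), nrow(sim$expr))
  tr <- readr::read_tsv(file.path(dir, "truth.tsv"), show_col_types = FALSE)
  expect_equal(tr$gene, sim$truth$gene)
  expect_equal(tr$pattern, sim$truth$pattern)
})

test_that("the grid generator covers the effect-size by time-point design", {
  set.seed(59)
  grid <- sim_grid("sustained", effect_sizes = c(0.25, 1),
                   time_points = c(3, 6), n_genes = 4, n_assoc = 2,
                   n_strains = 10, n_variants = 5)
  expect_equal(nrow(grid), 4)
  expect_equal(length(time_points(grid$collection[[2]]$expr)),
               grid$n_time[2])
})
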