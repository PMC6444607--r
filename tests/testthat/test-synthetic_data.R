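test_that("simulation_config validates its stated world", {
  cfg <- simulation_config()
  expect_equal(cfg$major_qtl_effects, c(-3, 3))
  spec <- cfg$dominance_spec
  expect_equal(spec$het[spec$type == "dominance"], 5.00)
  expect_equal(spec$hom2[spec$type == "dominance"], 5.01)
  expect_equal(spec$het[spec$type == "overdominance"], 5.00)
  expect_equal(spec$hom0[spec$type == "overdominance"], -0.01)
  expect_equal(spec$het[spec$type == "underdominance"], -5.00)
  expect_error(simulation_config(n_snps = 10, n_random_qtl = 28),
               "distinct loci")
  expect_error(simulation_config(maf_range = c(0, 0.5)))
})

test_that("genotypes follow Hardy-Weinberg proportions", {
  # fixed allele frequency 0.5: classes approach (0.25, 0.5, 0.25)
  g <- simulate_genotypes(simulation_config(
    n_individuals = 4000, n_snps = 5, maf_range = c(0.5, 0.5),
    n_random_qtl = 0, major_qtl_effects = numeric(),
    dominance_spec = data.frame(type = character(), het = numeric(),
                                hom0 = numeric(), hom2 = numeric()),
    seed = 8))
  n <- 4000
  for (j in 1:5) {
    freq <- tabulate(g$values[, j] + 1L, nbins = 3) / n
    se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / n)
    expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 3 * se))
  }
  # mean genotype ~ 2 * MAF at p = 0.3
  g3 <- simulate_genotypes(simulation_config(
    n_individuals = 10000, n_snps = 3, maf_range = c(0.3, 0.3),
    n_random_qtl = 0, major_qtl_effects = numeric(),
    dominance_spec = data.frame(type = character(), het = numeric(),
                                hom0 = numeric(), hom2 = numeric()),
    seed = 9))
  se_mean <- sqrt(2 * 0.3 * 0.7 / 10000)
  expect_true(all(abs(colMeans(g3$values) - 0.6) < 3 * se_mean))
})

test_that("random QTL effects respect the truncation bound", {
  cfg <- simulation_config(n_individuals = 10, n_snps = 1100,
                           n_random_qtl = 1000, seed = 12)
  truth <- assign_effects(cfg)
  rnd <- truth$a[truth$type == "random"]
  expect_length(rnd, 1000)
  expect_true(all(abs(rnd) < 2))
  expect_false(anyDuplicated(truth$locus) > 0)
  expect_equal(sort(truth$a[truth$type == "major"]), c(-3, 3))
})

test_that("phenotypes are exact locus sums when noiseless", {
  # single additive locus, effect 3
  cfg <- simulation_config(n_individuals = 50, n_snps = 20,
                           n_random_qtl = 0, major_qtl_effects = 3,
                           dominance_spec = data.frame(
                             type = character(), het = numeric(),
                             hom0 = numeric(), hom2 = numeric()),
                           seed = 4)
  G <- simulate_genotypes(cfg)
  truth <- assign_effects(cfg)
  y <- simulate_phenotypes(G, truth, noise_sd = 0, seed = 4)
  expect_equal(y, 3 * G$values[, truth$locus[1]])

  # single dominance locus: phenotype in {0, 5.00, 5.01} by class
  cfg_d <- simulation_config(n_individuals = 50, n_snps = 20,
                             n_random_qtl = 0,
                             major_qtl_effects = numeric(),
                             dominance_spec = data.frame(
                               type = "dominance", het = 5.00,
                               hom0 = 0, hom2 = 5.01),
                             seed = 5)
  G_d <- simulate_genotypes(cfg_d)
  truth_d <- assign_effects(cfg_d)
  y_d <- simulate_phenotypes(G_d, truth_d, noise_sd = 0, seed = 5)
  g <- G_d$values[, truth_d$locus[1]]
  expect_equal(y_d, c(0, 5.00, 5.01)[g + 1])
})

test_that("noise variance matches its nominal level", {
  cfg <- simulation_config(n_individuals = 10000, n_snps = 5,
                           n_random_qtl = 0,
                           major_qtl_effects = numeric(),
                           dominance_spec = data.frame(
                             type = character(), het = numeric(),
                             hom0 = numeric(), hom2 = numeric()),
                           seed = 21)
  G <- simulate_genotypes(cfg)
  truth <- assign_effects(cfg)
  y <- simulate_phenotypes(G, truth, noise_sd = 1, seed = 21)
  # var ~ chi2_{n-1}/(n-1): 3 standard errors of sampling spread
  expect_lt(abs(stats::var(y) - 1), 3 * sqrt(2 / (10000 - 1)))
})

test_that("datasets are a pure function of (config, seed)", {
  cfg <- simulation_config(n_individuals = 120, n_snps = 50, seed = 77)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$genotypes$values, s2$genotypes$values)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_dataset(simulation_config(n_individuals = 120,
                                           n_snps = 50, seed = 78))
  expect_false(identical(s1$genotypes$values, s3$genotypes$values))
})

test_that("default noise gives heritability near one half", {
  sim <- tiny_sim(n = 1500, p = 300, seed = 10)
  g_var <- stats::var(sim$phenotypes) - sim$noise_sd^2
  h2 <- g_var / stats::var(sim$phenotypes)
  expect_gt(h2, 0.35)
  expect_lt(h2, 0.65)
})

test_that("datasets round-trip through delimited text", {
  sim <- tiny_sim(n = 30, p = 12, seed = 2)
  dir <- withr::local_tempdir()
  write_dataset(sim, dir)
  suppressMessages(g <- read_genotypes(file.path(dir, "genotypes.tsv")))
  expect_equal(g$values, sim$genotypes$values)
  expect_equal(g$snp_ids, sim$genotypes$snp_ids)
  y <- read_phenotypes(file.path(dir, "phenotypes.tsv"))
  expect_equal(unname(y), sim$phenotypes)
})
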