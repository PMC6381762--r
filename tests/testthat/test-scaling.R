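# Summary statistics and demographic-unit scaling.

test_that("scale_estimates inverts the simulator parameterization exactly", {
  # theta_block = 2 * Ne_ref * mu * L: Ne_ref = 1e5, mu = 1e-9, L = 200
  theta <- 2 * 1e5 * 1e-9 * 200
  pars <- c(theta_block = theta, T_split = 2, c_x = 0.4, m = 0.576)
  cal <- calibration(mu = 1e-9, g = 3.5, block_len = 200)
  sc <- scale_estimates(pars, cal, model = model_grid()[["M3.3"]])
  expect_equal(sc$Ne_ref, 1e5)
  expect_equal(sc$Ne_V, 1e5)
  expect_equal(sc$Ne_B, 0.4 * 1e5)
  expect_equal(sc$T_split_generations, 2 * 2 * 1e5)
  expect_equal(sc$T_split_years, 2 * 2 * 1e5 * 3.5)
  # Nm into the recipient = c_V * Ne_ref * m / (2 Ne_ref) = m / 2
  expect_equal(sc$migrants_per_generation_Nm, 0.576 / 2)
  expect_equal(sc$migrants_per_generation_4Nm, 4 * 0.576 / 2)
  expect_identical(sc$gene_flow_direction, "B->V")
  # T_split = 0 gives zero years under any calibration
  pars0 <- c(theta_block = theta, T_split = 0, c_x = 1, m = 0)
  expect_equal(scale_estimates(pars0, cal,
                               model = model_grid()[["M3.3"]])$T_split_years, 0)
})

test_that("split-time scaling is linear in g and inverse in mu", {
  pars <- c(theta_block = 0.3, T_split = 1.7)
  model <- model_grid()[["M1.1"]]
  base <- scale_estimates(pars, calibration(1e-9, 3.5), model)
  for (g in c(1, 2, 7)) for (mu_fac in c(0.5, 1, 17.7)) {
    sc <- scale_estimates(pars, calibration(1e-9 * mu_fac, 3.5 * g), model)
    expect_equal(sc$T_split_years, base$T_split_years * g / mu_fac)
  }
  # the mechanism behind the published 1.15 vs 20.37 Mya pair: the same
  # dimensionless fit under mu = 1.77e-8 vs 1e-9 gives year scales in
  # ratio 17.7
  y1 <- scale_estimates(pars, calibration(1.77e-8, 3.5), model)$T_split_years
  y2 <- scale_estimates(pars, calibration(1e-9, 3.5), model)$T_split_years
  expect_equal(y2 / y1, 17.7)
})

test_that("mutation_rate_from_divergence is the documented arithmetic", {
  expect_equal(mutation_rate_from_divergence(0, 1e6)$mu, 0)
  expect_equal(mutation_rate_from_divergence(0.02, 2e7)$mu, 1e-9)
  expect_error(mutation_rate_from_divergence(0.02, 0))
  # consistency probe for the mitochondrial calibration: the total
  # separation implied by d = 6.19% at mu = 1.77e-8 is ~3.497e6 generations
  expect_equal(0.0619 / 1.77e-8, 3.497e6, tolerance = 1e-3)
})

test_that("diversity_stats computes pi, dxy and Hudson FST from a crafted VCF", {
  dir <- withr::local_tempdir()
  # 58 het_v + 44 het_b + 195 fixed over 20,000 callable sites reproduces
  # pi_V = 0.0029, pi_B = 0.0022, dxy = 0.0123
  df <- data.frame(chrom = "c1",
                   pos = seq_len(58 + 44 + 195),
                   ref = "A", alt = "G",
                   gt_v = c(rep("0/1", 58), rep("0/0", 44), rep("1/1", 195)),
                   gt_b = c(rep("0/0", 58), rep("0/1", 44), rep("0/0", 195)))
  vcf <- write_test_vcf(df, file.path(dir, "d.vcf"))
  st <- diversity_stats(vcf, callable_sites = 20000)
  expect_equal(st$pi_V, 0.0029)
  expect_equal(st$pi_B, 0.0022)
  expect_equal(st$dxy, (0.5 * (58 + 44) + 195) / 20000)  # = 0.0123
  expect_equal(st$fst, 1 - mean(c(0.0029, 0.0022)) / 0.0123)  # ~0.7927
  expect_equal(st$fst, 0.792683, tolerance = 1e-6)
  st2 <- diversity_stats(vcf, 20000, fst_estimator = "dxy_ratio")
  expect_equal(st2$fst, (0.0123 - 0.00255) / (0.0123 + 0.00255))
  # a single het_v site contributes 2/4 = 0.5 to its dxy term
  one <- write_test_vcf(df[1, ], file.path(dir, "one.vcf"))
  expect_equal(diversity_stats(one, 100)$dxy, 0.5 / 100)
  # no divergence -> FST undefined
  inv <- write_test_vcf(df[0, ], file.path(dir, "inv.vcf"))
  expect_true(is.na(diversity_stats(inv, 100)$fst))
})

test_that("simulated fixtures reproduce the generating diversity within 3 SE", {
  div <- demography_model(type = "DIV", T_split = 1.5)
  theta <- 0.3; n <- 1500; L <- 200
  dir <- withr::local_tempdir()
  fx <- simulate_genotype_fixture(sim_config(div, theta, n, L, seed = 140),
                                  file.path(dir, "s.vcf"),
                                  file.path(dir, "s.bed"),
                                  file.path(dir, "s.fa"))
  st <- diversity_stats(file.path(dir, "s.vcf"), callable_sites = n * L)
  het_sites <- fx$spectra[, "het_v"] + fx$spectra[, "shared_het"]
  se_pi <- sd(het_sites) / sqrt(n) / L
  expect_lt(abs(st$pi_V - 2 * theta / L), 3 * se_pi)
  dxy_blocks <- 0.5 * (fx$spectra[, "het_v"] + fx$spectra[, "het_b"] +
                         fx$spectra[, "shared_het"]) + fx$spectra[, "fixed_diff"]
  se_dxy <- sd(dxy_blocks) / sqrt(n) / L
  expect_lt(abs(st$dxy - 2 * theta * (1.5 + 1) / L), 3 * se_dxy)
})

test_that("generation_length is the fecundity-weighted mean mother age", {
  expect_equal(generation_length(data.frame(age = 3, n_females = 10,
                                            fecundity = 8.5)), 3)
  # first-time breeders lay 8.5 eggs, older females 11.1
  two <- data.frame(age = c(3, 5), n_females = c(10, 10),
                    fecundity = c(8.5, 11.1))
  expect_equal(generation_length(two), (3 * 85 + 5 * 111) / (85 + 111))
  expect_equal(generation_length(two), 810 / 196)
  # scale invariance and range
  two2 <- two; two2$n_females <- two2$n_females * 2
  expect_equal(generation_length(two2), generation_length(two))
  expect_gte(generation_length(two), min(two$age))
  expect_lte(generation_length(two), max(two$age))
  expect_error(generation_length(data.frame(age = 3, n_females = 0,
                                            fecundity = 0)), "weights")
})
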