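test_that("parameter validation rejects out-of-range settings", {
  expect_error(sim_params(maf_range = c(0, 0.5)), class = "prsinteract_param_error")
  expect_error(sim_params(ld_rho = 1), class = "prsinteract_param_error")
  expect_error(sim_params(exposure_probs = c(0.5, 0.5, 0, 0, 0.1)),
               class = "prsinteract_param_error")
  expect_error(sim_params(missing_rate = -0.1), class = "prsinteract_param_error")
  expect_error(sim_params(gwas_n = 5), class = "prsinteract_param_error")
  expect_error(sim_params(gec_rho = 1.5), class = "prsinteract_param_error")
})

test_that("allele frequencies match the generating MAF", {
  p <- sim_params(n_individuals = 1000, n_variants = 30,
                  maf_range = c(0.5, 0.5), ld_rho = 0, missing_rate = 0,
                  seed = 7)
  g <- simulate_genotypes(p)
  af <- colMeans(g$dosages) / 2
  se3 <- 3 * sqrt(0.5 * 0.5 / (2 * 1000))
  expect_true(all(abs(af - 0.5) < se3 + 0.01))
})

test_that("block LD produces the calibrated dosage correlation", {
  p <- sim_params(n_individuals = 5000, n_variants = 2, ld_block_size = 2,
                  ld_rho = 0.9, maf_range = c(0.2, 0.4), missing_rate = 0,
                  seed = 11)
  g <- simulate_genotypes(p)
  r <- cor(g$dosages[, 1], g$dosages[, 2])
  expect_gt(r, 0.6)  # Monte-Carlo calibration: latent 0.9 -> dosage 0.66-0.71
  p0 <- sim_params(n_individuals = 5000, n_variants = 2, ld_block_size = 2,
                   ld_rho = 0, missing_rate = 0, seed = 11)
  g0 <- simulate_genotypes(p0)
  expect_lt(abs(cor(g0$dosages[, 1], g0$dosages[, 2])), 0.05)
})

test_that("missingness honours missing_rate", {
  p0 <- sim_params(n_individuals = 300, n_variants = 40, missing_rate = 0, seed = 2)
  expect_false(anyNA(simulate_genotypes(p0)$dosages))
  p1 <- sim_params(n_individuals = 500, n_variants = 40, missing_rate = 0.1, seed = 2)
  expect_equal(mean(is.na(simulate_genotypes(p1)$dosages)), 0.1, tolerance = 0.1)
})

test_that("genotypes are in HWE by construction", {
  p <- sim_params(n_individuals = 800, n_variants = 200, ld_rho = 0,
                  missing_rate = 0, seed = 13)
  g <- simulate_genotypes(p)
  pvals <- apply(g$dosages, 2, function(d) {
    tab <- tabulate(round(d) + 1L, nbins = 3L)
    hwe_exact_test(tab[1], tab[2], tab[3])
  })
  expect_gte(mean(pvals > 0.001), 0.99)
})

test_that("simulation is deterministic under a fixed seed", {
  p <- sim_params(n_individuals = 150, n_variants = 30, seed = 42)
  g1 <- simulate_genotypes(p); g2 <- simulate_genotypes(p)
  expect_identical(g1, g2)
  s1 <- simulate_gwas_sumstats(g1$variants, p)
  s2 <- simulate_gwas_sumstats(g2$variants, p)
  expect_identical(s1, s2)
  c1 <- simulate_cohort_phenotypes(g1, s1$true_beta, p)
  c2 <- simulate_cohort_phenotypes(g2, s2$true_beta, p)
  expect_identical(c1, c2)
})

test_that("null GWAS gives uniform p-values and zero effects", {
  p <- sim_params(n_individuals = 100, n_variants = 2000, causal_fraction = 0,
                  seed = 5)
  g <- simulate_genotypes(p)
  gw <- simulate_gwas_sumstats(g$variants, p)
  expect_true(all(gw$true_beta == 0))
  frac <- mean(gw$sumstats$P < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))

  p0 <- sim_params(n_individuals = 100, n_variants = 500, causal_fraction = 1,
                   effect_sd = 0, seed = 5)
  gw0 <- simulate_gwas_sumstats(simulate_genotypes(p0)$variants, p0)
  expect_true(all(gw0$true_beta == 0))
})

test_that("sumstats randomization produces strand-complemented records", {
  p <- sim_params(n_individuals = 50, n_variants = 200, seed = 9)
  g <- simulate_genotypes(p)
  gw <- simulate_gwas_sumstats(g$variants, p)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flipped <- gw$sumstats$A1 == comp[g$variants$alt] &
    gw$sumstats$A2 == comp[g$variants$ref]
  expect_gt(sum(flipped), 0)
})

test_that("intercept-only outcome prevalence matches logistic(beta0)", {
  b0 <- stats::setNames(rep(stats::qlogis(0.04), 4), pe_outcomes())
  p <- sim_params(n_individuals = 10000, n_variants = 20,
                  beta0 = b0,
                  beta_exposure = stats::setNames(rep(0, 4), pe_outcomes()),
                  beta_prs = 0,
                  beta_gxe = stats::setNames(rep(0, 4), pe_outcomes()),
                  covariate_spec = list(), pe_missing_rate = 0, seed = 3)
  g <- simulate_genotypes(p)
  gw <- simulate_gwas_sumstats(g$variants, p)
  co <- simulate_cohort_phenotypes(g, gw$true_beta, p)
  se3 <- 3 * sqrt(0.04 * 0.96 / 10000)
  for (o in pe_outcomes()) {
    expect_lt(abs(mean(co[[o]]) - 0.04), se3 + 0.002)
  }
})

test_that("liability-threshold prevalence and exposure independence hold", {
  p <- sim_params(n_individuals = 10000, n_variants = 100,
                  scz_prevalence = 0.05, gec_rho = 0, seed = 21)
  g <- simulate_genotypes(p)
  gw <- simulate_gwas_sumstats(g$variants, p)
  co <- simulate_cohort_phenotypes(g, gw$true_beta, p)
  se3 <- 3 * sqrt(0.05 * 0.95 / 10000)
  expect_lt(abs(mean(co$scz_status) - 0.05), se3)
  # gec_rho = 0: cannabis frequency uncorrelated with liability
  r <- cor(co$cannabis_freq, attr(co, "liability"))
  expect_lt(abs(r), 3 / sqrt(10000))
  # invariants: freq 0 iff never; onset only with an experience
  expect_true(all((co$cannabis_freq == 0) == (co$cannabis_ever == 0)))
  expect_true(all(is.na(co$onset_age[is.na(co$pe_any) | co$pe_any == 0])))
})

test_that("gene-environment correlation shifts exposure with liability", {
  p <- sim_params(n_individuals = 10000, n_variants = 100, gec_rho = 0.4,
                  seed = 22)
  g <- simulate_genotypes(p)
  gw <- simulate_gwas_sumstats(g$variants, p)
  co <- simulate_cohort_phenotypes(g, gw$true_beta, p)
  expect_gt(cor(co$cannabis_freq, attr(co, "liability")), 0.15)
})
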