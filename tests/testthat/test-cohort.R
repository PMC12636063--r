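test_that("genotypes follow Hardy-Weinberg and the INFO model", {
  vt <- variant_table(1, maf = 0.25)
  spec <- cohort_spec(n = 10000, variants = vt, dosage_noise_sd = 0,
                      seed = 2)
  g <- simulate_genotypes(spec)
  counts <- table(factor(g$hardcall[, 1], levels = 0:2)) / spec$n
  hwe <- c((1 - 0.25)^2, 2 * 0.25 * 0.75, 0.25^2)
  se <- sqrt(hwe * (1 - hwe) / spec$n)
  expect_true(all(abs(as.numeric(counts) - hwe) < 3 * se))
  expect_equal(g$annotations$info[1], 1, tolerance = 0.05)
  expect_lt(abs(g$annotations$eaf[1] - 0.25),
            3 * sqrt(0.25 * 0.75 / (2 * spec$n)))

  # noisy dosages deflate INFO below the QC cutoff
  spec_noisy <- cohort_spec(n = 5000, variants = vt, dosage_noise_sd = 0.5,
                            seed = 2)
  gn <- simulate_genotypes(spec_noisy)
  expect_lt(gn$annotations$info[1], 0.9)
  expect_true(all(gn$dosage >= 0 & gn$dosage <= 2))

  expect_error(cohort_spec(variants = within(vt, maf <- 0.6)), "maf")
})

test_that("cohort generation is fully deterministic under a fixed seed", {
  spec <- cohort_spec(n = 300, variants = variant_table(5, seed = 4),
                      seed = 11)
  a <- simulate_genotypes(spec)
  b <- simulate_genotypes(spec)
  expect_identical(a, b)
  ta <- simulate_diet_disease(a, simulate_traits(a, spec), spec)
  tb <- simulate_diet_disease(b, simulate_traits(b, spec), spec)
  expect_identical(ta, tb)
  spec2 <- cohort_spec(n = 300, variants = variant_table(5, seed = 4),
                       seed = 12)
  expect_false(identical(simulate_genotypes(spec2), a))
})

test_that("trait fraction triplets always sum to one", {
  spec <- cohort_spec(n = 500, variants = variant_table(10, seed = 3),
                      seed = 7)
  g <- simulate_genotypes(spec)
  tr <- simulate_traits(g, spec)
  for (depot in c("sat", "vat")) {
    sums <- tr[[paste0(depot, "_fsfa")]] + tr[[paste0(depot, "_fmufa")]] +
      tr[[paste0(depot, "_fpufa")]]
    expect_true(all(abs(sums - 1) < 1e-9))
  }
  # depot baselines show through the means
  expect_gt(mean(tr$vat_fsfa), mean(tr$sat_fsfa))
})

test_that("planted depot effects are detected at the analytic power", {
  # one variant, beta_sat = -0.1 latent-SD per allele, maf 0.2, n = 5000;
  # the normal-approximation oracle gives power ~0.69 at alpha = 5e-4
  vt <- variant_table(1, maf = 0.2, beta_sat = -0.1, seed = 5)
  hits <- vapply(1:200, function(r) {
    spec <- cohort_spec(n = 5000, variants = vt, seed = 1000 + r)
    g <- simulate_genotypes(spec)
    tr <- simulate_traits(g, spec)
    y <- inverse_normal_transform(tr$sat_fsfa)
    a <- gwas_scan(g$dosage, y)
    a$p[1] < 5e-4
  }, TRUE)
  expect_equal(mean(hits), 0.69, tolerance = 0.12)
})

test_that("disease prevalence matches the model's analytic expectation", {
  vt <- variant_table(1, maf = 0.3, seed = 8)
  disease <- list(list(name = "cvd", prevalence = 0.10, beta_g = 0.2,
                       beta_diet = 0.15, gamma = 0.1, diet = "sfa",
                       variant = 1L, beta_age = 0, beta_sex = 0))
  spec <- cohort_spec(n = 50000, variants = vt, dosage_noise_sd = 0,
                      disease = disease, seed = 13)
  g <- simulate_genotypes(spec)
  tr <- simulate_diet_disease(g, simulate_traits(g, spec), spec)

  gbar <- 2 * 0.3
  hwe <- c((1 - 0.3)^2, 2 * 0.3 * 0.7, 0.3^2)
  expected <- sum(vapply(0:2, function(gg) {
    hwe[gg + 1] * integrate(function(z) {
      plogis(qlogis(0.10) + 0.2 * (gg - gbar) +
               (0.15 + 0.1 * (gg - gbar)) * z) * dnorm(z)
    }, -8, 8)$value
  }, 0))
  expect_equal(mean(tr$cvd), expected, tolerance = 0.02)
})

test_that("a null interaction coefficient is estimated as centred on zero", {
  ests <- vapply(1:60, function(r) {
    vt <- variant_table(1, maf = 0.3, seed = 6)
    spec <- cohort_spec(n = 1000, variants = vt, disease = list(
      list(name = "cvd", prevalence = 0.2, beta_g = 0.1, beta_diet = 0.1,
           gamma = 0, diet = "sfa", variant = 1L, beta_age = 0.02,
           beta_sex = 0.2)), seed = 3000 + r)
    g <- simulate_genotypes(spec)
    tr <- simulate_diet_disease(g, simulate_traits(g, spec), spec)
    interaction_logistic(tr$cvd, g$dosage[, 1], tr$diet_sfa_std, tr$age,
                         tr$sex)$gamma_hat
  }, 0)
  expect_lt(abs(mean(ests)), 3 * sd(ests) / sqrt(length(ests)))
})

test_that("LD-block genotypes decay in r2 and respect allele frequency", {
  G <- simulate_ld_genotypes(4000, 10, maf = 0.3, rho = 0.9, seed = 21)
  expect_true(all(G %in% 0:2))
  expect_equal(mean(G) / 2, 0.3, tolerance = 0.02)
  r2 <- cor(G)^2
  adj <- mean(r2[cbind(1:9, 2:10)])
  far <- r2[1, 10]
  expect_gt(adj, 0.3)   # thresholding attenuates the latent rho^2
  expect_lt(far, adj)
  expect_identical(G, simulate_ld_genotypes(4000, 10, maf = 0.3,
                                            rho = 0.9, seed = 21))
})
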