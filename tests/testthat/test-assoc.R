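test_that("inverse normal transform follows the Blom formula", {
  z <- inverse_normal_transform(c(1, 2, 3))
  z3 <- qnorm((3 - 3 / 8) / (3 + 1 / 4))
  expect_equal(z, c(-z3, 0, z3))
  expect_equal(z3, 0.869423773289, tolerance = 1e-10)

  # rank equivariance under permutation
  set.seed(51)
  x <- rexp(100)
  perm <- sample(100)
  expect_equal(inverse_normal_transform(x)[perm],
               inverse_normal_transform(x[perm]))

  # near-zero mean for tie-free input; ties get average ranks
  y <- rnorm(1000)
  expect_lt(abs(mean(inverse_normal_transform(y))), 1e-6)
  zt <- inverse_normal_transform(c(5, 5, 1))
  expect_equal(zt[1], zt[2])

  expect_error(inverse_normal_transform(rep(3, 10)), "degenerate")
  expect_error(inverse_normal_transform(2), "2 finite")

  # output of any continuous input passes a normality check
  ks <- ks.test(inverse_normal_transform(rexp(1000)), "pnorm")
  expect_gt(ks$p.value, 0.01)
})

test_that("variant QC uses strict MAF and INFO cutoffs", {
  tab <- data.frame(eaf = c(0.01, 0.2, 0.011, 0.2, 0.5),
                    info = c(0.95, 0.90, 0.95, 0.89, 0.95))
  kept <- filter_variants(tab)
  expect_equal(rownames(kept), c("3", "5"))  # maf == 0.01 and info <= 0.9 fail

  # constructed table: 20 fail MAF, 20 fail INFO, 5 overlap -> 65 retained
  n <- 100
  eaf <- rep(0.3, n); info <- rep(0.99, n)
  eaf[1:20] <- 0.005
  info[16:35] <- 0.5
  tab2 <- data.frame(eaf = eaf, info = info)
  kept2 <- filter_variants(tab2)
  expect_equal(nrow(kept2), 65)
  expect_equal(unname(attr(kept2, "filter_counts")["retained"]), 65)

  expect_error(filter_variants(data.frame(eaf = 0.2)), "info")
})

test_that("OLS engine matches closed forms and stats::lm exactly", {
  set.seed(61)
  n <- 400
  g <- rbinom(n, 2, 0.3) + rnorm(n, 0, 0.05)
  y <- 0.2 * g + rnorm(n)

  # no covariates: beta = cov(g, y) / var(g)
  a <- linear_assoc(g, y)
  expect_equal(a$beta, cov(g, y) / var(g), tolerance = 1e-12)

  # with covariates: agreement with lm at 1e-10
  cov_df <- data.frame(age = rnorm(n, 60, 5), sex = rbinom(n, 1, 0.5),
                       centre = factor(sample(1:3, n, TRUE)))
  a2 <- linear_assoc(g, y, cov_df)
  fit <- lm(y ~ age + sex + centre + g, data = cbind(cov_df, g = g, y = y))
  expect_equal(a2$beta, unname(coef(fit)["g"]), tolerance = 1e-10)
  expect_equal(a2$se, unname(sqrt(diag(vcov(fit)))["g"]), tolerance = 1e-10)

  # the vectorised scan reproduces per-variant lm fits
  G <- cbind(g, rbinom(n, 2, 0.4), rbinom(n, 2, 0.15))
  scan <- gwas_scan(G, y, cov_df)
  for (j in 1:3) {
    fj <- lm(y ~ age + sex + centre + gj,
             data = cbind(cov_df, gj = G[, j], y = y))
    expect_equal(scan$beta[j], unname(coef(fj)["gj"]), tolerance = 1e-10)
    expect_equal(scan$se[j], unname(sqrt(diag(vcov(fj)))["gj"]),
                 tolerance = 1e-10)
  }

  expect_error(linear_assoc(g, y, data.frame(x1 = g, x2 = g)), "collinear")
})

test_that("Cochran's Q reproduces the worked two-depot example", {
  mk <- function(beta, se) list(beta = beta, se = se)
  h <- cochran_q(mk(0.1, 0.05), mk(-0.1, 0.05))
  expect_equal(h$q, 8)
  expect_equal(h$df, 1)
  expect_equal(h$het_pval, 0.004677735, tolerance = 1e-6)
  expect_equal(h$i_squared, 87.5)
  expect_true(h$depot_specific)

  h0 <- cochran_q(mk(0.25, 0.1), mk(0.25, 0.2))
  expect_equal(h0$q, 0)
  expect_equal(h0$i_squared, 0)
  expect_false(h0$depot_specific)

  # flag rule needs both conditions
  hb <- cochran_q(mk(0.1, 0.07), mk(-0.1, 0.07))  # Q ~ 4.08, I2 ~ 75.5
  expect_true(hb$het_pval < 0.05)
  expect_identical(hb$depot_specific, hb$i_squared > 75)

  # Q invariant under a simultaneous allele flip
  hf <- cochran_q(mk(-0.1, 0.05), mk(0.1, 0.05))
  expect_equal(hf$q, h$q)

  expect_error(cochran_q(list(beta = 1, se = 1, ea = "A", oa = "G",
                              rsid = "rs1"),
                         list(beta = 1, se = 1, ea = "G", oa = "A",
                              rsid = "rs1")),
               "harmonize")
})

test_that("inverse-variance meta-analysis matches hand arithmetic", {
  m <- ivw_meta(c(0.2, 0.0), c(0.1, 0.1))
  expect_equal(m$beta, 0.1)
  expect_equal(m$se, 0.1 / sqrt(2), tolerance = 1e-12)

  m2 <- ivw_meta(c(0.3, 0.3), c(0.08, 0.08))
  expect_equal(m2$beta, 0.3)
  expect_equal(m2$se, 0.08 / sqrt(2))

  set.seed(71)
  ses <- runif(4, 0.05, 0.3)
  m3 <- ivw_meta(rnorm(4), ses)
  expect_lt(m3$se, min(ses))

  expect_warning(m1 <- ivw_meta(0.2, 0.1), "single study")
  expect_equal(m1$beta, 0.2)
})

test_that("IRLS logistic fit matches glm and direct likelihood maximisation", {
  set.seed(81)
  n <- 2000
  g <- rbinom(n, 2, 0.3)
  diet <- rnorm(n)
  age <- rnorm(n, 60, 7)
  sex <- rbinom(n, 1, 0.5)
  eta <- -1.5 + 0.2 * g + 0.1 * diet + 0.15 * g * diet + 0.01 * age +
    0.3 * sex
  y <- rbinom(n, 1, plogis(eta))

  res <- interaction_logistic(y, g, diet, age, sex)
  ref <- glm(y ~ g * diet + age + sex, family = binomial())
  expect_equal(res$gamma_hat, unname(coef(ref)["g:diet"]),
               tolerance = 1e-6)
  expect_equal(res$se, unname(sqrt(diag(vcov(ref)))["g:diet"]),
               tolerance = 1e-6)

  # independent direct maximisation of the log-likelihood
  X <- cbind(1, g, diet, g * diet, age, sex)
  nll_grad <- function(beta, X, y) {
    -as.vector(crossprod(X, y - plogis(as.vector(X %*% beta))))
  }
  opt <- optim(rep(0, 6), oracle_logistic_nll, gr = nll_grad, X = X, y = y,
               method = "BFGS", control = list(maxit = 1000,
                                               reltol = 1e-14))
  expect_equal(res$gamma_hat, opt$par[4], tolerance = 1e-6)

  expect_equal(nrow(res$stratified), 3)
  expect_true(all(res$stratified$lo95 <= res$stratified$beta_diet,
                  na.rm = TRUE))

  expect_error(interaction_logistic(rep(1, n), g, diet, age, sex),
               "both classes")
  ysep <- as.numeric(g > 0)  # perfectly separated outcome
  expect_error(interaction_logistic(ysep, g, rep(0, n), age, sex),
               "separation|singular")
})

test_that("significance thresholds reproduce the 17-test example and BH", {
  th <- significance_thresholds(17, 0.05)
  expect_equal(th$threshold, 0.05 / 17)
  expect_equal(th$rounded, 0.003)
  expect_equal(significance_thresholds(1, 0.05)$threshold, 0.05)
  expect_equal(bh_adjust(c(0.001, 0.02, 0.03, 0.8)),
               c(0.004, 0.04, 0.04, 0.8))
  expect_true(genome_wide_significant(5e-8))
  expect_false(genome_wide_significant(5.1e-8))
})

test_that("lead variant selection breaks ties deterministically", {
  tab <- data.frame(rsid = c("a", "b", "c", "d"),
                    bp = c(400, 300, 200, 100),
                    beta = c(0.5, -0.9, 0.9, 0.2),
                    p = c(0.01, 1e-6, 1e-6, 0.5))
  expect_equal(lead_variant(tab)$rsid, "c")  # tie in p -> |beta| tie -> low bp
  tab$beta[3] <- 0.1
  expect_equal(lead_variant(tab)$rsid, "b")
  expect_equal(lead_variant(tab[1, ])$rsid, "a")
})

test_that("null associations are calibrated", {
  set.seed(91)
  n <- 2000
  cover <- data.frame(age = rnorm(n, 60, 6), sex = rbinom(n, 1, 0.5))
  y <- rnorm(n)
  G <- vapply(runif(60, 0.05, 0.45), function(p) rbinom(n, 2, p),
              numeric(n))
  scan <- gwas_scan(G, y, cover)
  expect_gt(ks.test(scan$p, "punif")$p.value, 0.001)
  expect_lt(mean(abs(scan$beta / scan$se) > 3), 0.05)
})
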