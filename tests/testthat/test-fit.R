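test_that("fractions_from_ndb reproduces the printed fraction formulas", {
  f3 <- fractions_from_ndb(3)
  expect_equal(unlist(f3), c(f_sfa = 0.279, f_mufa = 0.442, f_pufa = 0.279))
  expect_equal(unlist(fractions_from_ndb(0)),
               c(f_sfa = 1, f_mufa = 0, f_pufa = 0))
  f1 <- fractions_from_ndb(1)
  expect_equal(f1$f_sfa, 0.6976667, tolerance = 1e-6)
  expect_equal(f1$f_pufa, 0.031)
  expect_error(fractions_from_ndb(6.5), "0, 6")
  expect_error(fractions_from_ndb(-0.1), "0, 6")

  x <- seq(0, 6, length.out = 200)
  fr <- fractions_from_ndb(x)
  expect_true(all(abs(fr$f_sfa + fr$f_mufa + fr$f_pufa - 1) < 1e-9))
  expect_true(all(fr$f_sfa >= 0 & fr$f_sfa <= 1 &
                    fr$f_mufa >= 0 & fr$f_mufa <= 1 &
                    fr$f_pufa >= 0 & fr$f_pufa <= 1))
})

test_that("noiseless single-voxel fits recover the generating parameters", {
  p <- acq_protocol()
  s <- simulate_signal(voxel_signal_params(10, 90, 40, tg_composition(2.5)),
                       p)
  f <- fit_voxel(s)
  expect_true(f$converged)
  expect_lt(abs(f$ndb - 2.5), 0.05)
  expect_lt(abs(f$fat_fraction - 0.9), 0.01)
  expect_lt(abs(f$r2star - 40), 1)
})

test_that("fitted ndb pins at the upper bound when the truth lies outside", {
  p <- acq_protocol()
  s <- simulate_signal(voxel_signal_params(5, 95, 40, tg_composition(8)), p)
  f <- fit_voxel(s)
  expect_equal(f$ndb, 6, tolerance = 1e-9)
})

test_that("water-only series yields negligible fitted fat fraction", {
  p <- acq_protocol()
  s <- simulate_signal(voxel_signal_params(100, 0, 20,
                                           tg_composition(2.5)), p)
  f <- fit_voxel(s)
  expect_lte(f$fat_fraction, 0.01)
})

test_that("degenerate series are rejected with informative errors", {
  p <- acq_protocol()
  expect_error(fit_voxel(rep(0, 10), p), "empty signal")
  expect_error(fit_voxel(c(1, NA, 3, 4, 5, 6, 7, 8, 9, 10), p),
               "non-finite")
  expect_error(fit_voxel(c(1, 2, 3), acq_protocol(echo_times = 1:3)),
               "5 echoes")
})

test_that("fits never leave the ndb box over random truths", {
  p <- acq_protocol()
  set.seed(31)
  for (i in 1:20) {
    truth_ndb <- runif(1, 0, 8)
    nm <- min(0.093 * truth_ndb^2, truth_ndb)
    s <- simulate_signal(
      voxel_signal_params(runif(1, 5, 60), runif(1, 40, 95),
                          runif(1, 10, 80),
                          tg_composition(truth_ndb, nmidb = nm)),
      p, noise_sd = 1, seed = i)
    f <- fit_voxel(s)
    expect_gte(f$ndb, 1)
    expect_lte(f$ndb, 6)
  }
})

test_that("full fit agrees with a brute-force 1-D ndb scan at fixed nuisance", {
  p <- acq_protocol()
  for (truth_ndb in c(1.7, 3.2, 4.9)) {
    s <- simulate_signal(
      voxel_signal_params(20, 80, 35, tg_composition(truth_ndb)), p)
    f <- fit_voxel(s)
    scan <- oracle_ndb_scan(s$values, 20, 80, 35, p$echo_times)
    expect_lt(abs(f$ndb - scan), 1e-3)
  }
})

test_that("fit_voxel agrees with an independent bounded least-squares solver", {
  skip_if_not_installed("minpack.lm")
  p <- acq_protocol()
  s <- simulate_signal(voxel_signal_params(25, 75, 45,
                                           tg_composition(3.1)), p,
                       noise_sd = 1, seed = 17)
  f <- fit_voxel(s)
  resid_fun <- function(th) {
    oracle_signal(th[1], th[2], th[3], th[4], p$echo_times) - s$values
  }
  nls <- minpack.lm::nls.lm(
    par = c(f$water, f$fat, f$ndb, f$r2star), fn = resid_fun,
    lower = c(0, 0, 1, 0), upper = c(1e4, 1e4, 6, 1000),
    control = minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14))
  expect_lt(abs(f$ndb - nls$par[3]), 1e-4)
  expect_lte(f$residual_ss, sum(resid_fun(nls$par)^2) + 1e-8)
})

test_that("fit_volume maps a constant-truth phantom to constant fractions", {
  p <- acq_protocol()
  g <- c(6L, 6L, 1L)
  mask <- array(TRUE, g)
  series <- simulate_signal(voxel_signal_params(10, 90, 40,
                                                tg_composition(2)), p)
  echoes <- array(rep(series$values, each = prod(g)), dim = c(g, 10))
  maps <- fit_volume(echoes, mask, p)
  target <- fractions_from_ndb(2)
  expect_true(all(abs(maps$f_sfa - target$f_sfa) < 1e-6))
  expect_equal(attr(maps, "convergence_rate"), 1)

  sums <- maps$f_sfa + maps$f_mufa + maps$f_pufa
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("fit_volume handles empty masks and shape mismatches", {
  p <- acq_protocol()
  echoes <- array(1, dim = c(4, 4, 1, 10))
  expect_warning(maps <- fit_volume(echoes, array(FALSE, c(4, 4, 1)), p),
                 "empty mask")
  expect_true(all(is.na(maps$ndb)))
  expect_error(fit_volume(echoes, array(TRUE, c(5, 5, 1)), p), "shape")
})

test_that("ndb error shrinks as acquisition noise decreases", {
  spec <- phantom_spec(grid = c(32L, 32L, 1L), seed = 12)
  truth <- make_phantom(spec)
  mask <- truth$sat_mask & !truth$rim_mask
  rmse <- vapply(c(4, 1, 0), function(ns) {
    echoes <- render_multiecho(truth, noise_sd = ns, seed = 5)
    maps <- fit_volume(echoes, mask)
    sqrt(mean((maps$ndb[mask] - truth$ndb[mask])^2, na.rm = TRUE))
  }, 0)
  expect_true(all(diff(rmse) < 0))
  expect_lt(rmse[3], 0.01)
})
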