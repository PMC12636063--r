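# Independent reference implementations used as oracles: plain-R direct
# summation over the nine-peak table and brute-force scans, kept separate
# from the package's computation paths.

oracle_shifts <- c(5.3, 5.2, 4.2, 2.75, 2.2, 2.0, 1.6, 1.3, 0.9)

oracle_protons <- function(ndb, nmidb, cl) {
  c(2 * ndb, 1, 4, 2 * nmidb, 6, 4 * (ndb - nmidb), 6,
    6 * (cl - 4) - 8 * ndb + 2 * nmidb, 9)
}

oracle_fat_modulation <- function(ndb, cl, te_ms, field = 1.5,
                                  water_ppm = 4.7,
                                  nmidb = 0.093 * ndb^2) {
  a <- oracle_protons(ndb, nmidb, cl)
  f_hz <- (oracle_shifts - water_ppm) * 42.577 * field
  sum(a * exp(1i * 2 * pi * f_hz * te_ms / 1000)) / sum(a)
}

oracle_signal <- function(water, fat, ndb, r2star, te_ms, cl = 17.4,
                          field = 1.5, water_ppm = 4.7) {
  vapply(te_ms, function(te) {
    Mod((water + fat * oracle_fat_modulation(ndb, cl, te, field,
                                             water_ppm)) *
          exp(-r2star * te / 1000))
  }, 0)
}

# Brute-force 1-D minimiser: residual sum of squares over an ndb grid with
# the other parameters held fixed.
oracle_ndb_scan <- function(y, water, fat, r2star, te_ms,
                            grid = seq(1, 6, by = 1e-4), cl = 17.4) {
  rss <- vapply(grid, function(nd) {
    sum((y - oracle_signal(water, fat, nd, r2star, te_ms, cl))^2)
  }, 0)
  grid[which.min(rss)]
}

# Negative log-likelihood of a logistic model, for direct-maximisation
# cross-checks of the IRLS fitter.
oracle_logistic_nll <- function(beta, X, y) {
  eta <- as.vector(X %*% beta)
  -sum(y * eta - log1p(exp(eta)))
}

default_tes <- c(2.38, 4.76, 7.15, 9.53, 11.91, 14.29, 16.67, 19.06,
                 21.44, 23.82)
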