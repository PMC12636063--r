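#' Phantom specification
#'
#' Parametric description of a synthetic abdominal slab: a subcutaneous-like
#' outer ring (SAT) and visceral-like interior blobs (VAT) on each slice,
#' with per-depot distributions for the ground-truth number of double bonds,
#' fat fraction and R2*. A one-voxel rim of each depot is deliberately
#' contaminated with water (partial-volume mixing) so that mask erosion has
#' something to remove.
#'
#' Default truth means place SAT at NDB 2.08 and VAT at NDB 1.94, the values
#' whose saturated-fat fractions are about 0.44 and 0.47 respectively,
#' typical of human subcutaneous and visceral fat.
#'
#' @param grid Integer triple, volume dimensions in voxels.
#' @param voxel_size Numeric triple, voxel edge lengths in mm.
#' @param sat Named list: `ndb_mean`, `ndb_sd`, `ff_mean`, `ff_sd`,
#'   `r2s_mean`, `r2s_sd` for the subcutaneous ring.
#' @param vat Same fields for the visceral blobs.
#' @param smooth Number of in-slice 3x3 box-smoothing passes applied to the
#'   truth noise fields (spatial coherence); 0 for white fields.
#' @param rim_mix Fraction of background water signal mixed into the signal
#'   of the 1-voxel partial-volume rim of each depot (in (0, 1)); the
#'   mixture has its own relaxation, so rim voxels deliberately violate the
#'   single-compartment fit model the way real depot edges do.
#' @param amplitude Total proton amplitude per tissue voxel (arbitrary
#'   units); water amplitude of background voxels is `0.4 * amplitude`.
#' @param noise_sd Per-channel complex acquisition noise SD used by
#'   [render_multiecho()] unless overridden there.
#' @param seed Integer seed; the phantom is deterministic given it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(96L, 96L, 6L),
                         voxel_size = c(2.5, 2.5, 6.0),
                         sat = list(ndb_mean = 2.08, ndb_sd = 0.15,
                                    ff_mean = 0.90, ff_sd = 0.04,
                                    r2s_mean = 40, r2s_sd = 8),
                         vat = list(ndb_mean = 1.94, ndb_sd = 0.15,
                                    ff_mean = 0.88, ff_sd = 0.04,
                                    r2s_mean = 45, r2s_sd = 8),
                         smooth = 1L,
                         rim_mix = 0.5,
                         amplitude = 100,
                         noise_sd = 1,
                         seed = 1L) {
  stopifnot(length(grid) == 3L, all(grid[1:2] >= 16), grid[3] >= 1,
            length(voxel_size) == 3L,
            all(voxel_size > 0), rim_mix > 0, rim_mix < 1,
            amplitude > 0, noise_sd >= 0)
  for (d in list(sat, vat)) {
    stopifnot(d$ndb_mean > 0, d$ndb_mean <= 6, d$ff_mean >= 0,
              d$ff_mean <= 1, d$r2s_mean >= 0)
  }
  structure(list(grid = as.integer(grid), voxel_size = voxel_size,
                 sat = sat, vat = vat, smooth = as.integer(smooth),
                 rim_mix = rim_mix, amplitude = amplitude,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# In-slice 3x3 box smoothing of a 2-D matrix (edge-replicated), k passes.
box_smooth2d <- function(m, k) {
  if (k <= 0) return(m)
  nx <- nrow(m); ny <- ncol(m)
  for (i in seq_len(k)) {
    xp <- m[c(1, 1:nx, nx), c(1, 1:ny, ny)]
    m <- (xp[1:nx, 1:ny] + xp[2:(nx + 1), 1:ny] + xp[3:(nx + 2), 1:ny] +
          xp[1:nx, 2:(ny + 1)] + xp[2:(nx + 1), 2:(ny + 1)] +
          xp[3:(nx + 2), 2:(ny + 1)] + xp[1:nx, 3:(ny + 2)] +
          xp[2:(nx + 1), 3:(ny + 2)] + xp[3:(nx + 2), 3:(ny + 2)]) / 9
  }
  m
}

# Smoothed standard-normal field over the grid, slice-wise smoothing.
smooth_normal_field <- function(grid, k) {
  arr <- array(rnorm(prod(grid)), dim = grid)
  if (k > 0) {
    for (z in seq_len(grid[3])) {
      s <- box_smooth2d(arr[, , z], k)
      arr[, , z] <- s / max(sd(s), 1e-12)
    }
  }
  arr
}

# Rim = mask voxels with at least one in-slice 4-neighbour outside the mask.
mask_rim <- function(mask) {
  rim <- array(FALSE, dim = dim(mask))
  nx <- dim(mask)[1]; ny <- dim(mask)[2]
  for (z in seq_len(dim(mask)[3])) {
    m <- mask[, , z]
    pad <- matrix(FALSE, nx + 2, ny + 2)
    pad[2:(nx + 1), 2:(ny + 1)] <- m
    inner <- pad[1:nx, 2:(ny + 1)] & pad[3:(nx + 2), 2:(ny + 1)] &
      pad[2:(nx + 1), 1:ny] & pad[2:(nx + 1), 3:(ny + 2)]
    rim[, , z] <- m & !inner
  }
  rim
}

#' Generate a phantom's ground-truth maps
#'
#' Builds disjoint SAT (outer annulus) and VAT (interior blob) masks on every
#' slice and draws the per-voxel truth fields from the spec's distributions.
#' The methylene-interrupted double-bond map is tied to the NDB map through
#' `0.093 * ndb^2` everywhere inside the masks.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `truth_maps`: arrays `ndb`, `nmidb`,
#'   `fat_fraction`, `r2star` (NA outside the depots), logical `sat_mask`,
#'   `vat_mask`, `rim_mask`, and the generating `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid
  cx <- (g[1] + 1) / 2; cy <- (g[2] + 1) / 2
  rmin <- min(g[1], g[2])
  xi <- matrix(seq_len(g[1]), g[1], g[2])
  yi <- matrix(seq_len(g[2]), g[1], g[2], byrow = TRUE)
  r <- sqrt((xi - cx)^2 + (yi - cy)^2)
  sat2d <- r >= 0.32 * rmin & r <= 0.42 * rmin
  blobs <- list(c(-0.12, -0.08, 0.10), c(0.13, 0.00, 0.08),
                c(-0.02, 0.13, 0.075))
  vat2d <- matrix(FALSE, g[1], g[2])
  for (b in blobs) {
    vat2d <- vat2d |
      (sqrt((xi - (cx + b[1] * rmin))^2 + (yi - (cy + b[2] * rmin))^2) <=
         b[3] * rmin)
  }
  vat2d <- vat2d & !sat2d
  if (!any(sat2d) || !any(vat2d)) stop("degenerate phantom geometry")
  sat_mask <- array(rep(sat2d, g[3]), dim = g)
  vat_mask <- array(rep(vat2d, g[3]), dim = g)

  with_seed(sub_seed(spec$seed, "phantom_truth"), {
    ndb <- array(NA_real_, g); ff <- array(NA_real_, g)
    r2s <- array(NA_real_, g)
    for (depot in c("sat", "vat")) {
      d <- spec[[depot]]
      msk <- if (depot == "sat") sat_mask else vat_mask
      ndb[msk] <- pmin(pmax(d$ndb_mean +
        d$ndb_sd * smooth_normal_field(g, spec$smooth)[msk], 0.3), 6)
      ff[msk] <- pmin(pmax(d$ff_mean +
        d$ff_sd * smooth_normal_field(g, spec$smooth)[msk], 0), 1)
      r2s[msk] <- pmax(d$r2s_mean +
        d$r2s_sd * smooth_normal_field(g, spec$smooth)[msk], 1)
    }
  })
  rim <- mask_rim(sat_mask) | mask_rim(vat_mask)
  structure(list(ndb = ndb, nmidb = 0.093 * ndb^2, fat_fraction = ff,
                 r2star = r2s, sat_mask = sat_mask, vat_mask = vat_mask,
                 rim_mask = rim, spec = spec),
            class = "truth_maps")
}

#' Render a phantom into a multi-echo magnitude volume
#'
#' Evaluates the voxel-wise forward model of [simulate_signal()] over the
#' whole grid: inside the depots, water and fat amplitudes follow the truth
#' fat fraction at the spec's total amplitude; outside, voxels carry a
#' water-only signal at 40% amplitude. Gaussian noise is applied on the real
#' and imaginary channels before taking the magnitude (Rician noise).
#'
#' @param truth A [make_phantom()] result.
#' @param protocol An [acq_protocol()].
#' @param noise_sd Per-channel noise SD; defaults to the spec's value.
#' @param seed Integer seed; defaults to the spec's seed.
#' @param cl Mean chain length used for the fat spectrum.
#' @return 4-D array `grid x n_echoes` of magnitude signals.
#' @export
render_multiecho <- function(truth, protocol = acq_protocol(),
                             noise_sd = truth$spec$noise_sd,
                             seed = truth$spec$seed, cl = 17.4) {
  stopifnot(inherits(truth, "truth_maps"), noise_sd >= 0)
  g <- dim(truth$sat_mask)
  nvox <- prod(g)
  te_s <- protocol$echo_times / 1000
  nte <- length(te_s)
  inmask <- truth$sat_mask | truth$vat_mask
  A <- truth$spec$amplitude
  ff <- ifelse(inmask, truth$fat_fraction, 0)
  W <- ifelse(inmask, A * (1 - ff), 0.4 * A)
  Fv <- ifelse(inmask, A * ff, 0)
  ndb <- ifelse(inmask, truth$ndb, 2)
  r2s <- ifelse(inmask, truth$r2star, 30)
  nmidb <- 0.093 * ndb^2
  shifts <- tg_peak_shifts()
  f_hz <- (shifts - protocol$water_ppm) * 42.577 * protocol$field_strength
  # proton amplitude matrix (nvox x 9), linear in ndb/nmidb
  amp <- cbind(2 * ndb, 1, 4, 2 * nmidb, 6, 4 * (ndb - nmidb), 6,
               6 * (cl - 4) - 8 * ndb + 2 * nmidb, 9)
  tot <- rowSums(amp)
  out <- array(NA_real_, dim = c(g, nte))
  noise <- if (noise_sd > 0) {
    with_seed(sub_seed(seed, "render_noise"),
              list(re = matrix(rnorm(nvox * nte, 0, noise_sd), nvox, nte),
                   im = matrix(rnorm(nvox * nte, 0, noise_sd), nvox, nte)))
  } else NULL
  rimv <- as.vector(truth$rim_mask)
  mix <- truth$spec$rim_mix
  for (e in seq_len(nte)) {
    ph <- exp(1i * 2 * pi * f_hz * te_s[e])
    cmod <- as.vector(amp %*% ph) / tot
    cplx <- (W + Fv * cmod) * exp(-r2s * te_s[e])
    # rim voxels: partial-volume mixture with the background water signal
    # (its own relaxation), breaking the single-compartment model there
    cplx[rimv] <- (1 - mix) * cplx[rimv] + mix * 0.4 * A * exp(-30 * te_s[e])
    if (!is.null(noise))
      cplx <- cplx + complex(real = noise$re[, e], imaginary = noise$im[, e])
    out[, , , e] <- array(Mod(cplx), dim = g)
  }
  out
}
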