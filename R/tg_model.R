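#' Methylene-interrupted double bonds implied by the number of double bonds
#'
#' Applies the empirical constraint NMIDB = 0.093 * NDB^2 used to tie the
#' polyunsaturation index of the triglyceride spectrum to its total
#' unsaturation, reducing the composition to a single free parameter.
#'
#' @param ndb Mean number of double bonds per triglyceride (>= 0); vectorized.
#' @return Mean number of methylene-interrupted double bonds per triglyceride.
#' @examples
#' nmidb_from_ndb(1)   # 0.093
#' nmidb_from_ndb(3)   # 0.837
#' @export
nmidb_from_ndb <- function(ndb) {
  if (!is.numeric(ndb) || any(!is.finite(ndb)) || any(ndb < 0))
    stop("ndb must be finite and non-negative")
  0.093 * ndb^2
}

#' Triglyceride composition
#'
#' Bundles the spectral composition parameters of a triglyceride: number of
#' double bonds (NDB), methylene-interrupted double bonds (NMIDB, by default
#' tied to NDB through [nmidb_from_ndb()]) and mean fatty-acid chain length
#' (CL, carbons per chain).
#'
#' @param ndb Number of double bonds per triglyceride (>= 0).
#' @param nmidb Methylene-interrupted double bonds; defaults to 0.093 * ndb^2.
#' @param cl Mean chain length in carbons (> 4); default 17.4.
#' @return An object of class `tg_composition`.
#' @export
tg_composition <- function(ndb, nmidb = nmidb_from_ndb(ndb), cl = 17.4) {
  stopifnot(length(ndb) == 1L, length(nmidb) == 1L, length(cl) == 1L)
  if (!is.finite(ndb) || ndb < 0) stop("ndb must be >= 0")
  if (!is.finite(nmidb) || nmidb < 0 || nmidb > ndb + 1e-12)
    stop("nmidb must satisfy 0 <= nmidb <= ndb")
  if (!is.finite(cl) || cl <= 4) stop("cl must exceed 4 carbons")
  comp <- structure(list(ndb = ndb, nmidb = nmidb, cl = cl),
                    class = "tg_composition")
  pa <- peak_amplitudes(comp)  # validates non-negative proton counts
  stopifnot(all(pa$protons >= 0))
  comp
}

# Chemical shifts (ppm) of the nine-peak triglyceride proton model.
tg_peak_shifts <- function() c(5.3, 5.2, 4.2, 2.75, 2.2, 2.0, 1.6, 1.3, 0.9)

#' Proton amplitudes of the nine-peak triglyceride spectrum
#'
#' Returns the spectral peak table for one triglyceride: chemical shift in
#' ppm and proton count per molecule, the latter linear in (NDB, NMIDB, CL).
#' Total protons always equal `6*cl - 2*ndb + 2`.
#'
#' @param comp A [tg_composition()], or a list with fields ndb, nmidb, cl.
#' @return A data frame with columns `shift_ppm`, `protons` and a `label`.
#' @examples
#' peak_amplitudes(tg_composition(ndb = 2, cl = 17))
#' @export
peak_amplitudes <- function(comp) {
  ndb <- comp$ndb; nmidb <- comp$nmidb; cl <- comp$cl
  protons <- c(2 * ndb,                              # olefinic
               1,                                    # glycerol CH
               4,                                    # glycerol CH2
               2 * nmidb,                            # diallylic
               6,                                    # alpha-carboxyl
               4 * (ndb - nmidb),                    # allylic
               6,                                    # beta-carboxyl
               6 * (cl - 4) - 8 * ndb + 2 * nmidb,   # bulk methylene
               9)                                    # terminal methyl
  if (any(protons < -1e-12))
    stop("composition yields a negative proton count; (ndb, nmidb, cl) ",
         "outside the supported range")
  data.frame(
    label = c("olefinic", "glycerol_ch", "glycerol_ch2", "diallylic",
              "alpha_carboxyl", "allylic", "beta_carboxyl", "methylene",
              "methyl"),
    shift_ppm = tg_peak_shifts(),
    protons = pmax(protons, 0))
}

#' Complex chemical-shift modulation of the fat signal
#'
#' Proton-weighted sum of the off-water phase factors of the nine fat peaks,
#' normalised so that the modulus never exceeds 1 and the value at TE = 0 is
#' exactly 1. Frequencies are `(shift - water_ppm) * 42.577 MHz/T * B0`.
#'
#' @param comp A [tg_composition()].
#' @param protocol An [acq_protocol()]; supplies field strength and water ppm.
#' @param te Echo time(s) in milliseconds (>= 0); vectorized.
#' @return Complex vector, one element per echo time.
#' @export
fat_modulation <- function(comp, protocol = acq_protocol(), te) {
  if (any(te < 0)) stop("te must be >= 0")
  pa <- peak_amplitudes(comp)
  f_hz <- (pa$shift_ppm - protocol$water_ppm) * 42.577 *
    protocol$field_strength
  te_s <- te / 1000
  phase <- outer(te_s, f_hz, function(t, f) 2 * pi * f * t)
  as.vector((exp(1i * phase) %*% pa$protons) / sum(pa$protons))
}

#' Per-voxel signal parameters
#'
#' @param water Water proton amplitude (arbitrary units, >= 0).
#' @param fat Fat proton amplitude (arbitrary units, >= 0).
#' @param r2star Effective transverse relaxation rate in 1/s (>= 0).
#' @param composition A [tg_composition()].
#' @return An object of class `voxel_signal_params`.
#' @export
voxel_signal_params <- function(water, fat, r2star, composition) {
  stopifnot(water >= 0, fat >= 0, r2star >= 0,
            inherits(composition, "tg_composition"))
  structure(list(water = water, fat = fat, r2star = r2star,
                 composition = composition),
            class = "voxel_signal_params")
}

#' Simulate a multi-echo magnitude signal for one voxel
#'
#' Evaluates `|W + F * c(te)| * exp(-r2star * te)` at the protocol's echo
#' times, where `c(te)` is [fat_modulation()]. With `noise_sd > 0`,
#' independent Gaussian noise is added on the real and imaginary channels
#' before taking the magnitude, i.e. the magnitude noise is Rician.
#'
#' @param params A [voxel_signal_params()].
#' @param protocol An [acq_protocol()].
#' @param noise_sd Standard deviation of the per-channel complex noise
#'   (same arbitrary units as the amplitudes); 0 for a noiseless series.
#' @param seed Optional integer seed; the call is deterministic given it.
#' @return An object of class `echo_series` with fields `values` and
#'   `protocol`.
#' @export
simulate_signal <- function(params, protocol = acq_protocol(),
                            noise_sd = 0, seed = NULL) {
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  te <- protocol$echo_times
  mod <- fat_modulation(params$composition, protocol, te)
  cplx <- (params$water + params$fat * mod) * exp(-params$r2star * te / 1000)
  values <- if (noise_sd > 0) {
    with_seed(seed, {
      nr <- rnorm(length(te), 0, noise_sd)
      ni <- rnorm(length(te), 0, noise_sd)
      Mod(cplx + complex(real = nr, imaginary = ni))
    })
  } else Mod(cplx)
  echo_series(values, protocol)
}

#' Echo series container
#'
#' @param values Non-negative magnitude signal, one value per protocol echo.
#' @param protocol The [acq_protocol()] the series was sampled on.
#' @return An object of class `echo_series`.
#' @export
echo_series <- function(values, protocol) {
  if (length(values) != length(protocol$echo_times))
    stop("values length must match the protocol's number of echoes")
  if (any(!is.finite(values)) || any(values < 0))
    stop("echo series values must be finite and >= 0")
  structure(list(values = as.numeric(values), protocol = protocol),
            class = "echo_series")
}
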