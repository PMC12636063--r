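#' Binary erosion of a depot mask
#'
#' In-slice morphological erosion with a 3x3 square structuring element
#' (no through-slice erosion: the acquisition is effectively single-slice
#' multi-echo, and thin depots would empty along z). The output is always a
#' subset of the input.
#'
#' @param mask Logical (or 0/1) array, 2-D or 3-D.
#' @param iterations Number of erosion passes; default 1.
#' @return Logical array of the same shape.
#' @export
erode_mask <- function(mask, iterations = 1L) {
  storage <- dim(mask)
  m <- if (length(storage) == 2L) array(mask, dim = c(storage, 1L)) else mask
  if (length(dim(m)) != 3L) stop("mask must be 2-D or 3-D")
  kern <- EBImage::makeBrush(3, shape = "box")
  out <- array(FALSE, dim = dim(m))
  for (z in seq_len(dim(m)[3])) {
    sl <- (m[, , z] != 0) * 1
    for (i in seq_len(iterations)) sl <- EBImage::erode(sl, kern)
    out[, , z] <- sl > 0
  }
  if (length(storage) == 2L) out <- out[, , 1]
  out
}

#' Fat-fraction filter
#'
#' Retains the mask voxels whose fitted fat fraction is at or above the
#' threshold; voxels with fat fractions below the threshold (the default
#' 20%), or with a missing fat fraction, are excluded.
#'
#' @param maps A [fit_volume()] result (`fraction_maps`).
#' @param mask Logical array of candidate voxels.
#' @param threshold Fat-fraction cutoff in `[0, 1]`; default 0.20.
#' @return Logical array: the retained voxels.
#' @export
apply_ff_filter <- function(maps, mask, threshold = 0.20) {
  stopifnot(threshold >= 0, threshold <= 1)
  ff <- maps$fat_fraction
  keep <- !is.na(ff) & ff >= threshold
  mask & keep
}

#' Depot-level fatty-acid summary
#'
#' Applies the mask-hygiene chain (binary erosion to trim partial-volume
#' edges, then the fat-fraction filter) and summarises the fraction maps
#' over the retained voxels with arithmetic mean and SD, recording the voxel
#' count at every stage.
#'
#' @param maps A [fit_volume()] result.
#' @param mask Logical depot mask.
#' @param label Depot label (e.g. "SAT").
#' @param erode_iterations Erosion passes before filtering; default 1.
#' @param ff_threshold Fat-fraction cutoff; default 0.20.
#' @return One-row data frame with counts and per-map mean/SD; all-NA (with
#'   a warning) when no voxel survives filtering.
#' @export
summarize_depot <- function(maps, mask, label = "depot",
                            erode_iterations = 1L, ff_threshold = 0.20) {
  n0 <- sum(mask)
  er <- if (erode_iterations > 0) erode_mask(mask, erode_iterations) else mask
  n1 <- sum(er)
  kept <- apply_ff_filter(maps, er, ff_threshold)
  n2 <- sum(kept)
  base <- data.frame(depot = label, n_voxels_initial = n0,
                     n_voxels_after_erosion = n1,
                     n_voxels_after_ff_filter = n2)
  vars <- c("f_sfa", "f_mufa", "f_pufa", "fat_fraction")
  if (n2 == 0) {
    warning("no voxels retained for depot '", label, "'; summary is missing")
    for (v in vars) {
      base[[paste0("mean_", v)]] <- NA_real_
      base[[paste0("sd_", v)]] <- NA_real_
    }
    return(base)
  }
  for (v in vars) {
    x <- maps[[v]][kept]
    base[[paste0("mean_", v)]] <- mean(x)
    base[[paste0("sd_", v)]] <- if (n2 > 1) sd(x) else 0
  }
  base
}
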