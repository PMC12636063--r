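logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Wakefield approximate log Bayes factor
#'
#' For an estimate `beta` with standard error `se` and a zero-centred
#' normal effect prior with SD `prior_sd`, the log approximate Bayes factor
#' in favour of an effect is `0.5 * (log(1 - r) + r z^2)` with
#' `r = prior_sd^2 / (prior_sd^2 + se^2)` and `z = beta / se`.
#'
#' @param beta Effect estimate(s); vectorized.
#' @param se Standard error(s) (> 0).
#' @param prior_sd Prior effect SD (> 0); 0.15 is conventional for
#'   quantitative traits, 0.2 for binary ones.
#' @return Log Bayes factor(s).
#' @export
log_abf <- function(beta, se, prior_sd = 0.15) {
  if (any(se <= 0)) stop("se must be > 0")
  if (any(prior_sd <= 0)) stop("prior_sd must be > 0")
  r <- prior_sd^2 / (prior_sd^2 + se^2)
  z <- beta / se
  0.5 * (log(1 - r) + r * z^2)
}

#' Colocalization posterior probabilities from per-variant log-ABFs
#'
#' Enumerates the five hypotheses of the standard colocalization model over
#' a locus (H0 no association; H1/H2 association with one trait only; H3
#' two distinct causal variants; H4 one shared causal variant) from two
#' equal-length, allele-harmonized log-ABF vectors, entirely in log space.
#'
#' @param labf1,labf2 Per-variant log approximate Bayes factors.
#' @param p1,p2 Prior probability a variant is causal for trait 1 / 2
#'   (defaults 1e-4).
#' @param p12 Prior probability a variant is causal for both (default
#'   1e-5).
#' @return Object of class `coloc_result`: `pp` (named h0..h4, sums to 1),
#'   `n_variants`, `priors`, and the input log-ABFs.
#' @export
coloc_pp <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  if (length(labf1) != length(labf2)) stop("log-ABF length mismatch")
  m <- length(labf1)
  stopifnot(m >= 1)
  l1 <- logsumexp(labf1)
  l2 <- logsumexp(labf2)
  l12 <- logsumexp(labf1 + labf2)
  h0 <- 0
  h1 <- log(p1) + l1
  h2 <- log(p2) + l2
  # sum over ordered pairs i != j: exp(l1 + l2) - exp(l12)
  h3 <- if (m > 1) {
    d <- l12 - (l1 + l2)           # <= 0 by rearrangement
    log(p1) + log(p2) + l1 + l2 + log1p(-pmin(exp(d), 1 - 1e-16))
  } else -Inf
  h4 <- log(p12) + l12
  lp <- c(h0 = h0, h1 = h1, h2 = h2, h3 = h3, h4 = h4)
  pp <- exp(lp - logsumexp(lp))
  pp <- pp / sum(pp)
  structure(list(pp = pp, n_variants = m,
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 labf1 = labf1, labf2 = labf2),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("<coloc_result>", x$n_variants, "variants\n")
  print(round(x$pp, 4))
  invisible(x)
}

#' Greedy LD pruning by p-value
#'
#' Orders variants by ascending p-value and keeps each one only if its r^2
#' with every previously kept variant does not exceed the threshold
#' (variants in high LD, r^2 > threshold, are removed). Deterministic.
#'
#' @param p P-values (ties keep input order).
#' @param r2 Symmetric r^2 matrix in `[0, 1]`.
#' @param threshold r^2 cutoff, default 0.5.
#' @return Integer indices of the retained variants (ascending).
#' @export
ld_prune <- function(p, r2, threshold = 0.5) {
  m <- length(p)
  stopifnot(nrow(r2) == m, ncol(r2) == m, all(r2 >= -1e-9), all(r2 <= 1 + 1e-9))
  ord <- order(p)
  kept <- integer(0)
  for (i in ord) {
    if (all(r2[i, kept] <= threshold)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Single-causal-variant posterior inclusion probabilities
#'
#' A simplified fine-mapping summary: assuming exactly one causal variant
#' in the locus and equal priors, the posterior inclusion probability of
#' each variant is the softmax of its log-ABF. This is an explicit
#' simplification of multi-signal fine mapping; the result carries a
#' `method` attribute saying so.
#'
#' @param labf Per-variant log approximate Bayes factors.
#' @return Numeric vector of PIPs summing to 1, with attribute
#'   `method = "single-causal-variant (simplified)"`.
#' @export
single_causal_pip <- function(labf) {
  stopifnot(length(labf) >= 1)
  pip <- exp(labf - logsumexp(labf))
  pip <- pip / sum(pip)
  attr(pip, "method") <- "single-causal-variant (simplified)"
  pip
}

#' Window a summary-statistics table around a lead variant
#'
#' @param stats Association table (summary-statistics schema).
#' @param lead_rsid rsID of the lead variant (must be present).
#' @param half_width Window half-width in bp (default 1e5, i.e. a 200-kb
#'   window).
#' @return The member rows, with the lead row as attribute `lead`.
#' @export
locus_window <- function(stats, lead_rsid, half_width = 1e5) {
  li <- match(lead_rsid, stats$rsid)
  if (is.na(li)) stop("lead variant ", lead_rsid, " not in table")
  lead <- stats[li, ]
  sel <- stats$chr == lead$chr & abs(stats$bp - lead$bp) <= half_width
  out <- stats[sel, , drop = FALSE]
  attr(out, "lead") <- lead
  out
}

# Align stats2 to stats1 on shared rsids; flip beta/eaf when EA/OA are
# swapped; error on irreconcilable alleles.
harmonize_stats <- function(stats1, stats2) {
  shared <- intersect(stats1$rsid, stats2$rsid)
  s1 <- stats1[match(shared, stats1$rsid), , drop = FALSE]
  s2 <- stats2[match(shared, stats2$rsid), , drop = FALSE]
  same <- s1$ea == s2$ea & s1$oa == s2$oa
  flipped <- s1$ea == s2$oa & s1$oa == s2$ea
  if (any(!same & !flipped))
    stop("allele mismatch for: ",
         paste(shared[!same & !flipped], collapse = ", "))
  s2$beta[flipped] <- -s2$beta[flipped]
  s2$eaf[flipped] <- 1 - s2$eaf[flipped]
  s2$ea <- s1$ea
  s2$oa <- s1$oa
  list(stats1 = s1, stats2 = s2)
}

#' Colocalization analysis of one locus
#'
#' Full locus workflow: select the 200-kb window around the lead variant
#' (lowest p in trait 1 unless given), harmonize the two tables, greedily
#' prune variants in high LD (r^2 > `r2_threshold`) by trait-1 p-value when
#' an r^2 matrix is supplied, and run [coloc_pp()] on the pruned set.
#'
#' @param stats1,stats2 Summary-statistics tables for the two traits.
#' @param lead_rsid Optional lead rsID; defaults to [lead_variant()] of
#'   `stats1`.
#' @param window_kb Total window width in kb (default 200).
#' @param r2 Optional symmetric r^2 matrix with dimnames matching rsids.
#' @param r2_threshold Pruning cutoff, default 0.5.
#' @param prior_sd1,prior_sd2 ABF prior SDs for the two traits.
#' @param p1,p2,p12 Colocalization priors.
#' @return `coloc_result` with extra fields `lead`, `n_variants_after_prune`
#'   and `pip` (single-causal PIPs for trait 1).
#' @export
coloc_locus <- function(stats1, stats2, lead_rsid = NULL, window_kb = 200,
                        r2 = NULL, r2_threshold = 0.5, prior_sd1 = 0.15,
                        prior_sd2 = 0.15, p1 = 1e-4, p2 = 1e-4,
                        p12 = 1e-5) {
  if (is.null(lead_rsid)) lead_rsid <- lead_variant(stats1)$rsid
  w1 <- locus_window(stats1, lead_rsid, half_width = window_kb * 1000 / 2)
  h <- harmonize_stats(w1, stats2)
  s1 <- h$stats1; s2 <- h$stats2
  if (!is.null(r2)) {
    ids <- s1$rsid
    r2m <- r2[ids, ids, drop = FALSE]
    keep <- ld_prune(s1$p, r2m, r2_threshold)
    s1 <- s1[keep, , drop = FALSE]
    s2 <- s2[keep, , drop = FALSE]
  }
  labf1 <- log_abf(s1$beta, s1$se, prior_sd1)
  labf2 <- log_abf(s2$beta, s2$se, prior_sd2)
  res <- coloc_pp(labf1, labf2, p1, p2, p12)
  res$lead <- lead_rsid
  res$n_variants_after_prune <- nrow(s1)
  res$rsid <- s1$rsid
  res$pip <- single_causal_pip(labf1)
  res
}
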