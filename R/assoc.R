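#' Rank-based inverse normal transform
#'
#' Blom-offset rank transform: values are ranked (ties receive average
#' ranks), mapped to `(rank - 3/8) / (n + 1/4)` and through the standard
#' normal quantile function. Order is preserved; NA values stay NA.
#'
#' @param values Numeric vector with at least two distinct finite values.
#' @return Numeric vector of normal scores, same length and order.
#' @export
inverse_normal_transform <- function(values) {
  ok <- is.finite(values)
  x <- values[ok]
  if (length(x) < 2) stop("need at least 2 finite values")
  if (length(unique(x)) < 2) stop("degenerate trait: all values identical")
  r <- rank(x, ties.method = "average")
  z <- qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  out <- rep(NA_real_, length(values))
  out[ok] <- z
  out
}

#' Variant QC filter
#'
#' Retains variants with minor allele frequency strictly above `maf_gt` and
#' INFO score strictly above `info_gt` (defaults 0.01 and 0.9). A variant
#' with MAF exactly at the cutoff is excluded.
#'
#' @param annotations Data frame with columns `eaf` and `info`.
#' @param maf_gt,info_gt Strict lower cutoffs.
#' @return The retained rows, with an attribute `filter_counts` recording
#'   how many variants failed each criterion.
#' @export
filter_variants <- function(annotations, maf_gt = 0.01, info_gt = 0.9) {
  req <- c("eaf", "info")
  miss <- setdiff(req, names(annotations))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  maf <- pmin(annotations$eaf, 1 - annotations$eaf)
  pass_maf <- maf > maf_gt
  pass_info <- annotations$info > info_gt
  out <- annotations[pass_maf & pass_info, , drop = FALSE]
  attr(out, "filter_counts") <- c(n_input = nrow(annotations),
                                  fail_maf = sum(!pass_maf),
                                  fail_info = sum(!pass_info),
                                  retained = nrow(out))
  out
}

# Design matrix from a covariate data frame / matrix, expanding factors.
covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1,
                                         dimnames = list(NULL, "intercept")))
  cm <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  colnames(cm)[1] <- "intercept"
  cm
}

#' Per-variant linear association
#'
#' Ordinary least squares of a (typically inverse-normal transformed) trait
#' on an allele dosage plus covariates; the effect estimate, standard error
#' and a normal-approximation p-value for the dosage term are returned in
#' the standard summary-statistics schema.
#'
#' @param dosage Numeric dosage vector in `[0, 2]`.
#' @param trait_z Numeric trait vector.
#' @param covariates Optional data frame or matrix of covariates (factors
#'   are expanded); an intercept is always included.
#' @param annotation Optional one-row list/data frame with rsid, chr, bp,
#'   ea, oa carried into the output.
#' @return One-row data frame: rsid, chr, bp, ea, oa, beta, se, p, eaf, n.
#' @export
linear_assoc <- function(dosage, trait_z, covariates = NULL,
                         annotation = NULL) {
  n <- length(trait_z)
  X <- cbind(covariate_matrix(covariates, n), dosage = dosage)
  if (n <= ncol(X) + 1) stop("too few observations for the design")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1, ncol(X))]]
    stop("collinear design; offending columns: ",
         paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qx, trait_z)
  res <- trait_z - X %*% coefs
  sigma2 <- sum(res^2) / (n - ncol(X))
  XtXinv_dd <- chol2inv(qr.R(qx))[ncol(X), ncol(X)]
  beta <- coefs[["dosage"]]
  se <- sqrt(sigma2 * XtXinv_dd)
  z <- beta / se
  data.frame(rsid = annotation$rsid %||% NA_character_,
             chr = annotation$chr %||% NA_integer_,
             bp = annotation$bp %||% NA_integer_,
             ea = annotation$ea %||% NA_character_,
             oa = annotation$oa %||% NA_character_,
             beta = beta, se = se, p = 2 * pnorm(-abs(z)),
             eaf = mean(dosage) / 2, n = n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genome-scan over a dosage matrix
#'
#' Runs [linear_assoc()]'s model for every variant efficiently by
#' residualising the trait and the dosages against the covariates once
#' (Frisch-Waugh-Lovell); estimates are identical to per-variant OLS.
#'
#' @param dosages n x m dosage matrix.
#' @param trait_z Trait vector (transform first: see
#'   [inverse_normal_transform()]).
#' @param covariates Optional covariate data frame / matrix.
#' @param annotations Optional m-row variant table (rsid, chr, bp, ea, oa).
#' @return m-row data frame in the summary-statistics schema.
#' @export
gwas_scan <- function(dosages, trait_z, covariates = NULL,
                      annotations = NULL) {
  n <- length(trait_z)
  stopifnot(nrow(dosages) == n)
  C <- covariate_matrix(covariates, n)
  qc <- qr(C)
  ry <- qr.resid(qc, trait_z)
  rg <- qr.resid(qc, dosages)
  gg <- colSums(rg^2)
  beta <- colSums(rg * ry) / gg
  rss <- sum(ry^2) - beta^2 * gg
  df <- n - ncol(C) - 1
  se <- sqrt(rss / df / gg)
  z <- beta / se
  out <- data.frame(beta = beta, se = se, p = 2 * pnorm(-abs(z)),
                    eaf = colMeans(dosages) / 2, n = n)
  if (!is.null(annotations)) {
    out <- cbind(annotations[, intersect(c("rsid", "chr", "bp", "ea", "oa"),
                                         names(annotations)),
                             drop = FALSE], out)
  }
  rownames(out) <- NULL
  out
}

#' Cochran's Q depot-heterogeneity test
#'
#' Fixed-effect heterogeneity between two per-depot estimates of the same
#' variant: with weights `w = 1/se^2` and pooled effect
#' `b = sum(w beta) / sum(w)`, `Q = sum(w (beta - b)^2)` on 1 df, and
#' `I^2 = max(0, (Q - df)/Q) * 100`. The depot-specificity rule flags
#' heterogeneity p < 0.05 together with I^2 > 75%.
#'
#' @param assoc_sat,assoc_vat One-row association results (lists or data
#'   frames with `beta`, `se`, and optionally rsid/ea/oa for harmonisation
#'   checks).
#' @return List of class `het_result`: `q`, `df`, `het_pval`, `i_squared`
#'   (percent), `depot_specific`.
#' @export
cochran_q <- function(assoc_sat, assoc_vat) {
  for (f in c("rsid", "ea", "oa")) {
    a <- assoc_sat[[f]]; b <- assoc_vat[[f]]
    if (!is.null(a) && !is.null(b) && !is.na(a) && !is.na(b) &&
        !identical(as.character(a), as.character(b)))
      stop("allele/variant mismatch between depots (", f,
           "): harmonize the inputs first")
  }
  beta <- c(assoc_sat$beta, assoc_vat$beta)
  se <- c(assoc_sat$se, assoc_vat$se)
  stopifnot(length(beta) == 2, all(se > 0))
  w <- 1 / se^2
  pooled <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - pooled)^2)
  df <- 1
  het_pval <- pchisq(q, df, lower.tail = FALSE)
  i2 <- max(0, (q - df) / q) * 100
  if (!is.finite(i2)) i2 <- 0
  structure(list(q = q, df = df, het_pval = het_pval, i_squared = i2,
                 depot_specific = het_pval < 0.05 && i2 > 75),
            class = "het_result")
}

#' Vectorised depot heterogeneity over matched summary-statistics tables
#'
#' @param tab_sat,tab_vat Association tables with matching `rsid` order and
#'   harmonized alleles.
#' @return Data frame with rsid, q, het_pval, i_squared, depot_specific.
#' @export
depot_heterogeneity <- function(tab_sat, tab_vat) {
  stopifnot(nrow(tab_sat) == nrow(tab_vat))
  if (!is.null(tab_sat$rsid) && !all(tab_sat$rsid == tab_vat$rsid))
    stop("tables are not variant-matched; harmonize first")
  out <- do.call(rbind, lapply(seq_len(nrow(tab_sat)), function(i) {
    h <- cochran_q(tab_sat[i, ], tab_vat[i, ])
    data.frame(rsid = tab_sat$rsid[i] %||% NA_character_, q = h$q,
               het_pval = h$het_pval, i_squared = h$i_squared,
               depot_specific = h$depot_specific)
  }))
  rownames(out) <- NULL
  out
}

#' Inverse-variance fixed-effect meta-analysis
#'
#' @param betas Effect estimates (or a list of association rows via
#'   `assocs`); `ses` their standard errors.
#' @param ses Standard errors, same length.
#' @return List of class `meta_result`: `beta`, `se`, `p`, `n_studies`,
#'   and the per-study inputs. A single study passes through with a
#'   warning.
#' @export
ivw_meta <- function(betas, ses) {
  if (is.list(betas) && !is.null(betas[[1]]$beta)) {
    ses <- vapply(betas, function(a) a$se, 0)
    betas <- vapply(betas, function(a) a$beta, 0)
  }
  stopifnot(length(betas) == length(ses), all(ses > 0))
  if (length(betas) == 1L) {
    warning("single study: meta-analysis is a pass-through")
    return(structure(list(beta = betas, se = ses,
                          p = 2 * pnorm(-abs(betas / ses)), n_studies = 1L,
                          inputs = data.frame(beta = betas, se = ses)),
                     class = "meta_result"))
  }
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se <- 1 / sqrt(sum(w))
  structure(list(beta = beta, se = se, p = 2 * pnorm(-abs(beta / se)),
                 n_studies = length(betas),
                 inputs = data.frame(beta = betas, se = ses)),
            class = "meta_result")
}

# IRLS core for a logistic GLM; returns coefficients and their covariance.
irls_logistic <- function(X, y, max_iter = 100, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  dev_old <- Inf
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    if (any(!is.finite(w)) || max(abs(beta)) > 50)
      stop("separation detected (diverging coefficients); ",
           "consider penalized regression")
    z <- eta + (y - mu) / pmax(w, 1e-12)
    wx <- X * w
    fit <- tryCatch(solve(crossprod(X, wx), crossprod(wx, z)),
                    error = function(e) stop("singular information matrix"))
    beta <- as.vector(fit)
    dev <- -2 * sum(y * log(pmax(plogis(as.vector(X %*% beta)), 1e-300)) +
                      (1 - y) *
                        log(pmax(1 - plogis(as.vector(X %*% beta)),
                                 1e-300)))
    if (abs(dev_old - dev) < tol * (abs(dev) + tol)) {
      vcov <- solve(crossprod(X, X * (plogis(as.vector(X %*% beta)) *
                                        (1 - plogis(as.vector(X %*% beta))))))
      return(list(coef = setNames(beta, colnames(X)), vcov = vcov,
                  deviance = dev, iterations = it, converged = TRUE))
    }
    dev_old <- dev
  }
  stop("IRLS did not converge after ", max_iter, " iterations")
}

#' Gene-diet interaction logistic regression
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares, implemented here) of a binary disease outcome on genotype
#' dosage, standardised dietary intake, their interaction, age and sex.
#' Alongside the interaction coefficient (log-odds per effect allele per SD
#' of intake) the genotype-stratified diet effects are reported: within
#' each rounded-dosage stratum, the diet log-odds with a 95% Wald interval.
#'
#' @param disease 0/1 outcome vector (both classes present).
#' @param dosage Allele dosage vector.
#' @param diet_std Standardised dietary intake.
#' @param age,sex Adjustment covariates.
#' @param max_iter IRLS iteration cap.
#' @return List of class `interaction_result`: `gamma_hat`, `se`, `p`,
#'   `coefficients`, `stratified` (data frame), `converged`.
#' @export
interaction_logistic <- function(disease, dosage, diet_std, age, sex,
                                 max_iter = 100) {
  y <- as.numeric(disease)
  if (length(unique(y[is.finite(y)])) < 2)
    stop("outcome must contain both classes")
  X <- cbind(intercept = 1, g = dosage, diet = diet_std,
             g_x_diet = dosage * diet_std, age = age, sex = sex)
  fit <- irls_logistic(X, y, max_iter = max_iter)
  k <- which(colnames(X) == "g_x_diet")
  gamma_hat <- fit$coef[[k]]
  se <- sqrt(fit$vcov[k, k])
  strata <- sort(unique(pmin(pmax(round(dosage), 0), 2)))
  strat <- do.call(rbind, lapply(strata, function(s) {
    sel <- pmin(pmax(round(dosage), 0), 2) == s
    if (sum(sel) < 30 || length(unique(y[sel])) < 2)
      return(data.frame(genotype = s, n = sum(sel), beta_diet = NA_real_,
                        lo95 = NA_real_, hi95 = NA_real_))
    Xs <- cbind(intercept = 1, diet = diet_std[sel], age = age[sel],
                sex = sex[sel])
    fs <- tryCatch(irls_logistic(Xs, y[sel], max_iter = max_iter),
                   error = function(e) NULL)
    if (is.null(fs))
      return(data.frame(genotype = s, n = sum(sel), beta_diet = NA_real_,
                        lo95 = NA_real_, hi95 = NA_real_))
    b <- fs$coef[["diet"]]; sb <- sqrt(fs$vcov[2, 2])
    data.frame(genotype = s, n = sum(sel), beta_diet = b,
               lo95 = b - 1.96 * sb, hi95 = b + 1.96 * sb)
  }))
  structure(list(gamma_hat = gamma_hat, se = se,
                 p = 2 * pnorm(-abs(gamma_hat / se)),
                 coefficients = data.frame(term = colnames(X),
                                           estimate = fit$coef,
                                           se = sqrt(diag(fit$vcov))),
                 stratified = strat, converged = fit$converged),
            class = "interaction_result")
}

#' Multiple-testing thresholds
#'
#' Division-based threshold `alpha / n_tests` together with its
#' one-significant-figure rounding (17 tests at alpha 0.05 gives 0.00294,
#' printed as 0.003). For vectors of p-values, Benjamini-Hochberg adjusted
#' values are available through [bh_adjust()].
#'
#' @param n_tests Number of tests (>= 1); `alpha` family-wise level.
#' @param alpha Family-wise alpha, default 0.05.
#' @return List with `threshold` and `rounded`.
#' @export
significance_thresholds <- function(n_tests, alpha = 0.05) {
  stopifnot(n_tests >= 1)
  th <- alpha / n_tests
  list(threshold = th, rounded = signif(th, 1))
}

#' Benjamini-Hochberg adjusted p-values
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values (step-up FDR).
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")

#' Genome-wide significance flag
#' @param p P-value vector.
#' @param alpha Threshold, default 5e-8 (inclusive).
#' @return Logical vector.
#' @export
genome_wide_significant <- function(p, alpha = 5e-8) p <= alpha

#' Lead variant of a locus
#'
#' The variant with the lowest p-value; ties are broken by largest absolute
#' effect, then lowest base-pair position.
#'
#' @param assocs Association table in the summary-statistics schema.
#' @return The selected row.
#' @export
lead_variant <- function(assocs) {
  stopifnot(nrow(assocs) >= 1)
  ord <- order(assocs$p, -abs(assocs$beta), assocs$bp)
  assocs[ord[1], , drop = FALSE]
}
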