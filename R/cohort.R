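#' Variant annotation table for the cohort simulator
#'
#' Convenience constructor for the variant list consumed by
#' [cohort_spec()]: rsIDs, positions, non-strand-ambiguous allele pairs
#' (A/T and C/G pairs are never generated), minor allele frequencies and
#' per-depot planted effects on the latent NDB (in latent-SD units per
#' effect allele).
#'
#' @param m Number of variants.
#' @param maf Length-2 range the MAFs are drawn from, or a length-m vector.
#' @param beta_sat,beta_vat Planted effect sizes (scalar or length m).
#' @param seed Integer seed.
#' @return Data frame with columns rsid, chr, bp, ea, oa, maf, beta_sat,
#'   beta_vat.
#' @export
variant_table <- function(m, maf = c(0.05, 0.5), beta_sat = 0,
                          beta_vat = 0, seed = 1L) {
  pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  with_seed(sub_seed(seed, "variant_table"), {
    mafs <- if (length(maf) == 2L && m != 2L) runif(m, maf[1], maf[2])
            else rep_len(maf, m)
    al <- pairs[sample.int(length(pairs), m, replace = TRUE)]
    data.frame(rsid = sprintf("rs%07d", sample.int(9999999, m)),
               chr = sample.int(22, m, replace = TRUE),
               bp = sort(sample.int(2e8, m)),
               ea = vapply(al, `[`, "", 1L),
               oa = vapply(al, `[`, "", 2L),
               maf = mafs,
               beta_sat = rep_len(beta_sat, m),
               beta_vat = rep_len(beta_vat, m))
  })
}

#' Cohort simulation specification
#'
#' Collects the generative model for a synthetic imaging-genetics cohort:
#' Hardy-Weinberg genotypes with imputation-style dosage noise, latent
#' depot NDB with planted variant effects mapped through
#' [fractions_from_ndb()] to fatty-acid fraction traits, dietary intakes
#' (means and SDs mirroring typical UK cohort descriptives: SFA 27.54 +/-
#' 11.78 g, MUFA 26.96 +/- 10.73 g, PUFA 19.90 +/- 7.51 g), and binary
#' disease outcomes with an optional planted genotype-by-diet interaction.
#'
#' @param n Number of participants (>= 50).
#' @param variants A [variant_table()]-style data frame.
#' @param dosage_noise_sd SD of the Gaussian imputation noise added to hard
#'   calls (dosages clipped to `[0, 2]`); 0 gives INFO ~ 1.
#' @param ndb Latent-trait model: per-depot baselines and SD, and small age
#'   and sex effects on the latent NDB.
#' @param diet Named list of `c(mean, sd)` for sfa, mufa, pufa grams/day.
#' @param disease List of disease models, each a list with `name`,
#'   `prevalence`, `beta_g` (log-odds per effect allele), `beta_diet`
#'   (log-odds per SD of intake), `gamma` (interaction log-odds per allele
#'   per SD), `diet` (which intake), `variant` (index of the interacting
#'   variant), `beta_age`, `beta_sex`.
#' @param seed Master integer seed; all sub-generators derive their own
#'   streams from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 5000,
                        variants = variant_table(100),
                        dosage_noise_sd = 0.05,
                        ndb = list(sat_base = 2.08, vat_base = 1.94,
                                   sd = 0.15, beta_age = -0.002,
                                   beta_sex = 0.05),
                        diet = list(sfa = c(27.54, 11.78),
                                    mufa = c(26.96, 10.73),
                                    pufa = c(19.90, 7.51)),
                        disease = list(
                          list(name = "hypertension", prevalence = 0.36,
                               beta_g = 0, beta_diet = 0.10, gamma = 0,
                               diet = "sfa", variant = 1L,
                               beta_age = 0.03, beta_sex = 0.3),
                          list(name = "t2d", prevalence = 0.053,
                               beta_g = 0, beta_diet = 0.10, gamma = 0,
                               diet = "sfa", variant = 1L,
                               beta_age = 0.03, beta_sex = 0.3),
                          list(name = "cvd", prevalence = 0.098,
                               beta_g = 0, beta_diet = 0.10, gamma = 0.15,
                               diet = "sfa", variant = 1L,
                               beta_age = 0.03, beta_sex = 0.3)),
                        seed = 1L) {
  stopifnot(n >= 50, is.data.frame(variants),
            all(c("rsid", "maf", "beta_sat", "beta_vat") %in%
                  names(variants)),
            all(variants$maf > 0), all(variants$maf <= 0.5),
            dosage_noise_sd >= 0)
  structure(list(n = as.integer(n), variants = variants,
                 dosage_noise_sd = dosage_noise_sd, ndb = ndb, diet = diet,
                 disease = disease, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate Hardy-Weinberg genotypes with imputation-style dosages
#'
#' Hard calls are Binomial(2, maf) per variant; dosages add truncated
#' Gaussian noise (clipped to `[0, 2]`). The per-variant INFO score is
#' computed as `var(dosage) / (2 p (1 - p))` with `p = mean(dosage) / 2`.
#'
#' @param spec A [cohort_spec()].
#' @return List with `dosage` (n x m matrix), `hardcall` (n x m integer
#'   matrix), and `annotations` (variant table with eaf, info added).
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  v <- spec$variants
  m <- nrow(v)
  with_seed(sub_seed(spec$seed, "genotypes"), {
    hard <- vapply(v$maf, function(p) rbinom(spec$n, 2L, p),
                   integer(spec$n))
    dos <- hard
    if (spec$dosage_noise_sd > 0)
      dos <- pmin(pmax(hard + matrix(rnorm(spec$n * m, 0,
                                           spec$dosage_noise_sd),
                                     spec$n, m), 0), 2)
    p_hat <- colMeans(dos) / 2
    info <- apply(dos, 2, var) / (2 * p_hat * (1 - p_hat))
    ann <- v
    ann$eaf <- p_hat
    ann$info <- info
    list(dosage = dos, hardcall = hard, annotations = ann)
  })
}

#' Simulate depot fatty-acid traits and covariates
#'
#' The latent per-depot NDB of each participant is the depot baseline plus
#' the planted per-allele variant effects (in latent-SD units), small age
#' and sex effects, and Gaussian noise; it is mapped through
#' [fractions_from_ndb()] so the fraction triplets inherit the model's
#' nonlinearity. Covariates mirror a GWAS covariate set structurally: age,
#' age squared, sex, 10 principal-component-like standard normals, a 2-level
#' genotyping-array factor and a 3-level imaging-centre factor.
#'
#' @param genotypes A [simulate_genotypes()] result.
#' @param spec The same [cohort_spec()].
#' @return Data frame with covariates and sat_/vat_ fraction triplets plus
#'   the latent `sat_ndb`, `vat_ndb`.
#' @export
simulate_traits <- function(genotypes, spec) {
  n <- spec$n
  stopifnot(nrow(genotypes$dosage) == n)
  with_seed(sub_seed(spec$seed, "traits"), {
    age <- rnorm(n, 64.5, 7.7)
    sex <- rbinom(n, 1L, 0.49)
    pcs <- matrix(rnorm(n * 10), n, 10,
                  dimnames = list(NULL, paste0("pc", 1:10)))
    array_f <- sample.int(2L, n, replace = TRUE)
    centre_f <- sample.int(3L, n, replace = TRUE)
    out <- data.frame(id = seq_len(n), age = age, age2 = age^2, sex = sex,
                      array = factor(array_f), centre = factor(centre_f))
    out <- cbind(out, as.data.frame(pcs))
    nm <- spec$ndb
    for (depot in c("sat", "vat")) {
      base <- if (depot == "sat") nm$sat_base else nm$vat_base
      betas <- spec$variants[[paste0("beta_", depot)]]
      gshift <- as.vector(genotypes$dosage %*% (betas * nm$sd))
      lat <- base + gshift + nm$beta_age * (age - mean(age)) +
        nm$beta_sex * nm$sd * sex + rnorm(n, 0, nm$sd)
      lat <- pmin(pmax(lat, 0.2), 6)
      fr <- fractions_from_ndb(lat)
      out[[paste0(depot, "_ndb")]] <- lat
      out[[paste0(depot, "_fsfa")]] <- fr$f_sfa
      out[[paste0(depot, "_fmufa")]] <- fr$f_mufa
      out[[paste0(depot, "_fpufa")]] <- fr$f_pufa
    }
    out
  })
}

#' Simulate dietary intakes and binary disease outcomes
#'
#' Dietary intakes are Gaussian (truncated at 0) with the spec's means and
#' SDs; each intake is z-standardised before entering the disease model.
#' Disease status follows a logistic model with genotype and diet main
#' effects, their interaction (the planted gamma), and age and sex effects;
#' the intercept is set so the covariate-free prevalence matches the spec.
#'
#' @param genotypes A [simulate_genotypes()] result.
#' @param traits A [simulate_traits()] result.
#' @param spec The same [cohort_spec()].
#' @return `traits` completed with diet_sfa/mufa/pufa (grams),
#'   diet_*_std (z-scores) and one 0/1 column per disease.
#' @export
simulate_diet_disease <- function(genotypes, traits, spec) {
  n <- spec$n
  with_seed(sub_seed(spec$seed, "diet_disease"), {
    for (d in names(spec$diet)) {
      mv <- spec$diet[[d]]
      g <- pmax(rnorm(n, mv[1], mv[2]), 0)
      traits[[paste0("diet_", d)]] <- g
      traits[[paste0("diet_", d, "_std")]] <- as.vector(scale(g))
    }
    for (dm in spec$disease) {
      g <- genotypes$dosage[, dm$variant]
      diet_std <- traits[[paste0("diet_", dm$diet, "_std")]]
      eta <- qlogis(dm$prevalence) +
        dm$beta_g * (g - mean(g)) + dm$beta_diet * diet_std +
        dm$gamma * (g - mean(g)) * diet_std +
        dm$beta_age * (traits$age - mean(traits$age)) +
        dm$beta_sex * (traits$sex - mean(traits$sex))
      traits[[dm$name]] <- rbinom(n, 1L, plogis(eta))
    }
    traits
  })
}

#' Block-correlated genotypes for colocalization experiments
#'
#' Draws two haplotypes per individual from a Gaussian copula with AR(1)
#' correlation `rho` across adjacent variants and thresholds them at the
#' allele frequency, giving Hardy-Weinberg genotypes with exponentially
#' decaying linkage disequilibrium inside the block.
#'
#' @param n Individuals; `m` variants; `maf` allele frequency (scalar or
#'   vector); `rho` adjacent-variant latent correlation; `seed` integer.
#' @param m,maf,rho,seed See above.
#' @return n x m dosage matrix (0/1/2).
#' @export
simulate_ld_genotypes <- function(n, m, maf = 0.3, rho = 0.9, seed = 1L) {
  maf <- rep_len(maf, m)
  with_seed(sub_seed(seed, "ld_genotypes"), {
    hap <- function() {
      z <- matrix(rnorm(n * m), n, m)
      for (j in 2:m) z[, j] <- rho * z[, j - 1] +
          sqrt(1 - rho^2) * z[, j]
      sweep(z, 2, qnorm(maf), `<`) * 1L
    }
    hap() + hap()
  })
}
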