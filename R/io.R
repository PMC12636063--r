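#' Write a volume as NIfTI-1
#'
#' @param arr 3-D or 4-D numeric array.
#' @param file Output path (`.nii` or `.nii.gz`).
#' @param voxel_size mm triple recorded in the header's pixdim.
#' @return The file path, invisibly.
#' @export
write_nifti_volume <- function(arr, file, voxel_size = c(2.5, 2.5, 6.0)) {
  attr(arr, "pixdim") <- c(voxel_size, rep(1, length(dim(arr)) - 3))
  img <- RNifti::asNifti(arr, datatype = "double")
  RNifti::writeNifti(img, file, datatype = "double")
  invisible(file)
}

#' Read a NIfTI-1 volume as a plain array
#' @param file Path to a `.nii`/`.nii.gz` file.
#' @return Numeric array with attribute `voxel_size`.
#' @export
read_nifti_volume <- function(file) {
  img <- RNifti::readNifti(file)
  arr <- array(as.numeric(img), dim = dim(img))
  attr(arr, "voxel_size") <- RNifti::pixdim(img)[1:3]
  arr
}

sumstats_schema <- c(rsID = "rsid", CHR = "chr", BP = "bp", EA = "ea",
                     OA = "oa", BETA = "beta", SE = "se", p = "p",
                     EAF = "eaf", N = "n")

#' Read a GWAS summary-statistics table
#'
#' Tab-separated with header columns rsID, CHR, BP, EA, OA, BETA, SE, p,
#' EAF, N (the `p` header may also be `P`). Positions may contain thousands
#' separators and p-values abbreviated scientific notation as printed in
#' journal tables (e.g. `4.E-293`); both are parsed exactly.
#'
#' @param path Input TSV path.
#' @return Data frame with lower-case internal column names.
#' @export
read_sumstats <- function(path) {
  raw <- read.delim(path, sep = "\t", colClasses = "character",
                    check.names = FALSE, strip.white = TRUE)
  names(raw)[names(raw) == "P"] <- "p"
  miss <- setdiff(names(sumstats_schema), names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  out <- raw[, names(sumstats_schema)]
  names(out) <- unname(sumstats_schema)
  num <- function(x, col) {
    x <- gsub(",", "", x)
    x <- gsub("−", "-", x)           # unicode minus as printed
    x <- sub("\\.E", "E", x)              # "4.E-293" style
    v <- suppressWarnings(as.numeric(x))
    if (any(is.na(v) & !(x %in% c("", "NA"))))
      stop("malformed value in column ", col, " at line ",
           which(is.na(v) & !(x %in% c("", "NA")))[1] + 1L)
    v
  }
  for (col in c("chr", "bp", "beta", "se", "p", "eaf", "n"))
    out[[col]] <- num(out[[col]], col)
  out
}

#' Write a GWAS summary-statistics table
#' @param stats Data frame with internal column names (see
#'   [read_sumstats()]).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_sumstats <- function(stats, path) {
  out <- stats[, unname(sumstats_schema)]
  names(out) <- names(sumstats_schema)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

pipeline_schema <- list(
  seed = NULL,
  out_format = NULL,
  protocol = c("field_strength", "echo_times", "repetition_time",
               "flip_angle", "water_ppm"),
  phantom = c("grid", "voxel_size", "sat", "vat", "smooth", "rim_mix",
              "amplitude", "noise_sd"),
  fit = c("cl", "ndb_bounds", "max_eval", "ftol"),
  postprocess = c("erode_iterations", "ff_threshold"),
  cohort = c("n", "m_variants", "maf_range", "dosage_noise_sd",
             "planted_index", "planted_beta_sat", "planted_beta_vat",
             "gamma", "interaction_diet", "interaction_disease"),
  coloc = c("n", "m", "maf", "rho", "beta_shared", "window_kb",
            "r2_threshold"))

validate_pipeline_config <- function(config) {
  unknown <- setdiff(names(config), names(pipeline_schema))
  if (length(unknown))
    stop("unknown config block(s): ", paste(unknown, collapse = ", "))
  for (blk in intersect(names(config), names(pipeline_schema))) {
    allowed <- pipeline_schema[[blk]]
    if (is.null(allowed)) next
    bad <- setdiff(names(config[[blk]]), allowed)
    if (length(bad))
      stop("unknown key(s) in config block '", blk, "': ",
           paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Default end-to-end pipeline configuration
#'
#' A demonstration-scale configuration: a 48 x 48 x 2 phantom, a cohort of
#' 2000 participants with 200 variants (one planted shared depot effect and
#' a planted genotype-by-diet interaction), and a 40-variant LD locus for
#' colocalization.
#'
#' @param seed Master seed for every stage.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       out_format = "nii",
       protocol = list(),
       phantom = list(grid = c(48L, 48L, 2L), noise_sd = 1),
       fit = list(cl = 17.4, ndb_bounds = c(1, 6)),
       postprocess = list(erode_iterations = 1L, ff_threshold = 0.20),
       cohort = list(n = 2000L, m_variants = 200L,
                     maf_range = c(0.05, 0.5), dosage_noise_sd = 0.05,
                     planted_index = 1L, planted_beta_sat = -0.12,
                     planted_beta_vat = -0.12, gamma = 0.15,
                     interaction_diet = "sfa",
                     interaction_disease = "cvd"),
       coloc = list(n = 2000L, m = 40L, maf = 0.3, rho = 0.9,
                    beta_shared = 0.25, window_kb = 200,
                    r2_threshold = 0.5))
}

#' Read and validate a pipeline configuration file
#' @param path YAML file.
#' @return Validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  config <- yaml::read_yaml(path)
  validate_pipeline_config(config)
  base <- default_pipeline_config(config$seed %||% 1L)
  for (blk in names(config)) {
    if (is.list(base[[blk]]) && is.list(config[[blk]])) {
      for (k in names(config[[blk]])) base[[blk]][[k]] <- config[[blk]][[k]]
    } else base[[blk]] <- config[[blk]]
  }
  base
}

#' Run the full synthetic pipeline
#'
#' Chains phantom generation, multi-echo rendering, voxel-wise fitting,
#' depot post-processing, cohort simulation, variant QC + GWAS of the
#' depot fSFA traits, depot heterogeneity, a two-half inverse-variance
#' meta-analysis of the planted variant's disease effect, the gene-diet
#' interaction model, and LD-locus colocalization. Every output file is
#' checksummed into a manifest enabling exact re-runs.
#'
#' @param config Configuration list from [default_pipeline_config()] or
#'   [read_pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest data frame (file, stage, md5, seed);
#'   also written to `manifest.tsv`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("adipocomp_run")) {
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  ext <- paste0(".", config$out_format %||% "nii")
  manifest <- data.frame(file = character(), stage = character(),
                         stringsAsFactors = FALSE)
  note <- function(files, stage) {
    manifest <<- rbind(manifest,
                       data.frame(file = basename(files), stage = stage))
  }
  protocol <- do.call(acq_protocol, config$protocol)

  ## stage 1: phantom truth + multi-echo rendering
  pspec <- do.call(phantom_spec,
                   c(config$phantom, list(seed = sub_seed(seed, "phantom"))))
  truth <- make_phantom(pspec)
  echoes <- render_multiecho(truth, protocol)
  f_ech <- file.path(out_dir, paste0("echoes", ext))
  write_nifti_volume(echoes, f_ech, pspec$voxel_size)
  f_sat <- file.path(out_dir, paste0("sat_mask", ext))
  f_vat <- file.path(out_dir, paste0("vat_mask", ext))
  write_nifti_volume(truth$sat_mask * 1, f_sat, pspec$voxel_size)
  write_nifti_volume(truth$vat_mask * 1, f_vat, pspec$voxel_size)
  note(c(f_ech, f_sat, f_vat), "phantom")

  ## stage 2: voxel-wise fitting
  fitcfg <- config$fit
  maps <- fit_volume(echoes, list(truth$sat_mask, truth$vat_mask), protocol,
                     cl = fitcfg$cl %||% 17.4,
                     ndb_bounds = unlist(fitcfg$ndb_bounds %||% c(1, 6)))
  map_files <- character()
  for (mname in c("f_sfa", "f_mufa", "f_pufa", "fat_fraction", "ndb")) {
    f <- file.path(out_dir, paste0(mname, ext))
    write_nifti_volume(maps[[mname]], f, pspec$voxel_size)
    map_files <- c(map_files, f)
  }
  note(map_files, "fit")

  ## stage 3: depot post-processing
  pp <- config$postprocess
  summ <- rbind(
    summarize_depot(maps, truth$sat_mask, "SAT",
                    pp$erode_iterations %||% 1L, pp$ff_threshold %||% 0.2),
    summarize_depot(maps, truth$vat_mask, "VAT",
                    pp$erode_iterations %||% 1L, pp$ff_threshold %||% 0.2))
  f_sum <- file.path(out_dir, "depot_summary.tsv")
  write.table(summ, f_sum, sep = "\t", quote = FALSE, row.names = FALSE)
  note(f_sum, "postprocess")

  ## stage 4: cohort simulation
  cc <- config$cohort
  vt <- variant_table(cc$m_variants, maf = unlist(cc$maf_range),
                      seed = sub_seed(seed, "variants"))
  pi <- cc$planted_index %||% 1L
  vt$beta_sat[pi] <- cc$planted_beta_sat %||% 0
  vt$beta_vat[pi] <- cc$planted_beta_vat %||% 0
  disease <- list(
    list(name = "hypertension", prevalence = 0.36, beta_g = 0,
         beta_diet = 0.10, gamma = 0, diet = "sfa", variant = pi,
         beta_age = 0.03, beta_sex = 0.3),
    list(name = "t2d", prevalence = 0.053, beta_g = 0, beta_diet = 0.10,
         gamma = 0, diet = "sfa", variant = pi, beta_age = 0.03,
         beta_sex = 0.3),
    list(name = "cvd", prevalence = 0.098, beta_g = 0.05, beta_diet = 0.10,
         gamma = cc$gamma %||% 0.15, diet = cc$interaction_diet %||% "sfa",
         variant = pi, beta_age = 0.03, beta_sex = 0.3))
  cspec <- cohort_spec(n = cc$n, variants = vt,
                       dosage_noise_sd = cc$dosage_noise_sd %||% 0.05,
                       disease = disease,
                       seed = sub_seed(seed, "cohort"))
  geno <- simulate_genotypes(cspec)
  pheno <- simulate_traits(geno, cspec)
  pheno <- simulate_diet_disease(geno, pheno, cspec)
  f_ann <- file.path(out_dir, "variants.tsv")
  f_phe <- file.path(out_dir, "phenotypes.tsv")
  f_dos <- file.path(out_dir, "dosages.tsv")
  write.table(geno$annotations, f_ann, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(pheno, f_phe, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(round(geno$dosage, 4), f_dos, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = geno$annotations$rsid)
  note(c(f_ann, f_phe, f_dos), "cohort")

  ## stage 5: QC + GWAS of depot fSFA traits
  keep <- filter_variants(geno$annotations)
  kidx <- match(keep$rsid, geno$annotations$rsid)
  covars <- pheno[, c("age", "age2", "sex", "array", "centre",
                      paste0("pc", 1:10))]
  stats_files <- character()
  gstats <- list()
  for (depot in c("sat", "vat")) {
    y <- inverse_normal_transform(pheno[[paste0(depot, "_fsfa")]])
    tab <- gwas_scan(geno$dosage[, kidx, drop = FALSE], y, covars, keep)
    gstats[[depot]] <- tab
    f <- file.path(out_dir, paste0("gwas_", depot, "_fsfa.tsv"))
    write_sumstats(tab, f)
    stats_files <- c(stats_files, f)
  }
  note(stats_files, "gwas")

  ## stage 6: depot heterogeneity
  het <- depot_heterogeneity(gstats$sat, gstats$vat)
  f_het <- file.path(out_dir, "heterogeneity.tsv")
  write.table(het, f_het, sep = "\t", quote = FALSE, row.names = FALSE)
  note(f_het, "het")

  ## stage 7: two-half IVW meta-analysis of the planted variant on disease
  dname <- cc$interaction_disease %||% "cvd"
  half <- rep(c(1L, 2L), length.out = cspec$n)
  halves <- lapply(1:2, function(h) {
    sel <- half == h
    X <- cbind(intercept = 1, g = geno$dosage[sel, pi],
               age = pheno$age[sel], sex = pheno$sex[sel])
    fit <- irls_logistic(X, pheno[[dname]][sel])
    data.frame(beta = fit$coef[["g"]], se = sqrt(fit$vcov[2, 2]))
  })
  meta <- ivw_meta(vapply(halves, `[[`, 0, "beta"),
                   vapply(halves, `[[`, 0, "se"))
  f_meta <- file.path(out_dir, "meta.tsv")
  write.table(data.frame(outcome = dname, beta = meta$beta, se = meta$se,
                         p = meta$p, n_studies = meta$n_studies),
              f_meta, sep = "\t", quote = FALSE, row.names = FALSE)
  note(f_meta, "meta")

  ## stage 8: gene-diet interaction
  ia <- interaction_logistic(pheno[[dname]], geno$dosage[, pi],
                             pheno[[paste0("diet_",
                                           cc$interaction_diet %||% "sfa",
                                           "_std")]],
                             pheno$age, pheno$sex)
  f_int <- file.path(out_dir, "interaction.tsv")
  write.table(data.frame(outcome = dname, gamma_hat = ia$gamma_hat,
                         se = ia$se, p = ia$p),
              f_int, sep = "\t", quote = FALSE, row.names = FALSE)
  note(f_int, "interact")

  ## stage 9: colocalization at a dedicated LD locus (shared causal)
  cl <- config$coloc
  locus <- simulate_coloc_locus(n = cl$n, m = cl$m, maf = cl$maf,
                                rho = cl$rho, beta1 = cl$beta_shared,
                                beta2 = cl$beta_shared, shared = TRUE,
                                seed = sub_seed(seed, "coloc"))
  cres <- coloc_locus(locus$stats1, locus$stats2, r2 = locus$r2,
                      r2_threshold = cl$r2_threshold %||% 0.5)
  f_col <- file.path(out_dir, "coloc.tsv")
  write.table(data.frame(hypothesis = names(cres$pp), pp = cres$pp,
                         n_variants_after_prune = cres$n_variants_after_prune),
              f_col, sep = "\t", quote = FALSE, row.names = FALSE)
  note(f_col, "coloc")

  ## manifest
  manifest$md5 <- unname(tools::md5sum(file.path(out_dir, manifest$file)))
  manifest$seed <- seed
  if (anyNA(manifest$md5)) stop("stage output missing: run marked invalid")
  f_man <- file.path(out_dir, "manifest.tsv")
  write.table(manifest, f_man, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Simulate a two-trait locus for colocalization experiments
#'
#' Block-correlated genotypes ([simulate_ld_genotypes()]) with one causal
#' variant per trait (the same variant when `shared`, otherwise two
#' variants picked at opposite ends of the block, in low LD), per-variant
#' association scans of both traits, and the empirical r^2 matrix.
#'
#' @param n Individuals; `m` variants in the block.
#' @param m,maf,rho Block parameters (see [simulate_ld_genotypes()]).
#' @param beta1,beta2 Causal effects on traits 1 and 2 (trait SD units).
#' @param shared One shared causal variant (TRUE) or two distinct ones.
#' @param seed Integer seed.
#' @return List: `stats1`, `stats2`, `r2`, `causal1`, `causal2`.
#' @export
simulate_coloc_locus <- function(n = 2000, m = 50, maf = 0.3, rho = 0.9,
                                 beta1 = 0.25, beta2 = 0.25, shared = TRUE,
                                 seed = 1L) {
  G <- simulate_ld_genotypes(n, m, maf, rho, seed = sub_seed(seed, "geno"))
  c1 <- floor(m / 2)
  c2 <- if (shared) c1 else max(1L, m - 2L)
  with_seed(sub_seed(seed, "traits"), {
    y1 <- beta1 * G[, c1] + rnorm(n)
    y2 <- beta2 * G[, c2] + rnorm(n)
  })
  ann <- data.frame(rsid = sprintf("rs%05d", seq_len(m)), chr = 1L,
                    bp = 500000L + seq_len(m) * 2000L,
                    ea = "A", oa = "G")
  s1 <- gwas_scan(G, y1, annotations = ann)
  s2 <- gwas_scan(G, y2, annotations = ann)
  r2 <- cor(G)^2
  dimnames(r2) <- list(ann$rsid, ann$rsid)
  list(stats1 = s1, stats2 = s2, r2 = r2,
       causal1 = ann$rsid[c1], causal2 = ann$rsid[c2])
}
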