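# Synthetic multiview cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: J
# feature views sharing a latent cluster structure (optionally through a
# nonlinear map), clinical measures shifted by subtype, conversion hazards
# that differ between subtypes with independent censoring, and
# additive-coded genotypes whose causal minor-allele frequencies differ
# between cases and controls.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a three-modality imaging cohort of mild cognitive
#' impairment (MCI) participants: 308 cases with 116 region-of-interest
#' features per view, 219 additional controls for the genetic arm, 2650
#' quality-controlled SNPs (minor allele frequency at least 5\%), 11
#' baseline clinical measures and 4 covariates.
#'
#' @param n_samples number of case (MCI-like) samples N.
#' @param n_views number of feature views J.
#' @param view_dims integer vector of view widths p_j (recycled to J).
#' @param latent_dim dimension d of the shared latent factor.
#' @param n_clusters number of latent clusters (subtypes).
#' @param cluster_separation pairwise Euclidean distance between latent
#'   cluster means, in units of the latent noise standard deviation (1).
#' @param nonlinearity one of `"linear"`, `"tanh"`, `"quadratic"`; the
#'   elementwise map applied to the mixed latent signal per view.
#' @param noise_sd additive Gaussian noise standard deviation per view.
#' @param n_controls size of the control cohort used by the genetic arm.
#' @param n_snps number of SNPs.
#' @param n_causal_snps number of SNPs whose case-group allele frequency is
#'   shifted.
#' @param maf_range length-2 vector in (0, 0.5]: minor allele frequencies
#'   are drawn uniformly from this range.
#' @param causal_af_shift additive shift of the case-group allele frequency
#'   at causal SNPs, in `[0, 0.5)`.
#' @param hazard_ratio conversion hazard of subtype 2 relative to subtype 1.
#' @param censor_rate target fraction of censored survival records in
#'   `[0, 1)`.
#' @param clinical_effect_sizes standardized mean shift of each of the 11
#'   clinical measures in subtype 2.
#' @param seed integer seed; every generator is deterministic given it.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 308L,
                             n_views = 3L,
                             view_dims = 116L,
                             latent_dim = 5L,
                             n_clusters = 2L,
                             cluster_separation = 4,
                             nonlinearity = c("linear", "tanh", "quadratic"),
                             noise_sd = 0.5,
                             n_controls = 219L,
                             n_snps = 2650L,
                             n_causal_snps = 25L,
                             maf_range = c(0.05, 0.5),
                             causal_af_shift = 0.1,
                             hazard_ratio = 2,
                             censor_rate = 0.3,
                             clinical_effect_sizes = rep(0.5, 11L),
                             seed = 1L) {
  nonlinearity <- match.arg(nonlinearity)
  view_dims <- rep_len(as.integer(view_dims), n_views)
  cfg <- list(
    n_samples = as.integer(n_samples), n_views = as.integer(n_views),
    view_dims = view_dims, latent_dim = as.integer(latent_dim),
    n_clusters = as.integer(n_clusters),
    cluster_separation = cluster_separation, nonlinearity = nonlinearity,
    noise_sd = noise_sd, n_controls = as.integer(n_controls),
    n_snps = as.integer(n_snps), n_causal_snps = as.integer(n_causal_snps),
    maf_range = maf_range, causal_af_shift = causal_af_shift,
    hazard_ratio = hazard_ratio, censor_rate = censor_rate,
    clinical_effect_sizes = clinical_effect_sizes, seed = as.integer(seed)
  )
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    for (nm in c("n_samples", "n_views", "latent_dim", "n_clusters"))
      if (!.is_count(cfg[[nm]])) .stopf("'%s' must be a count >= 1", nm)
    if (any(view_dims < 1)) .stopf("view_dims must all be >= 1")
    if (latent_dim > min(view_dims))
      .stopf("latent_dim (%d) exceeds min(view_dims) (%d)",
             latent_dim, min(view_dims))
    if (n_clusters > n_samples)
      .stopf("n_clusters (%d) exceeds n_samples (%d)", n_clusters, n_samples)
    if (n_clusters > latent_dim + 1L)
      .stopf("n_clusters must be <= latent_dim + 1 for a regular simplex")
    if (cluster_separation < 0) .stopf("cluster_separation must be >= 0")
    if (noise_sd < 0) .stopf("noise_sd must be >= 0")
    if (maf_range[1] <= 0 || maf_range[2] > 0.5 ||
        maf_range[1] > maf_range[2])
      .stopf("maf_range must satisfy 0 < low <= high <= 0.5")
    if (causal_af_shift < 0 || causal_af_shift >= 0.5)
      .stopf("causal_af_shift must lie in [0, 0.5)")
    if (hazard_ratio <= 0) .stopf("hazard_ratio must be > 0")
    if (censor_rate < 0 || censor_rate >= 1)
      .stopf("censor_rate must lie in [0, 1)")
    if (length(clinical_effect_sizes) != 11L)
      .stopf("clinical_effect_sizes must have length 11, got %d",
             length(clinical_effect_sizes))
    if (n_causal_snps > n_snps) .stopf("n_causal_snps exceeds n_snps")
  })
  invisible(cfg)
}

#' Bundle aligned feature views into a multiview dataset
#'
#' @param views list of J numeric matrices, all with N rows in the same
#'   sample order.
#' @param sample_ids character vector of N unique identifiers.
#' @param feature_names optional list of per-view feature-name vectors.
#' @param stage_labels optional per-sample categorical stage label (the
#'   early/late clinical-stage analog).
#' @param covariates optional data frame of per-sample covariates.
#' @return an object of class `mv_dataset`.
#' @export
multiview_dataset <- function(views, sample_ids = NULL, feature_names = NULL,
                              stage_labels = NULL, covariates = NULL) {
  if (!length(views)) .stopf("need at least one view")
  n <- nrow(views[[1L]])
  if (!all(vapply(views, nrow, 0L) == n))
    .stopf("all views must share the same number of rows")
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(n))
  if (anyDuplicated(sample_ids)) .stopf("sample_ids must be unique")
  if (length(sample_ids) != n) .stopf("sample_ids length mismatch")
  if (any(vapply(views, function(v) anyNA(v), TRUE)))
    .stopf("views must not contain missing values")
  if (is.null(feature_names))
    feature_names <- lapply(views, function(v)
      colnames(v) %||% sprintf("f%03d", seq_len(ncol(v))))
  views <- Map(function(v, fn) {
    colnames(v) <- fn
    rownames(v) <- sample_ids
    v
  }, views, feature_names)
  if (is.null(names(views))) names(views) <- paste0("view", seq_along(views))
  if (!is.null(stage_labels) && length(stage_labels) != n)
    .stopf("stage_labels length mismatch")
  structure(list(views = views, sample_ids = sample_ids,
                 feature_names = feature_names, stage_labels = stage_labels,
                 covariates = covariates),
            class = "mv_dataset")
}

#' @export
print.mv_dataset <- function(x, ...) {
  cat(sprintf("mv_dataset: %d samples, %d views (%s)\n",
              length(x$sample_ids), length(x$views),
              paste(vapply(x$views, ncol, 0L), collapse = ", ")))
  invisible(x)
}

# Vertices of a regular (c-1)-simplex in R^d, centered, all pairwise
# distances equal to `sep`.
.simplex_means <- function(n_clusters, d, sep) {
  if (n_clusters == 1L) return(matrix(0, 1L, d))
  V <- diag(n_clusters)
  V <- sweep(V, 2L, colMeans(V))           # center; rows span c-1 dims
  co <- svd(V)
  M <- (co$u %*% diag(co$d, n_clusters))[, seq_len(n_clusters - 1L),
                                         drop = FALSE]
  M <- M * sep / sqrt(2)                   # identity rows are sqrt(2) apart
  cbind(M, matrix(0, n_clusters, d - ncol(M)))
}

.apply_nonlinearity <- function(x, kind) {
  switch(kind,
         linear = x,
         tanh = tanh(x),
         # sign-preserving quadratic polynomial; a pure square would erase
         # the symmetric cluster signal entirely
         quadratic = x + 0.5 * x^2)
}

#' Generate multiview data with shared latent cluster structure
#'
#' Cluster labels are drawn uniformly; latent factors follow
#' `z_i ~ N(mu_c, I_d)` with cluster means at the vertices of a regular
#' simplex so every pair of means is `cluster_separation` apart. Each view
#' is `X_j = f_j(z A_j) + eps_j` with a fixed random mixing matrix `A_j`
#' (standard normal entries), `f_j` the configured elementwise
#' nonlinearity, and isotropic Gaussian noise.
#'
#' Stage labels (the early/late clinical-stage analog) are drawn with a
#' deliberately weak dependence on the latent cluster: the subtypes the
#' pipeline recovers are meant to be distinct from staging, not a relabeling
#' of it.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `dataset` (an [multiview_dataset()]) and
#'   `truth` (latent matrix, cluster labels, cluster means, mixing
#'   matrices).
#' @export
generate_multiview <- function(config) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  n <- config$n_samples; d <- config$latent_dim; cK <- config$n_clusters
  labels <- sample.int(cK, n, replace = TRUE)
  while (length(unique(labels)) < cK)      # every cluster inhabited
    labels <- sample.int(cK, n, replace = TRUE)
  mu <- .simplex_means(cK, d, config$cluster_separation)
  z <- mu[labels, , drop = FALSE] + matrix(stats::rnorm(n * d), n, d)
  views <- vector("list", config$n_views)
  mixing <- vector("list", config$n_views)
  for (j in seq_len(config$n_views)) {
    p <- config$view_dims[j]
    A <- matrix(stats::rnorm(d * p), d, p)
    Xj <- .apply_nonlinearity(z %*% A, config$nonlinearity)
    if (config$noise_sd > 0)
      Xj <- Xj + matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p)
    colnames(Xj) <- sprintf("ROI%03d", seq_len(p))
    views[[j]] <- Xj
    mixing[[j]] <- A
  }
  # weak cluster/stage association: subtypes are not a relabeled staging
  p_late <- ifelse(labels == 2L, 0.45, 0.35)
  stage <- ifelse(stats::runif(n) < p_late, "LMCI", "EMCI")
  covariates <- data.frame(
    age = stats::rnorm(n, 72, 7),
    gender = stats::rbinom(n, 1L, 0.5),
    education = stats::rnorm(n, 16, 2.6),
    apoe4 = stats::rbinom(n, 2L, 0.3)
  )
  ds <- multiview_dataset(views, sprintf("S%04d", seq_len(n)),
                          stage_labels = stage, covariates = covariates)
  list(dataset = ds,
       truth = list(latent = z, cluster_labels = labels, means = mu,
                    mixing = mixing))
}

.clinical_measures <- c("ADAS13", "MMSE", "CDRSB", "RAVLT", "FAQ",
                        "Ventricles", "Hippocampus", "WholeBrain",
                        "Entorhinal", "Fusiform", "MidTemp")

#' Generate a clinical table with subtype-shifted measures
#'
#' Each of the 11 measures (5 cognitive-score analogs and 6 brain-volume
#' analogs, on a standardized scale) is
#' `baseline + effect_size * 1[label == 2] + N(0, 1)` noise. Covariates
#' follow fixed simple distributions: age ~ N(72, 7), fair-coin gender,
#' education ~ N(16, 2.6), APOE4-like allele count ~ Binomial(2, 0.3).
#'
#' @param labels per-sample integer cluster/subtype labels.
#' @param config a [synthetic_config()]; `clinical_effect_sizes` must have
#'   length 11.
#' @return data frame with `sample_id`, 11 measure columns and 4 covariate
#'   columns.
#' @export
generate_clinical <- function(labels, config) {
  validate_synthetic_config(config)
  if (length(config$clinical_effect_sizes) != 11L)
    .stopf("clinical_effect_sizes must have length 11")
  n <- length(labels)
  set.seed(stage_seed(config$seed, 11L))
  shift <- as.numeric(labels == 2L)
  meas <- sapply(seq_len(11L), function(m)
    config$clinical_effect_sizes[m] * shift + stats::rnorm(n))
  colnames(meas) <- .clinical_measures
  data.frame(sample_id = sprintf("S%04d", seq_len(n)), meas,
             age = stats::rnorm(n, 72, 7),
             gender = stats::rbinom(n, 1L, 0.5),
             education = stats::rnorm(n, 16, 2.6),
             apoe4 = stats::rbinom(n, 2L, 0.3))
}

#' Generate conversion (survival) records with subtype-dependent hazard
#'
#' Event times are exponential with rate
#' `lambda0 * hazard_ratio^(label == 2)`; the baseline rate fixes a
#' 36-month median time to conversion for subtype 1. Censoring is an
#' independent exponential clock whose rate is tuned in closed form so that
#' approximately `censor_rate` of records are censored:
#' `mu = censor_rate * mean(lambda) / (1 - censor_rate)`.
#'
#' @param labels per-sample integer subtype labels.
#' @param config a [synthetic_config()].
#' @return data frame `sample_id`, `time` (months), `event` (1 =
#'   converted), `group` (subtype label).
#' @export
generate_survival <- function(labels, config) {
  validate_synthetic_config(config)
  if (config$censor_rate >= 1) .stopf("censor_rate must be < 1")
  n <- length(labels)
  set.seed(stage_seed(config$seed, 12L))
  lambda0 <- log(2) / 36
  rate <- lambda0 * config$hazard_ratio^(labels == 2L)
  tt <- stats::rexp(n, rate)
  if (config$censor_rate > 0) {
    mu <- config$censor_rate * mean(rate) / (1 - config$censor_rate)
    cens <- stats::rexp(n, mu)
    event <- as.integer(tt <= cens)
    tt <- pmin(tt, cens)
  } else {
    event <- rep(1L, n)
  }
  data.frame(sample_id = sprintf("S%04d", seq_len(n)),
             time = tt, event = event, group = labels)
}

#' Generate additive-coded genotypes for a case-control cohort
#'
#' Minor allele frequencies are drawn uniformly from `maf_range`. Every SNP
#' is generated by Hardy-Weinberg draws (`Binomial(2, AF)`); at causal SNPs
#' the case-group allele frequency is shifted by `causal_af_shift` while
#' controls stay at the common frequency. A control cohort of
#' `n_controls` samples is appended after the case samples.
#'
#' @param labels per-sample subtype labels for the case cohort (its length
#'   sets the number of cases).
#' @param n_controls number of control samples.
#' @param config a [synthetic_config()].
#' @return list with `genotypes` (samples x n_snps integer matrix, 0/1/2),
#'   `phenotype` (1 = case), `covariates` (age, gender, education),
#'   `subtype` (case subtype, NA for controls) and `snp_info` (snp_id,
#'   chromosome, maf, causal flag).
#' @export
generate_genotypes <- function(labels, n_controls = NULL, config) {
  validate_synthetic_config(config)
  n_controls <- n_controls %||% config$n_controls
  n_case <- length(labels)
  S <- config$n_snps
  set.seed(stage_seed(config$seed, 13L))
  maf <- stats::runif(S, config$maf_range[1], config$maf_range[2])
  causal <- sort(sample.int(S, config$n_causal_snps))
  case_af <- maf
  case_af[causal] <- maf[causal] + config$causal_af_shift
  if (any(case_af <= 0 | case_af >= 1))
    .stopf("causal_af_shift pushes an allele frequency outside (0, 1)")
  n <- n_case + n_controls
  geno <- matrix(0L, n, S)
  for (s in seq_len(S)) {
    geno[, s] <- c(stats::rbinom(n_case, 2L, case_af[s]),
                   stats::rbinom(n_controls, 2L, maf[s]))
  }
  snp_id <- sprintf("snp%04d", seq_len(S))
  colnames(geno) <- snp_id
  rownames(geno) <- c(sprintf("S%04d", seq_len(n_case)),
                      sprintf("C%04d", seq_len(n_controls)))
  list(genotypes = geno,
       phenotype = c(rep(1L, n_case), rep(0L, n_controls)),
       covariates = data.frame(age = stats::rnorm(n, 72, 7),
                               gender = stats::rbinom(n, 1L, 0.5),
                               education = stats::rnorm(n, 16, 2.6)),
       subtype = c(labels, rep(NA_integer_, n_controls)),
       snp_info = data.frame(snp_id = snp_id,
                             chromosome = sort(rep_len(1:22, S)),
                             maf = maf,
                             causal = seq_len(S) %in% causal))
}

#' Write multiview views as CSV files
#'
#' One file per view, `sample_id` as mandatory first column.
#'
#' @param dataset an [multiview_dataset()].
#' @param dir output directory (created if absent).
#' @return invisibly, the written paths.
#' @export
write_views_csv <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(dataset$views), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(data.frame(sample_id = dataset$sample_ids,
                                dataset$views[[nm]], check.names = FALSE),
                     p, row.names = FALSE)
    p
  }, "")
  invisible(paths)
}

#' Write genotypes in the PLINK additive text (.raw-style) dialect
#'
#' Header `FID IID PAT MAT SEX PHENOTYPE` then one 0/1/2 column per SNP.
#' PLINK coding: SEX 1 = male, 2 = female; PHENOTYPE 1 = control,
#' 2 = case.
#'
#' @param genotypes samples x SNPs matrix of 0/1/2 counts with rownames.
#' @param phenotype binary vector, 1 = case.
#' @param path output file.
#' @param sex optional binary vector (1 = male coded 1, 0 = female coded 2).
#' @return invisibly, `path`.
#' @export
write_plink_raw <- function(genotypes, phenotype, path, sex = NULL) {
  ids <- rownames(genotypes) %||% sprintf("S%04d", seq_len(nrow(genotypes)))
  sexcol <- if (is.null(sex)) rep(0L, nrow(genotypes)) else ifelse(sex == 1, 1L, 2L)
  df <- data.frame(FID = ids, IID = ids, PAT = 0L, MAT = 0L, SEX = sexcol,
                   PHENOTYPE = ifelse(phenotype == 1, 2L, 1L),
                   genotypes, check.names = FALSE)
  utils::write.table(df, path, quote = FALSE, sep = " ", row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a PLINK additive text (.raw-style) file
#'
#' @param path file written by [write_plink_raw()] or PLINK `--recode A`.
#' @return list with `genotypes` (matrix, IID rownames) and `phenotype`
#'   (1 = case).
#' @export
read_plink_raw <- function(path) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE)
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(meta %in% names(df))) .stopf("not a PLINK .raw-style file: %s", path)
  geno <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  rownames(geno) <- df$IID
  list(genotypes = geno, phenotype = as.integer(df$PHENOTYPE == 2L))
}
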