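# End-to-end orchestration of the multi-experiment subtyping design:
# per-view raw-feature experiments plus GCCA and DGCCA embedding
# experiments, each clustered into subtypes and validated against clinical
# measures, conversion, and genotypes. Deterministic under a single global
# seed fanned out to per-stage seeds (see stage_seed()).

#' Pipeline configuration
#'
#' Either a `synthetic` block ([synthetic_config()]) or a `paths` list of
#' CSV inputs must be supplied. Default experiments: one per raw view,
#' plus GCCA and DGCCA embedding experiments. The number of GCCA
#' components is chosen to match the variance explained by the DGCCA
#' embedding (variance matching); the DGCCA embedding uses its full k.
#'
#' @param synthetic optional [synthetic_config()] block.
#' @param paths optional named list: `views` (character vector of CSVs),
#'   `clinical`, `survival`, `genotypes` (PLINK .raw-style or CSV).
#' @param experiments character vector among `"raw"`, `"gcca"`, `"dgcca"`.
#' @param n_clusters clusters per experiment (default 2).
#' @param linkage clustering linkage (default "ward").
#' @param train a [train_config()] for DGCCA (its seed is overridden by
#'   the pipeline seed fan-out).
#' @param gcca_k number of GCCA components to compute before variance
#'   matching (default 100, capped at sample count).
#' @param alpha familywise level for the rank-sum battery (default 0.01).
#' @param q FDR level for association tests (default 0.05).
#' @param n_permutations permutations for the independence screen
#'   (default 199; 0 disables the screen).
#' @param cox_penalty elastic-net strength for the Cox fit (default 0.1).
#' @param outdir output directory.
#' @param seed global integer seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, paths = NULL,
                            experiments = c("raw", "gcca", "dgcca"),
                            n_clusters = 2L, linkage = "ward",
                            train = train_config(),
                            gcca_k = 100L, alpha = 0.01, q = 0.05,
                            n_permutations = 199L, cox_penalty = 0.1,
                            outdir = tempfile("mvsubtype_run_"),
                            seed = 1L) {
  experiments <- match.arg(experiments, several.ok = TRUE)
  if (is.null(synthetic) && is.null(paths))
    .stopf("either a synthetic block or input paths must be supplied")
  structure(list(synthetic = synthetic, paths = paths,
                 experiments = experiments, n_clusters = as.integer(n_clusters),
                 linkage = linkage, train = train, gcca_k = as.integer(gcca_k),
                 alpha = alpha, q = q,
                 n_permutations = as.integer(n_permutations),
                 cox_penalty = cox_penalty, outdir = outdir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load aligned views from CSV files
#'
#' Each file must have a `sample_id` first column and unique ids; rows are
#' inner-joined on `sample_id` and returned in a canonical (sorted) order.
#' Samples absent from any view are dropped and reported.
#'
#' @param paths character vector of CSV paths (optionally named).
#' @return an [multiview_dataset()].
#' @export
load_views <- function(paths) {
  tabs <- lapply(paths, function(p) {
    df <- utils::read.csv(p, check.names = FALSE)
    if (names(df)[1L] != "sample_id")
      .stopf("%s: first column must be 'sample_id'", p)
    if (anyDuplicated(df$sample_id))
      .stopf("%s: duplicated sample ids", p)
    df
  })
  ids <- Reduce(intersect, lapply(tabs, function(d) d$sample_id))
  if (!length(ids)) {
    counts <- paste(sprintf("%s: %d", basename(unlist(paths)),
                            vapply(tabs, nrow, 0L)), collapse = "; ")
    .stopf("views share no sample ids (%s)", counts)
  }
  dropped <- sum(vapply(tabs, nrow, 0L) - length(ids))
  if (dropped > 0)
    message(sprintf("load_views: dropped %d non-shared rows across views",
                    dropped))
  ids <- sort(as.character(ids))
  views <- lapply(tabs, function(d) {
    m <- as.matrix(d[match(ids, d$sample_id), -1L, drop = FALSE])
    storage.mode(m) <- "double"
    if (anyNA(m)) .stopf("missing values after load")
    m
  })
  nm <- names(paths) %||% tools::file_path_sans_ext(basename(unlist(paths)))
  names(views) <- nm
  multiview_dataset(views, sample_ids = ids)
}

.write_csv <- function(df, dir, name, manifest) {
  p <- file.path(dir, name)
  utils::write.csv(df, p, row.names = FALSE)
  manifest$files[[name]] <- list(path = p,
                                 md5 = unname(tools::md5sum(p)),
                                 rows = nrow(df))
  manifest
}

#' Run the full multi-experiment subtyping pipeline
#'
#' Stages: data generation/loading; GCCA and DGCCA fits with variance
#' matching; per-experiment agglomerative clustering, subtype mapping,
#' validity metrics and confusion tables; pairwise cross-experiment AMI;
#' independence screen between the first two views; clinical rank-sum
#' battery; survival (log-rank, penalized Cox, conversion curves); and
#' per-subtype-vs-control SNP association with BH flags. Stages whose
#' inputs are unavailable are skipped with a logged warning. Rerunning
#' with the same config reproduces every output bit-identically.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) the manifest: output files with MD5 hashes and row
#'   counts, per-stage seeds, and the per-experiment label sets.
#' @export
run_pipeline <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(files = list(), seeds = list(), skipped = character(),
                   experiments = list())
  log_skip <- function(stage, why) {
    manifest$skipped <<- c(manifest$skipped, stage)
    message(sprintf("run_pipeline: skipping %s (%s)", stage, why))
  }

  # --- stage 0: data ------------------------------------------------------
  clinical <- survdf <- geno <- truth <- NULL
  if (!is.null(config$synthetic)) {
    scfg <- config$synthetic
    scfg$seed <- stage_seed(config$seed, 0L)
    manifest$seeds$data <- scfg$seed
    gen <- generate_multiview(scfg)
    dataset <- gen$dataset
    truth <- gen$truth
    clinical <- generate_clinical(truth$cluster_labels, scfg)
    survdf <- generate_survival(truth$cluster_labels, scfg)
    geno <- generate_genotypes(truth$cluster_labels, scfg$n_controls, scfg)
  } else {
    dataset <- load_views(config$paths$views)
    if (!is.null(config$paths$clinical))
      clinical <- utils::read.csv(config$paths$clinical, check.names = FALSE)
    if (!is.null(config$paths$survival))
      survdf <- utils::read.csv(config$paths$survival, check.names = FALSE)
    if (!is.null(config$paths$genotypes)) {
      pg <- read_plink_raw(config$paths$genotypes)
      geno <- list(genotypes = pg$genotypes, phenotype = pg$phenotype,
                   covariates = NULL, subtype = NULL, snp_info = NULL)
    }
  }
  n <- length(dataset$sample_ids)
  J <- length(dataset$views)

  # --- stage 1: embeddings ------------------------------------------------
  Xs <- standardize_views(dataset$views)
  feature_sets <- list()
  if ("raw" %in% config$experiments)
    for (j in seq_len(J))
      feature_sets[[paste0("raw_", names(dataset$views)[j])]] <- Xs[[j]]
  gcca_fit_obj <- dgcca_model <- NULL
  dg_curve <- NULL
  if ("dgcca" %in% config$experiments) {
    tc <- config$train
    tc$seed <- stage_seed(config$seed, 2L)
    manifest$seeds$dgcca <- tc$seed
    k_eff <- min(tc$k, n - 2L, min(vapply(dataset$views, ncol, 0L)))
    tc$k <- as.integer(k_eff)
    dgcca_model <- train_dgcca(dataset, config = tc)
    emb <- dgcca_embed(dgcca_model, dataset)
    feature_sets[["dgcca"]] <- emb$G
    # variance matching target from the training-split embedding
    Xtr <- lapply(Xs, function(v) v[dgcca_model$train_idx, , drop = FALSE])
    dg_curve <- variance_curve(Xtr, dgcca_model$G_train)
    manifest$dgcca_variance <- dg_curve[length(dg_curve)]
    manifest <- .write_csv(dgcca_model$history, config$outdir,
                           "dgcca_history.csv", manifest)
  }
  if ("gcca" %in% config$experiments) {
    kg <- min(config$gcca_k, n, sum(vapply(dataset$views, ncol, 0L)))
    gcca_fit_obj <- fit_gcca(Xs, k = kg)
    g_curve <- variance_curve(Xs, gcca_fit_obj$G)
    target <- if (!is.null(dg_curve)) dg_curve[length(dg_curve)] else 0.7
    sel <- suppressWarnings(select_components(g_curve, target))
    manifest$gcca_components <- sel$chosen_r
    manifest$gcca_variance <- g_curve[sel$chosen_r]
    feature_sets[["gcca"]] <-
      gcca_fit_obj$G[, seq_len(sel$chosen_r), drop = FALSE]
  }

  # --- stage 2: clustering + metrics --------------------------------------
  outcomes <- list(); metrics <- list()
  for (nm in names(feature_sets)) {
    F <- feature_sets[[nm]]
    lab <- cluster_agglomerative(F, config$n_clusters, config$linkage)
    sub <- if (config$n_clusters == 2L && !is.null(dataset$stage_labels))
      assign_subtype_labels(lab, dataset$stage_labels)$subtypes else lab
    outcomes[[nm]] <- sub
    ami_stage <- if (!is.null(dataset$stage_labels))
      ami_score(sub, dataset$stage_labels) else NA_real_
    metrics[[nm]] <- data.frame(
      experiment = nm, n_features = ncol(F),
      ch = ch_score(F, sub), silhouette = silhouette_score(F, sub),
      ami_vs_stage = ami_stage,
      ami_vs_truth = if (!is.null(truth))
        ami_score(sub, truth$cluster_labels) else NA_real_)
    if (!is.null(dataset$stage_labels) && config$n_clusters == 2L) {
      ct <- as.data.frame(confusion_table(sub, dataset$stage_labels))
      manifest <- .write_csv(ct, config$outdir,
                             paste0("confusion_", nm, ".csv"), manifest)
    }
  }
  subtypes_df <- data.frame(sample_id = dataset$sample_ids,
                            as.data.frame(outcomes, check.names = FALSE))
  manifest <- .write_csv(subtypes_df, config$outdir, "subtypes.csv", manifest)
  manifest <- .write_csv(do.call(rbind, metrics), config$outdir,
                         "metrics.csv", manifest)
  sim <- pairwise_cluster_similarity(outcomes)
  manifest <- .write_csv(data.frame(experiment = rownames(sim), sim,
                                    check.names = FALSE),
                         config$outdir, "experiment_similarity.csv", manifest)
  manifest$experiments <- outcomes

  # --- stage 3: independence screen ---------------------------------------
  if (config$n_permutations > 0L && J >= 2L) {
    it <- independence_permutation_test(
      Xs[[1L]], Xs[[2L]], config$n_clusters,
      n_permutations = config$n_permutations,
      seed = stage_seed(config$seed, 3L), linkage = config$linkage)
    manifest$seeds$independence <- stage_seed(config$seed, 3L)
    manifest <- .write_csv(
      data.frame(view_pair = paste(names(dataset$views)[1:2], collapse = "-"),
                 statistic = it$statistic, p_value = it$p_value,
                 n_permutations = it$n_permutations),
      config$outdir, "independence_test.csv", manifest)
  }

  # --- stage 4: clinical battery ------------------------------------------
  if (!is.null(clinical)) {
    meas_cols <- intersect(.clinical_measures, names(clinical))
    if (!length(meas_cols))
      meas_cols <- setdiff(names(clinical),
                           c("sample_id", "age", "gender", "education",
                             "apoe4"))
    batteries <- lapply(names(outcomes), function(nm) {
      b <- ranksum_battery(clinical[, meas_cols, drop = FALSE],
                           outcomes[[nm]], alpha = config$alpha)
      cbind(experiment = nm, b)
    })
    manifest <- .write_csv(do.call(rbind, batteries), config$outdir,
                           "ranksum_battery.csv", manifest)
  } else log_skip("clinical", "no clinical table")

  # --- stage 5: survival --------------------------------------------------
  if (!is.null(survdf)) {
    covX <- if (!is.null(clinical))
      clinical[, setdiff(names(clinical), "sample_id"), drop = FALSE]
    else NULL
    surv_rows <- lapply(names(outcomes), function(nm) {
      grp <- outcomes[[nm]]
      lr <- logrank_test(survdf$time, survdf$event, grp)
      row <- data.frame(experiment = nm, chisq = lr$statistic, p = lr$p,
                        neg_log2_p = lr$neg_log2_p, concordance = NA_real_)
      if (!is.null(covX)) {
        fit <- fit_cox(survdf$time, survdf$event, covX,
                       penalty_strength = config$cox_penalty)
        row$concordance <- fit$concordance
        prof <- do.call(rbind, lapply(sort(unique(grp)), function(g)
          colMeans(covX[grp == g, , drop = FALSE])))
        rownames(prof) <- paste0("subtype", sort(unique(grp)))
        cc <- conversion_curves(fit, prof)
        manifest <<- .write_csv(cc, config$outdir,
                                paste0("conversion_", nm, ".csv"), manifest)
      }
      row
    })
    manifest <- .write_csv(do.call(rbind, surv_rows), config$outdir,
                           "survival_tests.csv", manifest)
  } else log_skip("survival", "no survival records")

  # --- stage 6: genetic association ---------------------------------------
  if (!is.null(geno)) {
    tests <- list()
    is_case <- geno$phenotype == 1L
    for (nm in names(outcomes)) {
      sub_full <- rep(NA_integer_, length(geno$phenotype))
      sub_full[is_case] <- outcomes[[nm]]
      for (stp in sort(unique(outcomes[[nm]]))) {
        keep <- !is_case | (!is.na(sub_full) & sub_full == stp)
        res <- case_control_assoc(
          geno$genotypes[keep, , drop = FALSE],
          geno$phenotype[keep],
          if (!is.null(geno$covariates))
            geno$covariates[keep, , drop = FALSE] else NULL)
        res$significant <- bh_fdr(res$p_value, config$q)
        tests[[sprintf("%s_subtype%d_vs_control", nm, stp)]] <- res
      }
    }
    flat <- do.call(rbind, lapply(names(tests), function(tn)
      cbind(test = tn, tests[[tn]])))
    manifest <- .write_csv(flat, config$outdir, "association.csv", manifest)
    chrom <- if (!is.null(geno$snp_info))
      stats::setNames(geno$snp_info$chromosome, geno$snp_info$snp_id)
    else NULL
    summ <- assoc_summary(tests, q = config$q, chromosomes = chrom)
    manifest <- .write_csv(summ, config$outdir, "association_summary.csv",
                           manifest)
  } else log_skip("association", "no genotypes")

  manifest$seed <- config$seed
  jsonlite::write_json(
    list(seed = config$seed, seeds = manifest$seeds,
         skipped = manifest$skipped,
         files = lapply(manifest$files, function(f)
           list(md5 = f$md5, rows = f$rows))),
    file.path(config$outdir, "manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write synthetic tables), `run-all` (full
#' pipeline). Arguments: `--seed`, `--outdir`, `--n-samples`,
#' `--n-permutations`. Used by the script in `inst/scripts/`.
#'
#' @param args character vector (defaults to `commandArgs(trailingOnly)`).
#' @return exit status 0 on success (invisibly).
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: <simulate|run-all> [--seed N] [--outdir D]")
  cmd <- args[1L]
  getopt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1L] else default
  }
  seed <- as.integer(getopt("--seed", "1"))
  outdir <- getopt("--outdir", "mvsubtype_out")
  n_samples <- as.integer(getopt("--n-samples", "308"))
  nperm <- as.integer(getopt("--n-permutations", "199"))
  scfg <- synthetic_config(n_samples = n_samples, seed = seed)
  if (cmd == "simulate") {
    gen <- generate_multiview(scfg)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_views_csv(gen$dataset, outdir)
    utils::write.csv(generate_clinical(gen$truth$cluster_labels, scfg),
                     file.path(outdir, "clinical.csv"), row.names = FALSE)
    utils::write.csv(generate_survival(gen$truth$cluster_labels, scfg),
                     file.path(outdir, "survival.csv"), row.names = FALSE)
    g <- generate_genotypes(gen$truth$cluster_labels, scfg$n_controls, scfg)
    write_plink_raw(g$genotypes, g$phenotype,
                    file.path(outdir, "genotypes.raw"),
                    sex = g$covariates$gender)
    message("simulate: wrote tables to ", outdir)
  } else if (cmd == "run-all") {
    run_pipeline(pipeline_config(synthetic = scfg, outdir = outdir,
                                 seed = seed, n_permutations = nperm))
    message("run-all: outputs in ", outdir)
  } else stop("unknown subcommand: ", cmd)
  invisible(0L)
}
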