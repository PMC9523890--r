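test_that("config validation rejects inconsistent settings", {
  expect_error(synthetic_config(latent_dim = 10, view_dims = 5), "latent_dim")
  expect_error(synthetic_config(n_samples = 3, n_clusters = 4, latent_dim = 5),
               "n_clusters")
  expect_error(synthetic_config(censor_rate = 1), "censor_rate")
  expect_error(synthetic_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(synthetic_config(clinical_effect_sizes = rep(0, 5)),
               "length 11")
})

test_that("noiseless linear views have rank exactly d", {
  cfg <- synthetic_config(n_samples = 60, view_dims = 12, latent_dim = 4,
                          noise_sd = 0, nonlinearity = "linear", seed = 2)
  gen <- generate_multiview(cfg)
  for (X in gen$dataset$views)
    expect_equal(qr(X)$rank, 4)
})

test_that("generators are bit-identical under a fixed seed", {
  cfg <- synthetic_config(n_samples = 40, view_dims = 8, latent_dim = 3,
                          n_snps = 12, n_causal_snps = 2, n_controls = 20,
                          seed = 33)
  a <- generate_multiview(cfg); b <- generate_multiview(cfg)
  expect_identical(a$dataset$views, b$dataset$views)
  expect_identical(a$truth$cluster_labels, b$truth$cluster_labels)
  expect_identical(generate_clinical(a$truth$cluster_labels, cfg),
                   generate_clinical(b$truth$cluster_labels, cfg))
  expect_identical(generate_survival(a$truth$cluster_labels, cfg),
                   generate_survival(b$truth$cluster_labels, cfg))
})

test_that("latent cluster means form a regular simplex at the set separation", {
  for (K in 2:4) {
    cfg <- synthetic_config(n_samples = 50, view_dims = 10, latent_dim = 5,
                            n_clusters = K, cluster_separation = 3, seed = 1)
    gen <- generate_multiview(cfg)
    mu <- gen$truth$means
    d <- as.matrix(dist(mu))
    expect_equal(unname(d[upper.tri(d)]), rep(3, K * (K - 1) / 2),
                 tolerance = 1e-10)
  }
})

test_that("zero separation gives chance-level AMI on any view", {
  amis <- sapply(1:20, function(s) {
    cfg <- synthetic_config(n_samples = 60, view_dims = 6, latent_dim = 3,
                            cluster_separation = 0, seed = 100 + s)
    gen <- generate_multiview(cfg)
    lab <- cluster_agglomerative(gen$dataset$views[[1]], 2)
    ami_score(lab, gen$truth$cluster_labels)
  })
  expect_lt(abs(mean(amis)), 0.05)
})

test_that("recovered AMI increases monotonically with separation", {
  mean_ami <- sapply(c(0, 3, 8), function(sep) {
    mean(sapply(1:20, function(s) {
      cfg <- synthetic_config(n_samples = 60, view_dims = 6, latent_dim = 3,
                              cluster_separation = sep, noise_sd = 0.5,
                              seed = 200 + s)
      gen <- generate_multiview(cfg)
      lab <- cluster_agglomerative(gen$dataset$views[[1]], 2)
      ami_score(lab, gen$truth$cluster_labels)
    }))
  })
  expect_true(all(diff(mean_ami) > 0))
  expect_gt(mean_ami[3], 0.9)
})

test_that("linear population cross-covariance between views has rank <= d", {
  cfg <- synthetic_config(n_samples = 2000, view_dims = 8, latent_dim = 3,
                          nonlinearity = "linear", noise_sd = 1, seed = 3)
  gen <- generate_multiview(cfg)
  cc <- cov(gen$dataset$views[[1]], gen$dataset$views[[2]])
  sv <- svd(cc)$d
  expect_lt(sv[4] / sv[1], 0.1)            # effective rank 3 at N = 2000
})

test_that("clinical generator shifts subtype-2 means by the effect size", {
  cfg <- synthetic_config(n_samples = 2000, view_dims = 8, latent_dim = 3,
                          clinical_effect_sizes = c(2, rep(0, 10)), seed = 4)
  lab <- rep(1:2, 1000)
  cl <- generate_clinical(lab, cfg)
  d1 <- mean(cl$ADAS13[lab == 2]) - mean(cl$ADAS13[lab == 1])
  expect_equal(d1, 2, tolerance = 0.15)
  d2 <- mean(cl$MMSE[lab == 2]) - mean(cl$MMSE[lab == 1])
  expect_lt(abs(d2), 0.15)
  cfg_bad <- cfg
  cfg_bad$clinical_effect_sizes <- 1:3
  expect_error(generate_clinical(lab, cfg_bad), "length 11")
})

test_that("clinical null has calibrated rank-sum rejections", {
  cfg <- synthetic_config(n_samples = 100, view_dims = 8, latent_dim = 3,
                          clinical_effect_sizes = rep(0, 11), seed = 6)
  rej <- sapply(1:40, function(s) {
    cfg$seed <- 600 + s
    lab <- rep(1:2, 50)
    cl <- generate_clinical(lab, cfg)
    b <- ranksum_battery(cl[, 2:12], lab, alpha = 0.05)
    mean(b$p < 0.05)
  })
  expect_lte(mean(rej), 0.05 + 0.03)
})

test_that("clinical effect size 2 at n=150/cluster is overwhelmingly detected", {
  hits <- sapply(1:50, function(s) {
    cfg <- synthetic_config(n_samples = 300, view_dims = 8, latent_dim = 3,
                            clinical_effect_sizes = c(2, rep(0, 10)),
                            seed = 700 + s)
    lab <- rep(1:2, 150)
    cl <- generate_clinical(lab, cfg)
    b <- ranksum_battery(cl[, 2:12, drop = FALSE], lab)
    b$p[1] < 0.01 / 11
  })
  expect_gte(mean(hits), 0.95)
})

test_that("censor_rate = 0 yields all events; rate is roughly achieved", {
  cfg <- synthetic_config(n_samples = 400, view_dims = 8, latent_dim = 3,
                          censor_rate = 0, seed = 7)
  sv <- generate_survival(rep(1:2, 200), cfg)
  expect_true(all(sv$event == 1))
  cfg2 <- synthetic_config(n_samples = 4000, view_dims = 8, latent_dim = 3,
                           censor_rate = 0.4, seed = 8)
  sv2 <- generate_survival(rep(1:2, 2000), cfg2)
  expect_equal(mean(sv2$event == 0), 0.4, tolerance = 0.06)
})

test_that("survival generator encodes the requested hazard ratio", {
  set.seed(30)
  betas <- sapply(1:20, function(s) {
    cfg <- synthetic_config(n_samples = 500, view_dims = 8, latent_dim = 3,
                            hazard_ratio = 2, censor_rate = 0.2,
                            seed = 800 + s)
    lab <- rep(1:2, 250)
    sv <- generate_survival(lab, cfg)
    fit_cox(sv$time, sv$event, data.frame(g = as.numeric(lab == 2)),
            penalty_strength = 0)$coefficients["g"]
  })
  expect_lt(abs(mean(betas) - log(2)), 0.2)
})

test_that("multiview CSV writer emits sample_id-first tables", {
  cfg <- synthetic_config(n_samples = 10, view_dims = 4, latent_dim = 2,
                          n_views = 2, seed = 10)
  gen <- generate_multiview(cfg)
  dir <- tempfile()
  paths <- write_views_csv(gen$dataset, dir)
  expect_length(paths, 2)
  df <- read.csv(paths[1])
  expect_equal(names(df)[1], "sample_id")
  expect_equal(nrow(df), 10)
  unlink(dir, recursive = TRUE)
})
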