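test_that("forward pass matches a hand-rolled matrix/ReLU oracle", {
  set.seed(51)
  spec <- network_spec(4, hidden_dims = c(6, 5), dropout_prob = 0,
                       output_dim = 3)
  params <- mlp_init(spec)
  X <- matrix(rnorm(5 * 4), 5, 4)
  out <- mlp_forward(params, X)
  # oracle: explicit loops
  H1 <- oracle_matmul(X, params[[1]]$W)
  H1 <- sweep(H1, 2, params[[1]]$b, `+`); H1[H1 < 0] <- 0
  H2 <- oracle_matmul(H1, params[[2]]$W)
  H2 <- sweep(H2, 2, params[[2]]$b, `+`); H2[H2 < 0] <- 0
  H3 <- sweep(oracle_matmul(H2, params[[3]]$W), 2, params[[3]]$b, `+`)
  expect_equal(out, H3, tolerance = 1e-6)
})

test_that("identity single-layer network reproduces its input; eval is deterministic", {
  X <- matrix(rnorm(12), 4, 3)
  params <- list(list(W = diag(3), b = rep(0, 3)))
  expect_equal(mlp_forward(params, X), X)
  spec <- network_spec(3, hidden_dims = 8, dropout_prob = 0.5)
  set.seed(52)
  p2 <- mlp_init(spec)
  expect_identical(mlp_forward(p2, X), mlp_forward(p2, X))
  # train mode with dropout is stochastic
  set.seed(1); a <- mlp_forward(p2, X, train_mode = TRUE)
  set.seed(2); b <- mlp_forward(p2, X, train_mode = TRUE)
  expect_false(identical(a, b))
  expect_error(mlp_forward(p2, cbind(X, 0)), "does not match")
})

test_that("eigen-sum loss matches dense eigen oracle; identical views saturate", {
  O <- qr.Q(qr(matrix(rnorm(12 * 3), 12, 3)))
  ls <- dgcca_loss(list(O, O), k = 3, ridge = 0)
  expect_equal(ls$L, 2 * 3, tolerance = 1e-10)
  set.seed(53)
  Os <- lapply(1:3, function(j) matrix(rnorm(15 * 5), 15, 5))
  ls2 <- dgcca_loss(Os, k = 4, ridge = 0)
  expect_equal(ls2$L, sum(oracle_projector_eigs(Os)[1:4]), tolerance = 1e-9)
  # appending a duplicated view adds exactly one more projector
  ls3 <- dgcca_loss(c(Os, Os[3]), k = 4, ridge = 0)
  expect_equal(ls3$L, sum(oracle_projector_eigs(c(Os, Os[3]))[1:4]),
               tolerance = 1e-9)
  expect_error(dgcca_loss(list(cbind(1:5, 1:5)), k = 1, ridge = 0),
               "rank-deficient")
})

test_that("with linear identity networks the loss equals the GCCA eigenvalue sum", {
  set.seed(54)
  views <- lapply(1:3, function(j) scale(matrix(rnorm(20 * 5), 20, 5)))
  ls <- dgcca_loss(views, k = 3, ridge = 0)
  f <- fit_gcca(views, k = 3, ridge = 0)
  expect_equal(ls$L, sum(f$eigenvalues), tolerance = 1e-8)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(55)
  for (rep in 1:3) {
    Os <- lapply(1:3, function(j) matrix(rnorm(12 * 4), 12, 4))
    ls <- dgcca_loss(Os, k = 2, ridge = 0)
    g <- loss_gradient(Os[[1]], ls$G, ridge = 0)
    h <- 1e-5
    fd <- matrix(0, 12, 4)
    for (i in 1:12) for (j in 1:4) {
      Op <- Os; Op[[1]][i, j] <- Op[[1]][i, j] + h
      Om <- Os; Om[[1]][i, j] <- Om[[1]][i, j] - h
      fd[i, j] <- (dgcca_loss(Op, 2, 0)$L - dgcca_loss(Om, 2, 0)$L) / (2 * h)
    }
    expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-4)
  }
})

test_that("gradient vanishes when G lies in the view's span", {
  set.seed(56)
  O <- qr.Q(qr(matrix(rnorm(10 * 3), 10, 3)))
  ls <- dgcca_loss(list(O, O), k = 3, ridge = 0)
  g <- loss_gradient(O, ls$G, ridge = 0)
  expect_lt(max(abs(g)), 1e-8)
})

test_that("gradient is equivariant under orthogonal right-rotation", {
  set.seed(57)
  Os <- lapply(1:2, function(j) matrix(rnorm(14 * 4), 14, 4))
  ls <- dgcca_loss(Os, k = 2, ridge = 0)
  R <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  g <- loss_gradient(Os[[1]], ls$G, ridge = 0)
  gR <- loss_gradient(Os[[1]] %*% R, ls$G, ridge = 0)
  expect_equal(gR, g %*% R, tolerance = 1e-8)
})

test_that("flat validation loss stops after patience epochs", {
  cfg <- synthetic_config(n_samples = 60, view_dims = 6, latent_dim = 2,
                          n_views = 2, seed = 58)
  gen <- generate_multiview(cfg)
  specs <- lapply(gen$dataset$views, function(v)
    network_spec(ncol(v), hidden_dims = 4, dropout_prob = 0))
  # zero learning rate: parameters frozen, validation loss exactly constant
  tc <- train_config(k = 2, learning_rate = 0, max_epochs = 50, patience = 5,
                     seed = 1)
  m <- train_dgcca(gen$dataset, specs, tc)
  expect_equal(m$epochs_ran, 6L)
  expect_equal(diff(range(m$history$val_loss)), 0, tolerance = 1e-12)
})

test_that("training is deterministic given the seed", {
  cfg <- synthetic_config(n_samples = 80, view_dims = 8, latent_dim = 2,
                          n_views = 2, seed = 59)
  gen <- generate_multiview(cfg)
  specs <- lapply(gen$dataset$views, function(v)
    network_spec(ncol(v), hidden_dims = 6, dropout_prob = 0.1))
  tc <- train_config(k = 2, max_epochs = 15, seed = 7)
  m1 <- train_dgcca(gen$dataset, specs, tc)
  m2 <- train_dgcca(gen$dataset, specs, tc)
  expect_identical(m1$epochs_ran, m2$epochs_ran)
  expect_equal(m1$history$train_loss, m2$history$train_loss, tolerance = 1e-6)
  expect_equal(m1$history$val_loss, m2$history$val_loss, tolerance = 1e-6)
  expect_identical(m1$train_idx, m2$train_idx)
})

test_that("training loss is bounded and best-so-far is nonincreasing", {
  cfg <- synthetic_config(n_samples = 80, view_dims = 8, latent_dim = 2,
                          n_views = 2, seed = 60)
  gen <- generate_multiview(cfg)
  tc <- train_config(k = 2, max_epochs = 30, seed = 3)
  specs <- lapply(gen$dataset$views, function(v)
    network_spec(ncol(v), hidden_dims = 6, dropout_prob = 0.1))
  m <- train_dgcca(gen$dataset, specs, tc)
  J <- 2
  expect_true(all(m$history$train_loss >= -1e-8))
  expect_true(all(m$history$train_loss <= J * 2 + 1e-8))
  best <- cummin(m$history$train_loss)
  expect_true(all(diff(best) <= 1e-12))
})

test_that("linear single-layer DGCCA approaches the GCCA solution", {
  cfg <- synthetic_config(n_samples = 150, view_dims = 8, latent_dim = 3,
                          n_views = 3, nonlinearity = "linear",
                          noise_sd = 0.5, seed = 61)
  gen <- generate_multiview(cfg)
  specs <- lapply(gen$dataset$views, function(v)
    network_spec(ncol(v), hidden_dims = integer(0), dropout_prob = 0))
  # for invertible linear maps the eigen-sum loss is flat in W (the span of
  # XW does not depend on W), so the model is optimal from initialization;
  # weight decay is off because it is the only force acting on a flat loss
  tc <- train_config(k = 3, weight_decay = 0, max_epochs = 60,
                     patience = 100, seed = 5)
  m <- train_dgcca(gen$dataset, specs, tc)
  va <- m$val_idx
  emb <- dgcca_embed(m, lapply(gen$dataset$views, function(v)
    v[va, , drop = FALSE]))
  dg <- heldout_cc(emb$projections, 3)
  Xs <- standardize_views(gen$dataset$views, train_idx = m$train_idx)
  fg <- fit_gcca(lapply(Xs, function(v) v[m$train_idx, , drop = FALSE]), k = 3)
  gc <- heldout_cc(lapply(seq_along(Xs), function(j)
    project_view(Xs[[j]][va, , drop = FALSE], fg$U[[j]])), 3)
  expect_lt(abs(dg - gc), 0.05)
})

test_that("embedding consistency: stored G on the training split, duplicates duplicate", {
  cfg <- synthetic_config(n_samples = 70, view_dims = 6, latent_dim = 2,
                          n_views = 2, seed = 62)
  gen <- generate_multiview(cfg)
  tc <- train_config(k = 2, max_epochs = 10, seed = 2)
  specs <- lapply(gen$dataset$views, function(v)
    network_spec(ncol(v), hidden_dims = 4, dropout_prob = 0))
  m <- train_dgcca(gen$dataset, specs, tc)
  trds <- multiview_dataset(
    lapply(gen$dataset$views, function(v) v[m$train_idx, , drop = FALSE]),
    sample_ids = gen$dataset$sample_ids[m$train_idx])
  emb_tr <- dgcca_embed(m, trds)
  expect_identical(emb_tr$G, m$G_train)
  # duplicated rows produce duplicated embedding rows
  dup <- lapply(gen$dataset$views, function(v) v[c(1, 1, 2), , drop = FALSE])
  emb_dup <- dgcca_embed(m, dup)
  expect_equal(emb_dup$G[1, ], emb_dup$G[2, ])
  expect_error(dgcca_embed(structure(list(), class = "dgcca_model"), dup),
               "not a trained")
})

test_that("non-finite loss aborts with an epoch diagnostic", {
  cfg <- synthetic_config(n_samples = 50, view_dims = 5, latent_dim = 2,
                          n_views = 2, seed = 63)
  gen <- generate_multiview(cfg)
  specs <- lapply(gen$dataset$views, function(v)
    network_spec(ncol(v), hidden_dims = 4, dropout_prob = 0))
  tc <- train_config(k = 2, learning_rate = 1e10, max_epochs = 20, seed = 1,
                     ridge = 0)
  expect_error(train_dgcca(gen$dataset, specs, tc),
               "epoch|rank-deficient")
})
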