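# Deep GCCA: each view passes through its own feedforward network before
# the GCCA objective. Training maximizes
#   L = sum_{i=1..k} lambda_i( sum_j O_j (O_j'O_j)^{-1} O_j' )
# over the network weights (equivalently minimizes J*k - L, the optimal
# reconstruction error), using the analytic gradient
#   dL/dO_j = 2 [I - O_j (O_j'O_j)^{-1} O_j'] G G' O_j (O_j'O_j)^{-1}
# with G the top-k eigenvectors, treated as fixed within a step, followed by
# ordinary backpropagation through each network. Optimization is full-batch
# Adam (the cohorts involved are small), with L2 weight decay added to the
# gradient (PyTorch-style coupled decay) and patience-based early stopping
# on a held-out validation split.

#' Specify a per-view feedforward network
#'
#' Default architecture: two hidden layers of width 96 with ReLU
#' activations, dropout probability 0.1 after each hidden layer, and a
#' linear output layer of the same width as the input.
#'
#' @param input_dim view width p_j.
#' @param hidden_dims integer vector of hidden-layer widths; `integer(0)`
#'   gives a purely linear network.
#' @param dropout_prob probability of zeroing a hidden activation during
#'   training (inverted dropout; inactive at evaluation).
#' @param output_dim network output width q_j (default: `input_dim`).
#' @return an object of class `network_spec`.
#' @export
network_spec <- function(input_dim, hidden_dims = c(96L, 96L),
                         dropout_prob = 0.1, output_dim = input_dim) {
  if (!.is_count(input_dim) || !.is_count(output_dim))
    .stopf("input_dim and output_dim must be counts >= 1")
  if (length(hidden_dims) && any(hidden_dims < 1))
    .stopf("hidden_dims must all be >= 1")
  if (dropout_prob < 0 || dropout_prob >= 1)
    .stopf("dropout_prob must lie in [0, 1)")
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dims = as.integer(hidden_dims),
                 dropout_prob = dropout_prob,
                 output_dim = as.integer(output_dim)),
            class = "network_spec")
}

#' Training configuration for DGCCA
#'
#' Defaults: embedding dimension k = 20, Adam with learning rate 5e-4 and
#' weight decay 0.01, 80/20 train/validation split, early stopping with
#' patience 5 once the validation loss stops improving by more than 0.05%
#' of the largest validation loss seen so far.
#'
#' @param k shared embedding dimension.
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty coefficient added to the weight gradient.
#' @param max_epochs hard cap on training epochs.
#' @param patience consecutive non-improving epochs tolerated before
#'   stopping.
#' @param early_stop_frac improvement threshold as a fraction of the
#'   running maximum validation loss (0.0005 = 0.05%).
#' @param train_frac fraction of samples used for training (rest validate).
#' @param seed integer seed controlling the split, weight initialization
#'   and dropout; fixed seed implies a bit-reproducible run.
#' @param ridge relative ridge for the projector inverses:
#'   `ridge * trace(O_j'O_j) / q_j` is added to the diagonal (0 disables).
#' @return an object of class `train_config`.
#' @export
train_config <- function(k = 20L, learning_rate = 5e-4, weight_decay = 0.01,
                         max_epochs = 200L, patience = 5L,
                         early_stop_frac = 5e-4, train_frac = 0.8,
                         seed = 1L, ridge = 1e-6) {
  if (train_frac <= 0 || train_frac >= 1) .stopf("train_frac must be in (0,1)")
  if (!.is_count(patience)) .stopf("patience must be >= 1")
  structure(list(k = as.integer(k), learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 early_stop_frac = early_stop_frac, train_frac = train_frac,
                 seed = as.integer(seed), ridge = ridge),
            class = "train_config")
}

#' Initialize network parameters
#'
#' He-scaled Gaussian weights (`sd = sqrt(2 / fan_in)`) and zero biases.
#' Draws from the current RNG stream.
#'
#' @param spec a [network_spec()].
#' @return list of layers, each `list(W, b)` with W of shape
#'   (in_dim x out_dim); the spec is attached as an attribute.
#' @export
mlp_init <- function(spec) {
  dims <- c(spec$input_dim, spec$hidden_dims, spec$output_dim)
  layers <- vector("list", length(dims) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- dims[l]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * dims[l + 1L], sd = sqrt(2 / fan_in)),
                 fan_in, dims[l + 1L]),
      b = numeric(dims[l + 1L])
    )
  }
  attr(layers, "spec") <- spec
  layers
}

#' Forward pass of a per-view network
#'
#' Affine then ReLU for hidden layers, inverted dropout after each hidden
#' activation when `train_mode` is on, and a linear output layer. With
#' `train_mode = FALSE` the pass is deterministic.
#'
#' @param params layers from [mlp_init()] (or a hand-built list of
#'   `list(W, b)` layers).
#' @param X N x p_j input matrix.
#' @param train_mode logical; activates dropout (consumes RNG draws).
#' @param keep_cache logical; also return intermediates for backprop.
#' @return N x q_j output matrix, or `list(out, cache)` if `keep_cache`.
#' @export
mlp_forward <- function(params, X, train_mode = FALSE, keep_cache = FALSE) {
  X <- as.matrix(X)
  spec <- attr(params, "spec")
  p_drop <- if (is.null(spec)) 0 else spec$dropout_prob
  if (ncol(X) != nrow(params[[1L]]$W))
    .stopf("input width %d does not match network input %d",
           ncol(X), nrow(params[[1L]]$W))
  L <- length(params)
  A <- X
  cache <- if (keep_cache) list(inputs = vector("list", L),
                                relu = vector("list", L),
                                mask = vector("list", L)) else NULL
  for (l in seq_len(L)) {
    if (keep_cache) cache$inputs[[l]] <- A
    H <- A %*% params[[l]]$W
    if (any(params[[l]]$b != 0))
      H <- H + rep(params[[l]]$b, each = nrow(H))
    if (l < L) {                               # hidden layer
      relu_mask <- H > 0
      A <- H * relu_mask
      if (keep_cache) cache$relu[[l]] <- relu_mask
      if (train_mode && p_drop > 0) {
        keep <- matrix(stats::runif(length(A)) >= p_drop,
                       nrow(A), ncol(A))
        A <- A * keep / (1 - p_drop)
        if (keep_cache) cache$mask[[l]] <- keep
      }
    } else {
      A <- H
    }
  }
  if (keep_cache) list(out = A, cache = cache) else A
}

# Backpropagate dLoss/dOut through the network; returns per-layer grads.
.mlp_backward <- function(params, cache, d_out, p_drop, train_mode) {
  L <- length(params)
  grads <- vector("list", L)
  dA <- d_out
  for (l in rev(seq_len(L))) {
    if (l < L) {                               # undo dropout + ReLU
      if (train_mode && p_drop > 0 && !is.null(cache$mask[[l]]))
        dA <- dA * cache$mask[[l]] / (1 - p_drop)
      dA <- dA * cache$relu[[l]]
    }
    grads[[l]] <- list(W = crossprod(cache$inputs[[l]], dA),
                       b = colSums(dA))
    if (l > 1L) dA <- dA %*% t(params[[l]]$W)
  }
  grads
}

# Regularized projector pieces for one output matrix.
.proj_pieces <- function(O, ridge_abs) {
  S <- crossprod(O)
  if (ridge_abs > 0) S <- S + diag(ridge_abs, ncol(O))
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch))
    .stopf("O'O is rank-deficient; supply ridge > 0")
  Sinv <- chol2inv(ch)
  list(Sinv = Sinv, P = O %*% Sinv %*% t(O))
}

.ridge_abs <- function(O, ridge) {
  if (ridge <= 0) return(0)
  ridge * sum(O * O) / ncol(O)
}

#' DGCCA eigen-sum loss
#'
#' Builds `M = sum_j O_j (O_j'O_j + r I)^{-1} O_j'` and returns the sum of
#' its top-k eigenvalues `L` together with the corresponding eigenvectors
#' `G`. Training minimizes `J*k - L`.
#'
#' @param outputs list of network output matrices O_j sharing N rows.
#' @param k number of shared components (k <= N).
#' @param ridge relative ridge (see [train_config()]); 0 disables and
#'   errors on rank-deficient O_j'O_j.
#' @return list with `L` (eigenvalue sum), `G` (N x k, sign-fixed),
#'   `eigenvalues` (top k) and `pieces` (per-view inverse factors, reused
#'   by [loss_gradient()]).
#' @export
dgcca_loss <- function(outputs, k, ridge = 0) {
  outputs <- lapply(outputs, as.matrix)
  n <- nrow(outputs[[1L]])
  if (!all(vapply(outputs, nrow, 0L) == n))
    .stopf("all outputs must share the same number of rows")
  if (!.is_count(k) || k > n) .stopf("k must be a count <= N")
  pieces <- lapply(outputs, function(O) .proj_pieces(O, .ridge_abs(O, ridge)))
  M <- Reduce(`+`, lapply(pieces, `[[`, "P"))
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  G <- .fix_signs(eg$vectors[, seq_len(k), drop = FALSE])
  list(L = sum(eg$values[seq_len(k)]), G = G,
       eigenvalues = eg$values[seq_len(k)], pieces = pieces)
}

#' Analytic gradient of the DGCCA eigen-sum loss
#'
#' Implements `dL/dO_j = 2 [I - O_j (O_j'O_j)^{-1} O_j'] G G' O_j
#' (O_j'O_j)^{-1}` with the same ridge as used in the loss; `G` is treated
#' as fixed (it is the exact gradient of the eigenvalue sum away from
#' eigenvalue ties).
#'
#' @param O one view's output matrix (N x q_j).
#' @param G the top-k eigenvectors from [dgcca_loss()] on the same outputs.
#' @param ridge relative ridge matching the loss call.
#' @return N x q_j gradient matrix.
#' @export
loss_gradient <- function(O, G, ridge = 0) {
  O <- as.matrix(O); G <- as.matrix(G)
  if (nrow(O) != nrow(G)) .stopf("O and G row counts differ")
  pp <- .proj_pieces(O, .ridge_abs(O, ridge))
  OSinv <- O %*% pp$Sinv
  GtO <- crossprod(G, OSinv)                  # k x q
  full <- G %*% GtO                           # G G' O Sinv
  2 * (full - pp$P %*% full)
}

#' Train DGCCA networks
#'
#' Splits samples into train/validation by `config$train_frac`, standardizes
#' each view with training-split statistics, and runs full-batch Adam on
#' the loss `J*k - L` (dropout active on the training pass, off for the
#' validation pass). An epoch counts toward the early-stopping patience
#' when the validation loss fails to improve on the best so far by more
#' than `early_stop_frac` times the running maximum validation loss.
#' After training, `U_j` and the training-split embedding `G_train` are
#' recomputed by a GCCA fit on evaluation-mode network outputs.
#'
#' @param data an [multiview_dataset()] or plain list of view matrices.
#' @param specs list of [network_spec()] per view (default: the standard
#'   two-hidden-layer architecture per view).
#' @param config a [train_config()].
#' @return an object of class `dgcca_model`: `params` (per-view weights),
#'   `specs`, `config`, `U`, `G_train`, `history` (epoch, train_loss,
#'   val_loss), `epochs_ran`, `train_idx`/`val_idx`, `center`/`scalev`
#'   (per-view standardization) and `train_ids`.
#' @export
train_dgcca <- function(data, specs = NULL, config = train_config()) {
  views <- if (inherits(data, "mv_dataset")) data$views else data
  ids <- if (inherits(data, "mv_dataset")) data$sample_ids else
    sprintf("S%04d", seq_len(nrow(views[[1L]])))
  views <- lapply(views, as.matrix)
  J <- length(views)
  n <- nrow(views[[1L]])
  if (is.null(specs))
    specs <- lapply(views, function(v) network_spec(ncol(v)))
  for (j in seq_len(J))
    if (ncol(views[[j]]) != specs[[j]]$input_dim)
      .stopf("view %d width %d does not match spec input_dim %d",
             j, ncol(views[[j]]), specs[[j]]$input_dim)
  set.seed(config$seed)
  n_train <- floor(config$train_frac * n)
  if (n_train < 2L || n - n_train < 2L)
    .stopf("need at least 2 samples in each split")
  perm <- sample.int(n)
  train_idx <- sort(perm[seq_len(n_train)])
  val_idx <- sort(perm[(n_train + 1L):n])

  center <- lapply(views, function(v) colMeans(v[train_idx, , drop = FALSE]))
  scalev <- lapply(views, function(v) {
    s <- apply(v[train_idx, , drop = FALSE], 2L, stats::sd)
    s[!is.finite(s) | s == 0] <- 1
    s
  })
  Xs <- Map(function(v, m, s) scale(v, center = m, scale = s)[, , drop = FALSE],
            views, center, scalev)
  Xtr <- lapply(Xs, function(v) v[train_idx, , drop = FALSE])
  Xval <- lapply(Xs, function(v) v[val_idx, , drop = FALSE])

  params <- lapply(specs, mlp_init)
  adam <- lapply(params, function(pl) lapply(pl, function(layer)
    list(mW = layer$W * 0, vW = layer$W * 0,
         mb = layer$b * 0, vb = layer$b * 0)))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  k <- config$k
  upper <- J * k
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best_val <- Inf; max_val <- -Inf; stall <- 0L; step <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    fw <- lapply(seq_len(J), function(j)
      mlp_forward(params[[j]], Xtr[[j]], train_mode = TRUE, keep_cache = TRUE))
    O <- lapply(fw, `[[`, "out")
    ls <- dgcca_loss(O, k, config$ridge)
    train_loss <- upper - ls$L
    if (!is.finite(train_loss))
      .stopf("non-finite training loss at epoch %d", epoch)
    stopifnot(train_loss > -1e-6, train_loss < upper + 1e-6)
    step <- step + 1L
    bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
    for (j in seq_len(J)) {
      dO <- -2 * ((ls$G %*% crossprod(ls$G, O[[j]] %*% ls$pieces[[j]]$Sinv)) -
                  ls$pieces[[j]]$P %*%
                    (ls$G %*% crossprod(ls$G, O[[j]] %*% ls$pieces[[j]]$Sinv)))
      grads <- .mlp_backward(params[[j]], fw[[j]]$cache, dO,
                             specs[[j]]$dropout_prob, train_mode = TRUE)
      for (l in seq_along(params[[j]])) {
        gW <- grads[[l]]$W + config$weight_decay * params[[j]][[l]]$W
        gb <- grads[[l]]$b
        st <- adam[[j]][[l]]
        st$mW <- beta1 * st$mW + (1 - beta1) * gW
        st$vW <- beta2 * st$vW + (1 - beta2) * gW^2
        st$mb <- beta1 * st$mb + (1 - beta1) * gb
        st$vb <- beta2 * st$vb + (1 - beta2) * gb^2
        params[[j]][[l]]$W <- params[[j]][[l]]$W -
          config$learning_rate * (st$mW / bc1) / (sqrt(st$vW / bc2) + eps)
        params[[j]][[l]]$b <- params[[j]][[l]]$b -
          config$learning_rate * (st$mb / bc1) / (sqrt(st$vb / bc2) + eps)
        adam[[j]][[l]] <- st
      }
      attr(params[[j]], "spec") <- specs[[j]]
    }
    # Validation loss. The in-sample formula J*k - L is degenerate out of
    # sample whenever q_j >= N_val (every projector is then the identity and
    # the loss is 0 for any weights), so validation uses the out-of-sample
    # reconstruction disagreement instead: fit U_j/G on eval-mode training
    # outputs (dropout off, so the early-stopping signal is smooth),
    # project eval-mode validation outputs, and measure
    # sum_j ||Gbar - O_j U_j||_F^2 with Gbar the optimal (unconstrained)
    # shared embedding mean_j O_j U_j, normalized by the projection energy
    # so that shrinking projections cannot masquerade as agreement.
    Oev <- lapply(seq_len(J), function(j)
      mlp_forward(params[[j]], Xtr[[j]], train_mode = FALSE))
    lse <- dgcca_loss(Oev, k, config$ridge)
    Uev <- lapply(seq_len(J), function(j)
      lse$pieces[[j]]$Sinv %*% crossprod(Oev[[j]], lse$G))
    Oval <- lapply(seq_len(J), function(j)
      mlp_forward(params[[j]], Xval[[j]], train_mode = FALSE))
    Pval <- lapply(seq_len(J), function(j) Oval[[j]] %*% Uev[[j]])
    Gbar <- Reduce(`+`, Pval) / J
    val_loss <- sum(vapply(Pval, function(P) sum((Gbar - P)^2), 0)) /
      sum(vapply(Pval, function(P) sum(P^2), 0))
    if (!is.finite(val_loss))
      .stopf("non-finite validation loss at epoch %d", epoch)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = train_loss,
                                         val_loss = val_loss))
    max_val <- max(max_val, val_loss)
    improvement <- best_val - val_loss
    if (epoch == 1L) {
      best_val <- val_loss
    } else if (improvement > config$early_stop_frac * abs(max_val)) {
      best_val <- val_loss
      stall <- 0L
    } else {
      best_val <- min(best_val, val_loss)
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }

  Otr <- lapply(seq_len(J), function(j)
    mlp_forward(params[[j]], Xtr[[j]], train_mode = FALSE))
  final <- fit_gcca(Otr, k = k, ridge = NULL)
  structure(list(params = params, specs = specs, config = config,
                 U = final$U, G_train = final$G,
                 eigenvalues = final$eigenvalues,
                 history = history, epochs_ran = nrow(history),
                 train_idx = train_idx, val_idx = val_idx,
                 center = center, scalev = scalev,
                 train_ids = ids[train_idx]),
            class = "dgcca_model")
}

#' @export
print.dgcca_model <- function(x, ...) {
  cat(sprintf("DGCCA model: %d views, k = %d, %d epochs, final val loss %.4f\n",
              length(x$params), x$config$k, x$epochs_ran,
              utils::tail(x$history$val_loss, 1L)))
  invisible(x)
}

#' Embed samples with a trained DGCCA model
#'
#' Views are standardized with the stored training-split statistics, passed
#' through the networks in evaluation mode, and projected with the stored
#' `U_j`. For the exact training split (matched by sample id) the stored
#' orthonormal `G_train` is returned; for any other sample set the shared
#' embedding is the least-squares combination `G = mean_j O_j U_j`, which
#' minimizes the reconstruction objective for fixed `U`.
#'
#' @param model a trained [train_dgcca()] model.
#' @param data an [multiview_dataset()] or list of view matrices (raw
#'   scale, as supplied to training).
#' @return list with `projections` (per-view `O_j U_j`), `outputs` (O_j)
#'   and `G`.
#' @export
dgcca_embed <- function(model, data) {
  if (!inherits(model, "dgcca_model") || is.null(model$U))
    .stopf("model is not a trained dgcca_model")
  views <- if (inherits(data, "mv_dataset")) data$views else data
  ids <- if (inherits(data, "mv_dataset")) data$sample_ids else NULL
  views <- lapply(views, as.matrix)
  Xs <- Map(function(v, m, s) scale(v, center = m, scale = s)[, , drop = FALSE],
            views, model$center, model$scalev)
  O <- lapply(seq_along(Xs), function(j)
    mlp_forward(model$params[[j]], Xs[[j]], train_mode = FALSE))
  projections <- Map(project_view, O, model$U)
  G <- if (!is.null(ids) && identical(ids, model$train_ids)) model$G_train
       else Reduce(`+`, projections) / length(projections)
  list(projections = projections, outputs = O, G = G)
}
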