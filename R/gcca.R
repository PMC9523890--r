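# Linear GCCA (MAXVAR-style formulation), solved in closed form.
#
# Given J views X_j (N x p_j), the shared embedding G minimizes
#   sum_j || G - X_j U_j ||_F^2   subject to  G'G = I_k.
# G holds the top-k eigenvectors of M = sum_j X_j (X_j'X_j + ridge I)^{-1}
# X_j', the per-view projections are U_j = (X_j'X_j + ridge I)^{-1} X_j' G,
# and the optimal objective equals J*k - sum of the top-k eigenvalues of M.

#' Column-standardize a list of views
#'
#' CCA-family methods are scale-sensitive and region-of-interest features
#' carry heterogeneous units, so each column is z-scored. Statistics may be
#' taken from a training subset and applied to all rows.
#'
#' @param views list of numeric matrices with equal row counts.
#' @param train_idx optional row indices used to compute means and standard
#'   deviations (default: all rows).
#' @return list of standardized matrices; zero-variance columns are centered
#'   but not scaled.
#' @export
standardize_views <- function(views, train_idx = NULL) {
  lapply(views, function(X) {
    tr <- if (is.null(train_idx)) X else X[train_idx, , drop = FALSE]
    mu <- colMeans(tr)
    sd <- apply(tr, 2L, stats::sd)
    sd[!is.finite(sd) | sd == 0] <- 1
    scale(X, center = mu, scale = sd)[, , drop = FALSE]
  })
}

# Per-view regularized inverse factor (X'X + ridge I)^{-1} X'.
# ridge = NULL uses the relative default 1e-8 * trace(X'X) / p_j.
.view_solve <- function(X, ridge, j) {
  S <- crossprod(X)
  r <- if (is.null(ridge)) 1e-8 * sum(diag(S)) / ncol(X) else ridge
  if (r > 0) S <- S + diag(r, ncol(X))
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(ch) && rcond(S) < 1e-12) ch <- NULL
  if (is.null(ch))
    .stopf(paste0("view %d: X'X is singular (rank-deficient view); ",
                  "supply ridge > 0"), j)
  list(WtX = chol2inv(ch) %*% t(X), ridge = r)
}

#' Fit generalized canonical correlation analysis (GCCA)
#'
#' @param views list of J standardized matrices X_j sharing N rows (see
#'   [standardize_views()]).
#' @param k number of embedding components (k <= N).
#' @param ridge nonnegative scalar added to the diagonal of each X_j'X_j
#'   before inversion; `NULL` (default) uses `1e-8 * trace(X_j'X_j) / p_j`
#'   per view, 0 requests exact unregularized inverses and errors on
#'   singular views.
#' @return an object of class `gcca_fit` with elements `G` (N x k,
#'   orthonormal columns, eigenvector signs fixed so the largest-magnitude
#'   entry of each column is positive), `U` (list of p_j x k projections),
#'   `eigenvalues` (top k, nonincreasing), `objective_value`
#'   (`J*k - sum(eigenvalues)`), `k` and `ridge` (per-view values used).
#' @export
fit_gcca <- function(views, k, ridge = NULL) {
  if (!length(views)) .stopf("need at least one view")
  views <- lapply(views, as.matrix)
  n <- nrow(views[[1L]])
  if (!all(vapply(views, nrow, 0L) == n))
    .stopf("all views must share the same number of rows")
  if (!.is_count(k) || k > n) .stopf("k must be a count <= N (%d)", n)
  solves <- Map(.view_solve, views, list(ridge), seq_along(views))
  M <- matrix(0, n, n)
  for (j in seq_along(views)) M <- M + views[[j]] %*% solves[[j]]$WtX
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  G <- .fix_signs(eg$vectors[, seq_len(k), drop = FALSE])
  lam <- eg$values[seq_len(k)]
  U <- lapply(solves, function(s) s$WtX %*% G)
  structure(list(G = G, U = U, eigenvalues = lam,
                 objective_value = length(views) * k - sum(lam),
                 k = k,
                 ridge = vapply(solves, `[[`, 0, "ridge")),
            class = "gcca_fit")
}

#' @export
print.gcca_fit <- function(x, ...) {
  cat(sprintf("GCCA fit: %d views, k = %d, objective = %.6g\n",
              length(x$U), x$k, x$objective_value))
  invisible(x)
}

#' Evaluate the GCCA reconstruction objective directly
#'
#' Computes `sum_j || G - X_j U_j ||_F^2`. At the optimum of [fit_gcca()]
#' this equals `J*k - sum(eigenvalues)`.
#'
#' @param views list of J matrices.
#' @param G N x k embedding.
#' @param U list of J projection matrices (p_j x k).
#' @return nonnegative scalar.
#' @export
gcca_objective <- function(views, G, U) {
  if (length(views) != length(U)) .stopf("views and U lengths differ")
  tot <- 0
  for (j in seq_along(views)) {
    Xj <- as.matrix(views[[j]]); Uj <- as.matrix(U[[j]])
    if (nrow(Xj) != nrow(G) || ncol(Xj) != nrow(Uj) || ncol(Uj) != ncol(G))
      .stopf("shape mismatch in view %d", j)
    tot <- tot + sum((G - Xj %*% Uj)^2)
  }
  tot
}

#' Project a view into the shared embedding space
#'
#' Plain matrix product `features %*% U_j`; used both for raw views
#' (GCCA) and network outputs (DGCCA).
#'
#' @param features N x q matrix.
#' @param U q x k projection matrix.
#' @return N x k matrix.
#' @export
project_view <- function(features, U) {
  features <- as.matrix(features); U <- as.matrix(U)
  if (ncol(features) != nrow(U))
    .stopf("feature columns (%d) do not match projection rows (%d)",
           ncol(features), nrow(U))
  features %*% U
}
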