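# Independent brute-force oracles. Each deliberately re-derives its
# quantity from first principles (loops, enumeration, grid search) so that
# agreement with the package implementation is informative.

# Triple-loop matrix multiply.
oracle_matmul <- function(A, B) {
  out <- matrix(0, nrow(A), ncol(B))
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(B)))
    for (l in seq_len(ncol(A))) out[i, j] <- out[i, j] + A[i, l] * B[l, j]
  out
}

# Naive Calinski-Harabasz with explicit loops.
oracle_ch <- function(X, lab) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  cls <- unique(lab)
  B <- 0; W <- 0
  for (cl in cls) {
    rows <- X[lab == cl, , drop = FALSE]
    muc <- colMeans(rows)
    B <- B + nrow(rows) * sum((muc - mu)^2)
    for (i in seq_len(nrow(rows))) W <- W + sum((rows[i, ] - muc)^2)
  }
  (B / (length(cls) - 1)) / (W / (nrow(X) - length(cls)))
}

# Naive O(N^2) silhouette with per-sample loops.
oracle_silhouette <- function(X, lab) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(lab == lab[i]), i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(vapply(own, function(j) d(i, j), 0))
    b <- Inf
    for (cl in setdiff(unique(lab), lab[i]))
      b <- min(b, mean(vapply(which(lab == cl), function(j) d(i, j), 0)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# Exact expected MI under the permutation model by enumerating all
# permutations of labels_b (small n only), plus plain MI / entropies.
oracle_mi <- function(a, b) {
  n <- length(a)
  tab <- table(a, b)
  mi <- 0
  for (i in rownames(tab)) for (j in colnames(tab)) {
    nij <- tab[i, j]
    if (nij > 0)
      mi <- mi + nij / n * log(n * nij / (sum(tab[i, ]) * sum(tab[, j])))
  }
  mi
}
oracle_ami <- function(a, b) {
  n <- length(a)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  emi <- mean(vapply(perms(seq_len(n)), function(p) oracle_mi(a, b[p]), 0))
  h <- function(l) {
    p <- table(l) / n
    -sum(p * log(p))
  }
  (oracle_mi(a, b) - emi) / ((h(a) + h(b)) / 2 - emi)
}

# Exact two-sided rank-sum p by enumerating all group assignments.
oracle_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  W_obs <- sum(rank(pooled)[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(n, nx)
  Ws <- apply(combs, 2L, function(idx)
    sum(rank(pooled)[idx]) - nx * (nx + 1) / 2)
  mu <- nx * (length(y)) / 2
  mean(abs(Ws - mu) >= abs(W_obs - mu))
}

# Grid-search maximizer of the (unpenalized, Breslow) Cox partial
# likelihood for a single covariate.
oracle_cox_beta <- function(time, event, x, grid = seq(-5, 5, by = 1e-3)) {
  loglik <- vapply(grid, function(b) {
    ll <- 0
    for (i in which(event == 1))
      ll <- ll + b * x[i] - log(sum(exp(b * x[time >= time[i]])))
    ll
  }, 0)
  grid[which.max(loglik)]
}

# Concordance by exhaustive pair enumeration.
oracle_concordance <- function(risk, time, event) {
  conc <- 0; comp <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (event[i] == 1 && time[i] < time[j]) {
      comp <- comp + 1
      if (risk[i] > risk[j]) conc <- conc + 1
      else if (risk[i] == risk[j]) conc <- conc + 0.5
    }
  }
  conc / comp
}

# Hand-tabulated two-group log-rank chi-square.
oracle_logrank <- function(time, event, group) {
  g1 <- group == sort(unique(group))[1L]
  U <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    n <- sum(time >= t); n1 <- sum(time >= t & g1)
    d <- sum(time == t & event == 1); d1 <- sum(time == t & event == 1 & g1)
    U <- U + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 <- 1 - n1 / n) * (n - d) / (n - 1)
  }
  U^2 / V
}

# Classical two-view CCA correlations via stats::cancor (SVD-based).
oracle_cca_cors <- function(A, B, k) stats::cancor(A, B)$cor[seq_len(k)]

# Brute-force eigen oracle for the projector-sum matrix.
oracle_projector_eigs <- function(mats, ridge = 0) {
  M <- Reduce(`+`, lapply(mats, function(O) {
    S <- crossprod(O)
    if (ridge > 0) S <- S + diag(ridge * sum(diag(S)) / ncol(O), ncol(O))
    O %*% solve(S) %*% t(O)
  }))
  eigen((M + t(M)) / 2, symmetric = TRUE)$values
}

# Two well-separated Gaussian blobs.
make_blobs <- function(n_per = 10, d = 2, gap = 50, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * d), n_per, d),
             matrix(rnorm(n_per * d, mean = gap), n_per, d))
  list(X = X, labels = rep(1:2, each = n_per))
}

# Mean held-out componentwise correlation over view pairs (top d).
heldout_cc <- function(projs, d) {
  vals <- c()
  for (a in seq_along(projs)) for (b in seq_along(projs)) {
    if (b <= a) next
    cc <- canonical_correlations(projs[[a]][, 1:d, drop = FALSE],
                                 projs[[b]][, 1:d, drop = FALSE])
    vals <- c(vals, mean(abs(cc), na.rm = TRUE))
  }
  mean(vals)
}
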