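# Subtype generation and evaluation: agglomerative clustering, elbow
# diagnostics, cluster-validity metrics (Calinski-Harabasz, silhouette,
# adjusted mutual information), cross-experiment similarity, and a
# permutation screen for independence of clusterings across views.

#' Agglomerative clustering of a feature matrix
#'
#' Hierarchical agglomeration on Euclidean distances cut at `n_clusters`.
#' The default Ward linkage (`ward.D2`, operating on distances) matches the
#' variance-based distortion elbow diagnostic; complete and average linkage
#' are available. Deterministic.
#'
#' @param features N x r numeric matrix.
#' @param n_clusters number of clusters (<= N).
#' @param linkage one of "ward", "complete", "average".
#' @return integer vector of cluster labels in 1..n_clusters.
#' @export
cluster_agglomerative <- function(features, n_clusters,
                                  linkage = c("ward", "complete", "average")) {
  linkage <- match.arg(linkage)
  features <- as.matrix(features)
  if (n_clusters > nrow(features))
    .stopf("n_clusters (%d) exceeds sample count (%d)",
           n_clusters, nrow(features))
  method <- switch(linkage, ward = "ward.D2", linkage)
  hc <- stats::hclust(stats::dist(features), method = method)
  unname(stats::cutree(hc, k = n_clusters))
}

#' Distortion elbow curve over candidate cluster counts
#'
#' Distortion at k is the mean squared Euclidean distance of samples to
#' their assigned-cluster centroid after agglomerative clustering at k.
#'
#' @param features N x r matrix.
#' @param k_range integer vector of candidate cluster counts within 1..N.
#' @param linkage passed to [cluster_agglomerative()].
#' @return data frame (k, distortion).
#' @export
elbow_distortion <- function(features, k_range, linkage = "ward") {
  if (!length(k_range)) .stopf("k_range must be nonempty")
  features <- as.matrix(features)
  if (any(k_range < 1) || any(k_range > nrow(features)))
    .stopf("k_range must lie within 1..N")
  distortion <- vapply(k_range, function(k) {
    lab <- cluster_agglomerative(features, k, linkage)
    tot <- 0
    for (cl in unique(lab)) {
      rows <- features[lab == cl, , drop = FALSE]
      mu <- colMeans(rows)
      tot <- tot + sum(sweep(rows, 2L, mu)^2)
    }
    tot / nrow(features)
  }, 0)
  data.frame(k = k_range, distortion = distortion)
}

#' Map clusters to subtype numbers by clinical-stage composition
#'
#' Subtype 1 is the cluster with the higher early-to-late stage ratio
#' (e.g. EMCI:LMCI); a cluster with zero late-stage members has ratio
#' +Inf. Exact ratio ties are broken by cluster size (larger cluster is
#' subtype 1), then by cluster index. Without stage labels, clusters map
#' to subtypes by index with a warning.
#'
#' @param labels integer cluster labels with exactly two clusters.
#' @param stage_labels per-sample binary stage factor/character; the early
#'   stage is `early_level` (default: first sorted level).
#' @param early_level value of `stage_labels` identifying the early stage.
#' @return list with `subtype_map` (named vector cluster -> subtype) and
#'   `subtypes` (per-sample 1/2 assignments).
#' @export
assign_subtype_labels <- function(labels, stage_labels = NULL,
                                  early_level = NULL) {
  cls <- sort(unique(labels))
  if (length(cls) != 2L) .stopf("expected exactly 2 clusters, got %d",
                                length(cls))
  if (is.null(stage_labels)) {
    .warnf("no stage labels; mapping clusters to subtypes by index")
    map <- stats::setNames(seq_along(cls), cls)
    return(list(subtype_map = map, subtypes = map[as.character(labels)]))
  }
  stage_labels <- as.character(stage_labels)
  lv <- sort(unique(stage_labels))
  if (length(lv) != 2L) .stopf("stage_labels must be binary")
  early_level <- early_level %||% lv[1L]
  ratio <- vapply(cls, function(cl) {
    e <- sum(labels == cl & stage_labels == early_level)
    l <- sum(labels == cl & stage_labels != early_level)
    if (l == 0L) Inf else e / l
  }, 0)
  size <- vapply(cls, function(cl) sum(labels == cl), 0L)
  ord <- order(-ratio, -size, cls)           # documented tie rules
  map <- stats::setNames(integer(2L), cls)
  map[as.character(cls[ord])] <- 1:2
  list(subtype_map = map, subtypes = unname(map[as.character(labels)]))
}

#' Calinski-Harabasz cluster-validity index
#'
#' `[B/(K-1)] / [W/(N-K)]` with between-cluster dispersion
#' `B = sum_c n_c ||mu_c - mu||^2` and within-cluster dispersion
#' `W = sum_c sum_{i in c} ||x_i - mu_c||^2`. Returns `Inf` when W = 0
#' with B > 0.
#'
#' @param features N x r matrix.
#' @param labels cluster labels with at least 2 nonempty clusters.
#' @return scalar (possibly `Inf`).
#' @export
ch_score <- function(features, labels) {
  features <- as.matrix(features)
  cls <- unique(labels)
  K <- length(cls); n <- nrow(features)
  if (K < 2L) .stopf("CH score undefined for a single cluster")
  mu <- colMeans(features)
  B <- 0; W <- 0
  for (cl in cls) {
    rows <- features[labels == cl, , drop = FALSE]
    muc <- colMeans(rows)
    B <- B + nrow(rows) * sum((muc - mu)^2)
    W <- W + sum(sweep(rows, 2L, muc)^2)
  }
  if (W == 0) return(if (B > 0) Inf else NaN)
  (B / (K - 1)) / (W / (n - K))
}

#' Mean silhouette width
#'
#' Per sample, `(b - a) / max(a, b)` with `a` the mean distance to its own
#' cluster (excluding itself) and `b` the smallest mean distance to another
#' cluster; singleton-cluster samples and all-zero distances score 0.
#'
#' @param features N x r matrix.
#' @param labels cluster labels with at least 2 clusters.
#' @return scalar in `[-1, 1]`.
#' @export
silhouette_score <- function(features, labels) {
  features <- as.matrix(features)
  cls <- unique(labels)
  if (length(cls) < 2L) .stopf("silhouette undefined for a single cluster")
  D <- as.matrix(stats::dist(features))
  n <- nrow(features)
  s <- vapply(seq_len(n), function(i) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) return(0)
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(cls, labels[i]), function(cl)
      mean(D[i, labels == cl]), 0))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, 0)
  mean(s)
}

#' Adjusted mutual information between two partitions
#'
#' `(MI - E[MI]) / (mean(H_a, H_b) - E[MI])` with the expected mutual
#' information taken under the permutation (hypergeometric) model and the
#' arithmetic mean of the entropies in the denominator. Returns 1 for
#' identical partitions, values near 0 for independent ones, and 0 by
#' convention when the denominator vanishes (e.g. a constant labeling).
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return scalar (at most 1; can be slightly negative).
#' @export
ami_score <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    .stopf("label vectors must have equal length")
  n <- length(labels_a)
  tab <- table(labels_a, labels_b)
  ai <- rowSums(tab); bj <- colSums(tab)
  mi <- 0
  for (i in seq_along(ai)) for (j in seq_along(bj)) {
    nij <- tab[i, j]
    if (nij > 0) mi <- mi + nij / n * log(n * nij / (ai[i] * bj[j]))
  }
  h <- function(w) { p <- w[w > 0] / n; -sum(p * log(p)) }
  ha <- h(ai); hb <- h(bj)
  emi <- 0
  for (i in seq_along(ai)) for (j in seq_along(bj)) {
    lo <- max(1, ai[i] + bj[j] - n); hi <- min(ai[i], bj[j])
    if (lo > hi) next
    for (nij in lo:hi) {
      lp <- lgamma(ai[i] + 1) + lgamma(bj[j] + 1) + lgamma(n - ai[i] + 1) +
        lgamma(n - bj[j] + 1) - lgamma(n + 1) - lgamma(nij + 1) -
        lgamma(ai[i] - nij + 1) - lgamma(bj[j] - nij + 1) -
        lgamma(n - ai[i] - bj[j] + nij + 1)
      emi <- emi + exp(lp) * nij / n * log(n * nij / (ai[i] * bj[j]))
    }
  }
  denom <- (ha + hb) / 2 - emi
  if (abs(denom) < 1e-12) return(0)
  unname((mi - emi) / denom)
}

#' Pairwise AMI between a set of clustering outcomes
#'
#' @param outcomes list of equal-length label vectors (or a named list).
#' @return symmetric matrix with unit diagonal.
#' @export
pairwise_cluster_similarity <- function(outcomes) {
  n <- length(outcomes)
  lens <- vapply(outcomes, length, 0L)
  if (length(unique(lens)) != 1L)
    .stopf("all outcomes must cover identical samples")
  M <- diag(1, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (b <= a) next
    M[a, b] <- M[b, a] <- ami_score(outcomes[[a]], outcomes[[b]])
  }
  dimnames(M) <- list(names(outcomes), names(outcomes))
  M
}

#' Stage-by-subtype confusion table
#'
#' @param labels per-sample subtype labels (binary).
#' @param stage_labels per-sample stage labels (binary).
#' @return 2 x 2 contingency table (stage x subtype).
#' @export
confusion_table <- function(labels, stage_labels) {
  if (length(labels) != length(stage_labels)) .stopf("length mismatch")
  table(stage = stage_labels, subtype = labels)
}

#' Permutation test for independence of two views' clusterings
#'
#' Observed statistic: AMI between the agglomerative clusterings of view A
#' and view B. The null distribution permutes the sample order of view B,
#' reclusters, and recomputes the AMI; the p-value uses add-one smoothing,
#' `p = (1 + #\{null >= observed\}) / (1 + n_permutations)`. Rejection
#' supports the working assumption that the views share a clustering.
#'
#' @param view_a_features,view_b_features matched N-row feature matrices.
#' @param n_clusters clusters per view (default 2).
#' @param n_permutations at least 99 (default 999).
#' @param seed integer seed for the permutations.
#' @param linkage passed to [cluster_agglomerative()].
#' @return list (class `independence_test`): `statistic`, `p_value`,
#'   `n_permutations`, `view_pair`.
#' @export
independence_permutation_test <- function(view_a_features, view_b_features,
                                          n_clusters = 2L,
                                          n_permutations = 999L,
                                          seed = 1L, linkage = "ward") {
  A <- as.matrix(view_a_features); B <- as.matrix(view_b_features)
  if (nrow(A) != nrow(B)) .stopf("views must share samples")
  if (n_permutations < 99L) .stopf("n_permutations must be >= 99")
  if (n_clusters > nrow(A)) .stopf("n_clusters exceeds sample count")
  la <- cluster_agglomerative(A, n_clusters, linkage)
  lb <- cluster_agglomerative(B, n_clusters, linkage)
  obs <- ami_score(la, lb)
  set.seed(seed)
  null_ge <- 0L
  for (p in seq_len(n_permutations)) {
    Bp <- B[sample.int(nrow(B)), , drop = FALSE]
    lp <- cluster_agglomerative(Bp, n_clusters, linkage)
    if (ami_score(la, lp) >= obs) null_ge <- null_ge + 1L
  }
  structure(list(statistic = obs,
                 p_value = (1 + null_ge) / (1 + n_permutations),
                 n_permutations = as.integer(n_permutations),
                 view_pair = "A-B"),
            class = "independence_test")
}
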