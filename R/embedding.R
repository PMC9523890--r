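# Component selection by variance explained, and per-pair per-component
# correlation diagnostics between projected views.

#' Fraction of view variance captured by the leading embedding columns
#'
#' For orthonormal `G` and standardized views, returns
#' `sum_j ||G_r G_r' X_j||_F^2 / sum_j ||X_j||_F^2` with `G_r` the first
#' `r` columns. The same definition is applied to GCCA and DGCCA
#' embeddings: in both cases the "original data" are the standardized
#' input views.
#'
#' @param views list of standardized view matrices.
#' @param G N x k matrix with orthonormal columns.
#' @param r number of leading columns to use (0 gives 0).
#' @return scalar in `[0, 1]`.
#' @export
variance_explained <- function(views, G, r) {
  G <- as.matrix(G)
  if (r > ncol(G)) .stopf("r (%d) exceeds the number of components (%d)",
                          r, ncol(G))
  gram <- crossprod(G)
  if (max(abs(gram - diag(ncol(G)))) > 1e-6)
    .stopf("G does not have orthonormal columns (max |G'G - I| = %.2e)",
           max(abs(gram - diag(ncol(G)))))
  if (r == 0) return(0)
  Gr <- G[, seq_len(r), drop = FALSE]
  num <- sum(vapply(views, function(X) sum(crossprod(Gr, as.matrix(X))^2), 0))
  den <- sum(vapply(views, function(X) sum(as.matrix(X)^2), 0))
  num / den
}

#' Variance-explained curve over all component counts
#'
#' @inheritParams variance_explained
#' @return numeric vector of length `ncol(G)`; nondecreasing, in `[0, 1]`.
#' @export
variance_curve <- function(views, G) {
  G <- as.matrix(G)
  den <- sum(vapply(views, function(X) sum(as.matrix(X)^2), 0))
  per <- vapply(seq_len(ncol(G)), function(i) {
    g <- G[, i]
    sum(vapply(views, function(X) sum(crossprod(as.matrix(X), g)^2), 0))
  }, 0)
  pmin(cumsum(per) / den, 1)
}

#' Smallest component count reaching a target variance fraction
#'
#' @param curve nondecreasing variance-explained curve.
#' @param target_fraction target in `[0, 1]`.
#' @return list with `chosen_r` and logical `target_met`; when the target is
#'   never reached, `chosen_r` is the curve length and a warning is issued.
#' @export
select_components <- function(curve, target_fraction) {
  if (!length(curve)) .stopf("empty variance curve")
  if (any(diff(curve) < -1e-10)) .stopf("curve must be nondecreasing")
  hit <- which(curve >= target_fraction)
  if (!length(hit)) {
    .warnf("target fraction %.3f never reached (max %.3f); using all %d",
           target_fraction, max(curve), length(curve))
    return(list(chosen_r = length(curve), target_met = FALSE))
  }
  list(chosen_r = max(1L, hit[1L]), target_met = TRUE)
}

#' Componentwise correlations between two projected views
#'
#' Pearson correlation between column i of each projection, for
#' i = 1..r — the per-embedded-feature quantity plotted per view pair on
#' training and validation samples. Columns with zero variance yield `NA`.
#'
#' @param proj_a,proj_b N x r projection matrices.
#' @return numeric vector of length r in `[-1, 1]` (or `NA`).
#' @export
canonical_correlations <- function(proj_a, proj_b) {
  proj_a <- as.matrix(proj_a); proj_b <- as.matrix(proj_b)
  if (!identical(dim(proj_a), dim(proj_b)))
    .stopf("projections must have matching shapes")
  vapply(seq_len(ncol(proj_a)), function(i) {
    a <- proj_a[, i]; b <- proj_b[, i]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, 0)
}

#' Per-pair per-component correlation table for a set of projections
#'
#' @param projections named list of N x r per-view projections (same split).
#' @param split label recorded in the output (e.g. "train", "validation").
#' @return data frame (component, view_pair, split, correlation).
#' @export
correlation_table <- function(projections, split = "train") {
  nms <- names(projections) %||% paste0("view", seq_along(projections))
  out <- list()
  for (a in seq_along(projections)) for (b in seq_along(projections)) {
    if (b <= a) next
    cc <- canonical_correlations(projections[[a]], projections[[b]])
    out[[length(out) + 1L]] <- data.frame(
      component = seq_along(cc),
      view_pair = paste(nms[a], nms[b], sep = "-"),
      split = split, correlation = cc)
  }
  do.call(rbind, out)
}
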