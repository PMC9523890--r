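# Case-control SNP association: per-SNP logistic regression with
# covariates (additive minor-allele coding), Wald p-values, and
# Benjamini-Hochberg FDR control.

#' Per-SNP case-control logistic association
#'
#' For each SNP, logistic regression of case/control status on the additive
#' allele count plus covariates, with a two-sided Wald p-value for the
#' genotype coefficient. Missing genotypes are dropped per SNP
#' (complete-case). Monomorphic SNPs, fits that fail to converge, and
#' quasi-separated fits (exploding standard error) are flagged untestable
#' rather than raising.
#'
#' @param genotypes samples x SNPs matrix of 0/1/2 minor-allele counts
#'   (NAs allowed).
#' @param phenotype binary vector, 1 = case; both classes must be present.
#' @param covariates optional data frame (e.g. age, gender, education)
#'   aligned with the genotype rows.
#' @return data frame (class `assoc_result`): snp_id, beta, se, p_value,
#'   neg_log10_p, testable.
#' @export
case_control_assoc <- function(genotypes, phenotype, covariates = NULL) {
  genotypes <- as.matrix(genotypes)
  if (length(unique(phenotype[!is.na(phenotype)])) != 2L)
    .stopf("phenotype must contain both cases and controls")
  y <- as.integer(phenotype == max(phenotype))
  C <- if (is.null(covariates)) NULL else as.matrix(as.data.frame(covariates))
  snps <- colnames(genotypes) %||% sprintf("snp%04d", seq_len(ncol(genotypes)))
  rows <- lapply(seq_len(ncol(genotypes)), function(s) {
    g <- genotypes[, s]
    keep <- !is.na(g) & !is.na(y)
    untest <- data.frame(snp_id = snps[s], beta = NA_real_, se = NA_real_,
                         p_value = NA_real_, neg_log10_p = NA_real_,
                         testable = FALSE)
    if (sum(keep) < 3L) return(untest)
    gk <- g[keep]; yk <- y[keep]
    if (stats::var(gk) == 0 || length(unique(yk)) < 2L) return(untest)
    Xk <- cbind(geno = gk, if (!is.null(C)) C[keep, , drop = FALSE])
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(cbind(1, Xk), yk,
                                      family = stats::binomial(),
                                      control = list(maxit = 50L))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(untest)
    # Wald statistics from the final IRLS weights
    W <- fit$weights
    XtWX <- crossprod(cbind(1, Xk) * sqrt(W))
    cov <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
    if (is.null(cov)) return(untest)
    beta <- fit$coefficients[2L]
    se <- sqrt(cov[2L, 2L])
    if (!is.finite(beta) || !is.finite(se) || se > 10) return(untest)
    p <- 2 * stats::pnorm(-abs(beta / se))
    data.frame(snp_id = snps[s], beta = unname(beta), se = se,
               p_value = p, neg_log10_p = -log10(p), testable = TRUE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("assoc_result", class(out))
  out
}

#' Benjamini-Hochberg FDR rejection flags
#'
#' Step-up rule: sort the m testable p-values ascending and reject all
#' hypotheses up to the largest i with `p_(i) <= (i/m) q`. Untestable
#' entries (`NA`) are excluded from m and returned as `NA`.
#'
#' @param p_values numeric vector in (0, 1] with NAs for untestable tests.
#' @param q target false discovery rate (default 0.05).
#' @return logical vector of rejection flags aligned with the input.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  out <- rep(NA, length(p_values))
  ok <- which(!is.na(p_values))
  if (!length(ok)) return(out)
  p <- p_values[ok]
  m <- length(p)
  ord <- order(p)
  thresh_ok <- p[ord] <= seq_len(m) / m * q
  cutoff <- if (any(thresh_ok)) max(which(thresh_ok)) else 0L
  rej <- logical(m)
  if (cutoff > 0L) rej[ord[seq_len(cutoff)]] <- TRUE
  out[ok] <- rej
  out
}

#' Cross-test summary of significant SNPs
#'
#' Restricts to SNPs significant (BH at `q`) in at least one test and
#' returns their `-log10(p)` across all tests, ordered by chromosome when
#' available; non-significant cells keep their p-values.
#'
#' @param results named list of [case_control_assoc()] tables sharing a SNP
#'   universe.
#' @param q FDR level used per test (default 0.05).
#' @param chromosomes optional named vector mapping snp_id to chromosome
#'   for ordering.
#' @return data frame: snp_id, chromosome (if given), one `neg_log10_p`
#'   column and one `significant` column per test. Empty when nothing is
#'   significant anywhere.
#' @export
assoc_summary <- function(results, q = 0.05, chromosomes = NULL) {
  if (!length(results)) .stopf("no association results supplied")
  nms <- names(results) %||% paste0("test", seq_along(results))
  universe <- results[[1L]]$snp_id
  for (r in results)
    if (!identical(sort(r$snp_id), sort(universe)))
      .stopf("all tests must share the same SNP universe")
  sig <- vapply(results, function(r) {
    flags <- bh_fdr(r$p_value, q)[match(universe, r$snp_id)]
    !is.na(flags) & flags
  }, logical(length(universe)))
  sig <- matrix(sig, nrow = length(universe))
  keep <- rowSums(sig) > 0
  if (!any(keep)) {
    return(data.frame(snp_id = character()))
  }
  out <- data.frame(snp_id = universe[keep])
  if (!is.null(chromosomes)) out$chromosome <- chromosomes[out$snp_id]
  for (i in seq_along(results)) {
    r <- results[[i]]
    idx <- match(out$snp_id, r$snp_id)
    out[[paste0(nms[i], "_neg_log10_p")]] <- r$neg_log10_p[idx]
    out[[paste0(nms[i], "_significant")]] <- sig[keep, i]
  }
  if (!is.null(chromosomes))
    out <- out[order(out$chromosome, out$snp_id), ]
  rownames(out) <- NULL
  out
}
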