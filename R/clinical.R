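# Subtype validation against clinical measures and conversion:
# Wilcoxon rank-sum battery with Bonferroni adjustment, elastic-net
# penalized Cox proportional-hazards model with Breslow baseline hazard,
# concordance index, two-group log-rank test, conversion curves, and
# longitudinal progression curves.

#' Wilcoxon rank-sum battery over clinical measures
#'
#' Two-sided rank-sum test of each measure between two groups. The exact
#' distribution is used when the combined sample size is at most 20 and
#' there are no ties; otherwise the normal approximation with tie
#' correction. Significance is declared at `alpha / n_measures`
#' (Bonferroni).
#'
#' @param measures N x m numeric matrix or data frame of measures.
#' @param labels two-group labels (e.g. subtype 1/2).
#' @param alpha familywise significance level (default 0.01).
#' @return data frame (measure, statistic, p, neg_log10_p, significant,
#'   tested).
#' @export
ranksum_battery <- function(measures, labels, alpha = 0.01) {
  measures <- as.data.frame(measures)
  groups <- sort(unique(labels))
  if (length(groups) != 2L) .stopf("labels must define exactly two groups")
  m <- ncol(measures)
  rows <- lapply(seq_len(m), function(i) {
    x <- measures[labels == groups[1L], i]
    y <- measures[labels == groups[2L], i]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (!length(x) || !length(y))
      return(data.frame(measure = names(measures)[i], statistic = NA_real_,
                        p = NA_real_, neg_log10_p = NA_real_,
                        significant = NA, tested = FALSE))
    if (length(unique(c(x, y))) == 1L) {      # all values identical
      stat <- length(x) * length(y) / 2
      p <- 1
    } else {
      ties <- anyDuplicated(c(x, y)) > 0L
      wt <- suppressWarnings(stats::wilcox.test(
        x, y, exact = (length(x) + length(y) <= 20L) && !ties,
        correct = TRUE))
      stat <- unname(wt$statistic)
      p <- min(1, wt$p.value)
    }
    data.frame(measure = names(measures)[i], statistic = stat, p = p,
               neg_log10_p = -log10(p), significant = p < alpha / m,
               tested = TRUE)
  })
  do.call(rbind, rows)
}

#' Fit a (penalized) Cox proportional-hazards model
#'
#' With zero penalty the fit is the Efron partial-likelihood maximizer
#' (via `survival::coxph`); with positive penalty an elastic-net penalized
#' fit (via `glmnet`, L1:L2 ratio `l1_ratio`, covariates standardized
#' internally, coefficients reported on the input scale; Breslow tie
#' handling). The baseline cumulative hazard is the Breslow estimator at
#' the fitted linear predictors, and the concordance index is computed on
#' the training records.
#'
#' @param time event/censoring times (months).
#' @param event binary indicator (1 = event).
#' @param covariates N x p numeric matrix or data frame.
#' @param penalty_strength overall elastic-net strength (glmnet lambda);
#'   default 0.1. Use 0 for an unpenalized fit.
#' @param l1_ratio L1 share of the penalty (glmnet alpha); default 0.5
#'   (L1:L2 = 1:1).
#' @return object of class `cox_fit`: `coefficients`, `lp` (linear
#'   predictors), `baseline` (data frame time, cumhaz), `concordance`,
#'   `penalty`.
#' @export
fit_cox <- function(time, event, covariates, penalty_strength = 0.1,
                    l1_ratio = 0.5) {
  X <- as.matrix(as.data.frame(covariates))
  storage.mode(X) <- "double"
  if (sum(event) < 1L) .stopf("no events; cannot fit a Cox model")
  if (all(apply(X, 2L, stats::sd) == 0)) {
    beta <- stats::setNames(rep(0, ncol(X)), colnames(X))
  } else if (penalty_strength == 0) {
    df <- data.frame(time = time, event = event, X)
    fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                   paste(colnames(X), collapse = " + ")))
    cf <- survival::coxph(fml, data = df, ties = "efron")
    beta <- stats::coef(cf)
    beta[is.na(beta)] <- 0
  } else {
    # glmnet requires >= 2 columns; pad single-covariate fits with a
    # zero dummy whose coefficient is discarded
    Xg <- if (ncol(X) == 1L) cbind(X, .dummy = 0) else X
    gf <- glmnet::glmnet(Xg, survival::Surv(time, event), family = "cox",
                         alpha = l1_ratio, lambda = penalty_strength,
                         standardize = TRUE)
    beta <- stats::setNames(as.numeric(stats::coef(gf))[seq_len(ncol(X))],
                            colnames(X))
  }
  lp <- as.numeric(X %*% beta)
  baseline <- .breslow_baseline(time, event, lp)
  structure(list(coefficients = beta, lp = lp, baseline = baseline,
                 concordance = concordance_index(lp, time, event),
                 penalty = list(strength = penalty_strength,
                                l1_ratio = l1_ratio)),
            class = "cox_fit")
}

# Breslow cumulative baseline hazard on the distinct event-time grid.
.breslow_baseline <- function(time, event, lp) {
  et <- sort(unique(time[event == 1]))
  risk <- exp(lp)
  ch <- vapply(et, function(t)
    sum(event == 1 & time == t) / sum(risk[time >= t]), 0)
  data.frame(time = et, cumhaz = cumsum(ch))
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit (penalty %.3g, L1 ratio %.2f), concordance %.3f\n",
              x$penalty$strength, x$penalty$l1_ratio, x$concordance))
  print(x$coefficients)
  invisible(x)
}

#' Concordance index of a risk score
#'
#' Fraction of comparable pairs (the earlier time is an observed event)
#' where the subject failing earlier has the higher risk score; risk ties
#' count one half.
#'
#' @param risk per-sample risk scores (higher = earlier expected failure).
#' @param time times; `event` binary indicators.
#' @param event binary event indicators.
#' @return fraction in `[0, 1]` (NaN when no pair is comparable).
#' @export
concordance_index <- function(risk, time, event) {
  n <- length(risk)
  conc <- 0; comp <- 0
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    later <- which(time > time[i])
    if (!length(later)) next
    comp <- comp + length(later)
    conc <- conc + sum(risk[i] > risk[later]) +
      0.5 * sum(risk[i] == risk[later])
  }
  conc / comp
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected log-rank chi-square with one degree of
#' freedom, with the hypergeometric variance at each distinct event time.
#'
#' @param time,event survival records.
#' @param group two-level group labels.
#' @return list: `statistic` (chi-square), `p`, `neg_log2_p`.
#' @export
logrank_test <- function(time, event, group) {
  groups <- sort(unique(group))
  if (length(groups) != 2L) .stopf("log-rank test needs exactly two groups")
  if (sum(event) < 1L) .stopf("no events")
  g1 <- group == groups[1L]
  et <- sort(unique(time[event == 1]))
  U <- 0; V <- 0
  for (t in et) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g1)
    U <- U + d1 - d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (V > 0) U^2 / V else 0
  p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  list(statistic = stat, p = p, neg_log2_p = -log2(p))
}

#' Conversion (survival) curves for covariate profiles
#'
#' `S(t | X) = exp(-H0(t) exp(beta' X))` on the fit's event-time grid, one
#' curve per row of `profiles` (typically per-group mean covariates).
#'
#' @param fit a [fit_cox()] result.
#' @param profiles matrix/data frame of covariate profiles (rows = groups),
#'   columns matching the fit's covariates.
#' @return data frame (group, time, survival).
#' @export
conversion_curves <- function(fit, profiles) {
  if (!inherits(fit, "cox_fit")) .stopf("fit must be a cox_fit")
  profiles <- as.matrix(as.data.frame(profiles))
  lp <- as.numeric(profiles %*% fit$coefficients[colnames(profiles)])
  nms <- rownames(profiles) %||% paste0("group", seq_len(nrow(profiles)))
  out <- lapply(seq_len(nrow(profiles)), function(g)
    data.frame(group = nms[g],
               time = c(0, fit$baseline$time),
               survival = c(1, exp(-fit$baseline$cumhaz * exp(lp[g])))))
  do.call(rbind, out)
}

#' Longitudinal progression curves by subtype
#'
#' Per (measure, month, subtype): group mean and normal-approximation 95%
#' confidence interval. Cells with fewer than 2 samples are flagged
#' (`reliable = FALSE`, CI collapsed to the mean).
#'
#' @param longitudinal long-format data frame with columns `sample_id`,
#'   `month`, `measure`, `value`.
#' @param labels named vector mapping sample_id to subtype.
#' @param horizon months beyond which records are dropped (default 60).
#' @return data frame (measure, month, subtype, n, mean, lower, upper,
#'   reliable).
#' @export
progression_curves <- function(longitudinal, labels, horizon = 60) {
  need <- c("sample_id", "month", "measure", "value")
  if (!all(need %in% names(longitudinal)))
    .stopf("longitudinal table needs columns %s", paste(need, collapse = ", "))
  df <- longitudinal[longitudinal$month >= 0 & longitudinal$month <= horizon, ]
  df$subtype <- labels[as.character(df$sample_id)]
  df <- df[!is.na(df$subtype), ]
  agg <- do.call(rbind, lapply(
    split(df, list(df$measure, df$month, df$subtype), drop = TRUE),
    function(s) {
      n <- nrow(s); m <- mean(s$value)
      se <- if (n > 1L) stats::sd(s$value) / sqrt(n) else 0
      data.frame(measure = s$measure[1L], month = s$month[1L],
                 subtype = s$subtype[1L], n = n, mean = m,
                 lower = m - 1.96 * se, upper = m + 1.96 * se,
                 reliable = n >= 2L)
    }))
  rownames(agg) <- NULL
  agg[order(agg$measure, agg$subtype, agg$month), ]
}
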