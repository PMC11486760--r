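#' Cohort-level statistics
#'
#' The statistics relating CIN status to clinical variables: two-sided
#' Fisher exact tests (point-probability summation), Cramér's V from the
#' uncorrected Pearson chi-square, Student's pooled-variance t-test,
#' univariate binary logistic regression with an optional
#' log10-then-standardize predictor transform and quasi-complete
#' separation detection, and an empirical ROC with Hanley-McNeil AUC
#' confidence interval and Youden-index threshold selection.
#'
#' @name cohort_statistics
NULL

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Sums the margin-fixed hypergeometric probabilities of every table whose
#' point probability does not exceed the observed one.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("cells must be non-negative integers")
  if (sum(table) == 0) stop("table total must be positive")
  stats::fisher.test(table, alternative = "two.sided")$p.value
}

#' Cramér's V association strength
#'
#' \code{V = sqrt(chi2 / (n * (min(r, c) - 1)))} with the uncorrected
#' Pearson chi-square (a continuity correction would not reproduce the
#' conventional value on 2x2 tables).
#'
#' @param table contingency matrix, any dimensions >= 2x2.
#' @return V in [0, 1].
#' @export
cramers_v <- function(table) {
  table <- as.matrix(table)
  if (min(dim(table)) < 2) stop("undefined for a single-row/column table")
  if (sum(table) == 0) stop("table total must be positive")
  chi2 <- suppressWarnings(
    stats::chisq.test(table, correct = FALSE)$statistic)
  v <- sqrt(as.numeric(chi2) / (sum(table) * (min(dim(table)) - 1)))
  unname(min(v, 1))
}

#' Independent-samples t-test
#'
#' Student's pooled-variance t by default (\code{equal_variance = FALSE}
#' gives Welch).
#'
#' @param x,y numeric samples, each of size >= 2.
#' @param equal_variance pooled-variance Student test when TRUE (default).
#' @return list with group \code{means}, \code{sds}, \code{t}, \code{df},
#'   two-sided \code{p}.
#' @export
independent_t_test <- function(x, y, equal_variance = TRUE) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 observations")
  tt <- stats::t.test(x, y, var.equal = equal_variance)
  list(means = c(mean(x), mean(y)), sds = c(stats::sd(x), stats::sd(y)),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Univariate binary logistic regression
#'
#' Maximum-likelihood fit (IRLS via \code{stats::glm}); with
#' \code{transform = "log10_standardize"} the predictor is log10-ed and
#' standardized to zero mean / unit SD before fitting, so the odds ratio
#' refers to one SD of the log10 predictor. Complete or quasi-complete
#' separation (the predictor perfectly orders the outcome classes) is
#' detected and flagged instead of reported as a valid odds ratio.
#'
#' @param x continuous predictor (strictly positive under log10).
#' @param y binary outcome, both classes present (0/1 or logical/factor).
#' @param transform \code{"log10_standardize"} or \code{"none"}.
#' @return list with \code{coefficient}, \code{se}, \code{or},
#'   \code{ci} (95\% Wald), \code{p}, \code{separation} flag,
#'   \code{converged}.
#' @export
logistic_univariate <- function(x, y,
                                transform = c("log10_standardize", "none")) {
  transform <- match.arg(transform)
  y <- as.integer(as.factor(y)) - 1L
  if (length(unique(y)) < 2) stop("outcome must contain both classes")
  if (transform == "log10_standardize") {
    if (any(x <= 0)) stop("log10 transform needs strictly positive x")
    x <- as.numeric(scale(log10(x)))
  }
  if (stats::var(x) == 0)
    return(list(coefficient = 0, se = NA_real_, or = 1,
                ci = c(NA_real_, NA_real_), p = 1, separation = FALSE,
                converged = TRUE))
  sep <- max(x[y == 0]) <= min(x[y == 1]) || max(x[y == 1]) <= min(x[y == 0])
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  b <- stats::coef(fit)[["x"]]
  se <- sqrt(diag(stats::vcov(fit)))[["x"]]
  separation <- sep || !fit$converged || abs(b) > 15
  list(coefficient = b, se = se, or = exp(b),
       ci = exp(b + c(-1, 1) * stats::qnorm(0.975) * se),
       p = summary(fit)$coefficients["x", "Pr(>|z|)"],
       separation = separation, converged = fit$converged)
}

#' Empirical ROC curve and AUC
#'
#' ROC over all score thresholds (predict positive when score >= t); AUC
#' by trapezoid, identical to the Mann-Whitney U statistic divided by
#' n1*n0 with ties counted one half. The 95\% CI uses the Hanley-McNeil
#' standard error.
#'
#' @param scores numeric predictor values.
#' @param labels binary outcome (positives = 1/TRUE/second factor level).
#' @return a \code{roc_result}: list with \code{points} data.frame
#'   (\code{threshold}, \code{fpr}, \code{tpr}), \code{auc}, \code{ci},
#'   \code{n_pos}, \code{n_neg}.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.integer(as.factor(labels)) - 1L
  if (length(unique(y)) < 2) stop("both outcome classes are required")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  thr <- c(sort(unique(scores), decreasing = TRUE), Inf)
  thr <- sort(thr, decreasing = TRUE)  # Inf first: nothing predicted positive
  pts <- t(vapply(thr, function(t0) {
    pos <- scores >= t0
    c(fpr = sum(pos & y == 0) / n0, tpr = sum(pos & y == 1) / n1)
  }, c(fpr = 0, tpr = 0)))
  points <- data.frame(threshold = thr, fpr = pts[, "fpr"],
                       tpr = pts[, "tpr"])
  # Mann-Whitney with half ties; equals the trapezoid over these points
  r <- rank(scores)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  structure(list(points = points, auc = auc,
                 ci = pmin(pmax(auc + c(-1, 1) * stats::qnorm(0.975) * se,
                                0), 1),
                 se = se, n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC %.3f (95%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$auc, x$ci[1], x$ci[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' Youden-index threshold of an ROC curve
#'
#' Maximizes J = sensitivity + specificity - 1 over the ROC's thresholds;
#' ties are broken toward higher specificity (lower false-positive rate).
#'
#' @param roc a \code{roc_result}.
#' @return list with \code{threshold}, \code{j}, \code{sensitivity},
#'   \code{specificity}.
#' @export
youden_threshold <- function(roc) {
  p <- roc$points
  j <- p$tpr - p$fpr
  best <- which(j == max(j))
  best <- best[which.min(p$fpr[best])]
  list(threshold = p$threshold[best], j = j[best],
       sensitivity = p$tpr[best], specificity = 1 - p$fpr[best])
}

#' Load the packaged 29-patient breast-cancer cohort
#'
#' Clinical covariates, sentinel-lymph-node biopsy outcome (SLNM) and
#' CIN High/Low group for 29 breast-cancer patients profiled by shallow
#' WGS, shipped as a plain-text resource. The per-patient
#' \code{arm_changes} column is a reconstruction: only its pairwise
#' cross-tabulations against CIN group and SLNM are constrained by the
#' source records, and the packaged assignment reproduces both exactly
#' (13 arm-changed patients, all SLNM-positive: 10 CIN-High, 3 CIN-Low).
#'
#' @return data.frame of 29 patient records.
#' @export
load_breast_cohort <- function() {
  path <- system.file("extdata", "breast_cohort_29.tsv",
                      package = "cinscore")
  cohort <- utils::read.delim(path, stringsAsFactors = FALSE,
                              check.names = FALSE)
  if (nrow(cohort) != 29 ||
      sum(cohort$slnm == "yes") != 24 ||
      sum(cohort$cin_group == "High") != 16 ||
      sum(cohort$arm_changes == "yes") != 13)
    stop("corrupted cohort resource: marginal counts do not match")
  cohort
}

cross_tab <- function(a, b, a_levels, b_levels) {
  table(factor(a, levels = a_levels), factor(b, levels = b_levels))
}

#' Association statistics across the cohort
#'
#' Recomputes, for each clinical variable, the Fisher exact p-value and
#' Cramér's V against both the CIN High/Low grouping and the SLNM
#' outcome, plus the sensitivity/specificity of CIN-High as a predictor
#' of SLNM.
#'
#' @param cohort data.frame from \code{\link{load_breast_cohort}} (or a
#'   compatible table).
#' @return list with \code{by_cin} and \code{by_slnm} data.frames
#'   (\code{variable}, \code{p}, \code{v}) and \code{classification}
#'   (sensitivity, specificity of CIN-High for SLNM).
#' @export
cohort_association_stats <- function(cohort = load_breast_cohort()) {
  dich <- list(
    age = factor(ifelse(cohort$age <= 60, "<=60", ">60")),
    tumor_size = factor(ifelse(cohort$tumor_size_cm <= 2.5, "<=2.5", ">2.5")),
    histologic_grade = factor(cohort$histologic_grade),
    er = factor(cohort$er), pr = factor(cohort$pr),
    her2 = factor(cohort$her2),
    ki67 = factor(cohort$ki67_category),
    molecular_type = factor(cohort$molecular_type),
    arm_changes = factor(cohort$arm_changes, levels = c("yes", "no")))
  cin <- factor(cohort$cin_group, levels = c("High", "Low"))
  slnm <- factor(cohort$slnm, levels = c("yes", "no"))
  assoc <- function(group, extra) {
    vars <- c(dich, extra)
    rows <- lapply(names(vars), function(v) {
      tab <- table(vars[[v]], group)
      p <- if (all(dim(tab) == c(2, 2))) fisher_exact_two_sided(tab)
           else stats::fisher.test(tab)$p.value
      data.frame(variable = v, p = p, v = cramers_v(tab))
    })
    do.call(rbind, rows)
  }
  by_cin <- assoc(cin, list(slnm = slnm))
  by_slnm <- assoc(slnm, list(cin_group = cin))
  sens <- sum(cin == "High" & slnm == "yes") / sum(slnm == "yes")
  spec <- sum(cin == "Low" & slnm == "no") / sum(slnm == "no")
  list(by_cin = by_cin, by_slnm = by_slnm,
       classification = c(sensitivity = sens, specificity = spec))
}
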