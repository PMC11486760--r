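#' End-to-end composition: normalize, segment, score, cohort statistics
#'
#' \code{run_sample} carries one tumor coverage profile through Z-score
#' normalization, CBS and CIN scoring; \code{run_cohort} runs a whole
#' simulated cohort and derives the group-level statistics (score
#' comparison, ROC/Youden threshold, High/Low-by-group association,
#' logistic fit on log10-standardized scores). Given identical inputs and
#' seeds both are deterministic.
#'
#' @name pipeline
NULL

#' Run the scoring pipeline on one sample
#'
#' @param profile a tumor \code{coverage_profile}.
#' @param panel a \code{control_panel} on the same grid.
#' @param params a \code{cbs_params}.
#' @param z_cut symmetric gain/loss threshold (default 3).
#' @param length_unit CIN score length unit (\code{"bins"} or \code{"Mb"}).
#' @return list with \code{normalized}, \code{segmentation}, \code{cin}
#'   (a \code{cin_result}) and \code{arm_changes}.
#' @export
run_sample <- function(profile, panel, params = cbs_params(), z_cut = 3,
                       length_unit = "bins") {
  nprof <- normalize_profile(profile, panel)
  segm <- segment_sample(nprof, params, z_cut)
  res <- cin_score(segm, length_unit)
  arms <- call_arm_changes(segm, mask = panel$mask)
  list(normalized = nprof, segmentation = segm, cin = res,
       arm_changes = arms)
}

#' Run the pipeline and group statistics on a simulated cohort
#'
#' Scores every tumor against the cohort's own control panel, selects the
#' Youden-optimal score threshold for the metastatic-like outcome, and
#' computes the downstream statistics. Groups with fewer than two samples
#' each skip the group statistics with a warning (scores are still
#' returned).
#'
#' @param cohort a \code{simulated_cohort}.
#' @param params a \code{cbs_params}; its seed should be tied to the
#'   cohort seed for full reproducibility.
#' @param z_cut symmetric gain/loss threshold (default 3).
#' @return list with \code{scores} data.frame (sample, group, cin_score,
#'   has_arm_changes, cin_group), \code{threshold} (Youden), \code{roc},
#'   \code{t_test}, \code{fisher_p}, \code{cramers_v}, \code{logistic}.
#' @export
run_cohort <- function(cohort, params = cbs_params(), z_cut = 3) {
  panel <- build_control_panel(cohort$controls)
  per_sample <- lapply(cohort$tumors, function(t)
    run_sample(t$profile, panel, params, z_cut))
  scores <- data.frame(
    sample = vapply(cohort$tumors, function(t) t$profile$sample_id, ""),
    group = cohort$groups,
    cin_score = vapply(per_sample, function(r) r$cin$cin_score, 0),
    has_arm_changes = vapply(per_sample, function(r)
      attr(r$arm_changes, "has_changes"), NA))
  if (min(table(cohort$groups)) < 2 || length(unique(cohort$groups)) < 2) {
    warning("need two groups with >= 2 samples each; group statistics skipped")
    return(list(scores = scores, threshold = NULL, roc = NULL,
                t_test = NULL, fisher_p = NULL, cramers_v = NULL,
                logistic = NULL, per_sample = per_sample))
  }
  y <- as.integer(scores$group == "metastatic")
  roc <- roc_auc(scores$cin_score, y)
  yt <- youden_threshold(roc)
  scores$cin_group <- ifelse(scores$cin_score >= yt$threshold,
                             "High", "Low")
  tt <- independent_t_test(scores$cin_score[y == 1],
                           scores$cin_score[y == 0])
  tab <- table(factor(scores$cin_group, levels = c("High", "Low")),
               factor(y, levels = c(1, 0)))
  # log10-standardized scores; zero scores get a one-bin-unit offset so
  # the log is defined (noted in the returned transform label)
  if (all(scores$cin_score > 0)) {
    logi <- logistic_univariate(scores$cin_score, y, "log10_standardize")
    transform <- "log10_standardize"
  } else {
    logi <- logistic_univariate(scores$cin_score + 1, y,
                                "log10_standardize")
    transform <- "log10_standardize_offset1"
  }
  list(scores = scores, threshold = yt, roc = roc, t_test = tt,
       fisher_p = fisher_exact_two_sided(tab), cramers_v = cramers_v(tab),
       logistic = c(logi, transform = transform), per_sample = per_sample)
}
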