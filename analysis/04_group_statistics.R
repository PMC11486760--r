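#!/usr/bin/env Rscript
# Group-level statistics on the simulated cohort scored by
# 03_segment_score.R: Student's t on CIN scores, ROC/AUC with the
# Youden-optimal threshold, High/Low x group Fisher test and Cramér's V,
# and a univariate logistic fit on log10-standardized scores — the same
# statistical battery the package applies to the packaged patient cohort.
# Writes results/sim_group_statistics.json.

suppressPackageStartupMessages(library(cinscore))

scores <- read.csv("results/sim/cin_scores.csv")
y <- as.integer(scores$group == "metastatic")
met <- scores$cin_score[y == 1]; non <- scores$cin_score[y == 0]

tt <- independent_t_test(met, non)
message(sprintf("t-test: mean %.1f vs %.1f, t = %.2f (df %d), p = %.4g",
                tt$means[1], tt$means[2], tt$t, tt$df, tt$p))

roc <- roc_auc(scores$cin_score, y)
yt <- youden_threshold(roc)
message(sprintf("AUC %.3f (95%% CI %.3f-%.3f)", roc$auc, roc$ci[1],
                roc$ci[2]))
message(sprintf(
  "Youden threshold %.1f: sensitivity %.3f, specificity %.3f",
  yt$threshold, yt$sensitivity, yt$specificity))

grp <- classify_cin(scores$cin_score, yt$threshold - 1e-9)
tab <- table(factor(grp, levels = c("High", "Low")),
             factor(y, levels = c(1, 0)))
fisher_p <- fisher_exact_two_sided(tab)
v <- cramers_v(tab)
message(sprintf("High/Low x group: Fisher p = %.4g, Cramér's V = %.3f",
                fisher_p, v))

# one-bin-unit offset keeps the log defined when a tumor scores zero
logi <- if (all(scores$cin_score > 0)) {
  logistic_univariate(scores$cin_score, y, "log10_standardize")
} else logistic_univariate(scores$cin_score + 1, y, "log10_standardize")
message(sprintf("logistic: OR %.3f (95%% CI %.3f-%.3f), p = %.3g%s",
                logi$or, logi$ci[1], logi$ci[2], logi$p,
                if (logi$separation) " [separation flagged]" else ""))

jsonlite::write_json(list(
  t_test = tt, auc = roc$auc, auc_ci = roc$ci,
  youden = yt, fisher_p = fisher_p, cramers_v = v,
  logistic = logi[c("or", "ci", "p", "separation")]),
  "results/sim_group_statistics.json", auto_unbox = TRUE, digits = NA)
message("wrote results/sim_group_statistics.json")
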