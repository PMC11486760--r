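test_that("Fisher p matches the printed cohort contingency values", {
  expect_lt(abs(fisher_exact_two_sided(matrix(c(16, 8, 0, 5), 2,
                                              byrow = TRUE)) - 0.011),
            0.0005)
  expect_lt(abs(fisher_exact_two_sided(matrix(c(13, 11, 0, 5), 2,
                                              byrow = TRUE)) - 0.048),
            0.0005)
  expect_equal(fisher_exact_two_sided(matrix(1, 2, 2)), 1)
})

test_that("Fisher p equals margin-fixed enumeration on random small tables", {
  set.seed(55)
  for (k in 1:200) {
    tab <- matrix(sample(0:10, 4, replace = TRUE), 2)
    if (sum(tab) == 0) tab[1, 1] <- 1
    expect_equal(fisher_exact_two_sided(tab), fisher_enumeration_p(tab),
                 tolerance = 1e-10)
  }
})

test_that("Fisher p is symmetric under transposition and label swaps", {
  set.seed(66)
  for (k in 1:20) {
    tab <- matrix(sample(0:12, 4, replace = TRUE) + c(1, 0, 0, 0), 2)
    p <- fisher_exact_two_sided(tab)
    expect_equal(fisher_exact_two_sided(t(tab)), p)
    expect_equal(fisher_exact_two_sided(tab[2:1, ]), p)
    expect_equal(fisher_exact_two_sided(tab[, 2:1]), p)
    expect_gt(p, 0); expect_lte(p, 1)
  }
})

test_that("Cramér's V reproduces the cohort association strengths", {
  expect_lt(abs(cramers_v(matrix(c(16, 8, 0, 5), 2, byrow = TRUE)) - 0.506),
            0.0005)
  expect_lt(abs(cramers_v(matrix(c(13, 11, 0, 5), 2, byrow = TRUE)) - 0.411),
            0.0005)
  expect_equal(cramers_v(matrix(10, 2, 2)), 0)
  expect_equal(cramers_v(matrix(c(7, 0, 0, 9), 2)), 1)
  expect_error(cramers_v(matrix(c(3, 4), 1)), "undefined")
})

test_that("Student's t-test matches its closed form", {
  tt0 <- independent_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tt0$t, 0)
  expect_equal(tt0$p, 1)
  set.seed(77)
  x <- rlnorm(16, 9.5, 0.5); y <- rlnorm(13, 9.0, 0.4)
  tt <- independent_t_test(x, y)
  sp2 <- ((15 * var(x) + 12 * var(y)) / 27)
  t_manual <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 16 + 1 / 13))
  expect_equal(tt$t, t_manual, tolerance = 1e-10)
  expect_equal(tt$p, 2 * pt(-abs(t_manual), 27), tolerance = 1e-10)
  near <- independent_t_test(c(0, 0, 0, 0) + rnorm(4, sd = 1e-3),
                             c(5, 5, 5, 5) + rnorm(4, sd = 1e-3))
  expect_lt(near$p, 0.001)
})

test_that("logistic regression recovers a known log-odds slope", {
  set.seed(88)
  x <- rnorm(500)
  y <- rbinom(500, 1, plogis(-0.3 + 1 * x))
  fit <- logistic_univariate(x, y, transform = "none")
  expect_false(fit$separation)
  expect_lt(abs(fit$coefficient - 1), 0.2)
  expect_true(fit$ci[1] < fit$or && fit$or < fit$ci[2])
  # log10-standardize of 10^x is the standardized x itself
  fit2 <- logistic_univariate(10^x, y, transform = "log10_standardize")
  ref <- logistic_univariate(as.numeric(scale(x)), y, transform = "none")
  expect_equal(fit2$coefficient, ref$coefficient, tolerance = 1e-8)
  expect_error(logistic_univariate(c(-1, 2, 3, 4), c(0, 1, 0, 1)),
               "positive")
  expect_error(logistic_univariate(1:4, rep(1, 4)), "both")
})

test_that("identical predictors give OR 1 and separation is flagged", {
  y <- rep(c(0, 1), each = 10)
  flat <- logistic_univariate(rep(c(5, 5), each = 10), y,
                              transform = "none")
  expect_equal(flat$or, 1, tolerance = 1e-6)
  expect_gt(flat$p, 0.9)
  sep <- logistic_univariate(c(rnorm(10, 0, 0.1), rnorm(10, 10, 0.1)), y,
                             transform = "none")
  expect_true(sep$separation)
  quasi <- logistic_univariate(c(rep(1, 10), 1, rnorm(9, 10, 0.1)), y,
                               transform = "none")
  expect_true(quasi$separation)
})

test_that("AUC equals the pairwise U-statistic oracle with half ties", {
  set.seed(110)
  for (k in 1:100) {
    n <- sample(6:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- sample(1:8, n, replace = TRUE)  # ties guaranteed
    expect_equal(roc_auc(scores, y)$auc, auc_pairwise(scores, y),
                 tolerance = 1e-12)
  }
})

test_that("ROC endpoints, complement symmetry, and degenerate cases hold", {
  y <- rep(c(0, 1), each = 5)
  perfect <- roc_auc(c(1:5, 11:15), y)
  expect_equal(perfect$auc, 1)
  expect_equal(roc_auc(rep(3, 10), y)$auc, 0.5)
  set.seed(120)
  s <- rnorm(30); yy <- rbinom(30, 1, 0.5); yy[1:2] <- c(0, 1)
  expect_equal(roc_auc(s, yy)$auc + roc_auc(-s, yy)$auc, 1)
  expect_error(roc_auc(1:5, rep(1, 5)), "both")
  pts <- perfect$points
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(130)
  s <- rnorm(40); y <- rbinom(40, 1, plogis(s)); y[1:2] <- c(0, 1)
  ours <- roc_auc(s, y)
  ref <- pROC::roc(y, s, quiet = TRUE, direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("Youden threshold maximizes tpr - fpr with specificity tie-break", {
  r <- roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))
  yt <- youden_threshold(r)
  expect_equal(yt$j, 1)
  expect_equal(yt$sensitivity, 1)
  expect_equal(yt$specificity, 1)
  expect_true(yt$threshold > 2 && yt$threshold <= 3)
  all_tied <- roc_auc(rep(2, 8), rep(c(0, 1), 4))
  expect_equal(youden_threshold(all_tied)$j, 0)
  set.seed(140)
  s <- rnorm(50); y <- rbinom(50, 1, plogis(2 * s)); y[1:2] <- c(0, 1)
  rr <- roc_auc(s, y)
  expect_equal(youden_threshold(rr)$j, max(rr$points$tpr - rr$points$fpr))
})

test_that("the packaged cohort has the documented margins", {
  cohort <- load_breast_cohort()
  expect_equal(nrow(cohort), 29)
  expect_equal(sum(cohort$slnm == "yes"), 24)
  expect_equal(sum(cohort$cin_group == "High"), 16)
  expect_equal(mean(cohort$tumor_size_cm), 2.221, tolerance = 0.001)
  expect_equal(range(cohort$age), c(30, 81))
  expect_equal(sum(cohort$er == "positive"), 24)
  expect_equal(sum(cohort$pr == "positive"), 22)
  expect_equal(sum(cohort$her2 == "positive"), 3)
})

test_that("cohort association statistics reproduce the published pattern", {
  stats <- cohort_association_stats()
  by_slnm <- stats$by_slnm
  expect_lt(abs(by_slnm$p[by_slnm$variable == "cin_group"] - 0.011), 0.0005)
  expect_lt(abs(by_slnm$v[by_slnm$variable == "cin_group"] - 0.506), 0.0005)
  expect_lt(abs(by_slnm$p[by_slnm$variable == "arm_changes"] - 0.048), 0.0005)
  expect_lt(abs(by_slnm$v[by_slnm$variable == "arm_changes"] - 0.411), 0.0005)
  expect_lt(abs(by_slnm$p[by_slnm$variable == "pr"] - 0.075), 0.0005)
  by_cin <- stats$by_cin
  expect_lt(abs(by_cin$p[by_cin$variable == "arm_changes"] - 0.061), 0.0005)
  expect_lt(abs(by_cin$p[by_cin$variable == "slnm"] - 0.011), 0.0005)
  expect_equal(unname(stats$classification["sensitivity"]), 16 / 24)
  expect_equal(unname(stats$classification["specificity"]), 1)
})

test_that("CIN-High as a binary score yields the published operating point", {
  cohort <- load_breast_cohort()
  scores <- as.integer(cohort$cin_group == "High")
  yt <- youden_threshold(roc_auc(scores, cohort$slnm == "yes"))
  expect_equal(round(yt$sensitivity, 2), 0.67)
  expect_equal(yt$specificity, 1)
})
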