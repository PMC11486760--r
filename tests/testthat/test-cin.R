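mk_segmentation <- function(segments, grid = toy_grid(c(4e6, 2e6), 2e5)) {
  structure(list(sample_id = "s", segments = segments, grid = grid,
                 params = cbs_params(), z_cut = 3),
            class = "segmentation")
}

test_that("the CIN score is length times |Z| over aberrant segments only", {
  seg <- data.frame(chrom = c("chr1", "chr1"),
                    start_bin = c(0L, 10L), end_bin = c(10L, 20L),
                    n_bins = c(10L, 10L), mean_z = c(5, 0.5),
                    call = c("gain", "neutral"))
  res <- cin_score(mk_segmentation(seg))
  expect_equal(res$cin_score, 50)
  expect_equal(unname(res$contributions[["chr1"]]), 50)
})

test_that("losses add |Z| rather than cancel, and a neutral genome scores 0", {
  seg <- data.frame(chrom = c("chr1", "chr2"),
                    start_bin = c(0L, 20L), end_bin = c(10L, 30L),
                    n_bins = c(10L, 10L), mean_z = c(4, -4),
                    call = c("gain", "loss"))
  res <- cin_score(mk_segmentation(seg))
  expect_equal(res$cin_score, 80)
  seg$call <- "neutral"
  expect_equal(cin_score(mk_segmentation(seg))$cin_score, 0)
})

test_that("score is additive across chromosomes and under equal-mean splits", {
  seg_joint <- data.frame(chrom = c("chr1", "chr2"),
                          start_bin = c(0L, 20L), end_bin = c(20L, 30L),
                          n_bins = c(20L, 10L), mean_z = c(4, -3.5),
                          call = c("gain", "loss"))
  seg_split <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                          start_bin = c(0L, 8L, 20L),
                          end_bin = c(8L, 20L, 30L),
                          n_bins = c(8L, 12L, 10L), mean_z = c(4, 4, -3.5),
                          call = c("gain", "gain", "loss"))
  expect_equal(cin_score(mk_segmentation(seg_joint))$cin_score,
               cin_score(mk_segmentation(seg_split))$cin_score)
  per_chrom <- cin_score(mk_segmentation(seg_joint))$contributions
  expect_equal(sum(per_chrom),
               cin_score(mk_segmentation(seg_joint))$cin_score)
})

test_that("score grows with aberrant length and |Z|", {
  base <- data.frame(chrom = "chr1", start_bin = 0L, end_bin = 10L,
                     n_bins = 10L, mean_z = 4, call = "gain")
  s0 <- cin_score(mk_segmentation(base))$cin_score
  longer <- base; longer$n_bins <- 15L; longer$end_bin <- 15L
  stronger <- base; stronger$mean_z <- 6
  expect_gt(cin_score(mk_segmentation(longer))$cin_score, s0)
  expect_gt(cin_score(mk_segmentation(stronger))$cin_score, s0)
})

test_that("the Mb length unit uses genomic extent", {
  seg <- data.frame(chrom = "chr1", start_bin = 0L, end_bin = 10L,
                    n_bins = 10L, mean_z = 5, call = "gain")
  res <- cin_score(mk_segmentation(seg), length_unit = "Mb")
  expect_equal(res$cin_score, 2 * 5)  # 10 bins x 200 kb = 2 Mb
})

test_that("classification is strict at the threshold", {
  expect_equal(classify_cin(20000, 13563), "High")
  expect_equal(classify_cin(13563, 13563), "Low")
  expect_equal(classify_cin(0, 13563), "Low")
  expect_equal(cin_threshold_reference, 13563)
})

test_that("arm calls require majority coverage and resolve direction conflicts", {
  grid <- toy_grid(c(4e6, 2e6), 2e5)  # chr1: 20 bins, centromere at bin 10
  full_gain <- data.frame(chrom = "chr1", start_bin = 10L, end_bin = 20L,
                          n_bins = 10L, mean_z = 5, call = "gain")
  rest <- data.frame(chrom = c("chr1", "chr2"),
                     start_bin = c(0L, 20L), end_bin = c(10L, 30L),
                     n_bins = c(10L, 10L), mean_z = c(0, 0),
                     call = c("neutral", "neutral"))
  ac <- call_arm_changes(mk_segmentation(rbind(full_gain, rest)))
  expect_equal(ac$change[ac$label == "1q"], "gain")
  expect_true(attr(ac, "has_changes"))

  partial <- full_gain; partial$start_bin <- 16L; partial$n_bins <- 4L
  rest2 <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                      start_bin = c(0L, 10L, 20L), end_bin = c(10L, 16L, 30L),
                      n_bins = c(10L, 6L, 10L), mean_z = 0,
                      call = "neutral")
  ac2 <- call_arm_changes(mk_segmentation(rbind(partial, rest2)))
  expect_equal(ac2$change[ac2$label == "1q"], "none")   # 4/10 < 0.5
  expect_false(attr(ac2, "has_changes"))
})

test_that("simulated whole-arm gain is recovered end-to-end", {
  set.seed(17)
  cfg <- sim_config(genome = toy_genome(c(4e6, 2e6)), bin_width = 1e5,
                    depth = 500, n_controls = 10, n_metastatic = 1,
                    n_non_metastatic = 1, p_event_metastatic = 1,
                    purity_range = c(0.8, 0.8),
                    catalog = data.frame(arm = "1q", direction = "gain",
                                         copy_number = 3L),
                    seed = 17)
  coh <- simulate_cohort(cfg)
  panel <- build_control_panel(coh$controls)
  r <- run_sample(coh$tumors[[1]]$profile, panel,
                  cbs_params(n_permutations = 500, rng_seed = 17))
  expect_equal(r$arm_changes$change[r$arm_changes$label == "1q"], "gain")
  expect_gt(r$cin$cin_score, 0)
})

test_that("empty segmentation scores zero with a warning", {
  empty <- mk_segmentation(data.frame())
  expect_warning(res <- cin_score(empty), "empty")
  expect_equal(res$cin_score, 0)
})
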