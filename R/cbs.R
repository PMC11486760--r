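#' Circular binary segmentation of per-bin Z-scores
#'
#' Each chromosome's Z vector is treated as a circle; the split maximizing
#' the absolute pooled-variance two-sample t statistic between an arc and
#' its complement is accepted when a seeded whole-vector permutation test
#' deems it significant, and the procedure recurses on the resulting
#' linear pieces. Masked bins are excised before segmentation and segments
#' are reported in original grid coordinates spanning the excised gaps.
#'
#' Segment calls use a symmetric threshold on the segment mean Z: gain
#' above \code{z_cut}, loss below \code{-z_cut}, neutral in between
#' (strict inequalities; the published rule names only the +3 side, and a
#' one-sided reading would leave no neutral state, so the cut is applied
#' symmetrically).
#'
#' @name cbs_segmentation
NULL

#' CBS tuning parameters
#'
#' @param alpha significance level for accepting a split (a split is kept
#'   when the permutation p-value is strictly below it; default 0.01).
#' @param n_permutations whole-vector shuffles per split test
#'   (default 10000, minimum 100).
#' @param min_seg_bins minimum bins per segment piece where feasible
#'   (default 3).
#' @param rng_seed integer seed driving every permutation stream.
#' @return a \code{cbs_params} list.
#' @export
cbs_params <- function(alpha = 0.01, n_permutations = 10000L,
                       min_seg_bins = 3L, rng_seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, n_permutations >= 100,
            min_seg_bins >= 1)
  structure(list(alpha = alpha,
                 n_permutations = as.integer(n_permutations),
                 min_seg_bins = as.integer(min_seg_bins),
                 rng_seed = as.integer(rng_seed)),
            class = "cbs_params")
}

#' Best circular split of a numeric vector
#'
#' Exhaustive scan over all arc/complement partitions (every circular
#' two-arc partition is a contiguous arc \code{[i, j)} in 0-based
#' half-open indexing), maximizing the absolute pooled-variance t
#' statistic. Constant input yields statistic 0 and no split.
#'
#' @param z numeric vector (finite values).
#' @param min_seg_bins minimum bins per part where feasible.
#' @return list with \code{i}, \code{j} (0-based half-open arc bounds, NA
#'   when no split exists) and \code{statistic}.
#' @export
best_circular_split <- function(z, min_seg_bins = 3L) {
  stopifnot(is.numeric(z), all(is.finite(z)))
  res <- cbs_best_split_cpp(as.numeric(z), as.integer(min_seg_bins))
  if (res$i < 0 || res$statistic == 0)
    return(list(i = NA_integer_, j = NA_integer_, statistic = 0))
  list(i = res$i, j = res$j, statistic = res$statistic)
}

#' Permutation p-value of a split statistic
#'
#' p = (1 + #\{shuffles with best statistic >= observed\}) / (1 + N),
#' the add-one estimator over N seeded whole-vector shuffles.
#'
#' @param z the vector the statistic was computed on.
#' @param statistic observed best-split statistic.
#' @param params a \code{cbs_params} (supplies N, min_seg_bins, seed).
#' @return p-value in (0, 1].
#' @export
split_significance <- function(z, statistic, params = cbs_params()) {
  res <- cbs_perm_pvalue_cpp(as.numeric(z), statistic,
                             params$n_permutations, params$min_seg_bins,
                             params$rng_seed, params$alpha,
                             early_stop = FALSE)
  res$p
}

# Recursive CBS on a gap-free vector; local 0-based coordinates.
# seed_env$k advances one step per significance test so every test in a
# sample draws an independent, reproducible permutation stream.
segment_recursive <- function(z, params, seed_env) {
  n <- length(z)
  one <- function() data.frame(start = 0L, end = n, mean_z = mean(z))
  if (n < 2L * params$min_seg_bins) return(one())
  sp <- cbs_best_split_cpp(z, params$min_seg_bins)
  if (sp$i < 0 || sp$statistic == 0) return(one())
  seed_env$k <- seed_env$k + 1L
  res <- cbs_perm_pvalue_cpp(z, sp$statistic, params$n_permutations,
                             params$min_seg_bins,
                             params$rng_seed + seed_env$k, params$alpha,
                             early_stop = TRUE)
  if (res$p >= params$alpha) return(one())
  cuts <- sort(unique(c(0L, sp$i, sp$j, n)))
  pieces <- lapply(seq_len(length(cuts) - 1L), function(k) {
    lo <- cuts[k]; hi <- cuts[k + 1L]
    sub <- segment_recursive(z[(lo + 1L):hi], params, seed_env)
    sub$start <- sub$start + lo
    sub$end <- sub$end + lo
    sub
  })
  do.call(rbind, pieces)
}

#' Segment one chromosome's Z vector
#'
#' @param z numeric vector of bin Z-scores (masked bins already removed).
#' @param params a \code{cbs_params}.
#' @return data.frame with \code{start}, \code{end} (0-based half-open,
#'   local coordinates), \code{n_bins}, \code{mean_z}.
#' @export
segment_chromosome <- function(z, params = cbs_params()) {
  stopifnot(length(z) >= 1, all(is.finite(z)))
  seed_env <- new.env()
  seed_env$k <- 0L
  seg <- segment_recursive(as.numeric(z), params, seed_env)
  seg$n_bins <- seg$end - seg$start
  seg[, c("start", "end", "n_bins", "mean_z")]
}

#' Segment a normalized profile genome-wide
#'
#' Masked bins are excised per chromosome before segmentation; reported
#' segments are mapped back to global grid indices and span any excised
#' gaps, with \code{n_bins} counting only unmasked bins.
#'
#' @param nprof a \code{normalized_profile}.
#' @param params a \code{cbs_params}.
#' @param z_cut symmetric gain/loss threshold on the segment mean Z
#'   (default 3).
#' @return a \code{segmentation} object: list with \code{sample_id},
#'   \code{segments} data.frame (\code{chrom}, \code{start_bin},
#'   \code{end_bin}, \code{n_bins}, \code{mean_z}, \code{call}),
#'   \code{grid}, \code{params}.
#' @export
segment_sample <- function(nprof, params = cbs_params(), z_cut = 3) {
  if (!inherits(nprof, "normalized_profile"))
    stop("nprof must be a normalized_profile")
  bins <- nprof$grid$bins
  chroms <- unique(bins$chrom)
  out <- list()
  for (ci in seq_along(chroms)) {
    idx <- which(bins$chrom == chroms[ci]) - 1L   # global 0-based
    keep <- idx[!nprof$mask[idx + 1L]]
    if (length(keep) == 0) next
    z <- nprof$z[keep + 1L]
    chr_params <- params
    chr_params$rng_seed <- params$rng_seed + 100003L * ci
    seg <- segment_chromosome(z, chr_params)
    # local (gap-free) -> global grid coordinates spanning masked gaps
    seg$start_bin <- keep[seg$start + 1L]
    seg$end_bin <- keep[seg$end] + 1L
    seg$chrom <- chroms[ci]
    out[[length(out) + 1L]] <-
      seg[, c("chrom", "start_bin", "end_bin", "n_bins", "mean_z")]
  }
  segments <- do.call(rbind, out)
  rownames(segments) <- NULL
  res <- structure(list(sample_id = nprof$sample_id,
                        segments = segments, grid = nprof$grid,
                        params = params, z_cut = z_cut),
                   class = "segmentation")
  call_segments(res, z_cut)
}

#' Fill gain/loss/neutral calls on a segmentation
#'
#' @param segmentation a \code{segmentation}.
#' @param z_cut symmetric threshold: gain when \code{mean_z > z_cut}, loss
#'   when \code{mean_z < -z_cut}, neutral otherwise (strict).
#' @return the segmentation with a \code{call} column filled.
#' @export
call_segments <- function(segmentation, z_cut = 3) {
  seg <- segmentation$segments
  seg$call <- ifelse(seg$mean_z > z_cut, "gain",
                     ifelse(seg$mean_z < -z_cut, "loss", "neutral"))
  segmentation$segments <- seg
  segmentation$z_cut <- z_cut
  segmentation
}

#' @export
print.segmentation <- function(x, ...) {
  tab <- table(x$segments$call)
  cat(sprintf("segmentation '%s': %d segments (%s)\n", x$sample_id,
              nrow(x$segments),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Write a segmentation as SEG-format TSV
#'
#' Columns sample, chrom, loc.start, loc.end, num.mark, seg.mean — the
#' de-facto interchange format consumed by genome viewers.
#'
#' @param segmentation a \code{segmentation}.
#' @param path output path.
#' @export
write_seg <- function(segmentation, path) {
  bins <- segmentation$grid$bins
  seg <- segmentation$segments
  out <- data.frame(sample = segmentation$sample_id,
                    chrom = seg$chrom,
                    loc.start = bins$start[seg$start_bin + 1L],
                    loc.end = bins$end[seg$end_bin],
                    num.mark = seg$n_bins,
                    seg.mean = seg$mean_z)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
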