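#' Bin-level coverage and control-panel Z-score normalization
#'
#' Raw per-bin fragment counts are standardized bin-by-bin against a panel
#' of diploid controls:
#' \deqn{Z_{bin} = (raw_{bin} - mean_{controls}) / sd_{controls}}
#' with the sample (m-1) standard deviation over the m panel members.
#' Bins where the panel has zero variance are masked and carry through the
#' whole pipeline as \code{NA}; no GC or mappability correction is applied
#' (raw counts enter the standardization directly).
#'
#' @name coverage_normalization
NULL

#' Construct a coverage profile
#'
#' @param sample_id sample label.
#' @param grid a \code{bin_grid}.
#' @param values numeric vector of non-negative per-bin counts, one per
#'   grid bin.
#' @return a \code{coverage_profile}.
#' @export
coverage_profile <- function(sample_id, grid, values) {
  if (!inherits(grid, "bin_grid")) stop("grid must be a bin_grid")
  if (length(values) != n_bins(grid))
    stop("values length (", length(values), ") != grid bin count (",
         n_bins(grid), ")")
  if (any(values < 0)) stop("coverage values must be non-negative")
  structure(list(sample_id = sample_id, grid = grid,
                 values = as.numeric(values)),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("coverage_profile '%s': %d bins, total %.0f, mean %.2f\n",
              x$sample_id, length(x$values), sum(x$values), mean(x$values)))
  invisible(x)
}

#' Count aligned fragments into grid bins
#'
#' Each fragment is assigned to the single bin containing its midpoint.
#' Fragments on chromosomes absent from the grid are skipped and counted
#' in the \code{skipped} attribute rather than raising an error.
#'
#' @param fragments data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open, as in BED).
#' @param grid a \code{bin_grid}.
#' @param sample_id label for the resulting profile.
#' @return a \code{coverage_profile}; \code{attr(, "skipped")} holds the
#'   number of out-of-grid fragments.
#' @export
bin_coverage <- function(fragments, grid, sample_id = "sample") {
  stopifnot(all(c("chrom", "start", "end") %in% names(fragments)))
  chr <- grid$genome$chromosomes
  # global index = chromosome bin offset + floor(midpoint / bin_width)
  first_bin <- c(0L, cumsum(ceiling(chr$length / grid$bin_width)))
  ci <- match(fragments$chrom, chr$name)
  mid <- (fragments$start + fragments$end) / 2
  in_range <- !is.na(ci) & mid >= 0 & mid < chr$length[ifelse(is.na(ci), 1L, ci)]
  idx <- first_bin[ci[in_range]] + floor(mid[in_range] / grid$bin_width)
  counts <- tabulate(idx + 1L, nbins = n_bins(grid))
  out <- coverage_profile(sample_id, grid, counts)
  attr(out, "skipped") <- sum(!in_range)
  out
}

#' Build a control panel from diploid coverage profiles
#'
#' Per-bin mean and sample (m-1) standard deviation across the panel;
#' bins with zero panel SD are masked.
#'
#' @param profiles list of \code{coverage_profile}s on a common grid
#'   (at least two).
#' @return a \code{control_panel}: list with \code{grid}, \code{m},
#'   \code{mean}, \code{sd}, and logical \code{mask} (TRUE = unusable bin).
#' @export
build_control_panel <- function(profiles) {
  if (length(profiles) < 2) stop("a control panel needs at least 2 profiles")
  grid <- profiles[[1]]$grid
  nb <- n_bins(grid)
  same <- vapply(profiles, function(p)
    inherits(p, "coverage_profile") && n_bins(p$grid) == nb &&
      identical(p$grid$bins$chrom, grid$bins$chrom), logical(1))
  if (!all(same)) stop("all control profiles must share one grid")
  mat <- do.call(cbind, lapply(profiles, `[[`, "values"))
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1, stats::sd)
  structure(list(grid = grid, m = length(profiles), mean = mu, sd = sdv,
                 mask = sdv == 0),
            class = "control_panel")
}

#' @export
print.control_panel <- function(x, ...) {
  cat(sprintf("control_panel: %d samples, %d bins (%d masked)\n",
              x$m, length(x$mean), sum(x$mask)))
  invisible(x)
}

#' Standardize a coverage profile against a control panel
#'
#' @param profile a \code{coverage_profile} on the panel's grid.
#' @param panel a \code{control_panel}.
#' @param rescale_depth if TRUE, the profile's total count is first scaled
#'   to the panel members' median total (off by default: raw coverage
#'   enters the standardization as-is).
#' @param panel_totals numeric vector of panel member totals, required
#'   when \code{rescale_depth = TRUE}.
#' @return a \code{normalized_profile} with per-bin \code{z} (\code{NA} at
#'   masked bins) and the panel's \code{mask}.
#' @export
normalize_profile <- function(profile, panel, rescale_depth = FALSE,
                              panel_totals = NULL) {
  if (!inherits(panel, "control_panel")) stop("panel must be a control_panel")
  if (n_bins(profile$grid) != length(panel$mean) ||
      !identical(profile$grid$bins$chrom, panel$grid$bins$chrom))
    stop("profile and panel are on different grids")
  vals <- profile$values
  if (rescale_depth) {
    if (is.null(panel_totals)) stop("rescale_depth needs panel_totals")
    vals <- vals * stats::median(panel_totals) / sum(vals)
  }
  z <- (vals - panel$mean) / panel$sd
  z[panel$mask] <- NA_real_
  structure(list(sample_id = profile$sample_id, grid = profile$grid,
                 z = z, mask = panel$mask),
            class = "normalized_profile")
}

#' @export
print.normalized_profile <- function(x, ...) {
  cat(sprintf(
    "normalized_profile '%s': %d bins (%d masked), %d with |Z| > 3\n",
    x$sample_id, length(x$z), sum(x$mask), sum(abs(x$z) > 3, na.rm = TRUE)))
  invisible(x)
}

#' Round-trippable per-bin TSV output (chrom, start, end, value)
#'
#' @param x a \code{coverage_profile} or \code{normalized_profile}.
#' @param path output path.
#' @export
write_profile_tsv <- function(x, path) {
  value <- if (inherits(x, "normalized_profile")) x$z else x$values
  out <- cbind(x$grid$bins[, c("chrom", "start", "end")], value = value)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-bin value TSV back onto a grid
#'
#' @param path TSV written by \code{write_profile_tsv}.
#' @param grid the \code{bin_grid} the values belong to.
#' @param sample_id label for the profile.
#' @return a \code{coverage_profile}.
#' @export
read_profile_tsv <- function(path, grid, sample_id = basename(path)) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) != n_bins(grid)) stop("row count does not match grid")
  coverage_profile(sample_id, grid, tab$value)
}
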