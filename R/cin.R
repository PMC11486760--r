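#' Genome-wide chromosomal-instability score
#'
#' The CIN score sums, over every segment called gain or loss, the product
#' of segment length and the magnitude of the segment's mean Z-score:
#' \deqn{CIN = \sum_{seg\,aberrant} L_{seg} \cdot |Z_{seg}|}
#' Neutral segments contribute nothing, and |Z| is used so that losses add
#' to the score instead of cancelling gains. Segment length is measured in
#' bins by default (one bin = one grid window); a megabase option is
#' provided. The absolute score therefore only has meaning relative to a
#' stated length unit, bin width and normalization configuration.
#'
#' @name cin_scoring
NULL

#' High/Low cutoff of the reference cohort configuration
#'
#' The score cutoff that best separated the High and Low instability
#' groups in the 29-patient reference cohort (Youden-optimal on its ROC
#' curve, under that cohort's 200-kb pipeline configuration). It is
#' exported for reference and is never applied to synthetic cohorts,
#' which derive their own Youden threshold.
#'
#' @export
cin_threshold_reference <- 13563

#' Compute the CIN score of a called segmentation
#'
#' @param segmentation a \code{segmentation} with calls filled.
#' @param length_unit \code{"bins"} (default) or \code{"Mb"} for segment
#'   length in Eq. score terms.
#' @return a \code{cin_result}: list with \code{sample_id},
#'   \code{cin_score}, per-chromosome \code{contributions}, and
#'   \code{length_unit}.
#' @export
cin_score <- function(segmentation, length_unit = c("bins", "Mb")) {
  length_unit <- match.arg(length_unit)
  seg <- segmentation$segments
  if (is.null(seg) || nrow(seg) == 0) {
    warning("empty segmentation: CIN score 0")
    return(structure(list(sample_id = segmentation$sample_id,
                          cin_score = 0, contributions = numeric(0),
                          length_unit = length_unit),
                     class = "cin_result"))
  }
  if (is.null(seg$call)) stop("segments must be called first")
  L <- if (length_unit == "bins") seg$n_bins else {
    bins <- segmentation$grid$bins
    (bins$end[seg$end_bin] - bins$start[seg$start_bin + 1L]) / 1e6
  }
  term <- ifelse(seg$call == "neutral", 0, L * abs(seg$mean_z))
  contrib <- tapply(term, seg$chrom, sum)
  contrib <- contrib[unique(seg$chrom)]  # keep genome order
  structure(list(sample_id = segmentation$sample_id,
                 cin_score = sum(term),
                 contributions = contrib,
                 length_unit = length_unit),
            class = "cin_result")
}

#' @export
print.cin_result <- function(x, ...) {
  cat(sprintf("cin_result '%s': score %.3f (%s)", x$sample_id,
              x$cin_score, x$length_unit))
  if (!is.null(x$group)) cat(" —", x$group)
  cat("\n")
  invisible(x)
}

#' Classify a CIN score as High or Low
#'
#' High when the score strictly exceeds the threshold; a score equal to
#' the threshold is Low.
#'
#' @param score numeric CIN score (vectorized).
#' @param threshold positive cutoff.
#' @return character vector \code{"High"}/\code{"Low"}.
#' @export
classify_cin <- function(score, threshold) {
  stopifnot(threshold > 0)
  ifelse(score > threshold, "High", "Low")
}

#' Call chromosome-arm gains and losses from a segmentation
#'
#' An arm is called gained (lost) when segments called gain (loss) cover
#' at least \code{min_arm_fraction} of the arm's unmasked bins; when both
#' directions qualify the one covering more bins wins; otherwise the arm
#' is \code{"none"}.
#'
#' @param segmentation a called \code{segmentation}.
#' @param arms data.frame from \code{\link{arm_intervals}} on the same
#'   build (defaults to the grid's own arms).
#' @param min_arm_fraction coverage fraction required to call an arm
#'   (default 0.5).
#' @param mask optional logical vector of masked bins (TRUE = masked);
#'   defaults to none.
#' @return an \code{arm_changes} object: data.frame with \code{label} and
#'   \code{change} in \code{gain}/\code{loss}/\code{none};
#'   \code{attr(, "has_changes")} is TRUE iff any arm is non-none.
#' @export
call_arm_changes <- function(segmentation, arms = NULL,
                             min_arm_fraction = 0.5, mask = NULL) {
  grid <- segmentation$grid
  if (is.null(arms)) arms <- arm_intervals(grid$genome)
  nb <- n_bins(grid)
  if (is.null(mask)) mask <- rep(FALSE, nb)
  bin_arm <- arm_of(grid, 0:(nb - 1L))
  seg <- segmentation$segments
  bin_call <- rep("neutral", nb)
  for (k in seq_len(nrow(seg)))
    bin_call[(seg$start_bin[k] + 1L):seg$end_bin[k]] <- seg$call[k]
  res <- lapply(seq_len(nrow(arms)), function(a) {
    in_arm <- bin_arm == arms$label[a] & !mask
    n_arm <- sum(in_arm)
    if (n_arm == 0) return(data.frame(label = arms$label[a], change = "none"))
    fg <- sum(bin_call[in_arm] == "gain") / n_arm
    fl <- sum(bin_call[in_arm] == "loss") / n_arm
    change <- "none"
    if (fg >= min_arm_fraction && fg >= fl) change <- "gain"
    else if (fl >= min_arm_fraction) change <- "loss"
    data.frame(label = arms$label[a], change = change)
  })
  out <- do.call(rbind, res)
  attr(out, "has_changes") <- any(out$change != "none")
  class(out) <- c("arm_changes", "data.frame")
  out
}

#' Write per-sample CIN results as JSON
#'
#' @param result a \code{cin_result}.
#' @param path output JSON path.
#' @export
write_cin_json <- function(result, path) {
  jsonlite::write_json(list(
    sample_id = result$sample_id,
    cin_score = result$cin_score,
    length_unit = result$length_unit,
    contributions = as.list(result$contributions),
    group = result$group), path, auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(path)
}
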