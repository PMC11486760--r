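#' Genome builds, chromosome arms and fixed-width bin grids
#'
#' All coverage data in the package are indexed against a \code{bin_grid}:
#' a tiling of every chromosome of a genome build into half-open,
#' fixed-width windows (200 kb by default, the resolution at which shallow
#' WGS read counts proxy copy number). Coordinates are 0-based, half-open
#' throughout.
#'
#' @name genome_model
NULL

#' Construct a genome build
#'
#' @param name build label, e.g. \code{"hg19"} or \code{"toy"}.
#' @param chromosomes data.frame with columns \code{name}, \code{length}
#'   (bp) and \code{centromere} (bp coordinate splitting the p and q arm;
#'   \code{NA} allowed for acrocentric/toy chromosomes without one).
#' @return A \code{genome_build} object.
#' @export
genome_build <- function(name, chromosomes) {
  stopifnot(is.character(name), length(name) == 1L)
  req <- c("name", "length", "centromere")
  if (!is.data.frame(chromosomes) || !all(req %in% names(chromosomes)))
    stop("chromosomes must be a data.frame with columns name, length, centromere")
  if (nrow(chromosomes) < 1L) stop("a genome build needs at least one chromosome")
  if (anyDuplicated(chromosomes$name)) stop("chromosome names must be unique")
  if (any(chromosomes$length <= 0)) stop("chromosome lengths must be positive")
  cen <- chromosomes$centromere
  bad <- !is.na(cen) & (cen <= 0 | cen >= chromosomes$length)
  if (any(bad)) stop("centromere must lie strictly inside the chromosome: ",
                     paste(chromosomes$name[bad], collapse = ", "))
  chromosomes$name <- as.character(chromosomes$name)
  chromosomes$length <- as.numeric(chromosomes$length)
  chromosomes$centromere <- as.numeric(cen)
  structure(list(name = name, chromosomes = chromosomes[, req]),
            class = "genome_build")
}

#' @export
print.genome_build <- function(x, ...) {
  cat(sprintf("genome_build '%s': %d chromosomes, %.1f Mb total\n",
              x$name, nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6))
  invisible(x)
}

#' The packaged hg19 build
#'
#' Chromosome lengths and centromere midpoints for chr1-chr22 and chrX,
#' shipped as a plain-text resource (no download).
#'
#' @return A \code{genome_build}.
#' @export
hg19_genome <- function() {
  path <- system.file("extdata", "hg19_chromosomes.tsv", package = "cinscore")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  genome_build("hg19", tab)
}

#' A small three-chromosome build for fast tests and examples
#'
#' @param lengths chromosome lengths in bp.
#' @param centromeres centromere coordinates (same length as \code{lengths}).
#' @return A \code{genome_build}.
#' @export
toy_genome <- function(lengths = c(5e6, 3e6, 1e6),
                       centromeres = lengths / 2) {
  genome_build("toy", data.frame(
    name = paste0("chr", seq_along(lengths)),
    length = lengths, centromere = centromeres))
}

#' Tile a genome build into a fixed-width bin grid
#'
#' Each chromosome is covered by \code{ceiling(length / bin_width)}
#' half-open bins \code{[start, end)}; the last bin of a chromosome is
#' truncated at the chromosome end. Bins carry consecutive 0-based global
#' indices in chromosome order.
#'
#' @param genome a \code{genome_build}.
#' @param bin_width bin width in bp (default 200 kb).
#' @return A \code{bin_grid}: list with \code{genome}, \code{bin_width} and
#'   a \code{bins} data.frame (\code{chrom}, \code{start}, \code{end},
#'   \code{index}).
#' @export
make_bins <- function(genome, bin_width = 200000) {
  if (!inherits(genome, "genome_build")) stop("genome must be a genome_build")
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("bin_width must be a positive number")
  chr <- genome$chromosomes
  pieces <- lapply(seq_len(nrow(chr)), function(i) {
    n <- ceiling(chr$length[i] / bin_width)
    start <- (seq_len(n) - 1) * bin_width
    data.frame(chrom = chr$name[i], start = start,
               end = pmin(start + bin_width, chr$length[i]),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, pieces)
  bins$index <- seq_len(nrow(bins)) - 1L
  rownames(bins) <- NULL
  structure(list(genome = genome, bin_width = bin_width, bins = bins),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("bin_grid on '%s': %d bins of %g bp\n",
              x$genome$name, nrow(x$bins), x$bin_width))
  invisible(x)
}

n_bins <- function(grid) nrow(grid$bins)

#' Chromosome-arm intervals of a build
#'
#' Arms partition each chromosome at its centromere; chromosomes without a
#' centromere coordinate contribute a single whole-chromosome interval
#' labelled \code{"q"}.
#'
#' @param genome a \code{genome_build}.
#' @return data.frame with \code{chrom}, \code{arm} (\code{"p"}/\code{"q"}),
#'   \code{start}, \code{end}, and \code{label} (e.g. \code{"1q"}).
#' @export
arm_intervals <- function(genome) {
  chr <- genome$chromosomes
  rows <- lapply(seq_len(nrow(chr)), function(i) {
    nm <- chr$name[i]; len <- chr$length[i]; cen <- chr$centromere[i]
    if (is.na(cen)) {
      data.frame(chrom = nm, arm = "q", start = 0, end = len)
    } else {
      data.frame(chrom = c(nm, nm), arm = c("p", "q"),
                 start = c(0, cen), end = c(cen, len))
    }
  })
  arms <- do.call(rbind, rows)
  arms$label <- paste0(sub("^chr", "", arms$chrom), arms$arm)
  rownames(arms) <- NULL
  arms
}

#' Arm membership of grid bins
#'
#' A bin belongs to the arm containing its midpoint; bins straddling the
#' centromere therefore go to whichever arm holds more than half the bin.
#'
#' @param grid a \code{bin_grid}.
#' @param index 0-based global bin index (vectorized).
#' @return character vector of arm labels (e.g. \code{"17p"}).
#' @export
arm_of <- function(grid, index) {
  if (!inherits(grid, "bin_grid")) stop("grid must be a bin_grid")
  if (any(index < 0 | index >= n_bins(grid)))
    stop("bin index out of range")
  b <- grid$bins[index + 1L, ]
  mid <- (b$start + b$end) / 2
  cen <- grid$genome$chromosomes$centromere[
    match(b$chrom, grid$genome$chromosomes$name)]
  arm <- ifelse(is.na(cen) | mid >= cen, "q", "p")
  paste0(sub("^chr", "", b$chrom), arm)
}

#' Export a bin grid as BED3 + index
#'
#' @param grid a \code{bin_grid}.
#' @param path output TSV path.
#' @export
write_bin_grid <- function(grid, path) {
  utils::write.table(grid$bins, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
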