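#' Read-pair quality control
#'
#' Whole-pair rejection filters for paired shallow-WGS FASTQ input, plus
#' the usual sequencing summary statistics (Q20/Q30/GC). A pair is
#' discarded if either mate fails a filter; filters are checked in the
#' order adapter -> N-fraction -> low-quality fraction and the first
#' matching reason is the one tallied. All thresholds are strict
#' ("exceeds"), so boundary values pass.
#'
#' @name read_qc
NULL

empty_qc_report <- function() {
  structure(list(n_reads = 0L, yield_bases = 0, q20 = NA_real_,
                 q30 = NA_real_, gc = NA_real_, error_rate = NA_real_),
            class = "qc_report")
}

# Illumina TruSeq adapter prefixes; "joint sequences" are detected as
# exact substring matches against this configurable list.
truseq_adapters <- function() c(
  "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
  "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT")

#' QC filter parameters
#'
#' @param n_fraction_max maximum tolerated fraction of N bases per mate
#'   (pair discarded when strictly exceeded; default 0.10).
#' @param low_quality_phred bases with Phred quality strictly below this
#'   count as low-quality (default 5).
#' @param low_quality_fraction_max maximum tolerated low-quality-base
#'   fraction per mate (default 0.50).
#' @param adapters character vector of adapter sequences searched as exact
#'   substrings.
#' @return a \code{qc_params} list.
#' @export
qc_params <- function(n_fraction_max = 0.10, low_quality_phred = 5L,
                      low_quality_fraction_max = 0.50,
                      adapters = truseq_adapters()) {
  stopifnot(n_fraction_max >= 0, n_fraction_max <= 1,
            low_quality_fraction_max >= 0, low_quality_fraction_max <= 1,
            low_quality_phred >= 0)
  structure(list(n_fraction_max = n_fraction_max,
                 low_quality_phred = as.integer(low_quality_phred),
                 low_quality_fraction_max = low_quality_fraction_max,
                 adapters = adapters),
            class = "qc_params")
}

#' Build a read-pair record
#'
#' @param id read identifier.
#' @param seq1,seq2 mate sequences (character scalars).
#' @param qual1,qual2 integer vectors of Phred qualities, one per base.
#' @return a \code{read_pair} list.
#' @export
read_pair <- function(id, seq1, qual1, seq2, qual2) {
  if (nchar(seq1) != length(qual1) || nchar(seq2) != length(qual2))
    stop("malformed record '", id, "': sequence and quality lengths differ")
  list(id = id, seq = c(seq1, seq2), qual = list(qual1, qual2))
}

#' Read paired FASTQ files into read-pair records
#'
#' Phred+33 encoding; files may be gzipped. Mates are paired by position.
#'
#' @param file1,file2 FASTQ paths for mate 1 and mate 2.
#' @return list of \code{read_pair} records.
#' @export
read_fastq_pairs <- function(file1, file2) {
  # Biostrings warns when it drops FASTQ metadata columns; irrelevant here
  r1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(file1))
  r2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(file2))
  if (length(r1) != length(r2))
    stop("mate files differ in read count (", length(r1), " vs ", length(r2), ")")
  q1 <- as(Biostrings::quality(r1), "IntegerList")
  q2 <- as(Biostrings::quality(r2), "IntegerList")
  s1 <- unname(as.character(r1)); s2 <- unname(as.character(r2))
  ids <- names(r1)
  if (is.null(ids)) ids <- as.character(seq_along(r1))
  lapply(seq_along(r1), function(i)
    read_pair(ids[i], s1[i], q1[[i]], s2[i], q2[[i]]))
}

mate_fail_reason <- function(seq, qual, params) {
  for (ad in params$adapters)
    if (grepl(ad, seq, fixed = TRUE)) return("adapter")
  len <- nchar(seq)
  n_frac <- lengths(regmatches(seq, gregexpr("N", seq, fixed = TRUE))) / len
  if (n_frac > params$n_fraction_max) return("n_fraction")
  if (mean(qual < params$low_quality_phred) > params$low_quality_fraction_max)
    return("low_quality")
  NA_character_
}

#' Filter read pairs
#'
#' Applies the adapter / N-fraction / low-quality filters pair-wise: a
#' single failing mate discards the whole pair.
#'
#' @param pairs list of \code{read_pair} records.
#' @param params a \code{qc_params} object.
#' @return list with \code{kept} (surviving pairs) and \code{report}
#'   (a \code{qc_report}).
#' @export
filter_read_pairs <- function(pairs, params = qc_params()) {
  reasons <- vapply(pairs, function(p) {
    for (m in 1:2) {
      r <- mate_fail_reason(p$seq[m], p$qual[[m]], params)
      if (!is.na(r)) return(r)
    }
    NA_character_
  }, character(1))
  kept <- pairs[is.na(reasons)]
  discarded <- table(factor(reasons[!is.na(reasons)],
                            levels = c("adapter", "n_fraction", "low_quality")))
  rep <- if (length(kept)) sequencing_stats(kept) else empty_qc_report()
  rep$total_pairs <- length(pairs)
  rep$kept_pairs <- length(kept)
  rep$discarded <- as.list(discarded)
  list(kept = kept, report = rep)
}

#' Sequencing summary statistics
#'
#' Q20/Q30 are the fractions of bases with Phred quality >= 20 / >= 30;
#' GC is (G+C)/(A+C+G+T), N bases excluded. The per-base sequencing error
#' rate requires alignment and is reported as \code{NA}.
#'
#' @param pairs list of \code{read_pair} records.
#' @return a \code{qc_report} list (read count, yield in bases, q20, q30,
#'   gc fractions).
#' @export
sequencing_stats <- function(pairs) {
  if (length(pairs) == 0) stop("empty input: no read pairs")
  quals <- unlist(lapply(pairs, function(p) unlist(p$qual)))
  seqs <- unlist(lapply(pairs, function(p) p$seq))
  base_counts <- colSums(do.call(
    rbind, lapply(seqs, function(s)
      vapply(c("A", "C", "G", "T"), function(b)
        lengths(regmatches(s, gregexpr(b, s, fixed = TRUE))), numeric(1)))))
  structure(list(
    n_reads = 2L * length(pairs),
    yield_bases = length(quals),
    q20 = mean(quals >= 20),
    q30 = mean(quals >= 30),
    gc = sum(base_counts[c("C", "G")]) / sum(base_counts),
    error_rate = NA_real_), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d reads, %.0f bases; Q20 %.3f, Q30 %.3f, GC %.3f\n",
              x$n_reads, x$yield_bases, x$q20, x$q30, x$gc))
  if (!is.null(x$total_pairs))
    cat(sprintf("  pairs: %d total, %d kept, discarded: %s\n",
                x$total_pairs, x$kept_pairs,
                paste(names(x$discarded), unlist(x$discarded),
                      sep = "=", collapse = ", ")))
  invisible(x)
}
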