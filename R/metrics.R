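## Evaluation metrics: label-based true positive rate and the blank-design
## false positive rate.

#' Label-based true positive rate
#'
#' A label (a genomic portion known to be differentially accumulated) counts
#' as recovered when at least one DER overlaps it by one or more bases; by
#' default the overlap must be on the same strand. With N labels and E
#' missed labels, `TPR = (N - E) / N`.
#'
#' @param labels a stranded `GRanges` of validated regions.
#' @param ders a stranded `GRanges` of called DERs.
#' @param ignore_strand count overlaps regardless of strand.
#' @return the TPR, a number in `[0, 1]`.
#' @export
tpr <- function(labels, ders, ignore_strand = FALSE) {
  if (length(labels) == 0L) stop("label set is empty")
  hit <- GenomicRanges::countOverlaps(labels, ders,
                                      ignore.strand = ignore_strand) > 0
  (length(labels) - sum(!hit)) / length(labels)
}

#' Blank-design false positive rate
#'
#' In a blank (same-condition) comparison every called DER is a false
#' positive: `FPR = n_ders / n_segments`.
#'
#' @param n_ders number of DERs called.
#' @param n_segments total number of segments (>= 1).
#' @return the FPR, a number in `[0, 1]`.
#' @export
fpr <- function(n_ders, n_segments) {
  if (n_segments < 1L) stop("need at least one segment")
  if (n_ders < 0L || n_ders > n_segments)
    stop("n_ders must lie in [0, n_segments]")
  n_ders / n_segments
}

#' Read labels from a BED6 file
#'
#' @param path BED file with strand in column 6.
#' @return a stranded `GRanges`.
#' @export
read_labels <- function(path) {
  rtracklayer::import(path, format = "bed")
}

#' Assemble (and optionally write) a benchmark report
#'
#' Combines the label-based [tpr()] with the blank-design [fpr()] inputs
#' into one record.
#'
#' @param labels,ders as in [tpr()]; `labels` may be `NULL` when only the
#'   FPR side is benchmarked.
#' @param n_ders,n_segments as in [fpr()]; `NULL` skips the FPR side.
#' @param path optional TSV output path.
#' @param ignore_strand passed to [tpr()].
#' @return a one-row data.frame with columns `n_labels`, `n_missed`, `tpr`,
#'   `n_segments`, `n_ders`, `fpr` (`NA` for the side not supplied).
#' @export
benchmark_report <- function(labels = NULL, ders = NULL, n_ders = NULL,
                             n_segments = NULL, path = NULL,
                             ignore_strand = FALSE) {
  if (!is.null(labels)) {
    t <- tpr(labels, ders, ignore_strand = ignore_strand)
    n_lab <- length(labels)
    missed <- as.integer(round((1 - t) * n_lab))
  } else {
    t <- NA_real_; n_lab <- NA_integer_; missed <- NA_integer_
  }
  f <- if (!is.null(n_ders) && !is.null(n_segments)) {
    fpr(n_ders, n_segments)
  } else NA_real_
  out <- data.frame(
    n_labels = n_lab, n_missed = missed, tpr = t,
    n_segments = if (is.null(n_segments)) NA_integer_ else n_segments,
    n_ders = if (is.null(n_ders)) NA_integer_ else n_ders,
    fpr = f
  )
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
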