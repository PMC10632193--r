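#' Construct a genomic window
#'
#' A window is a length-1 stranded [GenomicRanges::GRanges] on which
#' profiles are computed. Coordinates are 1-based inclusive (the native
#' GRanges convention); conversion to 0-based formats happens only when
#' files are written.
#'
#' @param chrom sequence name.
#' @param start,end 1-based inclusive interval bounds, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @return a length-1 `GRanges`.
#' @examples
#' genomic_window("chr1", 101, 200, "+")
#' @export
genomic_window <- function(chrom, start, end, strand = "+") {
  if (!is.character(chrom) || length(chrom) != 1L)
    stop("'chrom' must be a single sequence name")
  if (start < 1L || end < start)
    stop("invalid window: require 1 <= start <= end")
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-'")
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
}

#' Parse a samtools-style region string
#'
#' @param region a string `"chrom:start-end"` (1-based inclusive) or a
#'   length-1 `GRanges` (returned unstranded).
#' @return an unstranded length-1 `GRanges`.
#' @export
parse_region <- function(region) {
  if (is(region, "GRanges")) {
    if (length(region) != 1L) stop("'region' must be a single range")
    return(GenomicRanges::granges(region))
  }
  m <- regmatches(region, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", region))[[1]]
  if (length(m) != 4L)
    stop("cannot parse region '", region, "'; expected chrom:start-end")
  s <- as.integer(gsub(",", "", m[3]))
  e <- as.integer(gsub(",", "", m[4]))
  if (is.na(s) || is.na(e) || s < 1L || e < s)
    stop("invalid region coordinates in '", region, "'")
  GenomicRanges::GRanges(m[2], IRanges::IRanges(s, e))
}

#' Read a sample sheet
#'
#' Tab-separated file with header columns `sample`, `condition`,
#' `replicate` and `bam` (path to a coordinate-sorted, indexed BAM).
#' Exactly two condition labels are required.
#'
#' @param path TSV file path, or a data.frame with the same columns.
#' @return a data.frame with columns `sample`, `condition`, `replicate`,
#'   `bam`.
#' @export
read_sample_sheet <- function(path) {
  ss <- if (is.data.frame(path)) path else read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "condition", "replicate", "bam")
  miss <- setdiff(need, names(ss))
  if (length(miss))
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  ss$condition <- as.character(ss$condition)
  if (length(unique(ss$condition)) != 2L)
    stop("sample sheet must contain exactly two condition labels")
  if (anyDuplicated(ss$sample))
    stop("duplicated sample identifiers in sample sheet")
  ss[need]
}
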