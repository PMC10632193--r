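## Coverage profiles: per-base read-end and full-length coverage on one
## strand of a genomic window, and the per-base log2 fold-change between
## two conditions.

.check_bam <- function(bam_path, chrom = NULL) {
  if (!file.exists(bam_path)) stop("BAM file not found: ", bam_path)
  bai <- c(paste0(bam_path, ".bai"), sub("\\.bam$", ".bai", bam_path))
  if (!any(file.exists(bai)))
    stop("BAM index (.bai) not found for ", bam_path,
         "; the BAM must be coordinate-sorted and indexed")
  if (!is.null(chrom)) {
    targets <- Rsamtools::scanBamHeader(bam_path)[[1]]$targets
    if (!chrom %in% names(targets))
      stop("sequence '", chrom, "' is absent from the header of ", bam_path)
  }
  invisible(TRUE)
}

.bam_flags <- Rsamtools::scanBamFlag(
  isUnmappedQuery = FALSE,
  isSecondaryAlignment = FALSE,
  isSupplementaryAlignment = FALSE,
  isNotPassingQualityControls = FALSE
)

## Read alignment units overlapping `window` and assign each its biological
## (transcript) strand under the library protocol. A unit is either a single
## read (pairing_mode = "read") or a properly-paired fragment plus any
## unpaired reads (pairing_mode = "fragment"). Returns a GRanges of unit
## spans with a `blocks` GRangesList of aligned blocks (gaps excluded).
.read_units <- function(bam_path, window,
                        library_protocol = c("fr", "rf", "unstranded"),
                        pairing_mode = c("fragment", "read")) {
  library_protocol <- match.arg(library_protocol)
  pairing_mode <- match.arg(pairing_mode)
  chrom <- as.character(seqnames(window))
  .check_bam(bam_path, chrom)
  which <- GenomicRanges::GRanges(chrom, IRanges::ranges(window))

  if (pairing_mode == "fragment") {
    prm <- Rsamtools::ScanBamParam(flag = .bam_flags, which = which)
    pairs <- suppressWarnings(
      GenomicAlignments::readGAlignmentPairs(bam_path, param = prm,
                                             strandMode = 1L)
    )
    flag_unpaired <- Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE, isNotPassingQualityControls = FALSE,
      isPaired = FALSE
    )
    singles <- GenomicAlignments::readGAlignments(
      bam_path,
      param = Rsamtools::ScanBamParam(flag = flag_unpaired, which = which)
    )
    span <- c(
      GenomicRanges::granges(pairs),
      GenomicRanges::granges(singles)
    )
    blocks <- c(
      GenomicAlignments::grglist(pairs),
      GenomicAlignments::grglist(singles)
    )
    read_strand <- as.character(strand(span))
  } else {
    prm <- Rsamtools::ScanBamParam(flag = .bam_flags, which = which,
                                   what = "flag")
    aln <- GenomicAlignments::readGAlignments(bam_path, param = prm)
    span <- GenomicRanges::granges(aln)
    blocks <- GenomicAlignments::grglist(aln)
    read_strand <- as.character(strand(aln))
    ## mate-1-based inference: the second mate reports the opposite of the
    ## fragment strand
    fl <- mcols(aln)$flag
    second <- bitwAnd(fl, 128L) > 0L
    read_strand[second] <- ifelse(read_strand[second] == "+", "-", "+")
  }

  bio_strand <- switch(library_protocol,
    fr = read_strand,
    rf = ifelse(read_strand == "+", "-", "+"),
    unstranded = {
      warning("unstranded protocol: all reads assigned to the '+' strand")
      rep("+", length(read_strand))
    }
  )
  strand(span) <- bio_strand
  mcols(span)$blocks <- blocks
  names(span) <- NULL
  span
}

#' Extract read 5'/3' end positions over a window
#'
#' Retained alignment units (primary, mapped, QC-pass) overlapping the
#' window are reduced to their 5' and 3' end genomic positions on the
#' biological (transcript) strand implied by the library protocol. With
#' `pairing_mode = "fragment"` a properly paired read pair is one unit whose
#' ends are the fragment's outermost aligned positions; with `"read"` each
#' mate is an independent unit.
#'
#' @param bam_path coordinate-sorted, indexed BAM.
#' @param window a stranded [genomic_window()] (only chrom/start/end are
#'   used for retrieval; strand filtering happens downstream).
#' @param library_protocol `"fr"` (read strand = transcript strand), `"rf"`
#'   (opposite) or `"unstranded"` (all reads to `+`, with a warning).
#' @param pairing_mode `"fragment"` (default) or `"read"`.
#' @return a data.frame with columns `five_prime`, `three_prime` (1-based
#'   genomic positions) and `strand`.
#' @export
extract_read_ends <- function(bam_path, window,
                              library_protocol = c("fr", "rf", "unstranded"),
                              pairing_mode = c("fragment", "read")) {
  units <- .read_units(bam_path, window, library_protocol, pairing_mode)
  if (length(units) == 0L)
    return(data.frame(five_prime = integer(0), three_prime = integer(0),
                      strand = character(0)))
  st <- as.character(strand(units))
  fwd <- st == "+"
  data.frame(
    five_prime  = ifelse(fwd, start(units), end(units)),
    three_prime = ifelse(fwd, end(units), start(units)),
    strand = st
  )
}

#' Per-base read-end coverage
#'
#' Counts, at every base of the window, how many retained reads on the
#' window's strand have their selected (5' or 3') end at that base. Ends
#' falling outside the window are ignored.
#'
#' @param read_ends data.frame as returned by [extract_read_ends()].
#' @param window a stranded [genomic_window()].
#' @param which_end `"five_prime"` or `"three_prime"`.
#' @return an integer vector of length `width(window)`.
#' @export
end_coverage <- function(read_ends, window,
                         which_end = c("five_prime", "three_prime")) {
  which_end <- match.arg(which_end)
  w <- width(window)
  keep <- read_ends$strand == as.character(strand(window))
  pos <- read_ends[[which_end]][keep]
  off <- pos - start(window) + 1L
  off <- off[off >= 1L & off <= w]
  as.integer(tabulate(off, nbins = w))
}

#' Per-base full-length coverage
#'
#' Number of aligned intervals covering each base of the window. Intervals
#' are 1-based inclusive ([IRanges::IRanges] or a two-column matrix of
#' start/end pairs); for spliced reads pass aligned blocks so that gaps are
#' not covered.
#'
#' @param read_intervals an `IRanges` (or 2-column start/end matrix).
#' @param window a [genomic_window()].
#' @return an integer vector of length `width(window)`.
#' @export
full_length_coverage <- function(read_intervals, window) {
  if (is.matrix(read_intervals))
    read_intervals <- IRanges::IRanges(read_intervals[, 1], read_intervals[, 2])
  cov <- IRanges::coverage(read_intervals,
                           width = max(end(window), max(c(end(read_intervals), 0L))))
  as.integer(cov[start(window):end(window)])
}

#' Geometric-mean coverage from 5' and 3' end profiles
#'
#' Combines the two end profiles into a single per-base coverage summary:
#' `out[i] = sqrt((q5[i] + 1) * (q3[i] + 1)) - 1`. On equal inputs it is
#' the identity, and it is zero only where both end counts are zero.
#'
#' @param q5,q3 non-negative vectors of equal length.
#' @return a non-negative numeric vector.
#' @export
geometric_coverage <- function(q5, q3) {
  if (length(q5) != length(q3))
    stop("q5 and q3 must have the same length")
  if (any(q5 < 0) || any(q3 < 0)) stop("end counts must be non-negative")
  sqrt((q5 + 1) * (q3 + 1)) - 1
}

#' Build one coverage profile from a BAM
#'
#' Computes the per-base coverage of one sample on the window's strand,
#' under one of four summaries: the 5' end count, the 3' end count, the
#' full-length (aligned-block) coverage, or their geometric-mean combination
#' (the default; see [geometric_coverage()]).
#'
#' @inheritParams extract_read_ends
#' @param mode one of `"geometric"`, `"five_prime"`, `"three_prime"`,
#'   `"full_length"`.
#' @param sample_id,condition,replicate sample metadata carried along.
#' @return an object of class `coverage_profile`: a list with `window`,
#'   `sample_id`, `condition`, `replicate`, `mode` and the numeric `values`.
#' @export
coverage_profile <- function(bam_path, window,
                             mode = c("geometric", "five_prime",
                                      "three_prime", "full_length"),
                             library_protocol = c("fr", "rf", "unstranded"),
                             pairing_mode = c("fragment", "read"),
                             sample_id = basename(bam_path),
                             condition = NA_character_,
                             replicate = NA_integer_) {
  mode <- match.arg(mode)
  units <- .read_units(bam_path, window, library_protocol, pairing_mode)
  units <- units[as.character(strand(units)) == as.character(strand(window))]

  if (mode == "full_length") {
    blocks <- unlist(mcols(units)$blocks, use.names = FALSE)
    vals <- full_length_coverage(IRanges::ranges(blocks), window)
  } else {
    st <- as.character(strand(units))
    fwd <- st == "+"
    ends <- data.frame(
      five_prime  = ifelse(fwd, start(units), end(units)),
      three_prime = ifelse(fwd, end(units), start(units)),
      strand = st
    )
    vals <- switch(mode,
      five_prime  = end_coverage(ends, window, "five_prime"),
      three_prime = end_coverage(ends, window, "three_prime"),
      geometric   = geometric_coverage(
        end_coverage(ends, window, "five_prime"),
        end_coverage(ends, window, "three_prime")
      )
    )
  }
  structure(
    list(window = window, sample_id = sample_id, condition = condition,
         replicate = replicate, mode = mode, values = vals),
    class = "coverage_profile"
  )
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("coverage_profile:", x$sample_id,
      sprintf("(%s, replicate %s)", x$condition, x$replicate), "\n")
  cat("  window:", as.character(x$window), " mode:", x$mode, "\n")
  cat("  mean coverage:", round(mean(x$values), 3), "\n")
  invisible(x)
}

#' Per-base log2 fold-change profile between two conditions
#'
#' For every base, the replicate-averaged `log2(coverage + 1)` of condition
#' 1 minus that of condition 2 (the reference/denominator condition). This
#' differential transcription profile is the signal that is segmented.
#'
#' @param cond1_profiles,cond2_profiles lists of [coverage_profile()]
#'   objects sharing window, strand and mode, one list per condition.
#' @return an object of class `diff_profile`: list with `window`, `values`
#'   (the per-base log2-FC), `n_reps_cond1`, `n_reps_cond2`,
#'   `reference_condition`.
#' @export
log2_fc_profile <- function(cond1_profiles, cond2_profiles) {
  all_p <- c(cond1_profiles, cond2_profiles)
  if (length(cond1_profiles) == 0L || length(cond2_profiles) == 0L)
    stop("need at least one profile per condition")
  w0 <- all_p[[1]]$window
  for (p in all_p) {
    if (!identical(as.character(p$window), as.character(w0)))
      stop("all profiles must share the same window and strand")
    if (!identical(p$mode, all_p[[1]]$mode))
      stop("all profiles must share the same coverage mode")
  }
  l2 <- function(ps) {
    m <- vapply(ps, function(p) log2(p$values + 1), numeric(width(w0)))
    rowMeans(as.matrix(m))
  }
  structure(
    list(window = w0,
         values = l2(cond1_profiles) - l2(cond2_profiles),
         n_reps_cond1 = length(cond1_profiles),
         n_reps_cond2 = length(cond2_profiles),
         reference_condition = cond2_profiles[[1]]$condition),
    class = "diff_profile"
  )
}

#' @export
print.diff_profile <- function(x, ...) {
  cat("diff_profile over", as.character(x$window), "\n")
  cat(sprintf("  %d vs %d replicates (reference: %s)\n",
              x$n_reps_cond1, x$n_reps_cond2, x$reference_condition))
  cat(sprintf("  log2-FC range: [%.3f, %.3f]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Normalization offset between the two conditions
#'
#' The non-normalized and normalized per-base log2-FC differ only by the
#' constant `rho = mean(log2 s_1r) - mean(log2 s_2r)` computed from the
#' sample size factors. Because the segmentation is shift invariant, `rho`
#' never enters the changepoint search; it is reported for interpretation
#' only.
#'
#' @param size_factors_cond1,size_factors_cond2 positive size factors.
#' @return a single number.
#' @export
normalization_offset <- function(size_factors_cond1, size_factors_cond2) {
  if (any(size_factors_cond1 <= 0) || any(size_factors_cond2 <= 0))
    stop("size factors must be positive")
  mean(log2(size_factors_cond1)) - mean(log2(size_factors_cond2))
}
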