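## Assigning mapped reads to segments: the segments x samples count matrix.

#' Count reads per segment and sample
#'
#' Builds the segments x samples matrix of raw read counts. An alignment
#' unit (read or properly-paired fragment, mirroring the profile module) is
#' counted on a segment when it overlaps it by at least one base on the
#' segment's strand. By default a unit overlapping several segments
#' contributes one count to each of them; with `multi_overlap = FALSE` it is
#' assigned only to the segment with the largest overlap (earliest segment
#' on ties).
#'
#' @param bam_paths character vector of BAM paths, one per sample.
#' @param samples data.frame with columns `sample`, `condition`,
#'   `replicate`, parallel to `bam_paths`.
#' @param segments a stranded `GRanges` of segments.
#' @param library_protocol,pairing_mode see [extract_read_ends()].
#' @param multi_overlap logical; see Description.
#' @return an object of class `count_matrix`: list with `segments`,
#'   `samples` and the integer `counts` matrix.
#' @export
count_reads_in_segments <- function(bam_paths, samples, segments,
                                    library_protocol = c("fr", "rf", "unstranded"),
                                    pairing_mode = c("fragment", "read"),
                                    multi_overlap = TRUE) {
  stopifnot(length(bam_paths) == nrow(samples))
  window_all <- range(GenomicRanges::granges(segments), ignore.strand = TRUE)
  counts <- matrix(0L, nrow = length(segments), ncol = length(bam_paths))
  for (s in seq_along(bam_paths)) {
    units <- .read_units(bam_paths[s], window_all, library_protocol, pairing_mode)
    mcols(units) <- NULL
    if (multi_overlap) {
      counts[, s] <- GenomicRanges::countOverlaps(segments, units,
                                                  ignore.strand = FALSE)
    } else {
      hits <- GenomicRanges::findOverlaps(units, segments, ignore.strand = FALSE)
      if (length(hits)) {
        ov <- width(IRanges::pintersect(units[queryHits(hits)],
                                        segments[subjectHits(hits)]))
        ## per unit keep the largest overlap, earliest segment on ties
        o <- order(queryHits(hits), -ov, subjectHits(hits))
        keep <- !duplicated(queryHits(hits)[o])
        tab <- tabulate(subjectHits(hits)[o][keep], nbins = length(segments))
        counts[, s] <- tab
      }
    }
  }
  colnames(counts) <- samples$sample
  structure(
    list(segments = segments, samples = samples, counts = counts),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d segment(s) x %d sample(s)\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  library sizes:", paste(colSums(x$counts), collapse = ", "), "\n")
  invisible(x)
}

#' Write a count matrix as TSV
#'
#' Rows are keyed `chrom:start-end:strand`; columns are samples.
#'
#' @param x a `count_matrix`.
#' @param path output file.
#' @export
write_count_matrix <- function(x, path) {
  key <- sprintf("%s:%d-%d:%s", seqnames(x$segments), start(x$segments),
                 end(x$segments), strand(x$segments))
  df <- data.frame(segment = key, x$counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
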