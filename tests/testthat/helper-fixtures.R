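# Fixtures built in code: tiny hand-written SAM -> BAM alignments, count
# matrices, and an exhaustive segmentation oracle.

# Write a BAM from explicit alignments. `reads` is a data.frame with columns
# pos (1-based leftmost), flag, cigar, and optionally rnext/pnext/tlen for
# paired reads and qname.
make_bam <- function(reads, chrom = "chrT", ref_len = 10000L,
                     path = tempfile(fileext = ".bam")) {
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom, ref_len))
  if (nrow(reads)) {
    nr <- nrow(reads)
    qname <- if ("qname" %in% names(reads)) reads$qname
             else sprintf("q%03d", seq_len(nr))
    rnext <- rep_len(if ("rnext" %in% names(reads)) reads$rnext else "*", nr)
    pnext <- rep_len(if ("pnext" %in% names(reads)) reads$pnext else 0L, nr)
    tlen <- rep_len(if ("tlen" %in% names(reads)) reads$tlen else 0L, nr)
    cigar <- rep_len(reads$cigar, nr)
    flag <- rep_len(reads$flag, nr)
    o <- order(reads$pos)
    body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t%s\t%d\t%d\t*\t*",
                    qname[o], flag[o], chrom, reads$pos[o],
                    cigar[o], rnext[o], pnext[o], tlen[o])
    writeLines(c(hdr, body), sam)
  } else {
    writeLines(hdr, sam)
  }
  bam <- Rsamtools::asBam(sam, destination = sub("\\.bam$", "", path),
                          overwrite = TRUE, indexDestination = TRUE)
  unlink(sam)
  bam
}

# count_matrix without going through BAMs
make_count_matrix <- function(counts, conditions, segments = NULL) {
  counts <- as.matrix(counts)
  ns <- ncol(counts)
  samples <- data.frame(sample = paste0("s", seq_len(ns)),
                        condition = conditions,
                        replicate = ave(seq_len(ns), conditions, FUN = seq_along))
  colnames(counts) <- samples$sample
  structure(list(segments = segments, samples = samples, counts = counts),
            class = "count_matrix")
}

# Exhaustive segmentation oracle: minimizes SSE + D * beta over all 2^(n-1)
# segmentations; prefers fewer changepoints, then lexicographically earliest.
enumerate_best_segmentation <- function(y, beta) {
  n <- length(y)
  all_cps <- lapply(0:(2^(n - 1) - 1), function(mask) {
    if (n == 1L) integer(0) else which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
  })
  costs <- vapply(all_cps, function(cps) {
    bounds <- c(0L, cps, n)
    cost <- length(cps) * beta
    for (j in seq_len(length(bounds) - 1)) {
      seg <- y[(bounds[j] + 1):bounds[j + 1]]
      cost <- cost + sum((seg - mean(seg))^2)
    }
    cost
  }, numeric(1))
  ties <- which(costs <= min(costs) + 1e-12)
  nd <- vapply(all_cps[ties], length, integer(1))
  ties <- ties[nd == min(nd)]            # parsimony first
  if (length(ties) > 1L) {               # then earliest changepoints
    keys <- vapply(all_cps[ties], function(cps)
      paste(sprintf("%04d", cps), collapse = ","), character(1))
    ties <- ties[order(keys)][1]
  }
  list(changepoints = as.integer(all_cps[[ties[1]]]), cost = costs[ties[1]])
}

# standard small planted-DER scenario used across pipeline tests
small_scenario <- function(seed = 1L, window_end = 4100L, baseline = 20) {
  simulation_scenario(
    genomic_window("chrS", 101, window_end),
    baseline = baseline,
    planted_ders = data.frame(start = 1101, end = 2100, strand = "+",
                              effect = 2),
    dispersion = 0.05, reps_per_condition = c(2L, 2L),
    read_length = 50L, seed = seed
  )
}
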