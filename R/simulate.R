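## Synthetic stranded RNA-seq with planted DERs: per-base negative-binomial
## counts with piecewise-constant log2-FC structure, realized as small
## sorted/indexed BAMs so the whole pipeline is testable offline.

#' Define a simulation scenario
#'
#' Describes per-base 5'-end read intensities on both strands of a window, a
#' set of planted DERs (intervals with a log2 fold-change effect applied to
#' condition 1), negative-binomial replicate noise and per-sample depth
#' factors. All downstream draws are deterministic given `seed`.
#'
#' @param window a stranded or unstranded [genomic_window()]; both strands
#'   are simulated.
#' @param baseline single positive number or per-base vector of mean 5'-end
#'   counts (recycled to the window width; used for both strands unless a
#'   list `list(plus =, minus =)` is given).
#' @param planted_ders data.frame with columns `start`, `end` (1-based
#'   inclusive, inside the window), `strand`, `effect` (log2-FC of condition
#'   1 over condition 2).
#' @param dispersion NB dispersion (variance `mu + alpha mu^2`); 0 gives
#'   Poisson noise.
#' @param reps_per_condition integer vector `c(R1, R2)`.
#' @param depth_factors per-sample depth multipliers, length `R1 + R2`
#'   (condition 1 replicates first); default all 1.
#' @param read_length synthetic read length (bases).
#' @param seed integer seed making the scenario reproducible.
#' @return an object of class `sim_scenario`.
#' @export
simulation_scenario <- function(window, baseline = 5,
                                planted_ders = NULL,
                                dispersion = 0.05,
                                reps_per_condition = c(2L, 2L),
                                depth_factors = NULL,
                                read_length = 50L,
                                seed = 1L) {
  w <- width(window)
  bl <- if (is.list(baseline)) {
    lapply(baseline, function(b) rep_len(b, w))
  } else {
    list(plus = rep_len(baseline, w), minus = rep_len(baseline, w))
  }
  if (any(unlist(bl) <= 0)) stop("baseline intensities must be positive")
  if (is.null(planted_ders))
    planted_ders <- data.frame(start = integer(0), end = integer(0),
                               strand = character(0), effect = numeric(0))
  if (nrow(planted_ders)) {
    if (any(planted_ders$start < start(window)) ||
        any(planted_ders$end > end(window)))
      stop("planted DERs must lie within the window")
    if (any(!is.finite(planted_ders$effect))) stop("effects must be finite")
  }
  nrep <- sum(reps_per_condition)
  if (is.null(depth_factors)) depth_factors <- rep(1, nrep)
  if (length(depth_factors) != nrep || any(depth_factors <= 0))
    stop("depth_factors must be ", nrep, " positive numbers")
  structure(
    list(window = window, baseline = bl, planted_ders = planted_ders,
         dispersion = dispersion, reps_per_condition = as.integer(reps_per_condition),
         depth_factors = depth_factors, read_length = as.integer(read_length),
         seed = as.integer(seed)),
    class = "sim_scenario"
  )
}

## per-base effect vector (log2) for one strand
.effect_vector <- function(scenario, strand_sym) {
  w <- width(scenario$window)
  eff <- numeric(w)
  pd <- scenario$planted_ders
  if (nrow(pd)) {
    pd <- pd[pd$strand == strand_sym, , drop = FALSE]
    for (k in seq_len(nrow(pd))) {
      i1 <- pd$start[k] - start(scenario$window) + 1L
      i2 <- pd$end[k] - start(scenario$window) + 1L
      eff[i1:i2] <- eff[i1:i2] + pd$effect[k]
    }
  }
  eff
}

#' Labels of the planted DERs
#'
#' @param scenario a `sim_scenario`.
#' @return a stranded `GRanges`, one range per planted DER.
#' @export
planted_labels <- function(scenario) {
  pd <- scenario$planted_ders
  if (!nrow(pd)) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(as.character(seqnames(scenario$window)),
                         IRanges::IRanges(pd$start, pd$end),
                         strand = pd$strand)
}

#' Simulate per-base 5'-end counts for one condition
#'
#' Per base, the replicate mean is `depth * baseline * 2^effect` (the effect
#' applies to condition 1 only); counts are drawn NB with the scenario
#' dispersion, or Poisson when the dispersion is 0.
#'
#' @param scenario a [simulation_scenario()].
#' @param condition 1 or 2.
#' @return a list with one element per replicate, each a list with integer
#'   vectors `plus` and `minus` of per-base 5'-end counts.
#' @export
simulate_counts <- function(scenario, condition) {
  stopifnot(condition %in% 1:2)
  R <- scenario$reps_per_condition
  reps <- seq_len(R[condition])
  depth_off <- if (condition == 1L) 0L else R[1]
  lapply(reps, function(r) {
    set.seed(scenario$seed * 1000L + condition * 100L + r)
    depth <- scenario$depth_factors[depth_off + r]
    out <- lapply(c(plus = "+", minus = "-"), function(s) {
      bl <- if (s == "+") scenario$baseline$plus else scenario$baseline$minus
      eff <- .effect_vector(scenario, s)
      mu <- depth * bl * 2^(eff * (condition == 1L))
      if (scenario$dispersion == 0) {
        rpois(length(mu), mu)
      } else {
        rnbinom(length(mu), size = 1 / scenario$dispersion, mu = mu)
      }
    })
    names(out) <- c("plus", "minus")
    out
  })
}

#' Write per-base counts as a synthetic sorted, indexed BAM
#'
#' Emits single-end reads of the scenario's read length, placed so that the
#' 5'-end coverage on each strand equals the given count vectors exactly
#' (the 3'-end profile is the 5'-end profile shifted by `read_length - 1`,
#' so the geometric coverage mode is exercised non-trivially). Sequences are
#' omitted (`*`), keeping files small.
#'
#' @param count_vectors list with integer vectors `plus` and `minus` (one
#'   replicate's output of [simulate_counts()]).
#' @param scenario the [simulation_scenario()].
#' @param out_path output BAM path (an index is written alongside).
#' @return the BAM path, invisibly.
#' @export
write_synthetic_bam <- function(count_vectors, scenario, out_path) {
  w <- scenario$window
  L <- scenario$read_length
  chrom <- as.character(seqnames(w))
  ref_len <- end(w) + L + 10L
  if (start(w) - L + 1L < 1L && any(count_vectors$minus > 0))
    stop("minus-strand reads would start before the reference; ",
         "use a window starting after position read_length")

  pos_plus <- rep(start(w) + seq_along(count_vectors$plus) - 1L,
                  count_vectors$plus)
  ## minus-strand 5' end at p -> alignment [p - L + 1, p]
  p5_minus <- rep(start(w) + seq_along(count_vectors$minus) - 1L,
                  count_vectors$minus)
  pos_minus <- p5_minus - L + 1L

  n_plus <- length(pos_plus); n_minus <- length(pos_minus)
  pos <- c(pos_plus, pos_minus)
  flag <- c(rep(0L, n_plus), rep(16L, n_minus))
  o <- order(pos)
  pos <- pos[o]; flag <- flag[o]

  sam <- tempfile(fileext = ".sam")
  con <- file(sam, open = "wt")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom, ref_len)), con)
  if (length(pos)) {
    writeLines(sprintf("r%06d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                       seq_along(pos), flag, chrom, pos, L), con)
  }
  close(con)
  dest <- sub("\\.bam$", "", out_path)
  bam <- Rsamtools::asBam(sam, destination = dest, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  invisible(bam)
}

#' Write the synthetic reference FASTA for a scenario
#'
#' @param scenario a [simulation_scenario()].
#' @param out_path FASTA path.
#' @return the path, invisibly.
#' @export
write_synthetic_reference <- function(scenario, out_path) {
  w <- scenario$window
  ref_len <- end(w) + scenario$read_length + 10L
  writeLines(c(paste0(">", seqnames(w)),
               paste(rep("A", ref_len), collapse = "")), out_path)
  invisible(out_path)
}

#' Simulate a complete two-condition experiment as BAM files
#'
#' Convenience wrapper: draws counts for both conditions and writes one BAM
#' per replicate under `out_dir`, returning a sample sheet ready for
#' [derseg()].
#'
#' @param scenario a [simulation_scenario()].
#' @param out_dir output directory (created if needed).
#' @param conditions labels of conditions 1 and 2.
#' @return a data.frame sample sheet (`sample`, `condition`, `replicate`,
#'   `bam`).
#' @export
simulate_experiment <- function(scenario, out_dir,
                                conditions = c("mutant", "control")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (cond in 1:2) {
    counts <- simulate_counts(scenario, cond)
    for (r in seq_along(counts)) {
      id <- sprintf("%s_rep%d", conditions[cond], r)
      bam <- file.path(out_dir, paste0(id, ".bam"))
      write_synthetic_bam(counts[[r]], scenario, bam)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = id, condition = conditions[cond], replicate = r, bam = bam
      )
    }
  }
  do.call(rbind, rows)
}

#' Serialize a scenario as a flat key-value config file
#'
#' One `key = value` line per field; vectors are comma-separated and planted
#' DERs are `start:end:strand:effect` records separated by semicolons.
#' [read_scenario()] restores the scenario exactly.
#'
#' @param scenario a [simulation_scenario()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  w <- scenario$window
  pd <- scenario$planted_ders
  lines <- c(
    sprintf("chrom = %s", seqnames(w)),
    sprintf("start = %d", start(w)),
    sprintf("end = %d", end(w)),
    sprintf("baseline_plus = %s",
            paste(format(scenario$baseline$plus, trim = TRUE), collapse = ",")),
    sprintf("baseline_minus = %s",
            paste(format(scenario$baseline$minus, trim = TRUE), collapse = ",")),
    sprintf("planted_ders = %s",
            if (nrow(pd)) paste(sprintf("%d:%d:%s:%g", pd$start, pd$end,
                                        pd$strand, pd$effect),
                                collapse = ";") else ""),
    sprintf("dispersion = %g", scenario$dispersion),
    sprintf("reps_per_condition = %d,%d", scenario$reps_per_condition[1],
            scenario$reps_per_condition[2]),
    sprintf("depth_factors = %s",
            paste(format(scenario$depth_factors, trim = TRUE), collapse = ",")),
    sprintf("read_length = %d", scenario$read_length),
    sprintf("seed = %d", scenario$seed)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Restore a scenario from a flat key-value config file
#'
#' @param path file written by [write_scenario()].
#' @return a [simulation_scenario()].
#' @export
read_scenario <- function(path) {
  kv <- read.dcf(textConnection(gsub(" = ", ": ", readLines(path))))[1, ]
  num_vec <- function(x) as.numeric(strsplit(x, ",")[[1]])
  pd <- if (nzchar(kv[["planted_ders"]])) {
    recs <- strsplit(strsplit(kv[["planted_ders"]], ";")[[1]], ":")
    data.frame(start = as.integer(sapply(recs, `[`, 1)),
               end = as.integer(sapply(recs, `[`, 2)),
               strand = sapply(recs, `[`, 3),
               effect = as.numeric(sapply(recs, `[`, 4)))
  } else NULL
  simulation_scenario(
    genomic_window(kv[["chrom"]], as.integer(kv[["start"]]),
                   as.integer(kv[["end"]])),
    baseline = list(plus = num_vec(kv[["baseline_plus"]]),
                    minus = num_vec(kv[["baseline_minus"]])),
    planted_ders = pd,
    dispersion = as.numeric(kv[["dispersion"]]),
    reps_per_condition = as.integer(num_vec(kv[["reps_per_condition"]])),
    depth_factors = num_vec(kv[["depth_factors"]]),
    read_length = as.integer(kv[["read_length"]]),
    seed = as.integer(kv[["seed"]])
  )
}

#' Enumerate blank (same-condition) two-group designs
#'
#' Splits replicates of a single condition into two disjoint groups of equal
#' size; every DER found between such groups is a false positive. Designs
#' are unordered pairs of disjoint groups, enumerated exhaustively and
#' optionally subsampled.
#'
#' @param replicate_ids vector of replicate identifiers.
#' @param group_size size of each group (`2 * group_size <=` number of
#'   replicates).
#' @param seed seed used when subsampling.
#' @param max_designs maximum number of designs to return (`Inf` = all).
#' @return a list of `list(groupA =, groupB =)` pairs.
#' @export
blank_resample <- function(replicate_ids, group_size, seed = 1L,
                           max_designs = Inf) {
  n <- length(replicate_ids)
  if (2L * group_size > n)
    stop("group_size too large: need 2 * group_size <= number of replicates")
  if (group_size < 1L) stop("group_size must be >= 1")
  idxA <- combn(n, group_size, simplify = FALSE)
  designs <- list()
  for (A in idxA) {
    rest <- setdiff(seq_len(n), A)
    for (B in combn(rest, group_size, simplify = FALSE)) {
      ## each unordered pair once: the overall smallest index sits in A
      if (min(A) < min(B))
        designs[[length(designs) + 1L]] <-
          list(groupA = replicate_ids[A], groupB = replicate_ids[B])
    }
  }
  if (length(designs) > max_designs) {
    set.seed(seed)
    designs <- designs[sort(sample.int(length(designs), max_designs))]
  }
  designs
}
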