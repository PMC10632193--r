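#' Fit the differential-region model over a genomic window
#'
#' Runs the whole annotation-free DER pipeline on a two-condition stranded
#' RNA-seq experiment: per-strand coverage profiles and per-base log2
#' fold-change ([log2_fc_profile()]), exact FPOP segmentation of each
#' strand's profile ([segment_profile()]), per-segment read counting
#' ([count_reads_in_segments()]), negative-binomial Wald testing with BH
#' adjustment ([dea()]) and DER calling under a Simes post-hoc FDP bound
#' ([call_ders()]); segments from both strands form one multiplicity
#' family. Optionally labels DERs by their nearest annotation
#' ([annotate_nearest()]).
#'
#' @param sample_sheet TSV path or data.frame with columns `sample`,
#'   `condition`, `replicate`, `bam` (see [read_sample_sheet()]).
#' @param region `"chrom:start-end"` (1-based inclusive) or a length-1
#'   `GRanges`.
#' @param reference_condition the condition used as denominator of the
#'   fold change.
#' @param mode coverage summary; `"geometric"` (default), `"five_prime"`,
#'   `"three_prime"` or `"full_length"`.
#' @param library_protocol `"fr"`, `"rf"` or `"unstranded"`.
#' @param pairing_mode `"fragment"` (default) or `"read"`.
#' @param lam segmentation penalty multiplier (default 2).
#' @param fc_threshold DER fold-change threshold (default 1.5).
#' @param fdp_target maximum tolerated false discovery proportion (default
#'   0.05).
#' @param alpha level of the Simes joint error rate control (default 0.05).
#' @param annotation optional GFF3/GTF path or annotated `GRanges` used to
#'   label DERs.
#' @param sf_fallback passed to [median_of_ratios_size_factors()].
#' @param keep_profiles keep the per-base tracks in the returned object
#'   (needed by [write_tracks()] and [plot.derseg()]).
#' @param verbose log per-stage progress to standard error.
#' @return an object of class `derseg`; see [print.derseg()],
#'   [summary.derseg()], [coef.derseg()], [fitted.derseg()],
#'   [residuals.derseg()], [plot.derseg()], and the accessors [ders()] and
#'   [der_segments()].
#' @examples
#' \dontrun{
#' scen <- simulation_scenario(genomic_window("chrS", 101, 4100),
#'   planted_ders = data.frame(start = 1001, end = 2000,
#'                             strand = "+", effect = 2))
#' ss <- simulate_experiment(scen, tempfile("sim"))
#' fit <- derseg(ss, "chrS:101-4100", reference_condition = "control")
#' summary(fit)
#' }
#' @export
derseg <- function(sample_sheet, region, reference_condition,
                   mode = c("geometric", "five_prime", "three_prime",
                            "full_length"),
                   library_protocol = c("fr", "rf", "unstranded"),
                   pairing_mode = c("fragment", "read"),
                   lam = 2, fc_threshold = 1.5, fdp_target = 0.05,
                   alpha = 0.05, annotation = NULL, sf_fallback = FALSE,
                   keep_profiles = TRUE, verbose = FALSE) {
  mode <- match.arg(mode)
  library_protocol <- match.arg(library_protocol)
  pairing_mode <- match.arg(pairing_mode)
  say <- function(...) if (verbose) message("[derseg] ", ...)

  ss <- read_sample_sheet(sample_sheet)
  conds <- unique(ss$condition)
  if (!reference_condition %in% conds)
    stop("reference_condition '", reference_condition,
         "' not present in the sample sheet")
  cond1 <- setdiff(conds, reference_condition)
  win <- parse_region(region)

  ## -- step 1: profiles and per-base log2-FC, per strand ------------------
  strands <- c("+", "-")
  profiles <- list()
  for (s in strands) {
    w <- win
    strand(w) <- s
    prof <- lapply(seq_len(nrow(ss)), function(i) {
      tryCatch(
        coverage_profile(ss$bam[i], w, mode = mode,
                         library_protocol = library_protocol,
                         pairing_mode = pairing_mode,
                         sample_id = ss$sample[i],
                         condition = ss$condition[i],
                         replicate = ss$replicate[i]),
        error = function(e) stop("profiles stage failed for sample '",
                                 ss$sample[i], "': ", conditionMessage(e),
                                 call. = FALSE)
      )
    })
    p1 <- prof[ss$condition == cond1]
    p2 <- prof[ss$condition == reference_condition]
    dp <- log2_fc_profile(p1, p2)
    mean_l2 <- function(ps) {
      rowMeans(vapply(ps, function(p) log2(p$values + 1),
                      numeric(width(w))))
    }
    profiles[[s]] <- list(
      window = w, log2_fc = dp$values, diff_profile = dp,
      mean_log2_cov = setNames(list(mean_l2(p1), mean_l2(p2)),
                               c(cond1, reference_condition))
    )
    say("profiles strand ", s, ": ", length(prof), " samples, ",
        width(w), " bases")
  }

  ## -- step 2: segmentation per strand ------------------------------------
  seg_fits <- list()
  seg_list <- list()
  for (s in strands) {
    sp <- withCallingHandlers(
      segment_profile(profiles[[s]]$diff_profile, lam = lam),
      warning = function(wn) {
        say("segmentation strand ", s, ": ", conditionMessage(wn))
        invokeRestart("muffleWarning")
      }
    )
    seg_fits[[s]] <- sp
    seg_list[[s]] <- sp$segments
    say("segmentation strand ", s, ": ", length(sp$segments), " segment(s)")
  }
  segments <- c(seg_list[["+"]], seg_list[["-"]])

  ## -- step 2B: counting ---------------------------------------------------
  cm <- tryCatch(
    count_reads_in_segments(ss$bam, ss, segments,
                            library_protocol = library_protocol,
                            pairing_mode = pairing_mode),
    error = function(e) stop("counting stage failed: ", conditionMessage(e),
                             call. = FALSE)
  )
  say("counting: ", nrow(cm$counts), " segments x ", ncol(cm$counts),
      " samples")

  ## -- step 3: DEA + DER call ----------------------------------------------
  dt <- tryCatch(
    dea(cm, condition_of_interest = cond1,
        reference_condition = reference_condition, sf_fallback = sf_fallback),
    error = function(e) stop("dea stage failed: ", conditionMessage(e),
                             call. = FALSE)
  )
  call <- call_ders(dt, fc_threshold = fc_threshold, fdp_target = fdp_target,
                    alpha = alpha, start_order = start(segments))
  say("dea: ", attr(dt, "m_tested"), " tested segment(s), ",
      sum(call$selected), " DER(s)")

  results <- data.frame(
    chrom = as.character(seqnames(segments)),
    start = start(segments), end = end(segments),
    strand = as.character(strand(segments)),
    width = width(segments),
    mean_log2fc = mcols(segments)$mean_log2fc,
    baseMean = dt$baseMean, log2FoldChange = dt$log2FoldChange,
    lfcSE = dt$lfcSE, pvalue = dt$pvalue, padj = dt$padj,
    der = call$selected, fdp_bound = call$fdp_bound
  )

  ## -- step 4A: annotation --------------------------------------------------
  annotation_labels <- NULL
  if (!is.null(annotation)) {
    anno <- if (is.character(annotation)) read_annotation(annotation) else annotation
    der_gr <- segments[call$selected]
    if (length(der_gr)) {
      labs <- annotate_nearest(der_gr, anno)
      labs$der_id <- which(call$selected)[labs$der_id]
      annotation_labels <- labs
      first <- labs[!duplicated(labs$der_id), ]
      results$label <- NA_character_
      results$nearest_feature <- NA_character_
      results$label[first$der_id] <- first$label
      results$nearest_feature[first$der_id] <- first$feature_id
    }
    say("annotation: labeled ", length(der_gr), " DER(s)")
  }

  structure(
    list(window = win, samples = ss,
         condition_of_interest = cond1,
         reference_condition = reference_condition,
         profiles = if (keep_profiles) profiles else NULL,
         seg_fits = seg_fits, segments = segments,
         count_matrix = cm, dea_table = dt, der_call = call,
         results = results, annotation_labels = annotation_labels,
         rho = attr(dt, "rho"),
         config = list(mode = mode, library_protocol = library_protocol,
                       pairing_mode = pairing_mode, lam = lam,
                       fc_threshold = fc_threshold, fdp_target = fdp_target,
                       alpha = alpha)),
    class = "derseg"
  )
}

#' Extract called DERs
#'
#' @param fit a [derseg()] object.
#' @return a stranded `GRanges` of the DERs with their statistics.
#' @export
ders <- function(fit) {
  stopifnot(inherits(fit, "derseg"))
  gr <- fit$segments[fit$der_call$selected]
  idx <- which(fit$der_call$selected)
  mcols(gr)$log2FoldChange <- fit$results$log2FoldChange[idx]
  mcols(gr)$padj <- fit$results$padj[idx]
  gr
}

#' Extract all segments
#'
#' @param fit a [derseg()] object.
#' @return the segmentation as a stranded `GRanges`.
#' @export
der_segments <- function(fit) {
  stopifnot(inherits(fit, "derseg"))
  fit$segments
}

#' @export
print.derseg <- function(x, ...) {
  cat("derseg fit over", as.character(x$window), "\n")
  cat(sprintf("  %s vs %s (reference), %d samples, mode '%s'\n",
              x$condition_of_interest, x$reference_condition,
              nrow(x$samples), x$config$mode))
  cat(sprintf("  %d segment(s), %d DER(s); FDP bound %.3f (target %.2f)\n",
              length(x$segments), sum(x$der_call$selected),
              x$der_call$fdp_bound, x$config$fdp_target))
  invisible(x)
}

#' @method summary derseg
#' @export
summary.derseg <- function(object, ...) {
  res <- object$results
  der <- res$der %in% TRUE
  out <- list(
    window = as.character(object$window),
    conditions = c(object$condition_of_interest, object$reference_condition),
    n_segments = nrow(res),
    n_tested = attr(object$dea_table, "m_tested"),
    n_ders = sum(der),
    n_up = sum(der & res$log2FoldChange > 0),
    n_down = sum(der & res$log2FoldChange < 0),
    fdp_bound = object$der_call$fdp_bound,
    rho = object$rho,
    size_factors = attr(object$dea_table, "size_factors"),
    median_der_width = if (any(der)) median(res$width[der]) else NA_real_,
    median_not_der_width = if (any(!der)) median(res$width[!der]) else NA_real_,
    config = object$config
  )
  class(out) <- "summary.derseg"
  out
}

#' @export
print.summary.derseg <- function(x, ...) {
  cat("Differential-region analysis over", x$window, "\n")
  cat(sprintf("  conditions: %s vs %s (reference)\n",
              x$conditions[1], x$conditions[2]))
  cat(sprintf("  segments: %d (%d tested)\n", x$n_segments, x$n_tested))
  cat(sprintf("  DERs: %d (%d up, %d down), FDP bound %.3f\n",
              x$n_ders, x$n_up, x$n_down, x$fdp_bound))
  cat(sprintf("  median width: DER %s, not-DER %s\n",
              format(x$median_der_width), format(x$median_not_der_width)))
  cat(sprintf("  normalization offset rho: %.4f\n", x$rho))
  cat("  size factors:",
      paste(sprintf("%s=%.3f", names(x$size_factors), x$size_factors),
            collapse = ", "), "\n")
  invisible(x)
}

#' Per-segment coefficients
#'
#' @param object a [derseg()] object.
#' @param ... unused.
#' @return matrix with one row per segment: the segment-mean per-base
#'   log2-FC (the segmentation-model mean) and the fitted NB log2 fold
#'   change.
#' @export
coef.derseg <- function(object, ...) {
  cbind(mean_log2fc = object$results$mean_log2fc,
        log2FoldChange = object$results$log2FoldChange)
}

#' Fitted per-base values
#'
#' @param object a [derseg()] object fitted with `keep_profiles = TRUE`.
#' @param ... unused.
#' @return list per strand of the piecewise-constant fitted mean of the
#'   per-base log2-FC.
#' @export
fitted.derseg <- function(object, ...) {
  if (is.null(object$profiles))
    stop("profiles were not kept; re-fit with keep_profiles = TRUE")
  lapply(names(object$seg_fits), function(s) {
    fit <- object$seg_fits[[s]]$fit
    rep(fit$means, diff(c(0L, fit$changepoints, fit$n)))
  }) |> setNames(names(object$seg_fits))
}

#' Per-base residuals
#'
#' @inheritParams fitted.derseg
#' @return list per strand of `log2-FC - fitted segment mean`.
#' @export
residuals.derseg <- function(object, ...) {
  fv <- fitted(object)
  lapply(setNames(names(fv), names(fv)), function(s) {
    object$profiles[[s]]$log2_fc - fv[[s]]
  })
}

#' Plot the per-base log2-FC with the fitted segmentation
#'
#' Base-graphics view of one strand: the per-base log2 fold-change, the
#' piecewise-constant segment means, changepoints, and DERs shaded.
#'
#' @param x a [derseg()] object fitted with `keep_profiles = TRUE`.
#' @param strand strand to show (`"+"` or `"-"`).
#' @param ... passed to [plot()].
#' @export
plot.derseg <- function(x, strand = "+", ...) {
  if (is.null(x$profiles))
    stop("profiles were not kept; re-fit with keep_profiles = TRUE")
  pr <- x$profiles[[strand]]
  pos <- start(pr$window):end(pr$window)
  graphics::plot(pos, pr$log2_fc, type = "l", col = "grey60",
                 xlab = paste0("position on ", seqnames(x$window)),
                 ylab = "per-base log2 fold-change",
                 main = paste0("strand ", strand), ...)
  graphics::abline(h = 0, col = "grey80", lty = 2)
  res <- x$results[x$results$strand == strand, , drop = FALSE]
  for (i in seq_len(nrow(res))) {
    if (isTRUE(res$der[i]))
      graphics::rect(res$start[i], graphics::par("usr")[3], res$end[i],
                     graphics::par("usr")[4],
                     col = grDevices::adjustcolor(
                       if (res$log2FoldChange[i] > 0) "palegreen" else "plum",
                       alpha.f = 0.35),
                     border = NA)
    graphics::segments(res$start[i], res$mean_log2fc[i], res$end[i],
                       res$mean_log2fc[i], col = "blue", lwd = 2)
    if (i > 1) graphics::abline(v = res$start[i] - 0.5, col = "blue",
                                lty = 3)
  }
  invisible(x)
}
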