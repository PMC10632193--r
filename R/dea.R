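## Per-segment differential testing: median-of-ratios normalization,
## Cox-Reid-adjusted negative-binomial dispersion, two-group NB Wald test,
## Benjamini-Hochberg adjustment and a Simes-family post-hoc bound on the
## false discovery proportion of any segment selection.

#' Median-of-ratios size factors
#'
#' For each sample, the median across segments (restricted to segments with
#' positive counts in every sample) of the ratio of its count to the
#' per-segment geometric mean, rescaled so the size factors themselves have
#' geometric mean 1.
#'
#' Segments are genomic intervals of very different lengths, so an optional
#' weight vector (typically the segment widths) turns the median into a
#' weighted median: each base of the window then contributes equally, which
#' keeps the estimator robust when a few long or strongly differential
#' segments dominate the row count.
#'
#' @param counts a `count_matrix` or a numeric matrix (segments x samples).
#' @param fallback if `TRUE`, when no segment has all-positive counts the
#'   geometric means are computed over positive counts only (pseudo
#'   reference); if `FALSE` (default) this situation is an error.
#' @param weights optional non-negative per-segment weights for a weighted
#'   median (e.g. segment widths); `NULL` for the plain median.
#' @return a positive numeric vector, one size factor per sample.
#' @export
median_of_ratios_size_factors <- function(counts, fallback = FALSE,
                                          weights = NULL) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  m <- as.matrix(m)
  if (ncol(m) == 1L) return(setNames(1, colnames(m)))
  if (is.null(weights)) weights <- rep(1, nrow(m))
  if (length(weights) != nrow(m) || any(weights < 0))
    stop("'weights' must be one non-negative value per segment")
  wmedian <- function(x, w) {
    o <- order(x)
    x <- x[o]; w <- w[o]
    cw <- cumsum(w) / sum(w)
    k <- which(cw >= 0.5)[1]
    # split the tie exactly as the unweighted median does
    if (abs(cw[k] - 0.5) < 1e-12 && k < length(x)) (x[k] + x[k + 1]) / 2
    else x[k]
  }
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos)) {
    if (!fallback)
      stop("no segment has positive counts in every sample; ",
           "re-run with fallback = TRUE to use a positive-count pseudo-reference")
    lgm <- apply(m, 1L, function(r) {
      r <- r[r > 0]
      if (length(r)) mean(log(r)) else NA_real_
    })
    use <- which(!is.na(lgm))
    if (!length(use)) stop("counts are too sparse to estimate size factors")
    sf <- vapply(seq_len(ncol(m)), function(j) {
      r <- m[use, j]
      keep <- r > 0
      if (!any(keep)) return(NA_real_)
      exp(wmedian(log(r[keep]) - lgm[use][keep], weights[use][keep]))
    }, numeric(1))
    if (anyNA(sf)) stop("a sample has no positive counts; cannot normalize")
  } else {
    lgm <- rowMeans(log(m[all_pos, , drop = FALSE]))
    sf <- vapply(seq_len(ncol(m)), function(j) {
      exp(wmedian(log(m[all_pos, j]) - lgm, weights[all_pos]))
    }, numeric(1))
  }
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(m))
}

## Fit the two-group NB GLM with log link and offsets log(sf) for a fixed
## dispersion alpha: per-group Newton iterations on the group log-mean.
## Returns per-group q (expected count at size factor 1) and convergence
## info; q floored at `floor_mu` when a group is all zero (boundary fit).
.fit_two_group_nb <- function(k, sf, groups, alpha, floor_mu = 1e-8) {
  q <- numeric(2)
  boundary <- FALSE
  for (g in 1:2) {
    idx <- groups == g
    kg <- k[idx]; sg <- sf[idx]
    if (sum(kg) == 0) {
      q[g] <- floor_mu
      boundary <- TRUE
      next
    }
    ## initialize at the depth-normalized mean
    qg <- sum(kg) / sum(sg)
    for (it in 1:50) {
      mu <- sg * qg
      w <- mu / (1 + alpha * mu)
      score <- sum((kg - mu) / (1 + alpha * mu))
      info <- sum(w)
      step <- score / info
      qg_new <- qg * exp(step)
      if (!is.finite(qg_new) || qg_new <= 0) qg_new <- qg / 2
      if (abs(log(qg_new) - log(qg)) < 1e-10) { qg <- qg_new; break }
      qg <- qg_new
    }
    q[g] <- qg
  }
  list(q = q, boundary = boundary)
}

## Negative binomial log-likelihood (size = 1/alpha) with Poisson limit
.nb_loglik <- function(k, mu, alpha) {
  if (alpha < 1e-10) return(sum(stats::dpois(k, mu, log = TRUE)))
  sum(dnbinom(k, size = 1 / alpha, mu = mu, log = TRUE))
}

#' Per-segment NB dispersion by Cox-Reid-adjusted profile likelihood
#'
#' Maximizes over the dispersion `alpha` the profile likelihood of the
#' two-group negative-binomial model (variance `mu + alpha * mu^2`), with
#' the Cox-Reid adjustment `-0.5 * log det(X' W X)` that corrects for the
#' estimated group means. Clamped to `[0, alpha_max]`; returns `NA` for
#' untestable (all-zero) segments.
#'
#' @param counts_row integer counts for one segment (one per sample).
#' @param size_factors positive sample size factors.
#' @param groups a two-level factor or vector of condition labels.
#' @param alpha_max upper bound of the search interval.
#' @return the estimated dispersion (single number), `NA` if untestable.
#' @export
estimate_dispersion <- function(counts_row, size_factors, groups,
                                alpha_max = 20) {
  if (length(counts_row) < 2L) stop("need at least 2 samples")
  g <- as.integer(factor(groups))
  if (sum(counts_row) == 0) return(NA_real_)
  crll <- function(log_alpha) {
    alpha <- exp(log_alpha)
    fit <- .fit_two_group_nb(counts_row, size_factors, g, alpha)
    mu <- size_factors * fit$q[g]
    w <- mu / (1 + alpha * mu)
    ## X is the two-group indicator design: X'WX is diagonal
    cr <- 0.5 * sum(log(vapply(1:2, function(gg) {
      s <- sum(w[g == gg])
      max(s, 1e-300)
    }, numeric(1))))
    .nb_loglik(counts_row, mu, alpha) - cr
  }
  opt <- optimize(crll, interval = log(c(1e-8, alpha_max)), maximum = TRUE,
                  tol = 1e-6)
  ## under-dispersed data push the optimum to the lower bound: report 0
  alpha_hat <- exp(opt$maximum)
  if (opt$maximum < log(1e-8) + 1e-3 || alpha_hat < 1e-6) return(0)
  alpha_hat
}

#' Two-group negative-binomial Wald test
#'
#' Fits the two-group NB GLM with log link and `log(size factor)` offsets at
#' the given dispersion, and tests the group contrast (condition of
#' interest vs reference) with a Wald statistic on the log2 scale against
#' the standard normal.
#'
#' @param counts_row integer counts for one segment.
#' @param size_factors positive sample size factors.
#' @param dispersion NB dispersion `alpha >= 0` for this segment.
#' @param groups two-level factor; the **second** level is the reference
#'   (denominator).
#' @return a list with `log2fc`, `se`, `p` and `boundary` (`TRUE` when one
#'   group had zero counts so the fit sits at the parameter floor).
#' @export
nb_wald_test <- function(counts_row, size_factors, dispersion, groups) {
  if (is.na(dispersion)) stop("dispersion is undefined; segment is untestable")
  g <- as.integer(factor(groups))
  if (length(unique(g)) != 2L) stop("both groups must be non-empty")
  fit <- .fit_two_group_nb(counts_row, size_factors, g, dispersion)
  mu <- size_factors * fit$q[g]
  w <- mu / (1 + dispersion * mu)
  v <- vapply(1:2, function(gg) 1 / max(sum(w[g == gg]), 1e-300), numeric(1))
  log2fc <- (log(fit$q[1]) - log(fit$q[2])) / log(2)
  se <- sqrt(v[1] + v[2]) / log(2)
  z <- log2fc / se
  list(log2fc = log2fc, se = se, p = 2 * pnorm(-abs(z)),
       boundary = fit$boundary)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement; `NA` entries (untested
#' segments) are excluded from the family size and returned as `NA`.
#'
#' @param p numeric vector of p-values in `[0, 1]`, possibly with `NA`s.
#' @return the adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Simes-family post-hoc bound on the false discovery proportion
#'
#' For an arbitrary selection S of tested segments, returns the post-hoc
#' upper confidence bound on the number of false discoveries in S obtained
#' from the Simes reference family with thresholds `t_k = alpha * k / m`
#' (m = number of tested segments in the analysis):
#' `v_bar = min_k ( #\{i in S : p_i >= t_k\} + k - 1 )` over `k = 1..|S|`,
#' clipped to `[0, |S|]`. The FDP bound is `v_bar / |S|` (0 for empty S).
#'
#' @param p_all p-values of all m tested segments.
#' @param selection integer indices into `p_all` of the selected segments.
#' @param alpha significance level of the joint error rate control.
#' @return list with `v_bar` (integer bound on false discoveries) and
#'   `fdp_bound`.
#' @export
simes_fdp_bound <- function(p_all, selection, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  m <- length(p_all)
  sel_p <- p_all[selection]
  s <- length(sel_p)
  if (s == 0L) return(list(v_bar = 0L, fdp_bound = 0))
  ks <- seq_len(s)
  tk <- alpha * ks / m
  vk <- vapply(ks, function(k) sum(sel_p >= tk[k]) + k - 1L, numeric(1))
  v_bar <- as.integer(min(max(min(vk), 0L), s))
  list(v_bar = v_bar, fdp_bound = v_bar / s)
}

#' Run the differential expression analysis on a count matrix
#'
#' Per-segment pipeline: size factors (median-of-ratios), Cox-Reid NB
#' dispersion, two-group Wald test, BH adjustment. Per-segment dispersion
#' estimates below a fitted mean-dispersion trend (`a0 + a1 / mean`) are
#' floored at the trend: at few replicates the per-segment likelihood
#' routinely underestimates the dispersion, which would make the Wald test
#' anti-conservative; above-trend estimates are kept as is and no other
#' shrinkage is applied. All-zero segments are untestable: they carry `NA`
#' p-values and are excluded from the multiplicity family.
#'
#' @param counts a `count_matrix`.
#' @param condition_of_interest,reference_condition the two condition
#'   labels; `log2fc` is interest vs reference.
#' @param size_factors optional externally supplied size factors.
#' @param sf_fallback passed to [median_of_ratios_size_factors()].
#' @param trend_floor floor below-trend dispersions at the fitted trend;
#'   set `FALSE` to keep raw estimates.
#' @return an object of class `dea_table`: a data.frame with one row per
#'   segment (`baseMean`, `log2FoldChange`, `lfcSE`, `pvalue`, `padj`,
#'   `dispersion`, `tested`, `boundary`), with attributes `size_factors`,
#'   `rho` (the [normalization_offset()]) and `m_tested`.
#' @export
dea <- function(counts, condition_of_interest, reference_condition,
                size_factors = NULL, sf_fallback = FALSE,
                trend_floor = TRUE) {
  stopifnot(inherits(counts, "count_matrix"))
  cond <- counts$samples$condition
  if (!all(c(condition_of_interest, reference_condition) %in% cond))
    stop("condition labels not found in the sample table")
  groups <- factor(ifelse(cond == condition_of_interest, "interest", "reference"),
                   levels = c("interest", "reference"))
  m <- counts$counts
  if (is.null(size_factors)) {
    w <- if (!is.null(counts$segments)) width(counts$segments) else NULL
    size_factors <- median_of_ratios_size_factors(m, fallback = sf_fallback,
                                                  weights = w)
  }

  n_seg <- nrow(m)
  disp_raw <- vapply(seq_len(n_seg), function(k) {
    estimate_dispersion(m[k, ], size_factors, groups)
  }, numeric(1))
  base_mean <- rowMeans(sweep(m, 2, size_factors, "/"))

  disp <- disp_raw
  if (isTRUE(trend_floor)) {
    ok <- !is.na(disp_raw) & base_mean > 0
    if (sum(ok) >= 3) {
      ## gamma-family trend alpha(mu) = a0 + a1/mu, robust least squares on
      ## the raw estimates
      xf <- 1 / base_mean[ok]
      fit <- try(stats::lm(disp_raw[ok] ~ xf), silent = TRUE)
      if (!inherits(fit, "try-error")) {
        co <- pmax(stats::coef(fit), 0)
        trend <- pmax(co[1] + co[2] / base_mean, 1e-8)
        disp <- ifelse(!is.na(disp_raw), pmax(disp_raw, trend), NA_real_)
      }
    }
  }

  log2fc <- se <- p <- rep(NA_real_, n_seg)
  boundary <- rep(FALSE, n_seg)
  for (k in seq_len(n_seg)) {
    if (is.na(disp[k])) next
    wt <- nb_wald_test(m[k, ], size_factors, disp[k], groups)
    log2fc[k] <- wt$log2fc; se[k] <- wt$se; p[k] <- wt$p
    boundary[k] <- wt$boundary
  }
  padj <- bh_adjust(p)
  sf1 <- size_factors[groups == "interest"]
  sf2 <- size_factors[groups == "reference"]
  out <- data.frame(
    baseMean = base_mean, log2FoldChange = log2fc, lfcSE = se,
    pvalue = p, padj = padj, dispersion = disp,
    tested = !is.na(p), boundary = boundary
  )
  structure(out, class = c("dea_table", "data.frame"),
            size_factors = size_factors,
            rho = normalization_offset(sf1, sf2),
            m_tested = sum(!is.na(p)),
            reference_condition = reference_condition,
            condition_of_interest = condition_of_interest)
}

#' Call differentially expressed regions with an FDP guarantee
#'
#' Candidates are the tested segments whose fold change exceeds
#' `fc_threshold` (or is below its reciprocal). Candidates are ordered by
#' increasing p-value (ties by genomic start when available), and the
#' selection is the longest prefix whose Simes post-hoc FDP bound is at most
#' `fdp_target`; every prefix is checked explicitly.
#'
#' @param dea_table a [dea()] result.
#' @param fc_threshold fold-change threshold (natural scale, default 1.5).
#' @param fdp_target maximum tolerated false discovery proportion.
#' @param alpha level of the Simes joint error rate control.
#' @param start_order optional numeric vector (e.g. genomic starts) used to
#'   break p-value ties deterministically.
#' @return an object of class `der_call`: list with `selected` (logical per
#'   segment), `fdp_bound` (achieved bound for the selected set), `v_bar`,
#'   `n_candidates` and the thresholds used.
#' @export
call_ders <- function(dea_table, fc_threshold = 1.5, fdp_target = 0.05,
                      alpha = 0.05, start_order = NULL) {
  p <- dea_table$pvalue
  lfc <- dea_table$log2FoldChange
  tested_idx <- which(!is.na(p))
  cand <- tested_idx[abs(lfc[tested_idx]) > log2(fc_threshold)]
  n_seg <- nrow(dea_table)
  selected <- rep(FALSE, n_seg)
  if (length(cand) == 0L) {
    return(structure(list(selected = selected, fdp_bound = 0, v_bar = 0L,
                          n_candidates = 0L, fc_threshold = fc_threshold,
                          fdp_target = fdp_target, alpha = alpha),
                     class = "der_call"))
  }
  tie <- if (is.null(start_order)) cand else start_order[cand]
  cand <- cand[order(p[cand], tie)]
  ## p-values indexed within the tested family
  p_tested <- p[tested_idx]
  pos_in_family <- match(cand, tested_idx)
  best_len <- 0L; best_bound <- 0; best_v <- 0L
  for (len in seq_along(cand)) {
    b <- simes_fdp_bound(p_tested, pos_in_family[seq_len(len)], alpha)
    if (b$fdp_bound <= fdp_target) {
      best_len <- len; best_bound <- b$fdp_bound; best_v <- b$v_bar
    }
  }
  if (best_len > 0L) selected[cand[seq_len(best_len)]] <- TRUE
  structure(list(selected = selected, fdp_bound = best_bound, v_bar = best_v,
                 n_candidates = length(cand), fc_threshold = fc_threshold,
                 fdp_target = fdp_target, alpha = alpha),
            class = "der_call")
}

#' @export
print.der_call <- function(x, ...) {
  cat(sprintf("der_call: %d DER(s) among %d candidate(s)\n",
              sum(x$selected), x$n_candidates))
  cat(sprintf("  FDP bound %.3f (target %.3f, |FC| > %.2f, alpha %.2f)\n",
              x$fdp_bound, x$fdp_target, x$fc_threshold, x$alpha))
  invisible(x)
}
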