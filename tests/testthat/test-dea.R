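# Differential testing: normalization, dispersion, Wald test, BH and the
# post-hoc FDP bound.

test_that("median-of-ratios size factors match analytic cases", {
  m <- matrix(rep(c(10, 50, 200), 3), ncol = 3)
  expect_equal(unname(median_of_ratios_size_factors(m)), rep(1, 3))

  a <- c(10, 50, 200, 1000)
  m <- cbind(a, 2 * a)
  expect_equal(unname(median_of_ratios_size_factors(m)),
               c(1 / sqrt(2), sqrt(2)))

  # rows with zeros are excluded from the median: the zero row would drag
  # sample 2 down if it were used
  m <- rbind(cbind(a, 2 * a), c(0, 1000))
  expect_equal(unname(median_of_ratios_size_factors(m)),
               c(1 / sqrt(2), sqrt(2)))

  # no all-positive row: explicit error advising the fallback
  m <- matrix(c(0, 5, 5, 0), 2)
  expect_error(median_of_ratios_size_factors(m), "fallback")
  expect_silent(sf <- median_of_ratios_size_factors(m, fallback = TRUE))
  expect_equal(exp(mean(log(sf))), 1)
})

test_that("dispersion estimation recovers simulated truth", {
  groups <- rep(c("a", "b"), each = 20)
  sf <- rep(1, 40)
  expect_true(is.na(estimate_dispersion(rep(0L, 40), sf, groups)))

  set.seed(501)
  # Poisson data: estimates collapse to (near) zero
  disp_pois <- replicate(50, estimate_dispersion(rpois(40, 500), sf, groups))
  expect_lt(median(disp_pois), 0.005)

  # NB with alpha = 0.1: median estimate in a factor-2 band around truth
  disp_nb <- replicate(500, estimate_dispersion(
    rnbinom(40, mu = 200, size = 10), sf, groups))
  expect_gt(median(disp_nb), 0.05)
  expect_lt(median(disp_nb), 0.2)
})

test_that("the Wald test behaves at the null and at a known effect", {
  groups <- factor(rep(c("a", "b"), each = 4), levels = c("a", "b"))
  sf <- rep(1, 8)
  same <- nb_wald_test(rep(100L, 8), sf, 0.05, groups)
  expect_equal(same$log2fc, 0)
  expect_gt(same$p, 0.99)
  expect_false(same$boundary)

  # exact doubling at large counts: the fitted group-mean ratio is 2
  doubled <- nb_wald_test(c(2000L, 2000L, 2000L, 2000L,
                            1000L, 1000L, 1000L, 1000L), sf, 0.05, groups)
  expect_equal(doubled$log2fc, 1, tolerance = 1e-6)
  expect_lt(doubled$p, 1e-3)

  # permuting samples within a group changes nothing
  k <- c(120L, 80L, 210L, 55L, 30L, 44L, 19L, 71L)
  w1 <- nb_wald_test(k, sf, 0.1, groups)
  w2 <- nb_wald_test(k[c(3, 1, 4, 2, 7, 8, 5, 6)], sf, 0.1, groups)
  expect_equal(w1[c("log2fc", "se", "p")], w2[c("log2fc", "se", "p")])

  # one group all zero: boundary flagged, p still defined
  b <- nb_wald_test(c(100L, 120L, 90L, 110L, 0L, 0L, 0L, 0L), sf, 0.05, groups)
  expect_true(b$boundary)
  expect_true(is.finite(b$p))
  expect_gt(b$log2fc, 5)
})

test_that("size factors enter the fit as offsets", {
  groups <- factor(rep(c("a", "b"), each = 2), levels = c("a", "b"))
  # counts proportional to size factors: no differential signal
  w <- nb_wald_test(c(100L, 200L, 100L, 200L), c(1, 2, 1, 2), 0.01, groups)
  expect_equal(w$log2fc, 0, tolerance = 1e-6)
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(502)
  p <- c(runif(50), NA, NA)
  q <- bh_adjust(p)
  expect_true(all(q >= p, na.rm = TRUE))
  expect_true(all(is.na(q[51:52])))
  # monotone in p
  o <- order(p[1:50])
  expect_true(all(diff(q[1:50][o]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the Simes post-hoc bound evaluates correctly", {
  set.seed(503)
  filler <- runif(98, 0.5, 1)
  # both selected p below t_1 = alpha/m: zero false discoveries certified
  b <- simes_fdp_bound(c(1e-6, 1e-6, filler), 1:2, alpha = 0.05)
  expect_equal(b$v_bar, 0L)
  expect_equal(b$fdp_bound, 0)
  # hopeless selection: bound is vacuous
  b <- simes_fdp_bound(c(1, 1, filler), 1:2, alpha = 0.05)
  expect_equal(b$v_bar, 2L)
  expect_equal(b$fdp_bound, 1)
  # mixed: k=1 gives 1+0=1, k=2 gives 1+1=2 -> v_bar = 1
  b <- simes_fdp_bound(c(1e-4, 2e-3, filler), 1:2, alpha = 0.05)
  expect_equal(b$v_bar, 1L)
  expect_equal(b$fdp_bound, 0.5)
  # empty selection
  expect_equal(simes_fdp_bound(filler, integer(0))$fdp_bound, 0)
})

test_that("the Simes bound is monotone and permutation invariant", {
  set.seed(504)
  p <- runif(60)
  sel <- sample(60, 12)
  b0 <- simes_fdp_bound(p, sel)
  expect_equal(simes_fdp_bound(p, sample(sel))$v_bar, b0$v_bar)
  # decreasing a selected p can only tighten the bound
  p2 <- p
  p2[sel[1]] <- p2[sel[1]] / 100
  expect_lte(simes_fdp_bound(p2, sel)$v_bar, b0$v_bar)
})

test_that("DER calling selects the longest admissible p-ordered prefix", {
  mk_dea <- function(p, lfc) {
    structure(data.frame(baseMean = 100, log2FoldChange = lfc, lfcSE = 0.1,
                         pvalue = p, padj = bh_adjust(p), dispersion = 0.05,
                         tested = !is.na(p), boundary = FALSE),
              class = c("dea_table", "data.frame"))
  }
  # no candidate passes the FC threshold
  call <- call_ders(mk_dea(c(1e-8, 1e-8), c(0.1, -0.2)))
  expect_equal(sum(call$selected), 0L)
  expect_equal(call$fdp_bound, 0)

  # all candidates far below alpha/m: everything selected with v_bar = 0
  p <- rep(1e-10, 8)
  call <- call_ders(mk_dea(p, rep(2, 8)))
  expect_equal(sum(call$selected), 8L)
  expect_equal(call$v_bar, 0L)

  # mixed p-values: compare against exhaustive prefix search done by hand
  set.seed(505)
  p <- c(1e-9, 1e-7, 2e-4, 5e-3, 0.02, 0.3, 0.8, runif(43, 0.3, 1))
  lfc <- c(rep(1.5, 7), rep(0.1, 43))
  dt <- mk_dea(p, lfc)
  call <- call_ders(dt)
  cand <- order(p[1:7])
  best <- 0L
  for (len in 1:7) {
    b <- simes_fdp_bound(p, cand[1:len], 0.05)
    if (b$fdp_bound <= 0.05) best <- len
  }
  expect_equal(sum(call$selected), best)
  expect_true(all(which(call$selected) %in% cand[seq_len(best)]))

  # input order invariance: permuting rows permutes the selection with them
  perm <- sample(50)
  call_p <- call_ders(mk_dea(p[perm], lfc[perm]))
  expect_equal(call_p$selected, call$selected[perm])
})

test_that("dea() is consistent with DESeq2 on the same counts", {
  set.seed(506)
  n_seg <- 30
  mu <- exp(rnorm(n_seg, log(200), 1))
  lfc <- rnorm(n_seg, 0, 1)
  counts <- t(sapply(seq_len(n_seg), function(k) c(
    rnbinom(3, mu = mu[k] * 2^lfc[k], size = 20),
    rnbinom(3, mu = mu[k], size = 20))))
  cm <- make_count_matrix(counts, rep(c("mut", "wt"), each = 3))
  dt <- dea(cm, "mut", "wt")

  suppressMessages({
    library(DESeq2)
    dds <- DESeqDataSetFromMatrix(
      counts, data.frame(condition = factor(rep(c("mut", "wt"), each = 3),
                                            levels = c("wt", "mut"))),
      ~condition)
    dds <- DESeq(dds, quiet = TRUE)
    res <- results(dds, contrast = c("condition", "mut", "wt"))
  })
  # identical point estimates (both are the two-group NB MLE)
  expect_equal(dt$log2FoldChange, res$log2FoldChange, tolerance = 0.01)
  # same size factors after geometric-mean rescaling
  sfd <- sizeFactors(dds) / exp(mean(log(sizeFactors(dds))))
  expect_equal(unname(attr(dt, "size_factors")), unname(sfd),
               tolerance = 1e-9)
  # strongly concordant evidence ordering
  expect_gt(cor(log(dt$pvalue), log(res$pvalue)), 0.95)
})

test_that("dea() marks all-zero segments untestable and reports rho", {
  set.seed(507)
  counts <- rbind(matrix(rnbinom(40, mu = 100, size = 20), 10),
                  rep(0L, 4))
  cm <- make_count_matrix(counts, rep(c("a", "b"), each = 2))
  dt <- dea(cm, "a", "b")
  expect_false(dt$tested[11])
  expect_true(is.na(dt$pvalue[11]))
  expect_equal(attr(dt, "m_tested"), 10L)
  sf <- attr(dt, "size_factors")
  expect_equal(attr(dt, "rho"),
               mean(log2(sf[1:2])) - mean(log2(sf[3:4])))
})
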