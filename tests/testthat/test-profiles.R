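# Coverage profiles: read-end extraction, end/full-length coverage,
# the geometric-mean combination and the per-base log2-FC.

test_that("read ends are extracted with correct 5'/3' orientation", {
  # one forward and one reverse single-end 50 nt read starting at 101
  bam <- make_bam(data.frame(pos = c(101L, 101L), flag = c(0L, 16L),
                             cigar = c("50M", "50M")))
  w <- genomic_window("chrT", 1, 1000, "+")
  ends <- extract_read_ends(bam, w, library_protocol = "fr",
                            pairing_mode = "read")
  fwd <- ends[ends$strand == "+", ]
  rev <- ends[ends$strand == "-", ]
  expect_equal(c(fwd$five_prime, fwd$three_prime), c(101L, 150L))
  # on the minus strand 5' and 3' swap
  expect_equal(c(rev$five_prime, rev$three_prime), c(150L, 101L))
})

test_that("empty region gives an empty result, bad inputs give errors", {
  bam <- make_bam(data.frame(pos = 101L, flag = 0L, cigar = "50M"))
  w_empty <- genomic_window("chrT", 5000, 6000, "+")
  expect_equal(nrow(extract_read_ends(bam, w_empty)), 0L)

  expect_error(extract_read_ends(bam, genomic_window("chrX", 1, 10)),
               "absent from the header")
  noidx <- tempfile(fileext = ".bam")
  file.copy(bam, noidx)
  expect_error(extract_read_ends(noidx, genomic_window("chrT", 1, 10)),
               "index")
})

test_that("secondary/supplementary/unmapped records are excluded", {
  bam <- make_bam(data.frame(pos = c(101L, 101L, 101L),
                             flag = c(0L, 256L, 2048L),
                             cigar = c("50M", "50M", "50M")))
  w <- genomic_window("chrT", 1, 1000, "+")
  expect_equal(nrow(extract_read_ends(bam, w)), 1L)
})

test_that("rf protocol flips the biological strand", {
  bam <- make_bam(data.frame(pos = 101L, flag = 0L, cigar = "50M"))
  w <- genomic_window("chrT", 1, 1000, "+")
  expect_equal(extract_read_ends(bam, w, "rf")$strand, "-")
  expect_warning(
    ends <- extract_read_ends(bam, w, "unstranded"),
    "unstranded"
  )
  expect_equal(ends$strand, "+")
})

test_that("fragment pairing treats a proper pair as one unit", {
  # proper pair: mate1 + at 101 (50M), mate2 - at 301 (50M); fragment
  # spans 101..350
  reads <- data.frame(
    qname = c("p1", "p1"), pos = c(101L, 301L),
    flag = c(99L, 147L), cigar = c("50M", "50M"),
    rnext = c("=", "="), pnext = c(301L, 101L), tlen = c(250L, -250L)
  )
  bam <- make_bam(reads)
  w <- genomic_window("chrT", 1, 1000, "+")
  frag <- extract_read_ends(bam, w, pairing_mode = "fragment")
  expect_equal(nrow(frag), 1L)
  expect_equal(frag$five_prime, 101L)
  expect_equal(frag$three_prime, 350L)
  expect_equal(frag$strand, "+")
  per_read <- extract_read_ends(bam, w, pairing_mode = "read")
  expect_equal(nrow(per_read), 2L)
  # mate-1-based inference: both mates report the fragment strand
  expect_equal(per_read$strand, c("+", "+"))
})

test_that("end coverage counts selected ends inside the window", {
  w <- genomic_window("chrT", 101, 110, "+")
  ends <- data.frame(five_prime = c(103L, 103L, 103L, 105L, 500L),
                     three_prime = c(120L, 120L, 120L, 125L, 520L),
                     strand = "+")
  cov5 <- end_coverage(ends, w, "five_prime")
  expect_equal(cov5, c(0L, 0L, 3L, 0L, 1L, 0L, 0L, 0L, 0L, 0L))
  # ends outside the window are ignored
  expect_equal(sum(cov5), 4L)
  # 3' ends all outside this window
  expect_equal(end_coverage(ends, w, "three_prime"), rep(0L, 10))
  # no reads at all
  expect_equal(end_coverage(ends[0, ], w, "five_prime"), rep(0L, 10))
  # opposite-strand reads are not counted
  ends$strand <- "-"
  expect_equal(sum(end_coverage(ends, w, "five_prime")), 0L)
})

test_that("full-length coverage is additive over reads", {
  w <- genomic_window("chrT", 101, 105, "+")
  one <- full_length_coverage(IRanges::IRanges(101, 103), w)
  expect_equal(one, c(1L, 1L, 1L, 0L, 0L))
  two <- full_length_coverage(IRanges::IRanges(c(101, 101), c(103, 103)), w)
  expect_equal(two, 2L * one)
  disjoint <- full_length_coverage(IRanges::IRanges(c(101, 104), c(102, 105)), w)
  expect_equal(disjoint, c(1L, 1L, 0L, 1L, 1L))
})

test_that("geometric coverage is the identity on equal inputs", {
  q <- c(0L, 1L, 3L, 10L, 250L)
  expect_equal(geometric_coverage(q, q), as.numeric(q))
  expect_equal(geometric_coverage(0, 0), 0)
  expect_equal(geometric_coverage(3, 0), 1) # sqrt(4*1) - 1
  expect_error(geometric_coverage(1:3, 1:2), "length")
})

test_that("log2-FC profile follows the replicate-averaged definition", {
  w <- genomic_window("chrT", 1, 3, "+")
  mk <- function(vals, cond, rep)
    structure(list(window = w, sample_id = paste0(cond, rep),
                   condition = cond, replicate = rep, mode = "five_prime",
                   values = vals), class = "coverage_profile")
  # identical profiles -> Y == 0
  expect_equal(log2_fc_profile(list(mk(c(5, 5, 5), "a", 1)),
                               list(mk(c(5, 5, 5), "b", 1)))$values,
               c(0, 0, 0))
  # one replicate each: log2(4) - log2(2) = 1
  expect_equal(log2_fc_profile(list(mk(c(3, 3, 3), "a", 1)),
                               list(mk(c(1, 1, 1), "b", 1)))$values,
               c(1, 1, 1))
  # cond1 reps (1, 3), cond2 rep (0): (log2 2 + log2 4)/2 - 0 = 1.5
  expect_equal(log2_fc_profile(list(mk(c(1, 1, 1), "a", 1),
                                    mk(c(3, 3, 3), "a", 2)),
                               list(mk(c(0, 0, 0), "b", 1)))$values,
               c(1.5, 1.5, 1.5))
  # antisymmetry
  p1 <- list(mk(c(4, 0, 7), "a", 1)); p2 <- list(mk(c(1, 9, 2), "b", 1))
  expect_equal(log2_fc_profile(p1, p2)$values,
               -log2_fc_profile(p2, p1)$values)
  # mismatched windows refuse to combine
  w2 <- genomic_window("chrT", 1, 3, "-")
  bad <- mk(c(1, 1, 1), "b", 1); bad$window <- w2
  expect_error(log2_fc_profile(p1, list(bad)), "window")
})

test_that("profile locality holds for single-replicate full-length mode", {
  w <- genomic_window("chrT", 1, 4, "+")
  mk <- function(vals, cond)
    structure(list(window = w, sample_id = cond, condition = cond,
                   replicate = 1L, mode = "full_length", values = vals),
              class = "coverage_profile")
  a <- c(3, 8, 0, 2); b <- c(1, 1, 5, 2)
  y <- log2_fc_profile(list(mk(a, "a")), list(mk(b, "b")))$values
  expect_equal(y, log2(a + 1) - log2(b + 1))
})

test_that("normalization offset matches its definition", {
  expect_equal(normalization_offset(c(1, 1), c(1, 1, 1)), 0)
  expect_equal(normalization_offset(2, 1), 1)
  expect_equal(normalization_offset(c(2, 8), c(1, 1)), 2)
  expect_error(normalization_offset(c(1, -1), 1), "positive")
})

test_that("coverage_profile modes agree with their building blocks", {
  # three + reads 5' at 201, one at 210; reads are 50 nt
  bam <- make_bam(data.frame(pos = c(201L, 201L, 201L, 210L), flag = 0L,
                             cigar = "50M"))
  w <- genomic_window("chrT", 191, 290, "+")
  p5 <- coverage_profile(bam, w, mode = "five_prime")
  expect_equal(p5$values[11], 3L)
  expect_equal(p5$values[20], 1L)
  expect_equal(sum(p5$values), 4L)
  p3 <- coverage_profile(bam, w, mode = "three_prime")
  expect_equal(p3$values[60], 3L) # 201 + 49 = 250 -> offset 60
  pf <- coverage_profile(bam, w, mode = "full_length")
  expect_equal(pf$values[11], 3L) # position 201: the three early reads
  expect_equal(pf$values[20], 4L) # position 210: all four reads
  pg <- coverage_profile(bam, w, mode = "geometric")
  expect_equal(pg$values, geometric_coverage(p5$values, p3$values))
})

test_that("spliced reads cover only aligned blocks in full-length mode", {
  bam <- make_bam(data.frame(pos = 101L, flag = 0L, cigar = "10M20N10M"))
  w <- genomic_window("chrT", 101, 140, "+")
  pf <- coverage_profile(bam, w, mode = "full_length")
  expect_equal(pf$values, c(rep(1L, 10), rep(0L, 20), rep(1L, 10)))
  # end modes use the outermost aligned positions
  p5 <- coverage_profile(bam, w, mode = "five_prime")
  p3 <- coverage_profile(bam, w, mode = "three_prime")
  expect_equal(which(p5$values == 1L), 1L)
  expect_equal(which(p3$values == 1L), 40L)
})
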