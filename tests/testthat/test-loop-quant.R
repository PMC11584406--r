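# Loop strengths against donut backgrounds, priority merging, stage calls
# and APA contracts.

test_that("loop_strength is a pseudo-counted log10 ratio", {
  expect_equal(loop_strength(20, 4), log10(21 / 5))
  expect_equal(loop_strength(7, 7), 0)
  expect_error(loop_strength(-1, 1), "nonnegative")
})

test_that("loop_quantify recovers a planted spike over a flat background", {
  n <- 60
  m <- matrix(4, n, n)
  m[30, 45] <- m[45, 30] <- 40
  cm <- dense_to_cm(m)
  loops <- data.frame(chrom = "chr1", start1 = 29000, end1 = 30000,
                      start2 = 44000, end2 = 45000)
  out <- loop_quantify(cm, loops)
  expect_equal(out$observed, 40)
  expect_equal(out$expected, 4)
  expect_equal(out$strength, log10(41 / 5))
  # donut leaving the matrix flags the loop
  edge <- data.frame(chrom = "chr1", start1 = 0, end1 = 1000,
                     start2 = 3000, end2 = 4000)
  expect_true(loop_quantify(cm, edge)$flagged)
})

test_that("planted loops on simulated maps exceed random pixels and track
           planted enrichment", {
  co <- fixture_cohort()
  cm <- bin_matrix(co$records[["M01"]], 1000, co$truth$chrom_sizes)
  lq <- loop_quantify(cm, co$truth$loops)
  expect_gt(mean(lq$strength > 0.2, na.rm = TRUE), 0.95)
  # monotone in planted enrichment
  expect_gt(cor(lq$strength, co$truth$loops$enrichment, method = "spearman",
                use = "complete.obs"), 0.5)
  # pixels far from any planted structure are near zero on average
  set.seed(4)
  s1 <- round(runif(40, 5e5, 2.5e6) / 1000) * 1000 + 300
  rnd <- data.frame(chrom = "chr2", start1 = s1, end1 = s1 + 400)
  rnd$start2 <- rnd$start1 + round(runif(40, 3e4, 1.5e5) / 1000) * 1000
  rnd$end2 <- rnd$start2 + 400
  rq <- loop_quantify(cm, rnd)
  expect_lt(abs(mean(rq$strength, na.rm = TRUE)), 0.1)
})

test_that("merge_loop_lists keeps single-anchor overlaps and drops
           double-anchor overlaps by priority", {
  l1 <- data.frame(chrom = "chr1", start1 = 1000, end1 = 2000,
                   start2 = 50000, end2 = 51000)
  # same loop in a lower-priority list: dropped
  l2 <- l1
  # shares only anchor1: kept
  l3 <- data.frame(chrom = "chr1", start1 = 1500, end1 = 2500,
                   start2 = 80000, end2 = 81000)
  out <- merge_loop_lists(list(l1, l2, l3))
  expect_equal(nrow(out), 2L)
  expect_equal(out$priority, c(1L, 3L))

  # three-list hand-enumerated survivor set
  a <- data.frame(chrom = "chr1",
                  start1 = c(1000, 10000), end1 = c(1400, 10400),
                  start2 = c(30000, 40000), end2 = c(30400, 40400))
  b <- data.frame(chrom = "chr1",
                  start1 = c(1200, 60000), end1 = c(1600, 60400),
                  start2 = c(30200, 90000), end2 = c(30600, 90400))
  c_ <- data.frame(chrom = "chr1",
                   start1 = c(10100, 60100, 5000),
                   end1 = c(10500, 60500, 5400),
                   start2 = c(40100, 90100, 70000),
                   end2 = c(40500, 90500, 70400))
  out2 <- merge_loop_lists(list(a, b, c_))
  # survivors: both of a; b[2] (b[1] conflicts with a[1]); c_[3] only
  expect_equal(nrow(out2), 4L)
  expect_equal(out2$start1, c(1000, 10000, 60000, 5000))
  # within-priority order does not matter for non-conflicting loops
  out3 <- merge_loop_lists(list(a[2:1, ], b, c_))
  expect_setequal(out3$start1, out2$start1)
})

test_that("stage_positive uses a strict enrichment-ratio threshold", {
  lt <- data.frame(id = 1:3,
                   observed.s1 = c(25, 11, 2), expected.s1 = c(19, 9, 9),
                   observed.s2 = c(25, 11, 2), expected.s2 = c(19, 9, 9))
  # ratios: 26/20 = 1.3 ; 12/10 = 1.2 exactly ; 3/10 = 0.3
  out <- stage_positive(lt, c("s1", "s2"), fold = 1.2)
  expect_equal(out$id, 1L)
  expect_error(stage_positive(lt, character(0)), "at least one")
})

test_that("attenuated stages yield fewer stage-positive loops", {
  co <- fixture_cohort()
  lt <- co$truth$loops
  # thin the maps so weak loops sit near the enrichment threshold
  for (s in c("M01", "A01")) {
    thin <- subsample_contacts(co$records[[s]], 0.04, seed = 15)
    cm <- bin_matrix(thin, 1000, co$truth$chrom_sizes)
    q <- loop_quantify(cm, co$truth$loops)
    lt[[paste0("observed.", s)]] <- q$observed
    lt[[paste0("expected.", s)]] <- q$expected
  }
  n_muc <- nrow(stage_positive(lt, "M01"))
  n_ade <- nrow(stage_positive(lt, "A01"))
  expect_gt(n_muc, n_ade)
})

test_that("APA obeys the uniformity, block and scaling contracts", {
  # anchors separated beyond the window span so the aggregate window does
  # not cross the diagonal (mirrored signal would enter the corner)
  n <- 700
  flat <- matrix(2, n, n)
  cm <- dense_to_cm(flat, resolution = 1000)
  ap <- data.frame(chrom = "chr1", pos1 = 150 * 1000 + 500,
                   pos2 = 450 * 1000 + 500)
  res <- apa(cm, ap, half_width = 110, mode = "loop", center_n = 10,
             bg_n = 100)
  expect_equal(res$score, 1)
  # a 10x10 center block at 5x background scores exactly 5
  # (anchor pos 150500 sits in 0-based bin 150 = 1-based row 151; the
  # center_n = 10 block spans bins 146..155, i.e. rows 147..156)
  block <- flat
  block[147:156, 447:456] <- 10
  res2 <- apa(dense_to_cm(block, resolution = 1000), ap, half_width = 110,
              mode = "loop", center_n = 10, bg_n = 100)
  expect_equal(res2$score, 5)
  # global scaling leaves the score unchanged
  res3 <- apa(dense_to_cm(block * 7, resolution = 1000), ap,
              half_width = 110, mode = "loop", center_n = 10, bg_n = 100)
  expect_equal(res3$score, res2$score)
  # no valid anchor pairs is an error
  edge <- data.frame(chrom = "chr1", pos1 = 1000, pos2 = 5000)
  expect_error(apa(cm, edge, half_width = 110, mode = "loop",
                   center_n = 10, bg_n = 100), "no valid anchor")
  expect_error(apa(cm, ap, half_width = 20, mode = "loop"), "window too")
})

test_that("stripe-mode APA normalizes per diagonal", {
  # counts depending only on distance normalize to exactly 1 everywhere
  n <- 300
  sep <- abs(outer(seq_len(n), seq_len(n), `-`))
  m <- 100 / (1 + sep)
  cm <- dense_to_cm(m, resolution = 1000)
  ap <- data.frame(chrom = "chr1", pos1 = 100 * 1000 + 500,
                   pos2 = 180 * 1000 + 500)
  res <- apa(cm, ap, half_width = 50, mode = "stripe")
  expect_equal(res$score, 1, tolerance = 1e-10)
  # scale invariance holds in stripe mode too
  res2 <- apa(dense_to_cm(m * 3, resolution = 1000), ap, half_width = 50,
              mode = "stripe")
  expect_equal(res2$score, res$score, tolerance = 1e-10)
})
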