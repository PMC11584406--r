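# Synthetic cohort generator: distance decay, determinism, depth scaling,
# the saturating expression rule and the bias model.

test_that("background-only maps follow the planted distance decay", {
  truth <- synthetic_truth(chrom_sizes = c(chr1 = 8e6),
                           mix = c(background = 0.75, stripe = 0, loop = 0,
                                   self = 0.25),
                           decay_exponent = 1, seed = 2)
  # remove planted structures entirely: background + self only
  truth$stripe_anchors <- truth$stripe_anchors[0, ]
  truth$loops <- truth$loops[0, ]
  rec <- simulate_contacts(truth, "S1", depth = 3e5, seed = 4,
                           stage = "mucosa")
  d <- abs(rec$pos2 - rec$pos1)
  br <- 10^seq(log10(1100), log10(1.4e6), length.out = 15)
  d <- d[d > 1000 & d <= max(br)]
  h <- hist(d, breaks = c(1000, br), plot = FALSE)
  keep <- h$counts > 0
  # density per bp vs bin center on log-log axes: slope ~ -alpha
  fit <- stats::lm(log10(h$counts[keep] / diff(c(1000, br))[keep]) ~
                     log10(h$mids[keep]))
  expect_lt(abs(stats::coef(fit)[2] + 1), 0.1)
})

test_that("identical seeds give identical streams, different seeds differ", {
  truth <- synthetic_truth(chrom_sizes = c(chr1 = 2e6), genes_per_mb = 4,
                           seed = 5)
  a <- simulate_contacts(truth, "S1", depth = 2e4, seed = 9,
                         stage = "mucosa")
  b <- simulate_contacts(truth, "S1", depth = 2e4, seed = 9,
                         stage = "mucosa")
  c <- simulate_contacts(truth, "S1", depth = 2e4, seed = 10,
                         stage = "mucosa")
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a, c)))
  # simulation does not disturb the caller's RNG stream
  set.seed(1); x1 <- stats::runif(1)
  set.seed(1)
  invisible(simulate_contacts(truth, "S1", depth = 1e3, seed = 2,
                              stage = "mucosa"))
  expect_identical(stats::runif(1), x1)
})

test_that("doubling depth doubles expected counts within tolerance", {
  truth <- synthetic_truth(chrom_sizes = c(chr1 = 4e6), genes_per_mb = 6,
                           seed = 3)
  r1 <- simulate_contacts(truth, "S1", depth = 1e5, seed = 6,
                          stage = "mucosa")
  r2 <- simulate_contacts(truth, "S1", depth = 2e5, seed = 7,
                          stage = "mucosa")
  n1 <- nrow(r1); n2 <- nrow(r2)
  # total count: n2 ~ 2 * n1 within 3 s.d. of the Poisson/binomial noise
  expect_lt(abs(n2 - 2 * n1), 3 * sqrt(n2 + 4 * n1))
  # and per coarse genomic bin
  h1 <- tabulate(c(r1$pos1, r1$pos2) %/% 5e5 + 1, nbins = 8)
  h2 <- tabulate(c(r2$pos1, r2$pos2) %/% 5e5 + 1, nbins = 8)
  expect_true(all(abs(h2 - 2 * h1) < 3 * sqrt(h2 + 4 * h1) + 1))
})

test_that("stage attenuation makes planted stripe intensity monotone", {
  truth <- synthetic_truth(chrom_sizes = c(chr1 = 4e6), genes_per_mb = 6,
                           seed = 3)
  stage_cov <- sapply(c("mucosa", "polyp", "adenocarcinoma"), function(st) {
    rec <- simulate_contacts(truth, "S1", depth = 2e5, seed = 6, stage = st)
    a <- truth$stripe_anchors
    pos <- sort(c(rec$pos1, rec$pos2))
    sum(findInterval(a$end, pos) - findInterval(a$start, pos))
  })
  expect_true(stage_cov[1] > stage_cov[2] && stage_cov[2] > stage_cov[3])
})

test_that("expression follows the saturating two-phase rule exactly", {
  truth <- synthetic_truth(chrom_sizes = c(chr1 = 2e6), genes_per_mb = 5,
                           stage_attenuation = c(mucosa = 1, polyp = 0.25,
                                                 adenocarcinoma = 0.2),
                           seed = 8)
  # force C_true = 2*C_sat at mucosa -> 0.5*C_sat at polyp
  truth$genes$c_base <- rep(2, nrow(truth$genes))
  man <- cohort_manifest(1, 1, 1)
  tr <- simulate_tracks(truth, man, seed = 4, expr_noise_frac = 0)
  ratio <- tr$expression[, "P01"] / tr$expression[, "M01"]
  expect_equal(unname(ratio), rep(0.5, nrow(truth$genes)), tolerance = 1e-12)
})

test_that("simulated methylation round-trips through classification", {
  truth <- synthetic_truth(chrom_sizes = c(chr1 = 2e6), genes_per_mb = 5,
                           seed = 8)
  truth$genes$meth_mucosa <- rep(10, nrow(truth$genes))
  man <- cohort_manifest(1, 0, 0)
  tr <- simulate_tracks(truth, man, seed = 4)
  g <- gene_models(truth$genes)
  means <- vapply(seq_len(nrow(g)), function(i)
    region_methylation(tr$methylation,
                       data.frame(chrom = g$chrom[i], start = g$prom_start[i],
                                  end = g$prom_end[i])), numeric(1))
  expect_true(all(classify_state(means) == "demethylated"))
})

test_that("two seeds change the noise but not the truth columns", {
  truth <- synthetic_truth(chrom_sizes = c(chr1 = 2e6), genes_per_mb = 5,
                           seed = 8)
  man <- cohort_manifest(1, 1, 0)
  t1 <- simulate_tracks(truth, man, seed = 1)
  t2 <- simulate_tracks(truth, man, seed = 2)
  expect_identical(t1$peaks[c("chrom", "start", "end", "type")],
                   t2$peaks[c("chrom", "start", "end", "type")])
  expect_false(isTRUE(all.equal(t1$peak_fe, t2$peak_fe)))
  expect_false(isTRUE(all.equal(t1$expression, t2$expression)))
})

test_that("bias scales long and short coverage proportionally", {
  # a 2-kb biased locus: at this scale long-range partners lie outside the
  # biased zone, which is the regime the proportionality argument covers
  bias <- data.frame(chrom = "chr1", start = 1e6, end = 1.002e6, factor = 3)
  truth <- synthetic_truth(chrom_sizes = c(chr1 = 4e6), genes_per_mb = 0.5,
                           mix = c(background = 0.5, stripe = 0, loop = 0,
                                   self = 0.5),
                           bias = bias, seed = 12)
  truth$stripe_anchors <- truth$stripe_anchors[0, ]
  truth$loops <- truth$loops[0, ]
  rec <- simulate_contacts(truth, "S1", depth = 6e6, seed = 5,
                           stage = "mucosa")
  sp <- split_by_range(rec)
  cov_in <- function(df, lo, hi) {
    p <- c(df$pos1, df$pos2)
    sum(p >= lo & p < hi)
  }
  # biased 2-kb locus versus unbiased controls of the same width
  ctrl <- seq(1.5e6, 3.4e6, by = 1e5)
  long_ctrl <- mean(sapply(ctrl, function(x) cov_in(sp$long, x, x + 2000)))
  short_ctrl <- mean(sapply(ctrl, function(x) cov_in(sp$short, x, x + 2000)))
  ratio_biased <- cov_in(sp$long, 1e6, 1.002e6) /
    cov_in(sp$short, 1e6, 1.002e6)
  expect_lt(abs(ratio_biased / (long_ctrl / short_ctrl) - 1), 0.25)
  # while raw long coverage itself scales ~3x
  expect_gt(cov_in(sp$long, 1e6, 1.002e6) / long_ctrl, 2)
})

test_that("malformed truth and unknown samples are rejected", {
  expect_error(synthetic_truth(chrom_sizes = c(chr1 = 0)), "zero-length")
  expect_error(synthetic_truth(stage_attenuation = c(mucosa = 0.9,
                                                     polyp = 0.5,
                                                     adenocarcinoma = 0.3)),
               "mucosa")
  truth <- synthetic_truth(chrom_sizes = c(chr1 = 2e6), genes_per_mb = 4,
                           seed = 5)
  man <- cohort_manifest(1, 0, 0)
  expect_error(simulate_contacts(truth, "nope", depth = 10, seed = 1,
                                 manifest = man), "unknown sample")
  expect_error(simulate_contacts(truth, "M01", depth = 0, seed = 1,
                                 manifest = man), "depth")
  bad_bias <- data.frame(chrom = "chr1", start = 0, end = 10, factor = 10)
  expect_error(synthetic_truth(chrom_sizes = c(chr1 = 2e6), bias = bad_bias),
               "bias_range")
})
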