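# Promoter-enhancer pairing, normalization components and the connectivity
# score.

test_that("promoter zones are 2 kb and strand-oriented", {
  g <- gene_models(data.frame(gene_id = c("a", "b"), chrom = "chr1",
                              tss = c(10000L, 20000L), strand = c("+", "-")))
  expect_equal(g$prom_end - g$prom_start, c(2000L, 2000L))
  expect_equal(g$prom_start[1], 10000L - 1500L)
  expect_equal(g$prom_end[1], 10000L + 500L)
  expect_equal(g$prom_start[2], 20000L - 500L)
  expect_equal(g$prom_end[2], 20000L + 1500L)
})

test_that("pairing applies the distance window and excludes the promoter", {
  g <- gene_models(data.frame(gene_id = "g1", chrom = "chr1",
                              tss = 500000L, strand = "+"))
  peaks <- data.frame(
    peak_id = c("near", "far", "inprom"),
    chrom = "chr1",
    start = c(500000 + 150000, 500000 + 250000, 499500),
    end = c(500000 + 150400, 500000 + 250400, 499900)
  )
  out <- pair_promoter_enhancers(g, peaks, max_dist = 200000)
  expect_equal(out$peak_id, "near")
})

test_that("promoter mappability is an RPK ratio recovering planted bias", {
  g <- gene_models(data.frame(gene_id = "g1", chrom = "chr1",
                              tss = 100000L, strand = "+"))
  # uniform self-ligation coverage: regular endpoint grids cancel in RPK
  pos <- seq(50000, 150000, by = 100)
  uni <- make_contact_df("chr1", pos, pos + 400)
  expect_equal(promoter_mappability(uni, g), 1)
  # doubling promoter-zone coverage doubles the ratio: add 40 endpoints
  # strictly inside the zone (uniform zone coverage is 40)
  extra_pos <- seq(98600, by = 50, length.out = 20)
  extra <- make_contact_df("chr1", extra_pos, extra_pos + 400)
  expect_equal(promoter_mappability(rbind(uni, extra), g), 2)
  # zero neighborhood coverage -> undefined
  empty <- uni[0, ]
  expect_true(is.na(promoter_mappability(empty, g)))
  # planted bias is recovered on simulated data
  truth <- synthetic_truth(chrom_sizes = c(chr1 = 4e6), genes_per_mb = 1,
                           seed = 40)
  tss <- truth$genes$tss[1]
  truth$bias <- data.frame(chrom = "chr1", start = tss - 2500,
                           end = tss + 2500, factor = 3)
  rec <- simulate_contacts(truth, "S1", depth = 2e6, seed = 2,
                           stage = "mucosa")
  gm <- gene_models(truth$genes)
  m <- promoter_mappability(split_by_range(rec)$short, gm)
  expect_equal(m[1], 3, tolerance = 0.35)
  expect_equal(mean(m[-1]), 1, tolerance = 0.15)
})

test_that("background density is contacts per 1x1 kb ring square", {
  g <- gene_models(data.frame(gene_id = "g1", chrom = "chr1",
                              tss = 100000L, strand = "+"))
  # 900 long-range endpoints placed uniformly in the 5-50 kb ring:
  # 450 on each side -> D = 900 / 90 squares = 10
  right <- rep(seq(105000, 149500, length.out = 90), each = 5)
  left <- rep(seq(50500, 94500, length.out = 90), each = 5)
  ring_pos <- round(c(left, right))
  rec <- make_contact_df("chr1", ring_pos, ring_pos + 300000)
  d <- background_density(rec, g)
  expect_equal(d$density, 10)
  # doubling depth doubles the density
  d2 <- background_density(rbind(rec, rec), g)
  expect_equal(d2$density, 2 * d$density)
  # empty ring is floored and flagged
  far <- make_contact_df("chr1", 500000, 900000)
  d3 <- background_density(far, g)
  expect_true(d3$flagged)
  expect_equal(d3$density, 1 / 90)
})

test_that("connectivity composes raw / mappability / density", {
  g <- gene_models(data.frame(gene_id = "g1", chrom = "chr1",
                              tss = 100000L, strand = "+"))
  peaks <- data.frame(peak_id = "e1", chrom = "chr1",
                      start = 150000L, end = 150400L)
  pairs <- pair_promoter_enhancers(g, peaks)
  # uniform self-ligation -> M = 1
  selfpos <- seq(75000, 125000, by = 100)
  selfrec <- make_contact_df("chr1", selfpos, selfpos + 400)
  # 90 long endpoints in the ring -> D = 1 (one per square)
  ringpos <- round(c(seq(50500, 94500, length.out = 45),
                     seq(105500, 149500, length.out = 45)))
  ringrec <- make_contact_df("chr1", ringpos, ringpos + 400000)
  # 10 promoter-peak contacts
  pe <- make_contact_df("chr1", seq(99000, 99900, by = 100),
                        rep(150100, 10))
  rec <- rbind(selfrec, ringrec, pe)
  out <- connectivity(rec, g, pairs)
  expect_equal(out$n_pairs, 1L)
  expect_equal(out$raw_contacts, 10)
  # composition identity C = (raw / M) / D
  expect_equal(out$connectivity,
               (out$raw_contacts / out$mappability) / out$bg_density)
  expect_equal(out$mappability, 1, tolerance = 0.05)
  # no paired peaks -> zero connectivity
  out0 <- connectivity(rec, g, pairs[0, ])
  expect_equal(out0$connectivity, 0)
  expect_equal(out0$n_pairs, 0L)
})

test_that("connectivity tracks planted truth across genes and stages", {
  co <- fixture_cohort()
  genes <- gene_models(co$truth$genes)
  pairs <- pair_promoter_enhancers(genes, truth_peak_table(co$truth))
  ct <- connectivity(co$records[["M01"]], genes, pairs)
  expect_gte(nrow(ct), 200)
  expect_gt(cor(ct$connectivity, co$truth$genes$c_base,
                method = "spearman", use = "complete.obs"), 0.8)
  means <- sapply(c("M01", "P01", "A01"), function(s)
    mean(connectivity(co$records[[s]], genes, pairs)$connectivity,
         na.rm = TRUE))
  expect_true(means["M01"] > means["P01"] && means["P01"] > means["A01"])
})

test_that("connectivity is depth-invariant for well-paired genes", {
  co <- fixture_cohort()
  genes <- gene_models(co$truth$genes)
  pairs <- pair_promoter_enhancers(genes, truth_peak_table(co$truth))
  # a deeper sample so the normalization counts are informative
  deep <- simulate_contacts(co$truth, "M01", depth = 4e6, seed = 19,
                            manifest = co$manifest)
  full <- connectivity(deep, genes, pairs)
  half <- connectivity(subsample_contacts(deep, 0.5, seed = 77),
                       genes, pairs)
  # sampling tolerance: restrict to genes whose raw counts are informative
  sel <- full$n_pairs >= 3 & full$raw_contacts >= 80 &
    half$connectivity > 0
  expect_gt(sum(sel), 30)
  ratio <- half$connectivity[sel] / full$connectivity[sel]
  expect_gt(mean(ratio > 0.8 & ratio < 1.25), 0.9)
})

test_that("gene filtering removes all-stage-nonpositive genes and imputes", {
  tb <- function(conn, acc, stripe) {
    data.frame(gene_id = c("g1", "g2", "g3"), connectivity = conn,
               promoter_accessibility = acc,
               promoter_stripe_strength = stripe)
  }
  stages <- list(
    mucosa = tb(c(0, 2, 1), c(1, 1, 1), c(1, -0.2, 1)),
    polyp = tb(c(-1, 1, 1), c(1, 1, 1), c(1, 0.5, 1)),
    adenocarcinoma = tb(c(0, NA, 1), c(1, 1, 1), c(1, 0.1, 1))
  )
  out <- filter_gene_set(stages)
  # g1 has nonpositive connectivity in all three stages -> removed
  expect_equal(out$genes, c("g2", "g3"))
  # g2's negative stripe strength and missing connectivity become zero
  expect_equal(out$tables$mucosa$promoter_stripe_strength[1], 0)
  expect_equal(out$tables$adenocarcinoma$connectivity[1], 0)
  # all-positive gene unchanged
  expect_equal(out$tables$mucosa$connectivity[2], 1)
  expect_error(filter_gene_set(stages[1:2]), "three stages")
})
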