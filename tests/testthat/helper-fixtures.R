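# Shared fixtures: one simulated cohort built lazily and reused across test
# files, plus evaluation helpers for recovery metrics.

.fixture_env <- new.env(parent = emptyenv())

# Default-conditions cohort: 3 x 8 Mb genome, 2 samples per stage,
# 1e6 contacts per sample.
fixture_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    truth <- synthetic_truth(seed = 11)
    man <- cohort_manifest(2, 2, 2)
    recs <- lapply(stats::setNames(man$sample_id, man$sample_id),
                   function(s) simulate_contacts(truth, s, depth = 1e6,
                                                 seed = 3, manifest = man))
    .fixture_env$cohort <- list(truth = truth, manifest = man,
                                records = recs)
  }
  .fixture_env$cohort
}

fixture_stripes <- function() {
  if (is.null(.fixture_env$stripes)) {
    co <- fixture_cohort()
    .fixture_env$stripes <- lapply(co$records, call_sample_stripes,
                                   chrom_sizes = co$truth$chrom_sizes)
  }
  .fixture_env$stripes
}

# All planted anchor intervals: stripe anchors plus both anchors of every
# planted loop (loop anchors are focal distal-contact sources too).
truth_anchor_granges <- function(truth) {
  a <- truth$stripe_anchors
  l <- truth$loops
  GenomicRanges::reduce(c(
    GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start + 1, a$end)),
    GenomicRanges::GRanges(l$chrom, IRanges::IRanges(l$start1 + 1, l$end1)),
    GenomicRanges::GRanges(l$chrom, IRanges::IRanges(l$start2 + 1, l$end2))
  ))
}

anchors_granges <- function(anchors) {
  GenomicRanges::GRanges(anchors$chrom,
                         IRanges::IRanges(anchors$start + 1, anchors$end))
}

anchor_f1 <- function(anchors, truth) {
  called <- anchors_granges(anchors)
  planted <- truth_anchor_granges(truth)
  prec <- mean(IRanges::overlapsAny(called, planted))
  rec <- mean(IRanges::overlapsAny(planted, called))
  list(precision = prec, recall = rec, f1 = 2 * prec * rec / (prec + rec))
}

bp_jaccard <- function(a1, a2) {
  g1 <- anchors_granges(a1)
  g2 <- anchors_granges(a2)
  inter <- sum(IRanges::width(GenomicRanges::intersect(g1, g2)))
  uni <- sum(IRanges::width(GenomicRanges::union(g1, g2)))
  inter / uni
}

truth_peak_table <- function(truth) {
  rbind(truth$enhancers[c("peak_id", "gene_id", "chrom", "start", "end")],
        truth$decoys[c("peak_id", "gene_id", "chrom", "start", "end")])
}

# Independent brute-force upper-tail Poisson probability: direct pmf
# summation on the log scale, no calls into the distribution functions used
# by the implementation.
brute_poisson_upper <- function(observed, lambda) {
  if (observed <= 0) return(1)
  if (lambda == 0) return(0)
  k <- 0:(observed - 1)
  1 - sum(exp(-lambda + k * log(lambda) - lfactorial(k)))
}

make_contact_df <- function(chrom, pos1, pos2, strand1 = "+",
                            strand2 = "-") {
  n <- max(length(pos1), length(pos2))
  data.frame(chrom1 = rep_len(chrom, n), pos1 = as.integer(pos1),
             strand1 = rep_len(strand1, n),
             chrom2 = rep_len(chrom, n), pos2 = as.integer(pos2),
             strand2 = rep_len(strand2, n), stringsAsFactors = FALSE)
}

# Contact matrix builder for constructed APA / donut fixtures.
make_contact_matrix <- function(df, resolution, chrom_sizes) {
  structure(df, class = c("contact_matrix", "data.frame"),
            resolution = as.integer(resolution), chrom_sizes = chrom_sizes)
}

# Dense symmetric matrix -> COO contact_matrix (upper triangle).
dense_to_cm <- function(m, chrom = "chr1", resolution = 1000) {
  idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  df <- data.frame(chrom = chrom, bin1 = idx[, 1] - 1L, bin2 = idx[, 2] - 1L,
                   count = m[idx], stringsAsFactors = FALSE)
  make_contact_matrix(df, resolution,
                      stats::setNames(nrow(m) * resolution, chrom))
}
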