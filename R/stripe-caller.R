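#' Expected long-range count under the mappability-proportionality assumption
#'
#' The local long-range count of a bin is tested against
#' `(long_bg / short_bg) * short_local`: the short-range (self-ligation)
#' local count rescaled by the background long/short ratio. Because
#' self-ligation coverage tracks mappability but not distal interactivity,
#' mappability-driven over-representation cancels. Bins with `short_bg == 0`
#' carry no mappability estimate and return NA (they are marked unmappable
#' and excluded from testing).
#'
#' @param long_bg,short_bg Background-window long- and short-range counts.
#' @param short_local Local-window short-range count.
#' @return Expected local long-range count (NA where `short_bg == 0`).
#' @export
expected_count <- function(long_bg, short_bg, short_local) {
  if (any(long_bg < 0 | short_bg < 0 | short_local < 0, na.rm = TRUE))
    stop("counts must be nonnegative")
  out <- ifelse(short_bg == 0, NA_real_,
                (long_bg / short_bg) * short_local)
  out
}

#' Upper-tail Poisson p-values with Benjamini-Hochberg correction
#'
#' p = P(X >= observed | lambda = expected); q-values by BH across all
#' tested bins (one family per call, i.e. per sample).
#'
#' @param observed Observed counts.
#' @param expected Poisson means.
#' @return list(p, q).
#' @export
poisson_q <- function(observed, expected) {
  if (any(expected < 0, na.rm = TRUE)) stop("expected must be nonnegative")
  p <- stats::ppois(observed - 1, lambda = expected, lower.tail = FALSE)
  list(p = p, q = stats::p.adjust(p, method = "BH"))
}

#' Log fold-enrichment stripe strength
#'
#' `log10((observed + pseudo) / (expected + pseudo))`; the pseudo-count keeps
#' the value finite for empty bins.
#'
#' @param observed,expected Counts.
#' @param pseudo Pseudo-count (default 1).
#' @return Numeric strength.
#' @export
stripe_strength <- function(observed, expected, pseudo = 1) {
  log10((observed + pseudo) / (expected + pseudo))
}

#' Default stripe-calling parameters
#'
#' Long-range threshold 1.5 kb, short-range threshold 1 kb, 2-kb local and
#' 50-kb background windows at a 100-bp step.
#' @export
stripe_params <- function(long_min = 1500, short_max = 1000,
                          local_window = 2000, background_window = 50000,
                          step = 100, fdr = 0.01, pseudo = 1) {
  list(long_min = long_min, short_max = short_max,
       local_window = local_window, background_window = background_window,
       step = step, fdr = fdr, pseudo = pseudo)
}

#' Call per-sample stripe bin statistics
#'
#' For every `step`-sized bin of every chromosome, computes centered local
#' and background window counts of long- and short-range endpoint coverage,
#' the mappability-normalized expected count, the upper-tail Poisson q-value
#' (BH across all mappable bins of the sample) and the log fold-enrichment
#' strength. Bins whose background short-range count is zero are flagged
#' unmappable and excluded from significance testing.
#'
#' @param records Contact records of one sample.
#' @param chrom_sizes Named chromosome lengths.
#' @param params See [stripe_params()].
#' @return data.frame of class `stripe_bin_stats` with one row per bin:
#'   chrom, start, end, long_local, long_bg, short_local, short_bg,
#'   expected, p, q, strength, mappable.
#' @export
call_sample_stripes <- function(records, chrom_sizes,
                                params = stripe_params()) {
  if (!nrow(records)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), long_local = numeric(),
                      long_bg = numeric(), short_local = numeric(),
                      short_bg = numeric(), expected = numeric(),
                      p = numeric(), q = numeric(), strength = numeric(),
                      mappable = logical())
    class(out) <- c("stripe_bin_stats", "data.frame")
    return(out)
  }
  sp <- split_by_range(records, long_min = params$long_min,
                       short_max = params$short_max,
                       orientation_filter = TRUE)
  step <- params$step
  k_loc <- max(1L, round(params$local_window / step))
  k_bg <- max(1L, round(params$background_window / step))
  res <- lapply(names(chrom_sizes), function(ch) {
    L <- chrom_sizes[[ch]]
    if (L < params$background_window) {
      warning(sprintf("chromosome %s shorter than background window; skipped",
                      ch))
      return(NULL)
    }
    hl <- endpoint_histogram(endpoint_positions(sp$long, ch), L, step)
    hs <- endpoint_histogram(endpoint_positions(sp$short, ch), L, step)
    data.frame(
      chrom = ch,
      start = (seq_along(hl) - 1L) * step,
      end = pmin(L, seq_along(hl) * step),
      long_local = centered_rollsum(hl, k_loc),
      long_bg = centered_rollsum(hl, k_bg),
      short_local = centered_rollsum(hs, k_loc),
      short_bg = centered_rollsum(hs, k_bg),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(out) || !nrow(out)) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      long_local = numeric(), long_bg = numeric(),
                      short_local = numeric(), short_bg = numeric(),
                      expected = numeric(), p = numeric(), q = numeric(),
                      strength = numeric(), mappable = logical())
    class(out) <- c("stripe_bin_stats", "data.frame")
    return(out)
  }
  out$expected <- expected_count(out$long_bg, out$short_bg, out$short_local)
  out$mappable <- !is.na(out$expected)
  out$p <- NA_real_
  out$q <- NA_real_
  if (any(out$mappable)) {
    pq <- poisson_q(out$long_local[out$mappable],
                    out$expected[out$mappable])
    out$p[out$mappable] <- pq$p
    out$q[out$mappable] <- pq$q
  }
  out$strength <- ifelse(out$mappable,
                         stripe_strength(out$long_local, out$expected,
                                         params$pseudo),
                         NA_real_)
  class(out) <- c("stripe_bin_stats", "data.frame")
  out
}

#' Cross-sample consensus stripe anchors
#'
#' Counts, per bin, the samples whose stripe q-value is below `fdr`; bins
#' with at least `min_samples` hits are merged (adjacent or overlapping,
#' half-open interval arithmetic) and merged windows shorter than `min_size`
#' are dropped. Windows overlapping the blacklist are removed and only
#' chromosomes listed in `autosomes` (when given) are retained. Each anchor
#' carries the number of supporting samples (maximum per-bin hit count) and
#' the per-sample mean strength over its bins.
#'
#' @param per_sample List of `stripe_bin_stats` data.frames (one per
#'   sample); names are used as sample ids.
#' @param fdr q-value cutoff counting a sample hit.
#' @param min_samples Minimum number of supporting samples per bin.
#' @param min_size Minimum merged window size in bp.
#' @param blacklist Optional data.frame (chrom, start, end) of excluded
#'   regions.
#' @param autosomes Optional character vector of chromosomes to keep.
#' @return data.frame of class `stripe_anchors`: chrom, start, end,
#'   n_samples, mean_strength, plus one `strength.<sample>` column per
#'   sample.
#' @export
consensus_anchors <- function(per_sample, fdr = 0.01, min_samples = 3,
                              min_size = 500, blacklist = NULL,
                              autosomes = NULL) {
  if (length(per_sample) < min_samples)
    stop("fewer input samples than min_samples")
  if (is.null(names(per_sample)))
    names(per_sample) <- sprintf("s%02d", seq_along(per_sample))
  # Common chromosome universe so per-sample hit coverages are addable.
  all_ends <- do.call(rbind, lapply(per_sample, function(df)
    data.frame(chrom = df$chrom, end = df$end)))
  cs0 <- tapply(all_ends$end, all_ends$chrom, max)
  cs <- stats::setNames(as.integer(cs0), names(cs0))
  hit_cov <- lapply(per_sample, function(df) {
    hit <- !is.na(df$q) & df$q < fdr
    sub <- df[hit, , drop = FALSE]
    gr <- GenomicRanges::GRanges(
      seqnames = factor(sub$chrom, levels = names(cs)),
      ranges = IRanges::IRanges(start = sub$start + 1L, end = sub$end),
      seqlengths = cs
    )
    GenomicRanges::coverage(gr)
  })
  cov <- Reduce(`+`, hit_cov)
  grl <- lapply(names(cov), function(ch) {
    ir <- IRanges::ranges(IRanges::slice(cov[[ch]], lower = min_samples))
    GenomicRanges::GRanges(ch, ir)
  })
  gr <- GenomicRanges::reduce(suppressWarnings(do.call(c, grl)))
  gr <- gr[GenomicRanges::width(gr) >= min_size]
  if (!is.null(blacklist) && nrow(blacklist)) {
    bl <- df_to_granges(blacklist)
    gr <- gr[!IRanges::overlapsAny(gr, bl)]
  }
  if (!is.null(autosomes)) {
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) %in% autosomes]
  }
  out <- granges_to_df(gr)
  if (!nrow(out)) {
    out$n_samples <- integer()
    out$mean_strength <- numeric()
    class(out) <- c("stripe_anchors", "data.frame")
    return(out)
  }
  # Support count: maximum per-bp sample hit count within the anchor.
  out$n_samples <- vapply(seq_len(nrow(out)), function(i) {
    v <- cov[[out$chrom[i]]][(out$start[i] + 1):out$end[i]]
    as.integer(max(S4Vectors::runValue(v)))
  }, integer(1))
  # Per-sample mean strength over anchor bins.
  agr <- df_to_granges(out)
  for (s in names(per_sample)) {
    df <- per_sample[[s]]
    sgr <- df_to_granges(df[c("chrom", "start", "end")])
    hits <- GenomicRanges::findOverlaps(agr, sgr)
    ms <- tapply(df$strength[S4Vectors::subjectHits(hits)],
                 S4Vectors::queryHits(hits),
                 function(x) mean(x, na.rm = TRUE))
    col <- rep(NA_real_, nrow(out))
    col[as.integer(names(ms))] <- as.numeric(ms)
    out[[paste0("strength.", s)]] <- col
  }
  scols <- grep("^strength\\.", names(out))
  out$mean_strength <- rowMeans(out[, scols, drop = FALSE], na.rm = TRUE)
  out <- out[c("chrom", "start", "end", "n_samples", "mean_strength",
               names(out)[scols])]
  class(out) <- c("stripe_anchors", "data.frame")
  out
}

#' Raw interaction fold-enrichment track
#'
#' Per 100-bp bin ratio of long-range to short-range endpoint coverage,
#' `(long + pseudo) / (short + pseudo)`. This is the raw stripe strength
#' before normalization against the local background; by default it uses the
#' wider thresholds (> 2 kb long, < 1.5 kb short) of the mappability
#' diagnostic rather than the stripe-calling thresholds.
#'
#' @param records Contact records of one sample.
#' @param chrom Chromosome.
#' @param chrom_size Chromosome length.
#' @param long_min,short_max Distance thresholds (bp).
#' @param step Bin size (bp).
#' @param pseudo Pseudo-count.
#' @return `binned_track` of per-bin fold enrichment.
#' @export
interaction_fe_track <- function(records, chrom, chrom_size,
                                 long_min = 2000, short_max = 1500,
                                 step = 100, pseudo = 1) {
  if (long_min <= short_max) stop("long_min must exceed short_max")
  sp <- split_by_range(records, long_min = long_min, short_max = short_max,
                       orientation_filter = TRUE)
  hl <- endpoint_histogram(endpoint_positions(sp$long, chrom), chrom_size,
                           step)
  hs <- endpoint_histogram(endpoint_positions(sp$short, chrom), chrom_size,
                           step)
  structure(list(chrom = chrom, step = step, window = step,
                 start = (seq_along(hl) - 1L) * step,
                 values = (hl + pseudo) / (hs + pseudo)),
            class = "binned_track")
}
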