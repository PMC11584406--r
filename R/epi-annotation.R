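# Methylation state classification, differential methylation, ATAC
# consensus peaks and CRE priority annotation.

#' Mean methylation of a region
#'
#' Unweighted mean of the methylation percentages of all valid CpG sites
#' (coverage > 0) within the interval. Returns NA when the region contains
#' no valid CpG (such regions are excluded from classification).
#'
#' @param cpg_table data.frame with chrom, pos, pct_meth, coverage.
#' @param interval One-row data.frame (chrom, start, end), 0-based
#'   half-open.
#' @return Mean percentage or NA.
#' @export
region_methylation <- function(cpg_table, interval) {
  sel <- cpg_table$chrom == interval$chrom &
    cpg_table$pos >= interval$start & cpg_table$pos < interval$end &
    cpg_table$coverage > 0
  if (!any(sel)) return(NA_real_)
  mean(cpg_table$pct_meth[sel])
}

#' Classify a methylation state
#'
#' Mean < 25% is demethylated, > 40% methylated, the band in between
#' intermediate (and conventionally excluded from methyl-versus-demethyl
#' contrasts). Boundaries are strict as stated.
#'
#' @param mean_pct Mean methylation percentage(s).
#' @return Character vector in {demethylated, intermediate, methylated}
#'   (NA propagates).
#' @export
classify_state <- function(mean_pct) {
  ifelse(is.na(mean_pct), NA_character_,
         ifelse(mean_pct < 25, "demethylated",
                ifelse(mean_pct > 40, "methylated", "intermediate")))
}

#' Differential methylation between two groups of samples
#'
#' Per region, methylated and total CpG read counts are aggregated over all
#' CpGs and samples of each group and compared with a two-proportion z-test
#' (no continuity correction); p-values are BH-adjusted across regions. A
#' region is called hyper-/hypomethylated only when the group difference in
#' mean percentage exceeds `min_diff` percentage points AND the adjusted
#' q-value is below `fdr`; otherwise "NC". Degenerate counts give "NC".
#'
#' @param regions data.frame (region_id, chrom, start, end).
#' @param cpg_a,cpg_b CpG tables (chrom, pos, pct_meth, coverage) pooled
#'   over the samples of group A and B. Direction is B relative to A
#'   (delta = B - A).
#' @param min_diff Minimum absolute difference in percentage points.
#' @param fdr BH q-value threshold.
#' @return data.frame with per-region delta, p, q and
#'   change in {hypermethylated, hypomethylated, NC}.
#' @export
differential_methylation <- function(regions, cpg_a, cpg_b, min_diff = 15,
                                     fdr = 0.1) {
  agg <- function(cpg, rg) {
    sel <- cpg$chrom == rg$chrom & cpg$pos >= rg$start & cpg$pos < rg$end &
      cpg$coverage > 0
    tot <- sum(cpg$coverage[sel])
    meth <- sum(cpg$coverage[sel] * cpg$pct_meth[sel] / 100)
    pct <- if (any(sel)) mean(cpg$pct_meth[sel]) else NA_real_
    c(meth = meth, tot = tot, pct = pct)
  }
  n <- nrow(regions)
  delta <- p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- agg(cpg_a, regions[i, ])
    b <- agg(cpg_b, regions[i, ])
    if (a[["tot"]] == 0 || b[["tot"]] == 0) next
    delta[i] <- b[["pct"]] - a[["pct"]]
    x1 <- a[["meth"]]; n1 <- a[["tot"]]
    x2 <- b[["meth"]]; n2 <- b[["tot"]]
    ph <- (x1 + x2) / (n1 + n2)
    se <- sqrt(ph * (1 - ph) * (1 / n1 + 1 / n2))
    p[i] <- if (se == 0) 1 else
      2 * stats::pnorm(-abs((x2 / n2 - x1 / n1) / se))
  }
  q <- stats::p.adjust(p, method = "BH")
  change <- rep("NC", n)
  sig <- !is.na(delta) & !is.na(q) & abs(delta) > min_diff & q < fdr
  change[sig & delta > 0] <- "hypermethylated"
  change[sig & delta < 0] <- "hypomethylated"
  data.frame(region_id = regions$region_id, delta = delta, p = p, q = q,
             change = change, stringsAsFactors = FALSE)
}

#' Consensus accessible peaks across samples
#'
#' Counts, per 100-bp bin, the samples whose peaks overlap the bin; bins
#' with at least `min_hits` sample hits are merged and merged intervals
#' shorter than `min_size` are dropped.
#'
#' @param per_sample_peaks List of data.frames (chrom, start, end), one per
#'   sample.
#' @param min_hits Minimum supporting samples per bin.
#' @param min_size Minimum merged interval size (bp).
#' @param bin Bin size (bp).
#' @return data.frame (chrom, start, end) of consensus peaks.
#' @export
atac_consensus <- function(per_sample_peaks, min_hits = 3, min_size = 300,
                           bin = 100) {
  if (length(per_sample_peaks) < min_hits)
    stop("fewer samples than min_hits")
  all_pk <- do.call(rbind, lapply(per_sample_peaks,
                                  function(df) df[c("chrom", "start", "end")]))
  cs0 <- tapply(all_pk$end, all_pk$chrom, max)
  cs <- stats::setNames(as.integer(cs0), names(cs0))
  # Snap peaks outward to bin boundaries so hits are counted per bin.
  binned <- lapply(per_sample_peaks, function(df) {
    g <- GenomicRanges::GRanges(
      seqnames = factor(df$chrom, levels = names(cs)),
      IRanges::IRanges(start = (df$start %/% bin) * bin + 1,
                       end = as.integer(ceiling(df$end / bin)) * bin),
      seqlengths = stats::setNames(as.integer(ceiling(cs / bin)) * bin,
                                   names(cs))
    )
    GenomicRanges::coverage(GenomicRanges::reduce(g))
  })
  cov <- Reduce(`+`, binned)
  grl <- lapply(names(cov), function(ch) {
    ir <- IRanges::ranges(IRanges::slice(cov[[ch]], lower = min_hits))
    GenomicRanges::GRanges(ch, ir)
  })
  gr <- GenomicRanges::reduce(suppressWarnings(do.call(c, grl)))
  gr <- gr[GenomicRanges::width(gr) >= min_size]
  granges_to_df(gr)
}

#' Annotate intervals by cis-regulatory element priority
#'
#' Assigns each interval the first matching class in the reference priority
#' order (by default promoter > enhancer > CTCF > open chromatin);
#' non-overlapping intervals are "unannotated".
#'
#' @param intervals data.frame (chrom, start, end).
#' @param references Named list of reference interval data.frames in
#'   priority order, e.g. list(promoter=, enhancer=, ctcf=,
#'   open_chromatin=).
#' @return Character vector of classes.
#' @export
annotate_feature <- function(intervals, references) {
  gr <- df_to_granges(intervals)
  out <- rep("unannotated", length(gr))
  for (cls in rev(names(references))) {
    ref <- references[[cls]]
    if (is.null(ref) || !nrow(ref)) next
    hit <- IRanges::overlapsAny(gr, df_to_granges(ref))
    out[hit] <- cls
  }
  out
}
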