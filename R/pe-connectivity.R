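# Per-gene promoter-enhancer connectivity with mappability and coverage
# normalization, plus companion accessibility/stripe/methylation summaries.

#' Gene models with strand-oriented promoter zones
#'
#' The promoter interaction zone spans -1.5 kb to +0.5 kb around the TSS,
#' oriented by transcription direction (0-based half-open).
#'
#' @param genes data.frame with gene_id, chrom, tss, strand.
#' @return `genes` with added `prom_start`, `prom_end` columns.
#' @export
gene_models <- function(genes) {
  stopifnot_cols(genes, c("gene_id", "chrom", "tss", "strand"), "genes")
  z <- promoter_zones(genes)
  genes$prom_start <- z$start
  genes$prom_end <- z$end
  genes
}

#' Pair promoters with candidate distal enhancers
#'
#' Pairs every accessible peak lying within `max_dist` of the TSS with the
#' gene, excluding peaks that overlap the promoter zone itself (those are
#' promoter-proximal, not distal partners). Peaks that are other genes'
#' promoters are retained and labelled so promoter-promoter contacts can be
#' excluded downstream if desired.
#'
#' @param genes Output of [gene_models()].
#' @param peaks data.frame with peak_id, chrom, start, end (and optionally
#'   `type`).
#' @param max_dist Maximum TSS-to-peak distance (bp).
#' @return data.frame of (gene_id, peak_id) pairs with peak coordinates and
#'   a `peak_type` column.
#' @export
pair_promoter_enhancers <- function(genes, peaks, max_dist = 200000) {
  win <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1, genes$tss - max_dist + 1), genes$tss + max_dist)
  )
  pk <- df_to_granges(peaks)
  prom <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$prom_start + 1, genes$prom_end)
  )
  hits <- GenomicRanges::findOverlaps(win, pk, type = "any")
  gi <- S4Vectors::queryHits(hits)
  pi <- S4Vectors::subjectHits(hits)
  # Exclude peaks overlapping this gene's own promoter zone.
  in_prom <- IRanges::overlapsAny(pk[pi], prom[gi])
  gi <- gi[!in_prom]; pi <- pi[!in_prom]
  data.frame(
    gene_id = genes$gene_id[gi],
    peak_id = peaks$peak_id[pi],
    chrom = peaks$chrom[pi],
    start = peaks$start[pi],
    end = peaks$end[pi],
    peak_type = if ("type" %in% names(peaks)) peaks$type[pi] else NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Promoter mappability from self-ligation coverage
#'
#' Ratio of short-range self-ligation reads per kilobase in the promoter
#' zone versus the 50-kb neighborhood centered on the TSS (the per-million
#' factor of RPKM cancels in the ratio). The promoter zone itself is
#' excluded from the neighborhood denominator so the ratio is an unbiased
#' promoter-versus-surroundings contrast. Self-ligation coverage is
#' independent of distal interactivity, so this ratio isolates locus
#' mappability. A zero promoter count is floored at `pseudo` reads; zero
#' neighborhood coverage leaves the mappability undefined (NA, gene
#' flagged).
#'
#' @param short_records Short-range (self-ligation) contact records.
#' @param genes Output of [gene_models()].
#' @param neighborhood Neighborhood width (bp), centered on the TSS.
#' @param pseudo Floor for the promoter count.
#' @return Numeric vector of mappability ratios, one per gene.
#' @export
promoter_mappability <- function(short_records, genes, neighborhood = 50000,
                                 pseudo = 1) {
  half <- neighborhood %/% 2L
  out <- numeric(nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    pos <- sort(endpoint_positions(short_records, ch))
    cp <- count_in_intervals(pos, genes$prom_start[gi], genes$prom_end[gi])
    nb_s <- genes$tss[gi] - half
    nb_e <- genes$tss[gi] + half
    cn <- count_in_intervals(pos, nb_s, nb_e) - cp
    lp <- (genes$prom_end[gi] - genes$prom_start[gi]) / 1000
    ln <- (nb_e - nb_s) / 1000 - lp
    m <- (pmax(cp, pseudo) / lp) / (cn / ln)
    m[cn == 0] <- NA_real_
    out[gi] <- m
  }
  out
}

#' Long-range background contact density near a promoter
#'
#' Density of long-range contact endpoints in the 5-50 kb background region
#' flanking the TSS (both sides), in contacts per 1x1 kb square. This
#' per-sample density captures sequencing depth and local background level
#' without tying the estimate to the promoter's own mappability, and is the
#' between-sample coverage normalizer of the connectivity score.
#'
#' @param long_records Long-range contact records (distance > 1.5 kb).
#' @param genes Output of [gene_models()].
#' @param ring Inner and outer radii (bp) of the background region.
#' @param pseudo Floor count when the ring is empty (density flagged).
#' @return data.frame with columns `density` and `flagged`.
#' @export
background_density <- function(long_records, genes, ring = c(5000, 50000),
                               pseudo = 1) {
  out <- data.frame(density = numeric(nrow(genes)),
                    flagged = logical(nrow(genes)))
  n_sq <- 2 * (ring[2] - ring[1]) / 1000
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    pos <- sort(endpoint_positions(long_records, ch))
    cnt <- count_in_intervals(pos, genes$tss[gi] - ring[2],
                              genes$tss[gi] - ring[1]) +
      count_in_intervals(pos, genes$tss[gi] + ring[1],
                         genes$tss[gi] + ring[2])
    flag <- cnt == 0
    cnt[flag] <- pseudo
    out$density[gi] <- cnt / n_sq
    out$flagged[gi] <- flag
  }
  out
}

#' Per-gene promoter-enhancer connectivity for one sample
#'
#' Counts raw contacts between the promoter zone and each paired peak
#' (peak interval padded by `peak_pad` bp, both intervals expanded to
#' 1-kb bin boundaries), normalizes by the promoter mappability ratio and by
#' the long-range background density, and sums over peaks:
#' \deqn{C_g = \sum_{peaks} raw / M_g / D_g.}
#' Companion summaries: `n_pairs`, `enhancer_accessibility` (log10 of the
#' summed peak fold enrichments), and optionally `promoter_accessibility`
#' (from a per-bp fold-enrichment track), `promoter_stripe_strength` (mean
#' stripe strength over promoter bins) and `promoter_methylation` (mean CpG
#' percentage in the promoter zone).
#'
#' @param records Contact records of one sample.
#' @param genes Output of [gene_models()].
#' @param pairs Output of [pair_promoter_enhancers()].
#' @param peak_fe Optional named vector of per-peak fold enrichment for this
#'   sample (names = peak ids).
#' @param fe_track Optional data.frame (chrom, start, end, value) of per-bp
#'   accessibility fold enrichment (100-bp bins suffice).
#' @param stripe_stats Optional `stripe_bin_stats` for this sample.
#' @param methylation Optional CpG table (chrom, pos, pct_meth, coverage)
#'   for this sample.
#' @param resolution Bin size (bp) of raw contact extraction.
#' @param peak_pad Padding (bp) around peak intervals.
#' @param long_min Distance threshold defining long-range records for the
#'   background density.
#' @param params Stripe-calling parameters used for the short-range split.
#' @return data.frame of class `connectivity_table` with one row per gene.
#' @export
connectivity <- function(records, genes, pairs, peak_fe = NULL,
                         fe_track = NULL, stripe_stats = NULL,
                         methylation = NULL, resolution = 1000,
                         peak_pad = 500, long_min = 1500,
                         params = stripe_params()) {
  sp <- split_by_range(records, long_min = long_min,
                       short_max = params$short_max,
                       orientation_filter = TRUE)
  M <- promoter_mappability(sp$short, genes)
  D <- background_density(sp$long, genes)

  out <- data.frame(gene_id = genes$gene_id, connectivity = 0,
                    n_pairs = 0L, raw_contacts = 0,
                    mappability = M, bg_density = D$density,
                    flagged = is.na(M) | D$flagged,
                    stringsAsFactors = FALSE)

  pair_by_gene <- split(pairs, pairs$gene_id)
  for (ch in unique(genes$chrom)) {
    rec <- records[records$chrom1 == ch & records$chrom2 == ch, , drop = FALSE]
    o1 <- order(rec$pos1)
    p1 <- rec$pos1[o1]; q1 <- rec$pos2[o1]
    o2 <- order(rec$pos2)
    p2 <- rec$pos2[o2]; q2 <- rec$pos1[o2]
    gi <- which(genes$chrom == ch)
    for (g in gi) {
      gp <- pair_by_gene[[genes$gene_id[g]]]
      if (is.null(gp) || !nrow(gp)) next
      ps <- (genes$prom_start[g] %/% resolution) * resolution
      pe <- as.integer(ceiling(genes$prom_end[g] / resolution)) * resolution
      # Candidate contacts with an end in the (bin-expanded) promoter zone.
      i1 <- which(p1 >= ps & p1 < pe)
      i2 <- which(p2 >= ps & p2 < pe)
      other <- c(q1[i1], q2[i2])
      raw <- 0
      for (k in seq_len(nrow(gp))) {
        ks <- ((gp$start[k] - peak_pad) %/% resolution) * resolution
        ke <- as.integer(ceiling((gp$end[k] + peak_pad) / resolution)) *
          resolution
        raw <- raw + sum(other >= ks & other < ke)
      }
      out$raw_contacts[g] <- raw
      out$n_pairs[g] <- nrow(gp)
      if (!out$flagged[g]) {
        out$connectivity[g] <- (raw / M[g]) / D$density[g]
      } else {
        out$connectivity[g] <- NA_real_
      }
    }
  }
  out$connectivity[out$n_pairs == 0L] <- 0

  if (!is.null(peak_fe)) {
    fe_sum <- vapply(genes$gene_id, function(g) {
      gp <- pair_by_gene[[g]]
      if (is.null(gp)) return(0)
      sum(peak_fe[gp$peak_id], na.rm = TRUE)
    }, numeric(1))
    out$enhancer_accessibility <- ifelse(fe_sum > 0, log10(fe_sum), NA_real_)
  }
  if (!is.null(fe_track)) {
    out$promoter_accessibility <- promoter_accessibility(fe_track, genes)
  }
  if (!is.null(stripe_stats)) {
    out$promoter_stripe_strength <- promoter_stripe_strength(stripe_stats,
                                                             genes)
  }
  if (!is.null(methylation)) {
    zones <- data.frame(chrom = genes$chrom, start = genes$prom_start,
                        end = genes$prom_end)
    out$promoter_methylation <- vapply(seq_len(nrow(genes)), function(i)
      region_methylation(methylation, zones[i, ]), numeric(1))
  }
  class(out) <- c("connectivity_table", "data.frame")
  out
}

# Promoter accessibility: the mean of the two highest quartile means of the
# per-bp fold enrichment within the promoter zone, log10-transformed. This
# reads "top two quantiles of the mean fold change" as quartiles of the
# within-zone signal; configurable by pre-summarizing the track differently.
promoter_accessibility <- function(fe_track, genes) {
  vapply(seq_len(nrow(genes)), function(i) {
    sel <- fe_track$chrom == genes$chrom[i] &
      fe_track$end > genes$prom_start[i] & fe_track$start < genes$prom_end[i]
    v <- fe_track$value[sel]
    if (!length(v)) return(NA_real_)
    qs <- stats::quantile(v, c(0.5, 0.75))
    top2 <- c(mean(v[v >= qs[2]]),
              mean(v[v >= qs[1] & v < qs[2]]))
    top2 <- top2[is.finite(top2)]
    if (!length(top2)) return(NA_real_)
    log10(mean(top2))
  }, numeric(1))
}

promoter_stripe_strength <- function(stripe_stats, genes) {
  vapply(seq_len(nrow(genes)), function(i) {
    sel <- stripe_stats$chrom == genes$chrom[i] &
      stripe_stats$end > genes$prom_start[i] &
      stripe_stats$start < genes$prom_end[i]
    v <- stripe_stats$strength[sel]
    if (!length(v) || all(is.na(v))) return(NA_real_)
    mean(v, na.rm = TRUE)
  }, numeric(1))
}

#' Filter the gene set across stages and impute nonpositive values
#'
#' Removes genes for which any of P-E connectivity, promoter accessibility
#' or promoter stripe strength is nonpositive (or missing) in all three
#' stages; for the retained genes, missing or negative values are replaced
#' with zero.
#'
#' @param stage_tables Named list (one element per stage) of data.frames
#'   with gene_id, connectivity, promoter_accessibility,
#'   promoter_stripe_strength.
#' @return list(genes = retained gene ids, tables = zero-imputed stage
#'   tables).
#' @export
filter_gene_set <- function(stage_tables) {
  if (length(stage_tables) < 3) stop("three stages required")
  feats <- c("connectivity", "promoter_accessibility",
             "promoter_stripe_strength")
  ids <- stage_tables[[1]]$gene_id
  drop <- rep(FALSE, length(ids))
  for (f in feats) {
    vals <- sapply(stage_tables, function(tb)
      tb[[f]][match(ids, tb$gene_id)])
    nonpos <- is.na(vals) | vals <= 0
    drop <- drop | apply(nonpos, 1, all)
  }
  keep_ids <- ids[!drop]
  tables <- lapply(stage_tables, function(tb) {
    tb <- tb[match(keep_ids, tb$gene_id), , drop = FALSE]
    for (f in feats) {
      v <- tb[[f]]
      v[is.na(v) | v < 0] <- 0
      tb[[f]] <- v
    }
    rownames(tb) <- NULL
    tb
  })
  list(genes = keep_ids, tables = tables)
}
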