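#' Construct a synthetic ground truth for a multi-stage cohort
#'
#' Builds the planted "truth" object from which contact maps, accessibility
#' peaks, methylation tables and expression tables are simulated. The truth
#' holds a small genome, gene models with promoter stripe anchors, distal
#' enhancers, focal loops, an optional multiplicative mappability bias
#' \eqn{b(x)}, a distance-decay exponent \eqn{\alpha} for the background
#' (\eqn{P(d) \propto d^{-\alpha}}), and per-stage attenuation multipliers
#' applied to stripe and loop intensities.
#'
#' Expression follows the saturating two-phase rule
#' \deqn{E_g = \beta_g \min(C_g, C_{sat}) + \epsilon,}
#' so that in the unattenuated (mucosa) stage most genes sit above the
#' saturation point \eqn{C_{sat}} while attenuated stages push genes into the
#' connectivity-limited regime.
#'
#' @param chrom_sizes Named integer vector of chromosome lengths (bp).
#'   Coordinates are 0-based half-open throughout.
#' @param genes_per_mb Gene density; genes are laid out on a jittered grid.
#' @param enhancers_per_gene Number of distal enhancers planted per gene
#'   within roughly 15-150 kb of the TSS.
#' @param decoys_per_mb Density of accessible peaks not paired to any gene.
#' @param distal_anchors_per_mb Density of non-genic (CTCF-like) stripe
#'   anchors.
#' @param decay_exponent Background distance-decay exponent \eqn{\alpha}.
#' @param stage_attenuation Named multipliers on stripe/loop intensity per
#'   stage; the reference stage ("mucosa") must be 1.
#' @param accessibility_attenuation Milder per-stage multipliers applied to
#'   accessibility signal, reflecting that accessibility loss is marginal
#'   compared to connectivity loss.
#' @param c_sat Saturation point of the two-phase expression rule, in
#'   baseline connectivity units.
#' @param mix Named mixture weights of emitted contact classes
#'   (background, stripe, loop, self).
#' @param stripe_reach Maximum sliding distance (bp) of stripe contacts from
#'   their anchor.
#' @param anchor_width Width (bp) of planted stripe anchors.
#' @param d_max Truncation distance of the background decay (bp).
#' @param bias Optional data.frame (chrom, start, end, factor) of
#'   multiplicative mappability bias intervals; factor must lie in
#'   `bias_range`. Outside these intervals \eqn{b(x) = 1}.
#' @param bias_range Allowed range for bias factors.
#' @param expr_noise_frac Additive expression noise s.d. as a fraction of the
#'   gene's saturated expression level.
#' @param sample_cv Lognormal coefficient of variation of per-sample anchor
#'   strength jitter.
#' @param seed Integer seed; the truth is fully deterministic given it.
#'
#' @return An object of class `synthetic_truth`: a list with elements
#'   `chrom_sizes`, `genes`, `enhancers`, `decoys`, `stripe_anchors`,
#'   `loops`, `bias` and `params`.
#' @export
synthetic_truth <- function(chrom_sizes = c(chr1 = 8e6, chr2 = 8e6, chr3 = 8e6),
                            genes_per_mb = 10,
                            enhancers_per_gene = 3,
                            decoys_per_mb = 3,
                            distal_anchors_per_mb = 2,
                            decay_exponent = 1,
                            stage_attenuation = c(mucosa = 1, polyp = 0.6,
                                                  adenocarcinoma = 0.4),
                            accessibility_attenuation = c(mucosa = 1,
                                                          polyp = 0.95,
                                                          adenocarcinoma = 0.88),
                            c_sat = 1,
                            mix = c(background = 0.50, stripe = 0.20,
                                    loop = 0.05, self = 0.25),
                            stripe_reach = 1e5,
                            anchor_width = 800,
                            d_max = 2e6,
                            bias = NULL,
                            bias_range = c(0.3, 3),
                            expr_noise_frac = 0.15,
                            sample_cv = 0.1,
                            seed = 1) {
  chrom_sizes <- as.integer(chrom_sizes)
  names(chrom_sizes) <- names(chrom_sizes) %||% paste0("chr", seq_along(chrom_sizes))
  if (any(chrom_sizes <= 0)) stop("zero-length chromosome in chrom_sizes")
  if (is.na(stage_attenuation["mucosa"]) || stage_attenuation["mucosa"] != 1)
    stop("stage_attenuation must contain mucosa = 1")
  if (any(stage_attenuation <= 0 | stage_attenuation > 1))
    stop("stage_attenuation values must lie in (0, 1]")
  mix <- mix / sum(mix)

  if (!is.null(bias)) {
    stopifnot_cols(bias, c("chrom", "start", "end", "factor"), "bias")
    if (any(bias$factor < bias_range[1] | bias$factor > bias_range[2]))
      stop("bias factors outside declared bias_range")
    if (any(!bias$chrom %in% names(chrom_sizes)))
      stop("bias interval on unknown chromosome")
  }

  with_seed(seed, {
    margin <- 260000  # keep genes clear of edges: reach + background windows
    genes <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
      L <- chrom_sizes[[ch]]
      n <- max(1L, round(genes_per_mb * L / 1e6))
      spacing <- (L - 2 * margin) / n
      tss <- as.integer(margin + (seq_len(n) - 0.5) * spacing +
                          round(stats::runif(n, -0.08, 0.08) * spacing))
      data.frame(chrom = ch, tss = tss, stringsAsFactors = FALSE)
    }))
    n_genes <- nrow(genes)
    genes$gene_id <- sprintf("g%04d", seq_len(n_genes))
    genes$strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    genes$c_base <- stats::rlnorm(n_genes, meanlog = log(2), sdlog = 0.7)
    genes$beta <- stats::rlnorm(n_genes, meanlog = log(20), sdlog = 0.8)

    # Promoter methylation truth: mostly demethylated promoters, a methylated
    # minority; in advanced stages a low-connectivity subset gains methylation
    # and a small methylated subset loses it.
    demeth <- stats::runif(n_genes) < 0.7
    base_meth <- ifelse(demeth, stats::runif(n_genes, 5, 18),
                        stats::runif(n_genes, 45, 75))
    low_c <- genes$c_base < stats::quantile(genes$c_base, 0.3)
    hyper <- demeth & low_c & stats::runif(n_genes) < 0.35
    hypo <- !demeth & stats::runif(n_genes) < 0.15
    genes$meth_mucosa <- base_meth
    genes$meth_polyp <- pmin(95, pmax(1, base_meth + ifelse(hyper, 18, 0) -
                                        ifelse(hypo, 18, 0)))
    genes$meth_adenocarcinoma <- pmin(95, pmax(1, base_meth +
                                                 ifelse(hyper, 35, 0) -
                                                 ifelse(hypo, 32, 0)))

    # Distal enhancers per gene, avoiding the promoter neighborhood.
    enh <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
      off <- sample(c(-1, 1), enhancers_per_gene, replace = TRUE) *
        round(stats::runif(enhancers_per_gene, 15000, 150000))
      center <- genes$tss[i] + off
      data.frame(
        gene_id = genes$gene_id[i], chrom = genes$chrom[i],
        start = as.integer(center - 200), end = as.integer(center + 200),
        fe = pmax(1, genes$beta[i] / 4 *
                    stats::rlnorm(enhancers_per_gene, 0, 0.3)),
        stringsAsFactors = FALSE
      )
    }))
    enh$peak_id <- sprintf("e%05d", seq_len(nrow(enh)))

    # Decoy accessible peaks unrelated to any gene.
    decoys <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
      L <- chrom_sizes[[ch]]
      n <- max(0L, round(decoys_per_mb * L / 1e6))
      if (n == 0L) return(NULL)
      center <- as.integer(round(stats::runif(n, margin, L - margin)))
      data.frame(gene_id = rep(NA_character_, n), chrom = ch,
                 start = center - 200L, end = center + 200L,
                 fe = stats::rlnorm(n, log(3), 0.4),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(decoys)) {
      decoys <- data.frame(gene_id = character(), chrom = character(),
                           start = integer(), end = integer(),
                           fe = numeric(), stringsAsFactors = FALSE)
    }
    if (nrow(decoys)) decoys$peak_id <- sprintf("d%05d", seq_len(nrow(decoys)))
    else decoys$peak_id <- character()

    # Stripe anchors: every gene promoter plus non-genic distal anchors.
    half_w <- round(anchor_width / 2)
    prom_anchor <- data.frame(
      chrom = genes$chrom,
      start = as.integer(genes$tss - half_w),
      end = as.integer(genes$tss + half_w),
      strength = genes$c_base, type = "promoter", gene_id = genes$gene_id,
      stringsAsFactors = FALSE
    )
    distal_anchor <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
      L <- chrom_sizes[[ch]]
      n <- max(0L, round(distal_anchors_per_mb * L / 1e6))
      if (n == 0L) return(NULL)
      center <- as.integer(round(stats::runif(n, margin, L - margin)))
      data.frame(chrom = ch, start = center - half_w, end = center + half_w,
                 strength = stats::rlnorm(n, log(2), 0.7),
                 type = "distal", gene_id = rep(NA_character_, n),
                 stringsAsFactors = FALSE)
    }))
    anchors <- rbind(prom_anchor, distal_anchor)
    anchors$anchor_id <- sprintf("a%04d", seq_len(nrow(anchors)))

    # Loops: one promoter-enhancer loop per gene (to its first enhancer) and
    # CTCF-like loops between random distal anchor pairs on the same chrom.
    first_enh <- enh[!duplicated(enh$gene_id), ]
    first_enh <- first_enh[match(genes$gene_id, first_enh$gene_id), ]
    pe_loops <- data.frame(
      chrom = genes$chrom,
      start1 = prom_anchor$start, end1 = prom_anchor$end,
      start2 = first_enh$start, end2 = first_enh$end,
      enrichment = genes$c_base, type = "pe", gene_id = genes$gene_id,
      stringsAsFactors = FALSE
    )
    ctcf_loops <- if (is.null(distal_anchor)) NULL else
      do.call(rbind, lapply(split(distal_anchor, distal_anchor$chrom),
                                        function(da) {
      if (nrow(da) < 2) return(NULL)
      n <- max(1L, nrow(da) %/% 2)
      i <- sample(nrow(da), n)
      j <- sample(nrow(da), n)
      keep <- i != j
      i <- i[keep]; j <- j[keep]
      ii <- pmin(i, j); jj <- pmax(i, j)
      data.frame(chrom = da$chrom[1],
                 start1 = da$start[ii], end1 = da$end[ii],
                 start2 = da$start[jj], end2 = da$end[jj],
                 enrichment = stats::rlnorm(length(ii), log(2), 0.5),
                 type = "ctcf", gene_id = NA_character_,
                 stringsAsFactors = FALSE)
    }))
    loops <- rbind(pe_loops, ctcf_loops)
    swap <- loops$start1 > loops$start2
    if (any(swap)) {
      tmp <- loops[swap, c("start1", "end1")]
      loops[swap, c("start1", "end1")] <- loops[swap, c("start2", "end2")]
      loops[swap, c("start2", "end2")] <- tmp
    }
    loops <- loops[loops$end1 <= loops$start2, ]
    loops$loop_id <- sprintf("l%04d", seq_len(nrow(loops)))

    truth <- structure(list(
      chrom_sizes = chrom_sizes,
      genes = genes,
      enhancers = enh,
      decoys = decoys,
      stripe_anchors = anchors,
      loops = loops,
      bias = bias,
      params = list(
        decay_exponent = decay_exponent,
        stage_attenuation = stage_attenuation,
        accessibility_attenuation = accessibility_attenuation,
        c_sat = c_sat, mix = mix,
        stripe_reach = stripe_reach, anchor_width = anchor_width,
        d_min = 1000, d_max = d_max,
        self_min = 100, self_max = 999,
        bias_range = bias_range,
        expr_noise_frac = expr_noise_frac,
        sample_cv = sample_cv,
        seed = seed
      )
    ), class = "synthetic_truth")
    validate_truth(truth)
    truth
  })
}

validate_truth <- function(truth) {
  cs <- truth$chrom_sizes
  chk <- function(df, what) {
    if (is.null(df) || !nrow(df)) return(invisible())
    if (any(df$start < 0) || any(df$end > cs[df$chrom]))
      stop(sprintf("%s intervals exceed chromosome bounds", what))
  }
  chk(truth$stripe_anchors, "stripe anchor")
  chk(truth$enhancers, "enhancer")
  chk(truth$bias, "bias")
  invisible(truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic cohort truth\n")
  cat(sprintf("  genome: %d chromosome(s), %.1f Mb total\n",
              length(x$chrom_sizes), sum(x$chrom_sizes) / 1e6))
  cat(sprintf("  genes: %d  enhancers: %d  stripe anchors: %d  loops: %d\n",
              nrow(x$genes), nrow(x$enhancers), nrow(x$stripe_anchors),
              nrow(x$loops)))
  at <- x$params$stage_attenuation
  cat(sprintf("  stage attenuation: %s\n",
              paste(sprintf("%s=%.2f", names(at), at), collapse = ", ")))
  cat(sprintf("  decay exponent: %.2f  C_sat: %.2f\n",
              x$params$decay_exponent, x$params$c_sat))
  if (!is.null(x$bias)) {
    cat(sprintf("  mappability bias intervals: %d (factors %.2f-%.2f)\n",
                nrow(x$bias), min(x$bias$factor), max(x$bias$factor)))
  }
  invisible(x)
}

#' Sample manifest for a simulated cohort
#'
#' The default cohort shape mirrors a three-stage colon study design:
#' 7 mucosa, 19 polyp and 7 adenocarcinoma samples. Scale the counts down for
#' desk-size experiments.
#'
#' @param n_mucosa,n_polyp,n_adenocarcinoma Number of samples per stage.
#' @return data.frame with columns `sample_id` and `stage`.
#' @export
cohort_manifest <- function(n_mucosa = 7, n_polyp = 19, n_adenocarcinoma = 7) {
  data.frame(
    sample_id = c(sprintf("M%02d", seq_len(n_mucosa)),
                  sprintf("P%02d", seq_len(n_polyp)),
                  sprintf("A%02d", seq_len(n_adenocarcinoma))),
    stage = rep(c("mucosa", "polyp", "adenocarcinoma"),
                c(n_mucosa, n_polyp, n_adenocarcinoma)),
    stringsAsFactors = FALSE
  )
}

# Evaluate the planted mappability bias b(x) at integer positions.
bias_at <- function(truth, chrom, pos) {
  b <- rep(1, length(pos))
  bi <- truth$bias
  if (is.null(bi) || !nrow(bi)) return(b)
  bi <- bi[bi$chrom == chrom, , drop = FALSE]
  for (k in seq_len(nrow(bi))) {
    hit <- pos >= bi$start[k] & pos < bi$end[k]
    b[hit] <- b[hit] * bi$factor[k]
  }
  b
}

max_bias <- function(truth) {
  if (is.null(truth$bias) || !nrow(truth$bias)) 1 else max(1, truth$bias$factor)
}
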