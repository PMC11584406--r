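#' Simulate a pair-level contact stream for one sample
#'
#' Emits intra-chromosomal contact records with four components: (a) a
#' distance-decay background with density proportional to \eqn{d^{-\alpha}}
#' truncated at `d_max`; (b) stripe contacts between a planted anchor and
#' uniformly sliding positions within the stripe reach window; (c) focal loop
#' contacts between planted anchor pairs; and (d) short-range self-ligation
#' pairs (distance < 1 kb, inward +/- orientation).
#'
#' The planted mappability bias acts multiplicatively on acceptance: a
#' long-range pair with ends at \eqn{x_1, x_2} is retained with probability
#' proportional to \eqn{b(x_1) b(x_2)}, so endpoint coverage at a locus scales
#' as \eqn{b(x)}; self-ligation pairs are emitted at a final rate proportional
#' to \eqn{b(x)}. Long- and short-range coverage therefore scale
#' proportionally with the bias, which is exactly the assumption the stripe
#' caller's expected-count normalization exploits.
#'
#' Stripe and loop intensities are multiplied by the stage attenuation of the
#' sample's stage, and per-anchor strengths receive a per-sample lognormal
#' jitter (seeded by the sample id) to emulate biological variation across a
#' cohort.
#'
#' @param truth A [synthetic_truth()] object.
#' @param sample_id Sample identifier; must appear in `manifest` unless
#'   `stage` is given directly.
#' @param depth Nominal number of contacts drawn before bias thinning.
#' @param seed Integer base seed; combined with `sample_id` so every sample
#'   draws an independent reproducible stream.
#' @param manifest data.frame (sample_id, stage), e.g. [cohort_manifest()].
#' @param stage Stage name, overriding the manifest lookup.
#' @return data.frame of contact records with columns chrom1, pos1, strand1,
#'   chrom2, pos2, strand2, in canonical order (pos1 <= pos2), plus
#'   attributes `sample_id` and `stage`.
#' @export
simulate_contacts <- function(truth, sample_id, depth, seed,
                              manifest = NULL, stage = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (depth <= 0) stop("depth must be positive")
  if (is.null(stage)) {
    if (is.null(manifest)) stop("either manifest or stage must be supplied")
    i <- match(sample_id, manifest$sample_id)
    if (is.na(i)) stop(sprintf("unknown sample '%s'", sample_id))
    stage <- manifest$stage[i]
  }
  atten <- truth$params$stage_attenuation
  if (!stage %in% names(atten)) stop(sprintf("unknown stage '%s'", stage))
  a_s <- atten[[stage]]
  p <- truth$params
  cs <- truth$chrom_sizes
  bmax <- max_bias(truth)

  with_seed(sub_seed(seed, sample_id), {
    has_stripes <- nrow(truth$stripe_anchors) > 0
    has_loops <- nrow(truth$loops) > 0
    w <- p$mix
    if (!has_stripes) w["stripe"] <- 0
    if (!has_loops) w["loop"] <- 0
    w <- w / sum(w)
    n <- stats::rpois(4, depth * w)
    names(n) <- names(w)

    # Per-sample jitter of anchor/loop intensities.
    a_str <- truth$stripe_anchors$strength *
      stats::rlnorm(nrow(truth$stripe_anchors), 0, p$sample_cv)
    l_str <- truth$loops$enrichment *
      stats::rlnorm(nrow(truth$loops), 0, p$sample_cv)

    parts <- list(
      sim_background(n[["background"]], cs, p),
      if (has_stripes) sim_stripes(round(n[["stripe"]] * a_s),
                                   truth$stripe_anchors, a_str, cs, p),
      if (has_loops) sim_loops(round(n[["loop"]] * a_s),
                               truth$loops, l_str),
      sim_self(n[["self"]], cs, p)
    )
    rec <- do.call(rbind, parts[!vapply(parts, is.null, TRUE)])

    # Bias thinning: b(x1) b(x2) / bmax^2 for long-range classes; self pairs
    # carry a single b(x) factor (their ends share a locus).
    if (!is.null(truth$bias) && nrow(truth$bias) && nrow(rec)) {
      keep <- rep(TRUE, nrow(rec))
      for (ch in unique(rec$chrom1)) {
        idx <- which(rec$chrom1 == ch)
        is_self <- rec$class[idx] == "self"
        pr <- ifelse(is_self,
                     bias_at(truth, ch, rec$pos1[idx]) / bmax,
                     bias_at(truth, ch, rec$pos1[idx]) *
                       bias_at(truth, ch, rec$pos2[idx]) / bmax^2)
        keep[idx] <- stats::runif(length(idx)) < pr
      }
      rec <- rec[keep, , drop = FALSE]
    }
    rec$class <- NULL

    # Canonical order pos1 <= pos2.
    swap <- rec$pos1 > rec$pos2
    if (any(swap)) {
      tmp_p <- rec$pos1[swap]; tmp_s <- rec$strand1[swap]
      rec$pos1[swap] <- rec$pos2[swap]; rec$strand1[swap] <- rec$strand2[swap]
      rec$pos2[swap] <- tmp_p; rec$strand2[swap] <- tmp_s
    }
    rec <- rec[order(rec$chrom1, rec$pos1, rec$pos2), , drop = FALSE]
    rownames(rec) <- NULL
    attr(rec, "sample_id") <- sample_id
    attr(rec, "stage") <- stage
    rec
  })
}

# Truncated power-law distances: density proportional to d^-alpha on
# [d_min, d_max], drawn by inverse CDF.
rpowerlaw <- function(n, alpha, d_min, d_max) {
  u <- stats::runif(n)
  if (abs(alpha - 1) < 1e-12) {
    d_min * (d_max / d_min)^u
  } else {
    e <- 1 - alpha
    (u * (d_max^e - d_min^e) + d_min^e)^(1 / e)
  }
}

new_records <- function(chrom, pos1, pos2, strand1 = NULL, strand2 = NULL,
                        class) {
  n <- length(pos1)
  data.frame(
    chrom1 = chrom, pos1 = as.integer(round(pos1)),
    strand1 = strand1 %||% sample(c("+", "-"), n, replace = TRUE),
    chrom2 = chrom, pos2 = as.integer(round(pos2)),
    strand2 = strand2 %||% sample(c("+", "-"), n, replace = TRUE),
    class = class, stringsAsFactors = FALSE
  )
}

sim_background <- function(n, cs, p) {
  if (n <= 0) return(NULL)
  ch <- sample(names(cs), n, replace = TRUE, prob = cs / sum(cs))
  x1 <- floor(stats::runif(n) * (cs[ch] - 1))
  d <- round(rpowerlaw(n, p$decay_exponent, p$d_min, p$d_max))
  side <- sample(c(-1, 1), n, replace = TRUE)
  x2 <- x1 + side * d
  ok <- x2 >= 0 & x2 < cs[ch]
  new_records(ch[ok], x1[ok], x2[ok], class = "background")
}

sim_stripes <- function(n, anchors, strength, cs, p) {
  if (n <= 0 || !nrow(anchors)) return(NULL)
  i <- sample(nrow(anchors), n, replace = TRUE, prob = strength)
  x1 <- anchors$start[i] +
    floor(stats::runif(n) * (anchors$end[i] - anchors$start[i]))
  d <- round(stats::runif(n, 2000, p$stripe_reach))
  side <- sample(c(-1, 1), n, replace = TRUE)
  x2 <- x1 + side * d
  ch <- anchors$chrom[i]
  ok <- x2 >= 0 & x2 < cs[ch]
  new_records(ch[ok], x1[ok], x2[ok], class = "stripe")
}

sim_loops <- function(n, loops, strength) {
  if (n <= 0 || !nrow(loops)) return(NULL)
  i <- sample(nrow(loops), n, replace = TRUE, prob = strength)
  x1 <- loops$start1[i] +
    floor(stats::runif(n) * (loops$end1[i] - loops$start1[i]))
  x2 <- loops$start2[i] +
    floor(stats::runif(n) * (loops$end2[i] - loops$start2[i]))
  new_records(loops$chrom[i], x1, x2, class = "loop")
}

sim_self <- function(n, cs, p) {
  if (n <= 0) return(NULL)
  ch <- sample(names(cs), n, replace = TRUE, prob = cs / sum(cs))
  x1 <- floor(stats::runif(n) * (cs[ch] - p$self_max - 1))
  d <- floor(stats::runif(n, p$self_min, p$self_max + 1))
  # Inward orientation: +/- on the canonical (left, right) ends.
  new_records(ch, x1, x1 + d, strand1 = "+", strand2 = "-", class = "self")
}
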