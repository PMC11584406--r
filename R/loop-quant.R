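# Loop-strength quantification against donut backgrounds, priority merging
# of multi-source loop lists, stage-positive calls and APA.

# Dense symmetric window of a contact_matrix around bin center (i0, j0),
# rows i0 +/- half, cols j0 +/- half. COO triplets are upper-triangular;
# pixel (p, q) receives the count stored at (min, max).
dense_window <- function(sub, i0, j0, half) {
  n <- 2L * half + 1L
  ilo <- i0 - half; jlo <- j0 - half
  m <- matrix(0, n, n)
  lo <- min(ilo, jlo); hi <- max(i0, j0) + half
  s <- sub[sub$bin1 <= hi & sub$bin2 >= lo, , drop = FALSE]
  if (!nrow(s)) return(m)
  in_i1 <- s$bin1 >= ilo & s$bin1 < ilo + n
  in_j2 <- s$bin2 >= jlo & s$bin2 < jlo + n
  a <- which(in_i1 & in_j2)
  if (length(a)) {
    idx <- cbind(s$bin1[a] - ilo + 1L, s$bin2[a] - jlo + 1L)
    m[idx] <- m[idx] + s$count[a]
  }
  in_i2 <- s$bin2 >= ilo & s$bin2 < ilo + n
  in_j1 <- s$bin1 >= jlo & s$bin1 < jlo + n
  b <- which(in_i2 & in_j1 & s$bin1 != s$bin2)
  if (length(b)) {
    idx <- cbind(s$bin2[b] - ilo + 1L, s$bin1[b] - jlo + 1L)
    m[idx] <- m[idx] + s$count[b]
  }
  m
}

#' Log fold-change loop strength
#'
#' `log10((observed + pseudo) / (donut_expected + pseudo))`. The pseudo-count
#' is applied unconditionally to both terms for determinism.
#'
#' @param observed Observed count at the loop pixel(s).
#' @param donut_expected Expected count from the donut background.
#' @param pseudo Pseudo-count.
#' @return Numeric strength.
#' @export
loop_strength <- function(observed, donut_expected, pseudo = 1) {
  if (any(observed < 0 | donut_expected < 0, na.rm = TRUE))
    stop("counts must be nonnegative")
  log10((observed + pseudo) / (donut_expected + pseudo))
}

#' Quantify loops on a contact matrix against a donut background
#'
#' For each loop (anchor interval pair) the observed count is the sum over
#' the bin rectangle spanned by the anchors; the expected count is the mean
#' pixel intensity of the donut ring around the rectangle center (Chebyshev
#' radius in `(inner, outer]` bins, excluding the center row and column),
#' scaled to the rectangle's pixel count. Loops whose donut window leaves the
#' matrix bounds are flagged and get NA strength.
#'
#' @param cm A `contact_matrix`.
#' @param loops data.frame with chrom, start1, end1, start2, end2 (bp,
#'   0-based half-open; anchor1 upstream of anchor2).
#' @param inner,outer Donut radii in bins at the matrix resolution.
#' @param pseudo Pseudo-count for the strength transform.
#' @return `loops` with added columns observed, expected, strength, flagged.
#' @export
loop_quantify <- function(cm, loops, inner = 2, outer = 10, pseudo = 1) {
  res <- attr(cm, "resolution")
  cs <- attr(cm, "chrom_sizes")
  loops$observed <- NA_real_
  loops$expected <- NA_real_
  loops$flagged <- FALSE
  by_chrom <- split(seq_len(nrow(loops)), loops$chrom)
  for (ch in names(by_chrom)) {
    sub <- cm[cm$chrom == ch, , drop = FALSE]
    nb <- as.integer(ceiling(cs[[ch]] / res))
    for (i in by_chrom[[ch]]) {
      b1l <- loops$start1[i] %/% res; b1h <- (loops$end1[i] - 1L) %/% res
      b2l <- loops$start2[i] %/% res; b2h <- (loops$end2[i] - 1L) %/% res
      i0 <- (b1l + b1h) %/% 2L; j0 <- (b2l + b2h) %/% 2L
      if (i0 - outer < 0 || j0 + outer >= nb) {
        loops$flagged[i] <- TRUE
        next
      }
      w <- dense_window(sub, i0, j0, outer)
      c0 <- outer + 1L
      # Observed: anchor rectangle relative to the window center.
      rr <- (b1l:b1h) - i0 + c0
      cc <- (b2l:b2h) - j0 + c0
      rr <- rr[rr >= 1 & rr <= 2 * outer + 1]
      cc <- cc[cc >= 1 & cc <= 2 * outer + 1]
      obs <- sum(w[rr, cc])
      d <- pmax(abs(row(w) - c0), abs(col(w) - c0))
      ring <- d > inner & d <= outer & row(w) != c0 & col(w) != c0
      loops$observed[i] <- obs
      loops$expected[i] <- mean(w[ring]) * length(rr) * length(cc)
    }
  }
  loops$strength <- ifelse(loops$flagged, NA_real_,
                           loop_strength(loops$observed, loops$expected,
                                         pseudo))
  loops
}

#' Merge loop lists by source priority
#'
#' Lists are processed in the given order (highest priority first). A
#' candidate loop is dropped if and only if BOTH of its anchors overlap (by
#' any bp) the corresponding anchors of an already-accepted higher-priority
#' loop; sharing a single anchor is not sufficient. Within one priority
#' level, candidates are screened only against higher-priority acceptances,
#' so the within-list order does not affect the result.
#'
#' @param lists List of data.frames (chrom, start1, end1, start2, end2, ...)
#'   ordered by decreasing priority; each internally non-redundant.
#' @return Merged data.frame with a `priority` column (1 = highest).
#' @export
merge_loop_lists <- function(lists) {
  accepted <- NULL
  for (k in seq_along(lists)) {
    cand <- lists[[k]]
    if (is.null(cand) || !nrow(cand)) next
    cand$priority <- k
    if (is.null(accepted) || !nrow(accepted)) {
      accepted <- cand
      next
    }
    a1c <- df_to_granges(data.frame(chrom = cand$chrom, start = cand$start1,
                                    end = cand$end1))
    a2c <- df_to_granges(data.frame(chrom = cand$chrom, start = cand$start2,
                                    end = cand$end2))
    a1a <- df_to_granges(data.frame(chrom = accepted$chrom,
                                    start = accepted$start1,
                                    end = accepted$end1))
    a2a <- df_to_granges(data.frame(chrom = accepted$chrom,
                                    start = accepted$start2,
                                    end = accepted$end2))
    h1 <- GenomicRanges::findOverlaps(a1c, a1a)
    h2 <- GenomicRanges::findOverlaps(a2c, a2a)
    k1 <- paste(S4Vectors::queryHits(h1), S4Vectors::subjectHits(h1))
    k2 <- paste(S4Vectors::queryHits(h2), S4Vectors::subjectHits(h2))
    conflicted <- unique(S4Vectors::queryHits(h1)[k1 %in% k2])
    keep <- setdiff(seq_len(nrow(cand)), conflicted)
    accepted <- rbind(accepted, cand[keep, , drop = FALSE])
  }
  if (is.null(accepted)) return(NULL)
  rownames(accepted) <- NULL
  accepted
}

#' Stage-positive loop calls
#'
#' A loop is positive for a stage when its stage-averaged enrichment ratio
#' `(observed + 1) / (expected + 1)` exceeds `fold` (strictly). The ratio
#' (not its log) is compared against the fold threshold, since strengths are
#' logs of ratios.
#'
#' @param loop_table Output of [loop_quantify()] applied per sample: a
#'   data.frame with `observed.<sample>` and `expected.<sample>` columns.
#' @param samples_of_stage Character vector of sample ids in the stage.
#' @param fold Enrichment ratio threshold.
#' @return Subset of `loop_table` with a `stage_ratio` column.
#' @export
stage_positive <- function(loop_table, samples_of_stage, fold = 1.2) {
  if (!length(samples_of_stage)) stop("at least one sample required")
  ratios <- sapply(samples_of_stage, function(s) {
    (loop_table[[paste0("observed.", s)]] + 1) /
      (loop_table[[paste0("expected.", s)]] + 1)
  })
  if (is.null(dim(ratios))) ratios <- matrix(ratios, ncol = length(samples_of_stage))
  loop_table$stage_ratio <- rowMeans(ratios, na.rm = TRUE)
  loop_table[!is.na(loop_table$stage_ratio) & loop_table$stage_ratio > fold, ,
             drop = FALSE]
}

# Mean contact intensity per genomic separation (in bins), pooled over
# chromosomes of the matrix; used by the stripe-mode APA normalization.
distance_expected <- function(cm, max_sep) {
  res <- attr(cm, "resolution")
  cs <- attr(cm, "chrom_sizes")
  tot <- numeric(max_sep + 1)
  nb_tot <- numeric(max_sep + 1)
  for (ch in unique(cm$chrom)) {
    sub <- cm[cm$chrom == ch, , drop = FALSE]
    sep <- sub$bin2 - sub$bin1
    keep <- sep <= max_sep
    agg <- tapply(sub$count[keep], sep[keep], sum)
    tot[as.integer(names(agg)) + 1] <- tot[as.integer(names(agg)) + 1] + agg
    nb <- as.integer(ceiling(cs[[ch]] / res))
    nb_tot <- nb_tot + pmax(0, nb - 0:max_sep)
  }
  ifelse(nb_tot > 0, tot / nb_tot, NA_real_)
}

#' Aggregate peak analysis over anchor pairs
#'
#' Sums contact submatrices centered on the given anchor pairs. In `loop`
#' mode the enrichment score is the mean of the center `center_n x center_n`
#' pixels divided by the mean of the `bg_n x bg_n` pixels in the bottom-left
#' corner of the aggregate. In `stripe` mode every pixel is first divided by
#' the matrix-wide mean intensity at its genomic separation (per-diagonal
#' normalization) and the score is the mean of the ten center pixels of the
#' anchor column. Anchor pairs whose window leaves the matrix are skipped;
#' aggregation over zero valid pairs is an error. The aggregate matrix is
#' returned untransformed (log-transform only when plotting).
#'
#' @param cm A `contact_matrix`.
#' @param anchor_pairs data.frame with chrom, pos1, pos2 (bp midpoints of
#'   the two anchors, pos1 < pos2).
#' @param half_width Window half-width in bins (full window
#'   `2 * half_width + 1`).
#' @param mode "loop" or "stripe".
#' @param center_n Center block edge (loop mode) / center pixel count along
#'   the anchor column (stripe mode).
#' @param bg_n Bottom-left background block edge (loop mode).
#' @return Object of class `apa_result`: list(matrix, score, n_pairs, mode).
#' @export
apa <- function(cm, anchor_pairs, half_width = 250,
                mode = c("loop", "stripe"), center_n = 10, bg_n = 100) {
  mode <- match.arg(mode)
  res <- attr(cm, "resolution")
  cs <- attr(cm, "chrom_sizes")
  n <- 2L * half_width + 1L
  if (mode == "loop" && n < center_n + bg_n)
    stop("window too small for the center/background geometry")
  dexp <- if (mode == "stripe") {
    max_sep <- (max(anchor_pairs$pos2 - anchor_pairs$pos1) %/% res) +
      2L * half_width + 1L
    distance_expected(cm, max_sep)
  }
  agg <- matrix(0, n, n)
  n_ok <- 0L
  for (ch in unique(anchor_pairs$chrom)) {
    sub <- cm[cm$chrom == ch, , drop = FALSE]
    nb <- as.integer(ceiling(cs[[ch]] / res))
    rows <- which(anchor_pairs$chrom == ch)
    for (i in rows) {
      i0 <- anchor_pairs$pos1[i] %/% res
      j0 <- anchor_pairs$pos2[i] %/% res
      if (i0 - half_width < 0 || j0 + half_width >= nb) next
      w <- dense_window(sub, i0, j0, half_width)
      if (mode == "stripe") {
        sep <- abs(outer((i0 - half_width):(i0 + half_width),
                         (j0 - half_width):(j0 + half_width), `-`))
        e <- dexp[sep + 1]
        e[is.na(e) | e <= 0] <- NA
        w <- w / e
        w[is.na(w)] <- 0
      }
      agg <- agg + w
      n_ok <- n_ok + 1L
    }
  }
  if (n_ok == 0L) stop("no valid anchor pairs within matrix bounds")
  c0 <- half_width + 1L
  if (mode == "loop") {
    ci <- (c0 - floor((center_n - 1) / 2)):(c0 + ceiling((center_n - 1) / 2))
    bg <- agg[(n - bg_n + 1):n, 1:bg_n]
    score <- mean(agg[ci, ci]) / mean(bg)
  } else {
    ci <- (c0 - floor((center_n - 1) / 2)):(c0 + ceiling((center_n - 1) / 2))
    score <- mean(agg[ci, c0]) / n_ok
  }
  structure(list(matrix = agg / max(1L, n_ok), score = score,
                 n_pairs = n_ok, mode = mode),
            class = "apa_result")
}

#' @export
print.apa_result <- function(x, ...) {
  cat(sprintf("APA (%s mode): %d anchor pairs, enrichment score %.3f\n",
              x$mode, x$n_pairs, x$score))
  invisible(x)
}

#' Plot an APA aggregate as a heat map (log-transformed intensities)
#'
#' @param x An `apa_result`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.apa_result <- function(x, ...) {
  m <- log10(x$matrix + 1)
  graphics::image(t(m[nrow(m):1, ]), axes = FALSE,
                  main = sprintf("APA (%s), score %.2f", x$mode, x$score),
                  ...)
  invisible(x)
}
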