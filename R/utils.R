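# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so package functions never leak RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(old <- .GlobalEnv$.Random.seed)) {
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)),
            add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Deterministic 31-bit sub-seed from a base seed and a string key, so each
# sample/stage draws from an independent but reproducible stream.
sub_seed <- function(seed, key) {
  h <- 0
  for (v in utf8ToInt(as.character(key))) h <- (h * 131 + v) %% 1987654321
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

# Centered rolling sum over a numeric vector: element i gets
# sum(x[(i-half):(i+half)]) with zero padding outside the vector.
centered_rollsum <- function(x, k) {
  half <- floor(k / 2)
  n <- length(x)
  cs <- cumsum(c(0, x))
  hi <- pmin(n, seq_len(n) + half)
  lo <- pmax(0, seq_len(n) - half - 1)
  cs[hi + 1] - cs[lo + 1]
}

# Number of sorted integer positions in [start, end) for each interval.
count_in_intervals <- function(sorted_pos, start, end) {
  findInterval(end - 1L, sorted_pos) - findInterval(start - 1L, sorted_pos)
}

# data.frame(chrom,start,end,...) -> GRanges (0-based half-open input).
df_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

granges_to_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_cols <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
}
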