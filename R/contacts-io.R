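#' Read a 4DN-style .pairs file
#'
#' Parses the text .pairs dialect (comment header with a `#columns:` line,
#' then whitespace-separated records). Records are validated and returned in
#' canonical order (pos1 <= pos2 for intra-chromosomal pairs, swapping
#' strands alongside positions). Malformed lines are counted and reported as
#' a warning and an attribute.
#'
#' @param path Path to the .pairs file.
#' @param chrom_sizes Optional named vector; records on chromosomes absent
#'   from it are skipped with a warning.
#' @param intra_only Drop inter-chromosomal records (counted in the
#'   `n_inter_dropped` attribute).
#' @return data.frame with columns chrom1, pos1, strand1, chrom2, pos2,
#'   strand2 and attributes `n_malformed`, `n_skipped_chrom`,
#'   `n_inter_dropped`.
#' @export
read_pairs <- function(path, chrom_sizes = NULL, intra_only = FALSE) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  cols_line <- grep("^#columns:", lines, value = TRUE)
  if (!length(cols_line)) stop("missing '#columns:' header line in .pairs file")
  cols <- strsplit(sub("^#columns:\\s*", "", cols_line[1]), "\\s+")[[1]]
  need <- c("chrom1", "pos1", "chrom2", "pos2", "strand1", "strand2")
  if (!all(need %in% cols))
    stop(sprintf("missing header column(s): %s",
                 paste(setdiff(need, cols), collapse = ", ")))
  body <- lines[!hdr & nzchar(lines)]
  if (!length(body)) {
    out <- data.frame(chrom1 = character(), pos1 = integer(),
                      strand1 = character(), chrom2 = character(),
                      pos2 = integer(), strand2 = character())
    attr(out, "n_malformed") <- 0L
    attr(out, "n_skipped_chrom") <- 0L
    attr(out, "n_inter_dropped") <- 0L
    return(out)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  malformed <- nf < length(cols)
  parts <- parts[!malformed]
  m <- matrix(unlist(lapply(parts, `[`, seq_along(cols))),
              ncol = length(cols), byrow = TRUE)
  colnames(m) <- cols
  out <- data.frame(
    chrom1 = m[, "chrom1"], pos1 = suppressWarnings(as.integer(m[, "pos1"])),
    strand1 = m[, "strand1"],
    chrom2 = m[, "chrom2"], pos2 = suppressWarnings(as.integer(m[, "pos2"])),
    strand2 = m[, "strand2"], stringsAsFactors = FALSE
  )
  bad <- is.na(out$pos1) | is.na(out$pos2) | out$pos1 < 0 | out$pos2 < 0 |
    !out$strand1 %in% c("+", "-") | !out$strand2 %in% c("+", "-")
  n_malformed <- sum(malformed) + sum(bad)
  out <- out[!bad, , drop = FALSE]

  n_skip <- 0L
  if (!is.null(chrom_sizes)) {
    known <- out$chrom1 %in% names(chrom_sizes) &
      out$chrom2 %in% names(chrom_sizes)
    n_skip <- sum(!known)
    if (n_skip) warning(sprintf("%d record(s) on unknown chromosome skipped",
                                n_skip))
    out <- out[known, , drop = FALSE]
  }
  n_inter <- 0L
  if (intra_only) {
    intra <- out$chrom1 == out$chrom2
    n_inter <- sum(!intra)
    out <- out[intra, , drop = FALSE]
  }
  swap <- out$chrom1 == out$chrom2 & out$pos1 > out$pos2
  if (any(swap)) {
    tp <- out$pos1[swap]; ts <- out$strand1[swap]
    out$pos1[swap] <- out$pos2[swap]; out$strand1[swap] <- out$strand2[swap]
    out$pos2[swap] <- tp; out$strand2[swap] <- ts
  }
  rownames(out) <- NULL
  if (n_malformed) warning(sprintf("%d malformed record(s) dropped",
                                   n_malformed))
  attr(out, "n_malformed") <- as.integer(n_malformed)
  attr(out, "n_skipped_chrom") <- n_skip
  attr(out, "n_inter_dropped") <- as.integer(n_inter)
  out
}

#' Write contact records as a 4DN-style .pairs file
#'
#' @param records Contact record data.frame.
#' @param path Output path.
#' @param chrom_sizes Optional named vector written as `#chromsize:` header
#'   lines.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(records, path, chrom_sizes = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("## pairs format v1.0", con)
  if (!is.null(chrom_sizes)) {
    writeLines(sprintf("#chromsize: %s %d", names(chrom_sizes),
                       as.integer(chrom_sizes)), con)
  }
  writeLines("#columns: readID chrom1 pos1 chrom2 pos2 strand1 strand2", con)
  if (nrow(records)) {
    utils::write.table(
      data.frame(readID = sprintf("r%07d", seq_len(nrow(records))),
                 chrom1 = records$chrom1, pos1 = records$pos1,
                 chrom2 = records$chrom2, pos2 = records$pos2,
                 strand1 = records$strand1, strand2 = records$strand2),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Split contact records into long-range and short-range classes
#'
#' Long-range records have |pos2 - pos1| > `long_min`; short-range records
#' have distance < `short_max` and, when `orientation_filter` is on, inward
#' (+/-) orientation on the canonical (left, right) ends -- the signature of
#' self-ligation pairs. Records in the dead zone between the two thresholds
#' belong to neither class and are discarded.
#'
#' @param records Contact record data.frame (intra-chromosomal).
#' @param long_min Lower distance bound (exclusive) for long-range pairs (bp).
#' @param short_max Upper distance bound (exclusive) for short-range pairs.
#' @param orientation_filter Require +/- orientation for the short class.
#' @return list(long = data.frame, short = data.frame).
#' @export
split_by_range <- function(records, long_min = 1500, short_max = 1000,
                           orientation_filter = TRUE) {
  if (long_min <= short_max) stop("long_min must exceed short_max")
  if (!nrow(records)) return(list(long = records, short = records))
  d <- abs(records$pos2 - records$pos1)
  intra <- records$chrom1 == records$chrom2
  long <- records[intra & d > long_min, , drop = FALSE]
  short_ok <- intra & d < short_max
  if (orientation_filter) {
    short_ok <- short_ok & records$strand1 == "+" & records$strand2 == "-"
  }
  list(long = long, short = records[short_ok, , drop = FALSE])
}

#' Sliding-window coverage track of record endpoints
#'
#' Bin i (at `step` spacing) counts the record endpoints falling in
#' `[i*step, i*step + window)`. Both mates of an intra-chromosomal pair count
#' at their own loci. With `window == step` this is a plain histogram.
#'
#' @param records Contact record data.frame, or an integer vector of
#'   endpoint positions when `chrom` is given implicitly.
#' @param chrom Chromosome to compute the track for.
#' @param chrom_size Chromosome length (bp).
#' @param window Window width (bp), >= `step`.
#' @param step Sliding step (bp); defaults to 100.
#' @return list of class `binned_track`: chrom, step, window, start (vector
#'   of window starts) and values.
#' @export
coverage_track <- function(records, chrom, chrom_size, window, step = 100) {
  if (window < step) stop("window must be >= step")
  pos <- endpoint_positions(records, chrom)
  h <- endpoint_histogram(pos, chrom_size, step)
  k <- window %/% step
  n <- length(h)
  cs <- cumsum(c(0, h))
  hi <- pmin(n, seq_len(n) + k - 1L)
  vals <- cs[hi + 1] - cs[seq_len(n)]
  structure(list(chrom = chrom, step = step, window = window,
                 start = (seq_len(n) - 1L) * step, values = vals),
            class = "binned_track")
}

endpoint_positions <- function(records, chrom) {
  if (is.numeric(records)) return(as.integer(records))
  r <- records[records$chrom1 == chrom & records$chrom2 == chrom, ,
               drop = FALSE]
  c(r$pos1, r$pos2)
}

endpoint_histogram <- function(pos, chrom_size, step) {
  nb <- as.integer(ceiling(chrom_size / step))
  if (!length(pos)) return(integer(nb))
  b <- pos %/% step + 1L
  b <- b[b >= 1L & b <= nb]
  tabulate(b, nbins = nb)
}

#' Bin contact records into a sparse contact matrix
#'
#' Aggregates intra-chromosomal records to square bins at the given
#' resolution, stored as upper-triangular COO triplets.
#'
#' @param records Contact record data.frame.
#' @param resolution Bin size in bp.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @return Object of class `contact_matrix`: data.frame (chrom, bin1, bin2,
#'   count) with 0-based bin indices, bin1 <= bin2, plus attributes
#'   `resolution` and `chrom_sizes`.
#' @export
bin_matrix <- function(records, resolution, chrom_sizes) {
  stopifnot(resolution >= 1)
  r <- records[records$chrom1 == records$chrom2, , drop = FALSE]
  out <- do.call(rbind, lapply(unique(r$chrom1), function(ch) {
    rc <- r[r$chrom1 == ch, , drop = FALSE]
    b1 <- pmin(rc$pos1, rc$pos2) %/% resolution
    b2 <- pmax(rc$pos1, rc$pos2) %/% resolution
    nb <- max(b2) + 1
    key <- sort(as.numeric(b1) * nb + b2)
    runs <- rle(key)
    data.frame(chrom = ch,
               bin1 = as.integer(runs$values %/% nb),
               bin2 = as.integer(runs$values %% nb),
               count = runs$lengths, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$bin1, out$bin2), ]
  rownames(out) <- NULL
  structure(out, class = c("contact_matrix", "data.frame"),
            resolution = as.integer(resolution),
            chrom_sizes = chrom_sizes)
}

#' Randomly subsample contact records
#'
#' Each record is kept independently with probability `fraction`.
#'
#' @param records Contact record data.frame.
#' @param fraction Keep probability in (0, 1].
#' @param seed Integer seed.
#' @return Subsampled data.frame (same columns and attributes class).
#' @export
subsample_contacts <- function(records, fraction, seed = 1) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (fraction == 1) return(records)
  with_seed(seed, {
    keep <- stats::runif(nrow(records)) < fraction
    out <- records[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Write / read a sparse contact matrix as COO TSV
#'
#' @param cm A `contact_matrix`.
#' @param path File path.
#' @return `path` (write) or a `contact_matrix` (read).
#' @export
write_contact_matrix <- function(cm, path) {
  hdr <- sprintf("# resolution=%d", attr(cm, "resolution"))
  cs <- attr(cm, "chrom_sizes")
  hdr <- c(hdr, sprintf("# chromsize %s %d", names(cs), as.integer(cs)))
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(as.data.frame(cm), path, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      append = TRUE))
  invisible(path)
}

#' @rdname write_contact_matrix
#' @export
read_contact_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- lines[grepl("^#", lines)]
  res <- as.integer(sub("# resolution=", "", hdr[1]))
  csl <- strsplit(sub("^# chromsize ", "", hdr[-1]), " ")
  cs <- stats::setNames(as.integer(vapply(csl, `[`, "", 2)),
                        vapply(csl, `[`, "", 1))
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  structure(df, class = c("contact_matrix", "data.frame"),
            resolution = res, chrom_sizes = cs)
}

#' Iterative proportional fitting (matrix balancing) weights
#'
#' Optional balancing utility: computes per-bin weights for one chromosome of
#' a contact matrix such that the weighted matrix has approximately uniform
#' row sums (Sinkhorn iterations on the symmetric count matrix). Not used by
#' the connectivity pipeline, whose normative normalization path is the
#' self-ligation mappability ratio; provided for parity experiments.
#'
#' @param cm A `contact_matrix`.
#' @param chrom Chromosome name.
#' @param max_iter,tol Iteration controls.
#' @return Numeric vector of per-bin weights (NA for empty bins).
#' @export
ipf_balance <- function(cm, chrom, max_iter = 100, tol = 1e-6) {
  sub <- cm[cm$chrom == chrom, , drop = FALSE]
  if (!nrow(sub)) stop("no records for chromosome")
  nb <- max(sub$bin2) + 1L
  w <- rep(1, nb)
  i <- sub$bin1 + 1L; j <- sub$bin2 + 1L; x <- sub$count
  rowsum_w <- function(w) {
    s <- numeric(nb)
    v <- x * w[i] * w[j]
    s0 <- tapply(c(v, v[i != j]), c(i, j[i != j]), sum)
    s[as.integer(names(s0))] <- s0
    s
  }
  nz <- unique(c(i, j))
  for (it in seq_len(max_iter)) {
    s <- rowsum_w(w)
    target <- mean(s[nz])
    adj <- rep(1, nb)
    adj[nz] <- sqrt(target / pmax(s[nz], .Machine$double.eps))
    w <- w * adj
    if (max(abs(adj[nz] - 1)) < tol) break
  }
  w[-nz] <- NA_real_
  w
}
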