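# BED / bedGraph interchange (via rtracklayer) and TSV writers for the
# pipeline's tabular outputs. All coordinates are 0-based half-open on disk,
# the standard BED convention.

#' Write intervals as BED
#'
#' @param df data.frame with chrom, start, end and optionally name/score
#'   columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  gr <- df_to_granges(df)
  if (!is.null(df$name)) gr$name <- df$name
  if (!is.null(df$score)) gr$score <- df$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED file into a 0-based data.frame
#'
#' @param path BED path.
#' @return data.frame (chrom, start, end, and name/score when present).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- granges_to_df(gr)
  md <- S4Vectors::mcols(gr)
  if ("name" %in% names(md)) out$name <- md$name
  if ("score" %in% names(md)) out$score <- md$score
  out
}

#' Write a binned track as bedGraph
#'
#' @param track A `binned_track` (see [coverage_track()]), or a data.frame
#'   with chrom, start, end, value.
#' @param path Output path.
#' @param chrom_size Chromosome length used to clip the last bin (binned
#'   track input only).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, chrom_size = NULL) {
  if (inherits(track, "binned_track")) {
    end <- track$start + track$step
    if (!is.null(chrom_size)) end <- pmin(end, chrom_size)
    df <- data.frame(chrom = track$chrom, start = track$start, end = end,
                     value = track$values)
  } else {
    df <- track
  }
  gr <- df_to_granges(df)
  gr$score <- df$value
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file
#'
#' @param path bedGraph path.
#' @return data.frame (chrom, start, end, value), 0-based half-open.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- granges_to_df(gr)
  out$value <- S4Vectors::mcols(gr)$score
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
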