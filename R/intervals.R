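#' Construct a genomic interval table
#'
#' All coordinates in this package are 1-based and inclusive at both ends
#' (GTF/VCF convention). An interval set is represented as a plain
#' `data.frame` with columns `chrom`, `start`, `end`, `strand` and an
#' optional `label`, which converts losslessly to a `GRanges` when interval
#' algebra is needed.
#'
#' @param chrom chromosome name(s), non-empty strings
#' @param start 1-based inclusive start position(s)
#' @param end   1-based inclusive end position(s), `end >= start`
#' @param strand `"+"` or `"-"` (recycled)
#' @param label optional region label (recycled)
#' @return a `data.frame` with columns chrom, start, end, strand, label
#' @export
genomic_interval <- function(chrom, start, end, strand = "+", label = NA_character_) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(chrom) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), label = character(),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   strand = as.character(strand), label = as.character(label),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  if (any(is.na(df$chrom) | !nzchar(df$chrom)))
    stop("invalid interval: chrom must be a non-empty string", call. = FALSE)
  if (any(is.na(df$start)) || any(df$start < 1L))
    stop("invalid interval: start must be >= 1", call. = FALSE)
  if (any(is.na(df$end)) || any(df$end < df$start))
    stop("invalid interval: end must be >= start", call. = FALSE)
  if (!all(df$strand %in% c("+", "-")))
    stop("invalid interval: strand must be '+' or '-'", call. = FALSE)
  invisible(df)
}

#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                         strand = "*")
}

# 1-based inclusive overlap: max(starts) <= min(ends), chrom equal.
interval_overlaps <- function(chrom_a, s_a, e_a, chrom_b, s_b, e_b) {
  chrom_a == chrom_b & pmax(s_a, s_b) <= pmin(e_a, e_b)
}

# Subtract interval set `sub` from `x` (same chromosome space); returns the
# residual pieces of `x`, dropping anything that shrinks to zero length.
subtract_intervals <- function(x, sub) {
  if (nrow(x) == 0L) return(x)
  if (nrow(sub) == 0L) return(x)
  gr_x <- intervals_to_granges(x)
  gr_s <- GenomicRanges::reduce(intervals_to_granges(sub))
  res <- GenomicRanges::setdiff(gr_x, gr_s)
  if (length(res) == 0L)
    return(x[0L, , drop = FALSE])
  data.frame(chrom = as.character(GenomicRanges::seqnames(res)),
             start = GenomicRanges::start(res), end = GenomicRanges::end(res),
             strand = x$strand[1L], label = x$label[1L],
             stringsAsFactors = FALSE)
}
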