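#' Genomic interval table
#'
#' Builds the package's internal interval representation: a data.frame with
#' columns `chrom`, `start`, `end`, `label`, 0-based half-open (BED
#' convention). All interval arithmetic in the package uses this convention;
#' 1-based point positions (VCF convention) are converted at the boundary.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer-like vectors; `start < end`, 0-based half-open.
#' @param label free-text labels (recycled).
#' @return data.frame of class `genomic_intervals`.
#' @export
genomic_intervals <- function(chrom, start, end, label = "") {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(!is.finite(start)) || any(!is.finite(end)))
    stop("interval coordinates must be finite", call. = FALSE)
  if (any(start < 0)) stop("interval start must be >= 0", call. = FALSE)
  if (any(start >= end))
    stop("interval start must be < end (0-based half-open)", call. = FALSE)
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    label = rep_len(as.character(label),
                                    length.out = length(chrom)),
                    stringsAsFactors = FALSE)
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Test whether 1-based point positions fall inside intervals
#'
#' A 1-based position `p` occupies the 0-based half-open slot `[p-1, p)`, so
#' it lies inside `[start, end)` iff `start < p <= end`. A point exactly at a
#' half-open interval end (0-based `p - 1 == end`) is outside.
#'
#' @param chrom,pos vectors (1-based positions).
#' @param intervals a `genomic_intervals` table.
#' @return logical vector, `TRUE` where the point is inside any interval.
#' @export
point_in_intervals <- function(chrom, pos, intervals) {
  if (nrow(intervals) == 0L) return(rep(FALSE, length(pos)))
  vapply(seq_along(pos), function(i) {
    any(intervals$chrom == chrom[i] &
          intervals$start < pos[i] & pos[i] <= intervals$end)
  }, logical(1))
}

# 0-based half-open span overlap (single span vs interval table);
# returns logical vector over rows of `intervals`.
span_overlaps <- function(chrom, start, end, intervals) {
  intervals$chrom == chrom &
    pmax(start, intervals$start) < pmin(end, intervals$end)
}

# span [start, end) fully contains each interval row?
span_contains <- function(chrom, start, end, intervals) {
  intervals$chrom == chrom & start <= intervals$start & intervals$end <= end
}

#' Read a BED file into a `genomic_intervals` table
#'
#' Uses rtracklayer for parsing; the 1-based closed GRanges coordinates are
#' converted back to the native 0-based half-open BED values.
#'
#' @param path BED file (3, 4 or 6 columns).
#' @return `genomic_intervals` table; BED name column becomes `label`, and a
#'   `strand` column is attached when present.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "BED")
  lab <- if (!is.null(gr$name)) as.character(gr$name) else ""
  out <- genomic_intervals(as.character(GenomicRanges::seqnames(gr)),
                           GenomicRanges::start(gr) - 1L,
                           GenomicRanges::end(gr),
                           lab)
  str <- as.character(GenomicRanges::strand(gr))
  if (any(str %in% c("+", "-"))) out$strand <- str
  out
}

#' Write a `genomic_intervals` table to BED
#'
#' @param intervals `genomic_intervals` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end),
    strand = if (!is.null(intervals$strand)) intervals$strand else "*")
  gr$name <- if (!is.null(intervals$label)) intervals$label else "."
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
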