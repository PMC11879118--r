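#' @importFrom GenomicRanges GRanges findOverlaps countOverlaps pintersect
#'   reduce width start end seqnames strand
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

# All interval tables in this package are BED-convention data.frames:
# chrom (character), start/end (0-based half-open integers), optional strand.
# GRanges (1-based closed) is used internally for overlap arithmetic only.

#' Convert a BED-convention data.frame to a GRanges
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `strand`.
#' @param use_strand keep the strand column if present (default drops it, so
#'   that overlap queries are strand-blind, as in `bedtools intersect`).
#' @return A [GenomicRanges::GRanges] of the same length and order.
#' @keywords internal
as_granges <- function(df, use_strand = FALSE) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) > 0 && any(df$end < df$start)) {
    stop("interval with end < start")
  }
  st <- if (use_strand && "strand" %in% names(df)) df$strand else "*"
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges   = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand   = st
  )
}

#' Overlap two BED-convention tables
#'
#' Returns one row per overlapping pair with the number of shared base pairs.
#'
#' @param a,b BED-convention data.frames.
#' @return data.frame with `a_idx`, `b_idx`, `overlap_bp`.
#' @keywords internal
overlap_pairs <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(data.frame(a_idx = integer(), b_idx = integer(),
                      overlap_bp = integer()))
  }
  ga <- as_granges(a)
  gb <- as_granges(b)
  hits <- GenomicRanges::findOverlaps(ga, gb, minoverlap = 1L)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(ga[qi], gb[si]))
  data.frame(a_idx = qi, b_idx = si, overlap_bp = ov)
}

#' Merge intervals that overlap by at least 1 bp
#'
#' Single-linkage merge; abutting (zero-overlap) intervals are kept separate.
#'
#' @param df BED-convention data.frame.
#' @return data.frame `chrom`, `start`, `end` of merged regions, plus
#'   `members`: a list column of input row indices in each merged region.
#' @keywords internal
merge_overlapping <- function(df) {
  if (nrow(df) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  }
  g <- as_granges(df)
  red <- GenomicRanges::reduce(g, min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(g, red, minoverlap = 1L)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end   = GenomicRanges::end(red)
  )
  out$members <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
  out
}

# total bp covered by a set of (possibly overlapping) intervals
covered_bp <- function(df) {
  if (nrow(df) == 0) return(0L)
  sum(GenomicRanges::width(GenomicRanges::reduce(as_granges(df))))
}
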