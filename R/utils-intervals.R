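# Interval helpers. All user-facing tables use BED convention: 0-based,
# half-open [start, end). GenomicRanges (1-based, closed) is used internally
# for overlap arithmetic; these two helpers are the only place the conversion
# happens.

#' Convert a BED-convention interval tibble to a GRanges
#'
#' @param x data frame with `chrom`, `start`, `end` (0-based half-open).
#' @return A [GenomicRanges::GRanges] (1-based closed).
#' @keywords internal
#' @noRd
as_gr <- function(x) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

#' @noRd
gr_to_bed <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr)
  )
}

#' Fragment midpoints as 1 bp points
#' @noRd
midpoint_gr <- function(fragments) {
  m <- floor((fragments$start + fragments$end) / 2)
  GenomicRanges::GRanges(
    seqnames = fragments$chrom,
    ranges = IRanges::IRanges(start = m + 1L, width = 1L)
  )
}

#' Count fragment midpoints falling in each region
#'
#' A fragment is "in" a region iff its midpoint is (shifted-cut-site ATAC
#' convention for synthetic data).
#'
#' @param regions data frame with `chrom`, `start`, `end`.
#' @param fragments data frame of BED3 fragments.
#' @return Integer vector, one count per region row.
#' @export
count_midpoints <- function(regions, fragments) {
  if (nrow(regions) == 0) return(integer(0))
  if (nrow(fragments) == 0) return(rep(0L, nrow(regions)))
  GenomicRanges::countOverlaps(as_gr(regions), midpoint_gr(fragments))
}

#' Distance from a TSS position to an interval
#'
#' Zero when the TSS lies inside the half-open interval, otherwise the gap in
#' bp to the nearest covered base. Strand is ignored.
#' @noRd
tss_interval_distance <- function(tss, start, end) {
  pmax(0, start - tss, tss - (end - 1))
}

#' Validate a genome table
#' @noRd
check_genome <- function(genome) {
  stopifnot(all(c("chrom", "length") %in% names(genome)))
  if (any(genome$length <= 0)) abort("genome chromosome lengths must be positive")
  if (anyDuplicated(genome$chrom)) abort("duplicate chromosome names in genome")
  invisible(genome)
}
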