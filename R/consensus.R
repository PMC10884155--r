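# Cross-sample consensus peak construction: per-sample score-per-million
# normalization, summit-centred fixed-width resizing, and the iterative
# overlap-removal merge (keep the best-scoring peak, drop everything it
# touches, repeat) with an spm cutoff applied to the retained set.

#' Score-per-million normalization of peak scores
#'
#' Within each sample, `spm = score * 1e6 / sum(score)`, so a sample's spm
#' values sum to one million and are comparable across samples of different
#' peak counts and score scales.
#'
#' @param peaks peak tibble with `score` and `sample_id`.
#' @return The input with an `spm` column.
#' @export
score_per_million <- function(peaks) {
  stopifnot(all(c("score", "sample_id") %in% names(peaks)))
  if (any(peaks$score < 0)) abort("peak scores must be non-negative")
  out <- peaks %>%
    group_by(.data$sample_id) %>%
    mutate(spm = .data$score * 1e6 / sum(.data$score)) %>%
    ungroup()
  if (nrow(out) > 0 && any(!is.finite(out$spm))) {
    abort("undefined spm normalization: a sample has all-zero scores")
  }
  out
}

#' Resize peaks to a fixed width around their summits
#'
#' Each peak becomes `[summit - width/2, summit + width/2)`, clipped at
#' chromosome bounds; clipped peaks are flagged in a `clipped` column.
#'
#' @param peaks peak tibble with `chrom` and `summit`.
#' @param width even positive target width (bp).
#' @param genome tibble with `chrom`, `length`.
#' @return The peaks with new `start`/`end` and a `clipped` flag.
#' @export
resize_to_width <- function(peaks, width, genome) {
  if (width <= 0 || width %% 2 != 0) abort("width must be even and positive")
  check_genome(genome)
  if (nrow(peaks) == 0) return(mutate(peaks, clipped = logical(0)))
  chrom_len <- genome$length[match(peaks$chrom, genome$chrom)]
  if (any(is.na(chrom_len))) abort("peak chromosome absent from genome")
  if (any(peaks$summit < 0 | peaks$summit >= chrom_len)) {
    abort("peak summit outside chromosome bounds")
  }
  start <- pmax(0, peaks$summit - width / 2)
  end <- pmin(chrom_len, peaks$summit + width / 2)
  mutate(peaks, clipped = .env$start > .data$summit - width / 2 |
           .env$end < .data$summit + width / 2,
         start = .env$start, end = .env$end)
}

#' Iterative overlap-removal merge of pooled fixed-width peaks
#'
#' Pooled peaks are ranked by spm (descending; ties broken by chrom then
#' start, smaller first). The top peak is retained and every remaining peak
#' overlapping it by at least 1 bp is discarded; this repeats until no peaks
#' remain. Retained peaks with `spm < spm_cutoff` are then removed.
#'
#' @param peaks pooled peak tibble with `chrom`, `start`, `end`, `spm`
#'   (already resized to a common width and spm-normalized per sample).
#' @param spm_cutoff minimum spm for a retained peak (default 2).
#' @return Non-overlapping consensus peak tibble, sorted by chrom and start.
#' @export
iterative_merge <- function(peaks, spm_cutoff = 2) {
  if (nrow(peaks) == 0) return(peaks)
  stopifnot("spm" %in% names(peaks))
  ord <- order(-peaks$spm, peaks$chrom, peaks$start)
  peaks <- peaks[ord, ]
  gr <- as_gr(peaks)
  hits <- GenomicRanges::findOverlaps(gr, gr)
  ov <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  n <- nrow(peaks)
  discarded <- rep(FALSE, n)
  kept <- logical(n)
  for (i in seq_len(n)) {
    if (discarded[i]) next
    kept[i] <- TRUE
    discarded[ov[[as.character(i)]]] <- TRUE
  }
  out <- peaks[kept & peaks$spm >= spm_cutoff, ]
  arrange(out, .data$chrom, .data$start)
}

#' Build a consensus peak set from per-sample peak calls
#'
#' Convenience wrapper: spm-normalizes each sample, resizes every peak to
#' `width` around its summit, pools, and runs [iterative_merge()].
#'
#' @param peaksets list of per-sample peak tibbles (each with `chrom`,
#'   `summit`, `score`); names are used as `sample_id`.
#' @param genome genome tibble.
#' @param width fixed consensus peak width (bp, default 500).
#' @param spm_cutoff spm cutoff (default 2).
#' @return Consensus peak tibble with `peak_id`.
#' @export
consensus_peaks <- function(peaksets, genome, width = 500, spm_cutoff = 2) {
  pooled <- purrr::imap_dfr(peaksets, function(p, id) {
    if (nrow(p) == 0) return(p)
    p$sample_id <- if (!is.null(id) && nzchar(id)) id else "sample"
    p
  })
  if (nrow(pooled) == 0) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  spm = double(), peak_id = character()))
  }
  pooled <- score_per_million(pooled)
  pooled <- resize_to_width(pooled, width, genome)
  out <- iterative_merge(pooled, spm_cutoff)
  out$peak_id <- sprintf("peak_%05d", seq_len(nrow(out)))
  out
}
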