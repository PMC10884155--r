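# Peak-recall machinery: merge all foreground peaks, strip the fragments
# that overlap them to form a pseudo-input, call background peaks on the
# pseudo-input, normalize signal to RP10M, take the (1 - FDR) quantile of
# the background signal as the openness threshold, and dichotomize every
# consensus peak into common / A-specific / B-specific / unassigned.

#' Merge peak sets into a coalesced union of intervals
#'
#' Overlapping and book-ended (gap 0) intervals are coalesced.
#'
#' @param peaksets a list of interval tibbles (or a single tibble) with
#'   `chrom`, `start`, `end`.
#' @return Sorted tibble of disjoint merged intervals.
#' @export
merge_all_peaks <- function(peaksets) {
  if (is.data.frame(peaksets)) peaksets <- list(peaksets)
  pooled <- bind_rows(lapply(peaksets, function(p) p[, c("chrom", "start", "end")]))
  if (nrow(pooled) == 0) return(pooled)
  gr_to_bed(GenomicRanges::reduce(as_gr(pooled))) %>%
    arrange(.data$chrom, .data$start)
}

#' Remove fragments overlapping a merged peak set (pseudo-input)
#'
#' A fragment is removed if it overlaps any merged interval by at least
#' 1 bp. The retained set is the empirical background ("pseudo-input").
#'
#' @param fragments BED3 fragment tibble.
#' @param merged merged intervals from [merge_all_peaks()].
#' @return The retained fragments.
#' @export
make_pseudo_input <- function(fragments, merged) {
  if (nrow(fragments) == 0 || nrow(merged) == 0) return(fragments)
  hits <- GenomicRanges::countOverlaps(as_gr(fragments), as_gr(merged))
  fragments[hits == 0, ]
}

#' Simplified sliding-window Poisson peak caller
#'
#' Fragment midpoints are counted in sliding windows (`window` bp wide,
#' every `step` bp). Window counts are tested against the upper tail of
#' Poisson(lambda) with `lambda = total_midpoints * window / genome_length`.
#' With `correct = "BH"`, Benjamini-Hochberg-adjusted p-values are
#' thresholded at `q`; with `correct = "none"`, raw p-values are (the
#' permissive mode used to harvest background fluctuations from a
#' pseudo-input). Significant overlapping windows are merged into peaks;
#' the summit is the centre of the highest-count window (leftmost on ties).
#'
#' @param fragments BED3 fragment tibble.
#' @param genome genome tibble (`chrom`, `length`).
#' @param window window width in bp (must be a multiple of `step`).
#' @param step window spacing in bp.
#' @param q significance threshold on (adjusted) p-values.
#' @param correct `"BH"` for Benjamini-Hochberg across all windows,
#'   `"none"` for raw p-values.
#' @return Peak tibble with `chrom`, `start`, `end`, `name`, `score` (max
#'   window count), `strand`, `signal`, `pvalue` (min window p, -log10),
#'   `qvalue` and `summit`.
#' @export
call_peaks_simple <- function(fragments, genome, window = 300, step = 150,
                              q = 0.05, correct = c("BH", "none")) {
  correct <- match.arg(correct)
  check_genome(genome)
  if (window <= 0 || step <= 0 || window %% step != 0) {
    abort("window must be a positive multiple of step")
  }
  empty <- tibble(chrom = character(), start = double(), end = double(),
                  name = character(), score = double(), strand = character(),
                  signal = double(), pvalue = double(), qvalue = double(),
                  summit = double())
  if (nrow(fragments) == 0) return(empty)

  wpb <- window / step                      # bins per window
  total_len <- sum(genome$length)
  mids <- floor((fragments$start + fragments$end) / 2)
  lambda <- nrow(fragments) * window / total_len

  per_chrom <- purrr::map(seq_len(nrow(genome)), function(ci) {
    len <- genome$length[ci]
    nbin <- ceiling(len / step)
    m <- mids[fragments$chrom == genome$chrom[ci]]
    binc <- tabulate(pmin(floor(m / step), nbin - 1) + 1L, nbins = nbin)
    # rolling sum of wpb consecutive bins -> window counts
    cs <- cumsum(c(0, binc))
    nwin <- max(nbin - wpb + 1L, 1L)
    counts <- cs[seq_len(nwin) + min(wpb, nbin)] - cs[seq_len(nwin)]
    list(counts = counts, nwin = nwin)
  })
  counts <- unlist(purrr::map(per_chrom, "counts"))
  pvals <- ppois(counts - 1, lambda, lower.tail = FALSE)
  padj <- if (correct == "BH") p.adjust(pvals, "BH") else pvals
  sig <- padj <= q
  if (!any(sig)) return(empty)

  offs <- cumsum(c(0, purrr::map_dbl(per_chrom, "nwin")))
  out <- purrr::map_dfr(seq_len(nrow(genome)), function(ci) {
    idx <- seq_len(per_chrom[[ci]]$nwin)
    s <- sig[offs[ci] + idx]
    if (!any(s)) return(empty)
    w <- which(s)
    cnt <- counts[offs[ci] + idx]
    pv <- pvals[offs[ci] + idx]
    qv <- padj[offs[ci] + idx]
    # group significant windows whose spans overlap (index gap < wpb)
    grp <- cumsum(c(1, diff(w) >= wpb))
    purrr::map_dfr(split(w, grp), function(wi) {
      len <- genome$length[ci]
      start <- (min(wi) - 1) * step
      end <- min((max(wi) - 1) * step + window, len)
      top <- wi[which.max(cnt[wi])]
      summit <- min(floor((top - 1) * step + window / 2), len - 1)
      tibble(chrom = genome$chrom[ci], start = start, end = end,
             name = NA_character_, score = max(cnt[wi]), strand = ".",
             signal = max(cnt[wi]),
             pvalue = -log10(max(min(pv[wi]), 1e-300)),
             qvalue = -log10(max(min(qv[wi]), 1e-300)),
             summit = summit)
    })
  })
  out <- arrange(out, .data$chrom, .data$start)
  out$name <- sprintf("called_%05d", seq_len(nrow(out)))
  out
}

#' Normalize region fragment counts to RP10M
#'
#' RP10M = midpoint count in the region x 1e7 / total unique fragments of
#' the library ("reads per 10 million").
#'
#' @param regions interval tibble.
#' @param fragments BED3 fragment tibble (the full library).
#' @param total_unique library size; defaults to `nrow(fragments)`.
#' @param col name of the output signal column.
#' @return `regions` with the RP10M column appended.
#' @export
normalize_rp10m <- function(regions, fragments, total_unique = nrow(fragments),
                            col = "rp10m") {
  if (total_unique <= 0) abort("total_unique must be positive")
  regions[[col]] <- count_midpoints(regions, fragments) * 1e7 / total_unique
  regions
}

#' FDR-quantile background openness threshold
#'
#' The threshold is the empirical (1 - fdr) quantile of the pooled
#' background-peak signal distribution, taken as the next order statistic
#' (inverse-ECDF / "higher" interpolation): `x_(ceil(n * (1 - fdr)))`. The
#' fraction of background values strictly above it is therefore at most
#' `fdr`.
#'
#' @param background_signals numeric vector of background-peak RP10M values
#'   (both conditions pooled).
#' @param fdr nominal false discovery rate (default 0.005).
#' @return The threshold (same units as the input).
#' @export
estimate_background_threshold <- function(background_signals, fdr = 0.005) {
  if (length(background_signals) == 0) abort("empty background signal set")
  if (fdr < 0 || fdr > 1) abort("fdr must be in [0, 1]")
  if (length(background_signals) < 200) {
    warn("fewer than 200 background signals; threshold estimate is unstable")
  }
  x <- sort(background_signals)
  n <- length(x)
  k <- min(n, max(1L, as.integer(ceiling((1 - fdr) * n))))
  x[k]
}

#' Dichotomize consensus peaks into openness clusters
#'
#' A peak is called open in a condition iff its signal is strictly greater
#' than the background threshold. Labels: `C` (open in both), `I` (open in
#' A only), `N` (open in B only), `unassigned` (open in neither).
#'
#' @param consensus consensus peak tibble carrying `signal_a` and
#'   `signal_b` columns (RP10M, see [normalize_rp10m()]).
#' @param threshold background threshold from
#'   [estimate_background_threshold()].
#' @return An `openness_calls` tibble (input + `label`), with the threshold
#'   stored as an attribute; see [tidy()]/[glance()] methods.
#' @export
classify_openness <- function(consensus, threshold) {
  stopifnot(all(c("signal_a", "signal_b") %in% names(consensus)))
  open_a <- consensus$signal_a > threshold
  open_b <- consensus$signal_b > threshold
  out <- mutate(consensus, label = case_when(
    open_a & open_b ~ "C",
    open_a ~ "I",
    open_b ~ "N",
    TRUE ~ "unassigned"
  ))
  structure(out, threshold = threshold,
            class = c("openness_calls", class(out)))
}

#' Cluster size summary of openness calls
#'
#' @param calls an `openness_calls` tibble.
#' @return One row per label with its count; the four counts partition the
#'   consensus set.
#' @export
openness_summary <- function(calls) {
  lv <- c("C", "I", "N", "unassigned")
  tibble(label = lv,
         n = as.integer(table(factor(calls$label, levels = lv))))
}

#' Full openness-calling stage on two fragment libraries
#'
#' Runs the complete peak-recall procedure: per-condition foreground peak
#' calls (BH-corrected Poisson caller) unless peak sets are supplied,
#' consensus construction, pseudo-input assembly from the pooled fragments,
#' permissive background peak calling, RP10M normalization, FDR-quantile
#' thresholding and classification.
#'
#' @param frags_a,frags_b per-condition BED3 fragment tibbles.
#' @param genome genome tibble.
#' @param peaks_a,peaks_b optional pre-called per-condition peak tibbles
#'   (narrowPeak columns); when `NULL` the built-in caller is used.
#' @param width consensus peak width (bp).
#' @param spm_cutoff consensus spm cutoff.
#' @param fdr background FDR for the openness threshold.
#' @param bg_window,bg_step background caller window/step; the width is
#'   matched to the consensus width so count-based RP10M values are
#'   comparable across the two sets.
#' @return List with `calls` (an `openness_calls` tibble), `consensus`,
#'   `background` (background peaks with per-condition signal), `threshold`
#'   and `summary`.
#' @export
call_openness <- function(frags_a, frags_b, genome,
                          peaks_a = NULL, peaks_b = NULL,
                          width = 500, spm_cutoff = 2, fdr = 0.005,
                          bg_window = 500, bg_step = 250) {
  if (is.null(peaks_a)) peaks_a <- call_peaks_simple(frags_a, genome)
  if (is.null(peaks_b)) peaks_b <- call_peaks_simple(frags_b, genome)
  consensus <- consensus_peaks(list(A = peaks_a, B = peaks_b), genome,
                               width = width, spm_cutoff = spm_cutoff)

  merged <- merge_all_peaks(list(peaks_a, peaks_b))
  pooled <- bind_rows(frags_a, frags_b)
  pseudo <- make_pseudo_input(pooled, merged)
  background <- call_peaks_simple(pseudo, genome, window = bg_window,
                                  step = bg_step, q = 0.05, correct = "none")
  # enforce disjointness from the merged foreground set
  if (nrow(background) > 0 && nrow(merged) > 0) {
    background <- background[
      GenomicRanges::countOverlaps(as_gr(background), as_gr(merged)) == 0, ]
  }
  background <- background %>%
    normalize_rp10m(frags_a, col = "signal_a") %>%
    normalize_rp10m(frags_b, col = "signal_b")
  threshold <- estimate_background_threshold(
    c(background$signal_a, background$signal_b), fdr = fdr)

  consensus <- consensus %>%
    normalize_rp10m(frags_a, col = "signal_a") %>%
    normalize_rp10m(frags_b, col = "signal_b")
  calls <- classify_openness(consensus, threshold)
  list(calls = calls, consensus = consensus, background = background,
       threshold = threshold, summary = openness_summary(calls))
}
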