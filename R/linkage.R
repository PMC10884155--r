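# Peak-to-gene linkage: assign peaks to genes whose TSS lies within a
# fixed window of the peak interval, filter condition-specific links by
# signal fold change, call induction genes from Cluster C links and
# expression, extract primed promoter peaks, and compute the TSS-proximity
# fraction.

#' Link peaks to genes within a TSS window
#'
#' A link is emitted for every (peak, gene) pair whose TSS-to-peak-interval
#' distance is at most `window` bp (0 when the TSS lies inside the peak).
#' Strand is ignored.
#'
#' @param peaks peak tibble (`chrom`, `start`, `end`; `peak_id`, `label`,
#'   `signal_a`, `signal_b` carried through when present).
#' @param genes gene tibble (`chrom`, `tss`, `gene_id`).
#' @param window maximum TSS distance in bp (default 5000).
#' @return Link tibble: peak columns plus `gene_id`, `tss`, `distance`.
#' @export
link_peaks_to_genes <- function(peaks, genes, window = 5000) {
  if (!"peak_id" %in% names(peaks)) {
    peaks$peak_id <- sprintf("peak_%05d", seq_len(max(nrow(peaks), 0)))
  }
  keep <- intersect(c("peak_id", "chrom", "start", "end", "label",
                      "signal_a", "signal_b"), names(peaks))
  empty <- as_tibble(peaks[0, keep]) %>%
    mutate(gene_id = character(), tss = double(), distance = double())
  if (nrow(peaks) == 0 || nrow(genes) == 0) return(empty)
  tss_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$tss + 1L, width = 1L)
  )
  hits <- GenomicRanges::findOverlaps(as_gr(peaks), tss_gr,
                                      maxgap = as.integer(window))
  if (length(hits) == 0) return(empty)
  pi <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  out <- as_tibble(peaks[pi, keep])
  out$gene_id <- genes$gene_id[gi]
  out$tss <- genes$tss[gi]
  out$distance <- tss_interval_distance(genes$tss[gi],
                                        peaks$start[pi], peaks$end[pi])
  out %>%
    filter(.data$distance <= window) %>%
    arrange(.data$chrom, .data$start, .data$gene_id)
}

#' Fold-change filter for condition-specific links
#'
#' Cluster `I`/`N` links are kept only when the pseudocounted signal ratio
#' in the cluster's own direction exceeds `min_fc`; Cluster `C` links pass
#' unfiltered. Links with other labels are dropped.
#'
#' @param links link tibble with `label`, `signal_a`, `signal_b`.
#' @param min_fc minimum fold change (default 2).
#' @param pseudocount added to both signals before the ratio (default 1).
#' @return The filtered links.
#' @export
fold_change_filter <- function(links, min_fc = 2, pseudocount = 1) {
  stopifnot(all(c("label", "signal_a", "signal_b") %in% names(links)))
  fc_i <- (links$signal_a + pseudocount) / (links$signal_b + pseudocount)
  fc_n <- (links$signal_b + pseudocount) / (links$signal_a + pseudocount)
  keep <- links$label == "C" |
    (links$label == "I" & fc_i > min_fc) |
    (links$label == "N" & fc_n > min_fc)
  links[keep, ]
}

#' Mean-TPM log2 fold change per gene between two conditions
#' @noRd
expression_lfc <- function(expression, samples_a, samples_b, pseudocount = 1) {
  stopifnot(all(c(samples_a, samples_b) %in% names(expression)))
  mean_a <- rowMeans(as.matrix(expression[, samples_a, drop = FALSE]))
  mean_b <- rowMeans(as.matrix(expression[, samples_b, drop = FALSE]))
  tibble(gene_id = expression$gene_id,
         mean_tpm_a = mean_a, mean_tpm_b = mean_b,
         lfc = log2((mean_b + pseudocount) / (mean_a + pseudocount)))
}

#' Induction genes among Cluster C-linked genes
#'
#' A gene is an induction gene iff it is linked to a Cluster `C` peak and
#' its mean-TPM log2 fold change (condition B vs A, pseudocounted) is at
#' least `min_lfc`.
#'
#' @param links link tibble with `label` and `gene_id` (only `C` rows are
#'   used).
#' @param expression TPM tibble (`gene_id` + sample columns).
#' @param samples_a,samples_b sample column names for conditions A and B.
#' @param min_lfc induction threshold on log2 fold change (default 1).
#' @param pseudocount TPM pseudocount (default 1).
#' @return Tibble of induction genes (`gene_id`, `lfc`). Linked genes
#'   missing from the expression table are recorded in the
#'   `missing_genes` attribute and skipped.
#' @export
induction_genes <- function(links, expression, samples_a, samples_b,
                            min_lfc = 1, pseudocount = 1) {
  c_genes <- unique(links$gene_id[links$label == "C"])
  missing <- setdiff(c_genes, expression$gene_id)
  if (length(missing) > 0) {
    warn(sprintf("%d linked genes absent from expression matrix; skipped",
                 length(missing)))
  }
  lfc <- expression_lfc(expression, samples_a, samples_b, pseudocount)
  out <- lfc %>%
    filter(.data$gene_id %in% c_genes, .data$lfc >= min_lfc) %>%
    select("gene_id", "lfc") %>%
    arrange(.data$gene_id)
  attr(out, "missing_genes") <- missing
  out
}

#' Primed promoter peaks
#'
#' Peaks already open in the stem-cell state (label `C`) whose nearest
#' linked gene (minimal TSS distance; all tied genes consulted) is an
#' induction gene.
#'
#' @param calls `openness_calls` tibble (or any peak tibble with `peak_id`
#'   and `label`).
#' @param links link tibble from [link_peaks_to_genes()].
#' @param induced tibble or character vector of induction genes.
#' @return The primed subset of `calls` (always a subset of the `C` peaks).
#' @export
primed_promoter_peaks <- function(calls, links, induced) {
  induced_ids <- if (is.data.frame(induced)) induced$gene_id else induced
  nearest <- links %>%
    filter(.data$label == "C") %>%
    group_by(.data$peak_id) %>%
    filter(.data$distance == min(.data$distance)) %>%
    summarise(primed = any(.data$gene_id %in% induced_ids))
  primed_ids <- nearest$peak_id[nearest$primed]
  calls[calls$label == "C" & calls$peak_id %in% primed_ids, ]
}

#' Fraction of peaks within a TSS window
#'
#' @param peaks peak tibble.
#' @param genes gene tibble with `tss`.
#' @param window maximum TSS distance in bp (default 5000).
#' @return Fraction in \[0, 1\] of peaks with any TSS within `window` bp.
#' @export
tss_fraction <- function(peaks, genes, window = 5000) {
  if (nrow(peaks) == 0) abort("empty peak set")
  if (nrow(genes) == 0) return(0)
  links <- link_peaks_to_genes(peaks, genes, window = window)
  length(unique(links$peak_id)) / nrow(peaks)
}
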