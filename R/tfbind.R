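# TF binding overlay: intersect TF ChIP peaks with enhancer-promoter BEDPE
# pairs and with promoter windows, and export deduplicated target-gene
# lists with their evidence class.

#' TF-bound enhancer-promoter pairs
#'
#' A pair is retained iff at least one ChIP peak overlaps the selected
#' anchor by >= 1 bp. Each retained pair records how many ChIP peaks hit it
#' and the largest single-peak overlap in bp.
#'
#' @param pairs BEDPE tibble (anchor 1 = enhancer, anchor 2 = promoter).
#' @param chip ChIP peak tibble (`chrom`, `start`, `end`).
#' @param anchor `"enhancer"` (anchor 1 only, the default) or `"either"`.
#' @return The retained pairs with `n_chip` and `chip_overlap_bp` columns,
#'   ordered by (chrom1, start1, name).
#' @export
intersect_pairs <- function(pairs, chip, anchor = c("enhancer", "either")) {
  anchor <- match.arg(anchor)
  empty <- mutate(pairs[0, ], n_chip = integer(), chip_overlap_bp = double())
  if (nrow(pairs) == 0 || nrow(chip) == 0) return(empty)
  chip_gr <- as_gr(chip)
  overlap_stats <- function(prefix) {
    a <- tibble(chrom = pairs[[paste0("chrom", prefix)]],
                start = pairs[[paste0("start", prefix)]],
                end = pairs[[paste0("end", prefix)]])
    hits <- GenomicRanges::findOverlaps(as_gr(a), chip_gr)
    ov <- GenomicRanges::width(GenomicRanges::pintersect(
      as_gr(a)[S4Vectors::queryHits(hits)],
      chip_gr[S4Vectors::subjectHits(hits)]
    ))
    n <- tabulate(S4Vectors::queryHits(hits), nbins = nrow(pairs))
    best <- rep(0, nrow(pairs))
    if (length(hits) > 0) {
      agg <- tapply(ov, S4Vectors::queryHits(hits), max)
      best[as.integer(names(agg))] <- agg
    }
    list(n = n, best = best)
  }
  s1 <- overlap_stats("1")
  if (anchor == "enhancer") {
    n <- s1$n; best <- s1$best
  } else {
    s2 <- overlap_stats("2")
    n <- s1$n + s2$n
    best <- pmax(s1$best, s2$best)
  }
  out <- pairs[n > 0, ]
  out$n_chip <- n[n > 0]
  out$chip_overlap_bp <- best[n > 0]
  arrange(out, .data$chrom1, .data$start1, .data$name)
}

#' Genes with TF binding at their promoter
#'
#' A gene is returned iff a ChIP peak overlaps
#' `[TSS - promoter_window, TSS + promoter_window)` by >= 1 bp.
#'
#' @param chip ChIP peak tibble.
#' @param genes gene tibble (`chrom`, `tss`, `gene_id`).
#' @param promoter_window promoter half-width in bp (default 2000).
#' @return Tibble `gene_id`, `n_chip`, ordered by gene_id.
#' @export
promoter_binding <- function(chip, genes, promoter_window = 2000) {
  if (nrow(chip) == 0 || nrow(genes) == 0) {
    return(tibble(gene_id = character(), n_chip = integer()))
  }
  prom <- tibble(chrom = genes$chrom,
                 start = pmax(0, genes$tss - promoter_window),
                 end = genes$tss + promoter_window)
  n <- GenomicRanges::countOverlaps(as_gr(prom), as_gr(chip))
  tibble(gene_id = genes$gene_id[n > 0], n_chip = as.integer(n[n > 0])) %>%
    arrange(.data$gene_id)
}

#' Export deduplicated TF target-gene lists
#'
#' Combines enhancer-bound pair targets and promoter-bound genes into one
#' list with an evidence class per gene: `enhancer`, `promoter` or `both`.
#'
#' @param bound_pairs retained pairs from [intersect_pairs()] (`name` is
#'   the target gene id).
#' @param promoter_bound tibble from [promoter_binding()].
#' @param path optional TSV output path.
#' @return Tibble `gene_id`, `evidence`, ordered by gene_id.
#' @export
export_target_genes <- function(bound_pairs, promoter_bound, path = NULL) {
  enh <- unique(bound_pairs$name)
  prom <- unique(promoter_bound$gene_id)
  out <- tibble(gene_id = sort(union(enh, prom))) %>%
    mutate(evidence = case_when(
      .data$gene_id %in% enh & .data$gene_id %in% prom ~ "both",
      .data$gene_id %in% enh ~ "enhancer",
      TRUE ~ "promoter"
    ))
  if (!is.null(path)) readr::write_tsv(out, path, progress = FALSE)
  out
}
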