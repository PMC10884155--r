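# Truth-comparison helpers for synthetic datasets: map recovered calls back
# onto planted regions/genes and score them.

#' Assign openness labels to planted truth regions
#'
#' Each planted region receives the label of the consensus peak overlapping
#' it (the one with the largest overlap when several do), or `unassigned`
#' when no consensus peak covers it. Decoy regions are expected to come
#' back `unassigned`.
#'
#' @param truth_regions truth region tibble (from `sim_dataset$truth`).
#' @param calls `openness_calls` tibble.
#' @return `truth_regions` with `predicted` and `expected` label columns.
#' @export
match_truth_regions <- function(truth_regions, calls) {
  predicted <- rep("unassigned", nrow(truth_regions))
  if (nrow(calls) > 0 && nrow(truth_regions) > 0) {
    hits <- GenomicRanges::findOverlaps(as_gr(truth_regions), as_gr(calls))
    if (length(hits) > 0) {
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      ov <- GenomicRanges::width(GenomicRanges::pintersect(
        as_gr(truth_regions)[qh], as_gr(calls)[sh]))
      best <- tapply(seq_along(qh), qh, function(i) sh[i[which.max(ov[i])]])
      predicted[as.integer(names(best))] <- calls$label[unlist(best)]
    }
  }
  mutate(truth_regions, predicted = predicted,
         expected = ifelse(.data$class == "decoy", "unassigned", .data$class))
}

#' Balanced accuracy of recovered openness labels
#'
#' Mean per-class recall over the truth classes (C, I, N and
#' decoy-as-unassigned).
#'
#' @param truth_regions truth region tibble.
#' @param calls `openness_calls` tibble.
#' @return A scalar in \[0, 1\].
#' @export
openness_balanced_accuracy <- function(truth_regions, calls) {
  m <- match_truth_regions(truth_regions, calls)
  recalls <- m %>%
    group_by(.data$expected) %>%
    summarise(recall = mean(.data$predicted == .data$expected))
  mean(recalls$recall)
}

#' Precision/recall/F1 of a recovered gene or region set
#'
#' @param recovered character vector of recovered ids.
#' @param truth character vector of true ids.
#' @return Tibble with `precision`, `recall`, `f1`, `n_recovered`,
#'   `n_truth`.
#' @export
set_f1 <- function(recovered, truth) {
  recovered <- unique(recovered)
  truth <- unique(truth)
  tp <- length(intersect(recovered, truth))
  precision <- if (length(recovered) > 0) tp / length(recovered) else NA_real_
  recall <- if (length(truth) > 0) tp / length(truth) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  tibble(precision = precision, recall = recall, f1 = f1,
         n_recovered = length(recovered), n_truth = length(truth))
}

#' Recall of planted enhancer-target links by ABC pairs
#'
#' A planted link (enhancer region, target gene) counts as recovered when
#' some emitted non-promoter pair for that gene overlaps the enhancer
#' region. Only enhancers open in the scored condition participate.
#'
#' @param pairs pair tibble from [abc_scores()] / [run_abc()].
#' @param truth_regions truth region tibble.
#' @param classes openness classes of enhancers that the scored condition
#'   can see (default `c("C", "N")` for a condition-B model).
#' @return Tibble with `recall`, `n_recovered`, `n_truth`.
#' @export
abc_link_recall <- function(pairs, truth_regions, classes = c("C", "N")) {
  enh <- truth_regions %>%
    filter(.data$role == "enhancer", .data$class %in% classes,
           !is.na(.data$target_gene))
  if (nrow(enh) == 0) {
    return(tibble(recall = NA_real_, n_recovered = 0L, n_truth = 0L))
  }
  ep <- pairs[!pairs$is_promoter, ]
  hit <- vapply(seq_len(nrow(enh)), function(i) {
    cand <- ep[ep$gene_id == enh$target_gene[i] & ep$chrom == enh$chrom[i], ]
    any(cand$start < enh$end[i] & enh$start[i] < cand$end)
  }, logical(1))
  tibble(recall = mean(hit), n_recovered = sum(hit), n_truth = nrow(enh))
}
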