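# Knockdown-response classification: define the wild-type differentiation
# response (induced / repressed / flat) from mean TPM, then measure how
# much of that response the knockdown line retains. The attenuation ratio
# r = kd_delta / wt_delta is the fraction of the WT log2 change achieved
# under knockdown; genes with r below the cutoff are "affected".

#' Wild-type differentiation response per gene
#'
#' `wt_delta = log2((mean TPM NPC + pc) / (mean TPM ESC + pc))` over the
#' wild-type samples; a gene is induced iff `wt_delta >= lfc_threshold`,
#' repressed iff `<= -lfc_threshold`, else flat.
#'
#' @param expression TPM tibble (`gene_id` + sample columns).
#' @param sample_sheet tibble with `sample`, `genotype` (`WT`/`KD`),
#'   `stage` (`ESC`/`NPC`).
#' @param lfc_threshold response threshold on |log2 fold change| (default
#'   1).
#' @param pseudocount TPM pseudocount (default 1).
#' @return Tibble `gene_id`, `wt_delta`, `response`.
#' @export
define_wt_response <- function(expression, sample_sheet, lfc_threshold = 1,
                               pseudocount = 1) {
  esc <- sample_sheet$sample[sample_sheet$genotype == "WT" &
                               sample_sheet$stage == "ESC"]
  npc <- sample_sheet$sample[sample_sheet$genotype == "WT" &
                               sample_sheet$stage == "NPC"]
  if (length(esc) == 0 || length(npc) == 0) {
    abort("need at least one WT ESC and one WT NPC sample")
  }
  lfc <- expression_lfc(expression, esc, npc, pseudocount)
  tibble(gene_id = lfc$gene_id, wt_delta = lfc$lfc) %>%
    mutate(response = case_when(
      .data$wt_delta >= lfc_threshold ~ "induced",
      .data$wt_delta <= -lfc_threshold ~ "repressed",
      TRUE ~ "flat"
    ))
}

#' Four-cluster knockdown-effect classification
#'
#' For non-flat genes the knockdown delta (same log2 ratio over the KD
#' samples) is compared to the wild-type delta through the attenuation
#' ratio `r = kd_delta / wt_delta`; the gene is "affected" iff
#' `r < attenuation_cutoff` (the KD line fails to achieve that fraction of
#' the WT change in the same direction). Clusters: 1 = WT up, KD
#' unaffected; 2 = WT up, KD affected; 3 = WT down, KD unaffected;
#' 4 = WT down, KD affected; flat genes get `none`.
#'
#' @param response tibble from [define_wt_response()].
#' @param expression TPM tibble.
#' @param sample_sheet sample sheet (needs KD ESC and KD NPC samples).
#' @param attenuation_cutoff affected iff `r` < this (default 0.5).
#' @param pseudocount TPM pseudocount (default 1).
#' @return A `kd_response_calls` tibble: `gene_id`, `wt_delta`,
#'   `response`, `kd_delta`, `attenuation`, `cluster`; see
#'   [tidy()]/[glance()].
#' @export
classify_kd_effect <- function(response, expression, sample_sheet,
                               attenuation_cutoff = 0.5, pseudocount = 1) {
  esc <- sample_sheet$sample[sample_sheet$genotype == "KD" &
                               sample_sheet$stage == "ESC"]
  npc <- sample_sheet$sample[sample_sheet$genotype == "KD" &
                               sample_sheet$stage == "NPC"]
  if (length(esc) == 0 || length(npc) == 0) {
    abort("need at least one KD ESC and one KD NPC sample")
  }
  if (any(response$response != "flat" & response$wt_delta == 0)) {
    abort("internal consistency error: non-flat gene with wt_delta = 0")
  }
  kd <- expression_lfc(expression, esc, npc, pseudocount)
  out <- response %>%
    left_join(tibble(gene_id = kd$gene_id, kd_delta = kd$lfc),
              by = "gene_id") %>%
    mutate(
      attenuation = ifelse(.data$response == "flat", NA_real_,
                           .data$kd_delta / .data$wt_delta),
      affected = !is.na(.data$attenuation) &
        .data$attenuation < attenuation_cutoff,
      cluster = case_when(
        .data$response == "flat" ~ "none",
        .data$response == "induced" & !.data$affected ~ "1",
        .data$response == "induced" & .data$affected ~ "2",
        .data$response == "repressed" & !.data$affected ~ "3",
        TRUE ~ "4"
      )
    ) %>%
    select(-"affected")
  structure(out, attenuation_cutoff = attenuation_cutoff,
            class = c("kd_response_calls", class(out)))
}

#' Agglomerative-clustering cross-check of the KD classification
#'
#' Hierarchical clustering (Euclidean distance, average linkage) of the
#' per-gene `(wt_delta, kd_delta)` profiles of non-flat genes, cut at `k`
#' clusters. Provided as an unsupervised cross-check of the deterministic
#' attenuation rule; cluster numbers are arbitrary.
#'
#' @param calls a `kd_response_calls` tibble.
#' @param k number of clusters (default 4).
#' @return `calls` (non-flat genes only) with an `hclust_cluster` column.
#' @export
kd_cluster_hclust <- function(calls, k = 4) {
  x <- calls[calls$response != "flat", ]
  if (nrow(x) < k) abort("fewer non-flat genes than clusters")
  hc <- hclust(dist(cbind(x$wt_delta, x$kd_delta)), method = "average")
  x$hclust_cluster <- cutree(hc, k = k)
  x
}
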