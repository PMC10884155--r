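# Self-contained Activity-by-Contact scoring. Candidate elements are
# fixed-width summit-centred peak cores ranked by ATAC signal; activity is
# the geometric mean of ATAC and H3K27ac counts; contact follows a
# power-law distance decay (or a binned table); the ABC score of an
# element for a gene is its activity x contact share of all elements in
# the gene's window, the gene's own promoter element included.

#' Build candidate enhancer elements from peaks
#'
#' Peaks are resized to `width` bp around their summits, ranked by ATAC
#' midpoint count (ties broken by chrom, start) and the top `top_n` kept.
#' Elements overlapping the blacklist are removed; remaining overlapping
#' elements are merged into their combined span and their reads recounted
#' over the merged span (no double counting).
#'
#' @param peaks peak tibble with `chrom`, `summit`.
#' @param fragments ATAC BED3 fragment tibble.
#' @param genome genome tibble.
#' @param top_n number of top elements retained (default 150000).
#' @param width element width in bp (default 250).
#' @param blacklist optional BED3 tibble of excluded regions.
#' @return Element tibble: `chrom`, `start`, `end`, `atac_count`,
#'   `element_id`.
#' @export
make_candidate_elements <- function(peaks, fragments, genome,
                                    top_n = 150000, width = 250,
                                    blacklist = NULL) {
  if (nrow(peaks) == 0) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  atac_count = integer(), element_id = character()))
  }
  # width 250 is odd-ended: use floor/ceiling halves around the summit
  chrom_len <- genome$length[match(peaks$chrom, genome$chrom)]
  el <- tibble(chrom = peaks$chrom,
               start = pmax(0, peaks$summit - floor(width / 2)),
               end = pmin(chrom_len, peaks$summit + ceiling(width / 2)))
  el$atac_count <- count_midpoints(el, fragments)
  el <- el[order(-el$atac_count, el$chrom, el$start), ]
  el <- head(el, top_n)
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    el <- el[GenomicRanges::countOverlaps(as_gr(el), as_gr(blacklist)) == 0, ]
  }
  if (nrow(el) == 0) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  atac_count = integer(), element_id = character()))
  }
  merged <- gr_to_bed(GenomicRanges::reduce(as_gr(el))) %>%
    arrange(.data$chrom, .data$start)
  merged$atac_count <- count_midpoints(merged, fragments)
  merged$element_id <- sprintf("element_%05d", seq_len(nrow(merged)))
  merged
}

#' Element activity: geometric mean of ATAC and H3K27ac counts
#'
#' `A = sqrt(atac_count * k27ac_count)`; zero if either count is zero.
#'
#' @param elements element tibble.
#' @param atac_fragments,k27ac_fragments BED3 fragment tibbles; counts are
#'   midpoint counts over each element.
#' @return `elements` with `atac_count`, `k27ac_count` and `activity`.
#' @export
element_activity <- function(elements, atac_fragments, k27ac_fragments) {
  elements$atac_count <- count_midpoints(elements, atac_fragments)
  elements$k27ac_count <- count_midpoints(elements, k27ac_fragments)
  if (any(elements$atac_count < 0 | elements$k27ac_count < 0)) {
    abort("negative counts")
  }
  elements$activity <- sqrt(elements$atac_count * elements$k27ac_count)
  elements
}

#' Contact model for element-TSS distance decay
#'
#' Power-law mode: `C(d) = (d + d0)^(-gamma)`. Table mode: the contact
#' value of the distance bin containing `d` (2-column table: `bin_start`
#' in bp, `contact`); distances beyond the last bin are an error.
#'
#' @param mode `"powerlaw"` or `"table"`.
#' @param gamma decay exponent (power-law mode, default 1).
#' @param d0 distance floor in bp (default 5000).
#' @param table binned contact tibble (table mode).
#' @return A `contact_model` object for [contact()].
#' @export
contact_model <- function(mode = c("powerlaw", "table"), gamma = 1.0,
                          d0 = 5000, table = NULL) {
  mode <- match.arg(mode)
  if (mode == "powerlaw") {
    if (gamma <= 0 || d0 <= 0) abort("gamma and d0 must be positive")
  } else {
    stopifnot(is.data.frame(table),
              all(c("bin_start", "contact") %in% names(table)))
    table <- arrange(table, .data$bin_start)
    if (any(table$contact <= 0)) abort("table contact values must be positive")
    if (is.unsorted(-table$contact)) {
      warn("contact table is not non-increasing in distance")
    }
  }
  structure(list(mode = mode, gamma = gamma, d0 = d0, table = table),
            class = "contact_model")
}

#' Evaluate a contact model at given distances
#'
#' @param model a [contact_model()].
#' @param distance numeric vector of distances in bp (>= 0).
#' @return Contact values (strictly positive).
#' @export
contact <- function(model, distance) {
  stopifnot(inherits(model, "contact_model"))
  if (any(distance < 0)) abort("distance must be non-negative")
  if (model$mode == "powerlaw") {
    return((distance + model$d0)^(-model$gamma))
  }
  tb <- model$table
  idx <- findInterval(distance, tb$bin_start)
  if (any(idx == 0)) abort("distance below the first contact table bin")
  # bins are [bin_start_i, bin_start_{i+1}); the last bin keeps the width
  # of its predecessor (single-bin tables are open-ended)
  last_end <- if (nrow(tb) > 1) {
    tb$bin_start[nrow(tb)] + diff(tail(tb$bin_start, 2))
  } else Inf
  if (any(distance >= last_end)) {
    abort("distance beyond the contact table range")
  }
  tb$contact[idx]
}

#' ABC scores and thresholded enhancer-gene pairs
#'
#' For each gene, every candidate element whose midpoint lies within
#' `window` bp of the TSS participates, together with the gene's own
#' promoter element (TSS +/- `promoter_halfwidth`; candidate elements
#' overlapping it are replaced by it to avoid double counting). The score
#' of element e is `A_e C_e / sum(A C)` over the participants, so scores
#' for a gene sum to 1. Pairs with `score >= threshold` are returned.
#'
#' @param elements element tibble with `activity` (see
#'   [element_activity()]).
#' @param genes gene tibble (`chrom`, `tss`, `gene_id`); an optional
#'   `promoter_activity` column gives the promoter element activity
#'   (default 0, in which case the promoter contributes nothing).
#' @param model a [contact_model()].
#' @param window scoring window around the TSS in bp (default 5e6).
#' @param threshold minimum reported score (default 0.02; use 0 to get all
#'   pairs).
#' @param promoter_halfwidth promoter element half-width in bp (default
#'   250).
#' @return Pair tibble: element columns, `gene_id`, `tss`, `distance`,
#'   `abc_score`, `is_promoter`. Genes whose window holds only zero
#'   activities yield no pairs and are recorded in the `flagged_genes`
#'   attribute.
#' @export
abc_scores <- function(elements, genes, model, window = 5e6,
                       threshold = 0.02, promoter_halfwidth = 250) {
  stopifnot("activity" %in% names(elements))
  if (!"element_id" %in% names(elements)) {
    elements$element_id <- sprintf("element_%05d", seq_len(max(nrow(elements), 0)))
  }
  mid <- floor((elements$start + elements$end) / 2)
  flagged <- character(0)
  res <- purrr::map_dfr(seq_len(nrow(genes)), function(gi) {
    g <- genes[gi, ]
    prom_activity <- if ("promoter_activity" %in% names(genes)) {
      g$promoter_activity
    } else 0
    prom <- tibble(
      chrom = g$chrom,
      start = max(0, g$tss - promoter_halfwidth),
      end = g$tss + promoter_halfwidth,
      element_id = paste0("promoter_", g$gene_id),
      activity = prom_activity,
      is_promoter = TRUE
    )
    near <- elements$chrom == g$chrom & abs(mid - g$tss) <= window &
      !(elements$start < prom$end & prom$start < elements$end)
    cand <- elements[near, c("chrom", "start", "end", "element_id", "activity")]
    cand$is_promoter <- FALSE
    parts <- bind_rows(cand, prom)
    parts$distance <- abs(floor((parts$start + parts$end) / 2) - g$tss)
    denom <- sum(parts$activity * contact(model, parts$distance))
    if (denom <= 0) {
      flagged <<- c(flagged, g$gene_id)
      return(parts[0, ])
    }
    parts$abc_score <- parts$activity * contact(model, parts$distance) / denom
    parts$gene_id <- g$gene_id
    parts$tss <- g$tss
    parts[parts$abc_score >= threshold, ]
  })
  if (length(flagged) > 0) {
    warn(sprintf("%d genes had all-zero activity in their window", length(flagged)))
  }
  if (nrow(res) > 0) {
    res <- arrange(res, .data$gene_id, desc(.data$abc_score))
  }
  attr(res, "flagged_genes") <- flagged
  res
}

#' Convert enhancer-gene pairs to 10-column BEDPE
#'
#' Anchor 1 is the element, anchor 2 the promoter window
#' (TSS +/- `promoter_halfwidth`), `name` the gene id, `score` the ABC
#' score.
#'
#' @param pairs pair tibble from [abc_scores()].
#' @param promoter_halfwidth promoter anchor half-width in bp.
#' @return BEDPE tibble (see [write_bedpe()]).
#' @export
pairs_to_bedpe <- function(pairs, promoter_halfwidth = 250) {
  tibble(
    chrom1 = pairs$chrom, start1 = pairs$start, end1 = pairs$end,
    chrom2 = pairs$chrom, start2 = pmax(0, pairs$tss - promoter_halfwidth),
    end2 = pairs$tss + promoter_halfwidth,
    name = pairs$gene_id, score = pairs$abc_score,
    strand1 = ".", strand2 = "."
  )
}

#' Full ABC stage: elements, activities, promoter activities, scores
#'
#' @param peaks peak tibble for the scored condition (with summits).
#' @param atac_fragments,k27ac_fragments BED3 fragment tibbles.
#' @param genes gene tibble.
#' @param genome genome tibble.
#' @param model a [contact_model()]; defaults to power-law with
#'   `gamma = 1`, `d0 = 5000`.
#' @param top_n,width,blacklist passed to [make_candidate_elements()].
#' @param window,threshold,promoter_halfwidth passed to [abc_scores()].
#' @return List with `elements` and `pairs`.
#' @export
run_abc <- function(peaks, atac_fragments, k27ac_fragments, genes, genome,
                    model = contact_model("powerlaw"),
                    top_n = 150000, width = 250, blacklist = NULL,
                    window = 5e6, threshold = 0.02,
                    promoter_halfwidth = 250) {
  elements <- make_candidate_elements(peaks, atac_fragments, genome,
                                      top_n = top_n, width = width,
                                      blacklist = blacklist)
  elements <- element_activity(elements, atac_fragments, k27ac_fragments)
  promoters <- tibble(chrom = genes$chrom,
                      start = pmax(0, genes$tss - promoter_halfwidth),
                      end = genes$tss + promoter_halfwidth)
  prom_act <- element_activity(promoters, atac_fragments, k27ac_fragments)
  genes$promoter_activity <- prom_act$activity
  pairs <- abc_scores(elements, genes, model, window = window,
                      threshold = threshold,
                      promoter_halfwidth = promoter_halfwidth)
  list(elements = elements, pairs = pairs)
}
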