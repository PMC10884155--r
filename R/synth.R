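# Synthetic two-condition multi-omic generator. Condition A plays the
# stem-cell (iPSC/ESC) state and condition B the neural-progenitor state.
# Planted regions come in four classes: C (open in both), I (A-specific),
# N (B-specific) and decoy (closed in both). Open regions are either gene
# promoters (a gene TSS sits at the region centre) or distal enhancers
# paired with the nearest promoter-anchored gene. Expression, H3K27ac and TF
# ChIP peaks are coupled to those roles so every downstream stage has a
# recoverable ground truth.

#' Simulation configuration
#'
#' Region count rates are expressed per 10 million fragments: the negative
#' binomial mean for a region is `rate * n_background_reads / 1e7`, with the
#' background read count standing in for library size. With the defaults an
#' open region carries a planted mean of 200 midpoints against a ~50-read
#' local background per 500 bp, and a closed region a planted mean of 2 —
#' a desk-scale emulation of a deeply sequenced ATAC library.
#'
#' @param genome tibble with `chrom`, `length` (bp).
#' @param n_common,n_a_specific,n_b_specific,n_closed_decoy planted region
#'   counts per class.
#' @param region_width planted region width (bp).
#' @param open_rate,closed_rate expected fragment midpoints per open/closed
#'   region per 10M fragments; `open_rate` must exceed `closed_rate`.
#' @param dispersion negative binomial size parameter for region counts.
#' @param n_background_reads uniform background fragments per condition.
#' @param n_genes number of genes.
#' @param frac_genes_near_peak fraction of genes whose TSS is planted at the
#'   centre of an open region (the promoter-anchored genes).
#' @param frac_kd_dependent fraction of non-flat genes whose induction or
#'   repression is attenuated in the knockdown line.
#' @param tf_frac_enh,tf_frac_prom fractions of true (B-open) enhancers and
#'   promoters receiving a TF ChIP peak.
#' @param gamma contact decay exponent carried into the ABC stage.
#' @param seed integer seed; the whole dataset is deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome = tibble(chrom = c("chr1", "chr2"),
                                       length = c(6e6, 4e6)),
                       n_common = 50, n_a_specific = 30, n_b_specific = 30,
                       n_closed_decoy = 50,
                       region_width = 500,
                       open_rate = 2000, closed_rate = 20,
                       dispersion = 10,
                       n_background_reads = 1e6,
                       n_genes = 150,
                       frac_genes_near_peak = 0.6,
                       frac_kd_dependent = 0.3,
                       tf_frac_enh = 0.6, tf_frac_prom = 0.4,
                       gamma = 1.0,
                       seed = 1L) {
  check_genome(genome)
  counts <- c(n_common, n_a_specific, n_b_specific, n_closed_decoy, n_genes)
  if (any(counts < 0)) abort("region and gene counts must be non-negative")
  if (region_width <= 0 || n_background_reads <= 0) {
    abort("region_width and n_background_reads must be positive")
  }
  if (open_rate <= closed_rate) abort("open_rate must exceed closed_rate")
  if (frac_genes_near_peak < 0 || frac_genes_near_peak > 1) {
    abort("frac_genes_near_peak must be in [0, 1]")
  }
  structure(
    list(genome = genome, n_common = n_common, n_a_specific = n_a_specific,
         n_b_specific = n_b_specific, n_closed_decoy = n_closed_decoy,
         region_width = region_width, open_rate = open_rate,
         closed_rate = closed_rate, dispersion = dispersion,
         n_background_reads = n_background_reads, n_genes = n_genes,
         frac_genes_near_peak = frac_genes_near_peak,
         frac_kd_dependent = frac_kd_dependent,
         tf_frac_enh = tf_frac_enh, tf_frac_prom = tf_frac_prom,
         gamma = gamma, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# internal generator constants (documented in the methods vignette)
.synth <- list(
  min_gap = 10000,        # bp between planted features; > 2x the 5 kb link window
  frag_len = 100,         # written fragment length
  k27_background_frac = 0.2,
  k27_coupling = 0.5,     # H3K27ac planted mean = coupling * ATAC count in B
  frac_c_primed = 0.5,    # probability a class-C promoter gene is induced
  tpm_base_range = c(20, 200),
  lfc_range = c(1, 3),    # log2 fold-change of induced/repressed genes
  tpm_noise_sd = 0.15,    # log2-scale per-sample noise
  kd_affected_range = c(0, 0.3),
  kd_unaffected_range = c(0.8, 1.2),
  body_len_range = c(2000, 20000),
  tf_peak_width = 200,
  n_reps = 2
)

#' @noRd
place_regions <- function(genome, n, width, min_gap = .synth$min_gap,
                          max_attempts = 200 * n + 1000) {
  if (n == 0) {
    return(tibble(chrom = character(), start = double(), end = double()))
  }
  if (any(genome$length < width)) abort("region_width exceeds a chromosome length")
  chroms <- character(n); starts <- double(n)
  placed <- 0L; attempts <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      abort("placement failure: could not place non-overlapping regions; genome too crowded")
    }
    ci <- sample.int(nrow(genome), 1, prob = genome$length)
    s <- floor(runif(1, 0, genome$length[ci] - width))
    ok <- TRUE
    if (placed > 0) {
      same <- chroms[seq_len(placed)] == genome$chrom[ci]
      if (any(same)) {
        ps <- starts[seq_len(placed)][same]
        ok <- all(s + width + min_gap <= ps | ps + width + min_gap <= s)
      }
    }
    if (ok) {
      placed <- placed + 1L
      chroms[placed] <- genome$chrom[ci]
      starts[placed] <- s
    }
  }
  tibble(chrom = chroms, start = starts, end = starts + width) %>%
    arrange(.data$chrom, .data$start)
}

#' @noRd
uniform_fragments <- function(genome, n, frag_len = .synth$frag_len) {
  if (n == 0) return(tibble(chrom = character(), start = double(), end = double()))
  ci <- sample.int(nrow(genome), n, replace = TRUE, prob = genome$length)
  len <- genome$length[ci]
  mid <- floor(runif(n, 0, len))
  tibble(chrom = genome$chrom[ci],
         start = pmax(0, mid - frag_len / 2),
         end = pmin(len, mid + frag_len / 2))
}

#' @noRd
region_fragments <- function(regions, counts, genome,
                             frag_len = .synth$frag_len) {
  keep <- counts > 0
  if (!any(keep)) {
    return(tibble(chrom = character(), start = double(), end = double()))
  }
  idx <- rep(which(keep), counts[keep])
  len <- genome$length[match(regions$chrom[idx], genome$chrom)]
  mid <- floor(runif(length(idx), regions$start[idx], regions$end[idx]))
  tibble(chrom = regions$chrom[idx],
         start = pmax(0, mid - frag_len / 2),
         end = pmin(len, mid + frag_len / 2))
}

#' Generate a complete synthetic two-condition multi-omic dataset
#'
#' @param config a [sim_config()].
#' @return A `sim_dataset` list with elements `fragments` (list `A`, `B` of
#'   BED3 tibbles), `peaks` (per-condition idealized peak calls at the open
#'   planted regions), `k27ac` (H3K27ac fragments, condition B), `genes`,
#'   `expression` (gene x sample TPM), `sample_sheet`, `chip` (TF ChIP
#'   peaks), `truth` (list `regions`, `genes`) and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_dataset_impl(config))
}

#' @noRd
simulate_dataset_impl <- function(cfg) {
  genome <- cfg$genome
  scale <- cfg$n_background_reads / 1e7
  mu_open <- cfg$open_rate * scale
  mu_closed <- cfg$closed_rate * scale

  n_regions <- cfg$n_common + cfg$n_a_specific + cfg$n_b_specific +
    cfg$n_closed_decoy
  regions <- place_regions(genome, n_regions, cfg$region_width)
  cls <- sample(rep(c("C", "I", "N", "decoy"),
                    c(cfg$n_common, cfg$n_a_specific, cfg$n_b_specific,
                      cfg$n_closed_decoy)))
  regions$region_id <- sprintf("region_%03d", seq_len(nrow(regions)))
  regions$class <- if (n_regions > 0) cls else character(0)
  regions$open_a <- regions$class %in% c("C", "I")
  regions$open_b <- regions$class %in% c("C", "N")

  # genes: anchored at open-region centres, remainder on clear background
  n_anchor <- min(round(cfg$frac_genes_near_peak * cfg$n_genes),
                  sum(regions$class != "decoy"))
  open_idx <- which(regions$class != "decoy")
  anchor_idx <- if (n_anchor > 0) sort(sample(open_idx, n_anchor)) else integer(0)
  regions$role <- ifelse(regions$class == "decoy", "decoy", "enhancer")
  regions$role[anchor_idx] <- "promoter"

  genes <- make_genes(cfg, regions, anchor_idx)

  # enhancer targets: nearest promoter-anchored gene on the same chromosome
  regions$target_gene <- NA_character_
  enh <- which(regions$role == "enhancer")
  if (length(enh) > 0 && nrow(genes) > 0) {
    anch <- filter(genes, !is.na(.data$anchor_region))
    for (i in enh) {
      cand <- anch[anch$chrom == regions$chrom[i], ]
      if (nrow(cand) > 0) {
        mid <- (regions$start[i] + regions$end[i]) / 2
        regions$target_gene[i] <- cand$gene_id[which.min(abs(cand$tss - mid))]
      }
    }
  }

  # per-region ATAC counts and fragments
  draw_counts <- function(open) {
    mu <- ifelse(open, mu_open, mu_closed)
    if (length(mu) == 0) return(integer(0))
    rnbinom(length(mu), mu = mu, size = cfg$dispersion)
  }
  count_a <- draw_counts(regions$open_a)
  count_b <- draw_counts(regions$open_b)
  frags_a <- bind_rows(
    uniform_fragments(genome, cfg$n_background_reads),
    region_fragments(regions, count_a, genome)
  )
  frags_b <- bind_rows(
    uniform_fragments(genome, cfg$n_background_reads),
    region_fragments(regions, count_b, genome)
  )

  # idealized per-condition peak calls at the open planted regions
  peak_tbl <- function(open, counts) {
    r <- regions[open, ]
    if (nrow(r) == 0) {
      return(tibble(chrom = character(), start = double(), end = double(),
                    name = character(), score = double(), strand = character(),
                    signal = double(), pvalue = double(), qvalue = double(),
                    summit = double()))
    }
    tibble(chrom = r$chrom, start = r$start, end = r$end,
           name = r$region_id, score = as.double(counts[open]), strand = ".",
           signal = as.double(counts[open]), pvalue = -1, qvalue = -1,
           summit = floor((r$start + r$end) / 2))
  }
  peaks <- list(A = peak_tbl(regions$open_a, count_a),
                B = peak_tbl(regions$open_b, count_b))

  # H3K27ac (condition B): coupled to ATAC at B-open elements
  k27_counts <- ifelse(regions$open_b,
                       rpois(max(nrow(regions), 0),
                             .synth$k27_coupling * (count_b + 1)),
                       0L)
  k27ac <- bind_rows(
    uniform_fragments(genome,
                      round(.synth$k27_background_frac * cfg$n_background_reads)),
    region_fragments(regions, k27_counts, genome)
  )

  # TF ChIP peaks on B-open enhancers and promoters
  regions$tf_bound <- FALSE
  bind_tf <- function(idx, frac) {
    if (length(idx) == 0 || frac <= 0) return(integer(0))
    k <- round(frac * length(idx))
    if (k == 0) return(integer(0))
    sort(sample(idx, k))
  }
  tf_idx <- c(
    bind_tf(which(regions$role == "enhancer" & regions$open_b), cfg$tf_frac_enh),
    bind_tf(which(regions$role == "promoter" & regions$open_b), cfg$tf_frac_prom)
  )
  regions$tf_bound[tf_idx] <- TRUE
  chip <- if (length(tf_idx) > 0) {
    mid <- floor((regions$start[tf_idx] + regions$end[tf_idx]) / 2)
    tibble(chrom = regions$chrom[tf_idx],
           start = mid - .synth$tf_peak_width / 2,
           end = mid + .synth$tf_peak_width / 2,
           name = paste0("tf_", regions$region_id[tf_idx]),
           score = 100, strand = ".", signal = 100, pvalue = -1, qvalue = -1,
           summit = mid) %>%
      arrange(.data$chrom, .data$start)
  } else {
    peaks$A[0, ]
  }

  expr <- make_expression(cfg, genes)

  truth_regions <- select(regions, "chrom", "start", "end", "region_id",
                          "class", "role", "target_gene", "tf_bound")
  truth_genes <- select(genes, "gene_id", "class", "anchor_region",
                        "kd_dependent")

  structure(
    list(fragments = list(A = frags_a, B = frags_b),
         peaks = peaks, k27ac = k27ac,
         genes = select(genes, "chrom", "tss", "strand", "gene_id",
                        "body_start", "body_end"),
         expression = expr$tpm, sample_sheet = expr$sample_sheet,
         chip = chip,
         truth = list(regions = truth_regions, genes = truth_genes),
         config = cfg),
    class = "sim_dataset"
  )
}

#' @noRd
make_genes <- function(cfg, regions, anchor_idx) {
  n_bg <- cfg$n_genes - length(anchor_idx)
  genome <- cfg$genome

  gene_row <- function(chrom, tss, anchor_region) {
    strand <- sample(c("+", "-"), 1)
    len <- floor(runif(1, .synth$body_len_range[1], .synth$body_len_range[2]))
    chrom_len <- genome$length[match(chrom, genome$chrom)]
    if (strand == "+") {
      body_start <- tss
      body_end <- min(chrom_len, tss + len)
    } else {
      body_start <- max(0, tss + 1 - len)
      body_end <- tss + 1
    }
    tibble(chrom = chrom, tss = tss, strand = strand,
           body_start = body_start, body_end = body_end,
           anchor_region = anchor_region)
  }

  anchored <- purrr::map_dfr(anchor_idx, function(i) {
    gene_row(regions$chrom[i], floor((regions$start[i] + regions$end[i]) / 2),
             regions$region_id[i])
  })

  background <- purrr::map_dfr(seq_len(max(n_bg, 0)), function(i) {
    for (attempt in 1:1000) {
      ci <- sample.int(nrow(genome), 1, prob = genome$length)
      tss <- floor(runif(1, .synth$min_gap, genome$length[ci] - .synth$min_gap))
      near <- regions$chrom == genome$chrom[ci] &
        regions$start - .synth$min_gap < tss &
        tss < regions$end + .synth$min_gap
      if (!any(near)) return(gene_row(genome$chrom[ci], tss, NA_character_))
    }
    abort("placement failure: could not place background gene away from regions")
  })

  genes <- bind_rows(anchored, background)
  if (nrow(genes) == 0) {
    return(tibble(chrom = character(), tss = double(), strand = character(),
                  body_start = double(), body_end = double(),
                  anchor_region = character(), gene_id = character(),
                  class = character(), kd_dependent = logical()))
  }
  genes <- arrange(genes, .data$chrom, .data$tss)
  genes$gene_id <- sprintf("gene_%03d", seq_len(nrow(genes)))

  anchor_class <- regions$class[match(genes$anchor_region, regions$region_id)]
  primed <- runif(nrow(genes)) < .synth$frac_c_primed
  genes$class <- dplyr::case_when(
    is.na(anchor_class) ~ "flat",
    anchor_class == "N" ~ "induced",
    anchor_class == "I" ~ "repressed",
    anchor_class == "C" & primed ~ "induced",
    TRUE ~ "flat"
  )
  genes$kd_dependent <- genes$class != "flat" &
    runif(nrow(genes)) < cfg$frac_kd_dependent
  genes
}

#' @noRd
make_expression <- function(cfg, genes) {
  reps <- .synth$n_reps
  sample_sheet <- tibble(
    sample = c(paste0("WT_ESC_", 1:reps), paste0("WT_NPC_", 1:reps),
               paste0("KD_ESC_", 1:reps), paste0("KD_NPC_", 1:reps)),
    genotype = rep(c("WT", "KD"), each = 2 * reps),
    stage = rep(rep(c("ESC", "NPC"), each = reps), 2)
  )
  n <- nrow(genes)
  if (n == 0) {
    tpm <- tibble(gene_id = character())
    for (s in sample_sheet$sample) tpm[[s]] <- double()
    return(list(tpm = tpm, sample_sheet = sample_sheet))
  }
  base <- runif(n, .synth$tpm_base_range[1], .synth$tpm_base_range[2])
  lfc <- runif(n, .synth$lfc_range[1], .synth$lfc_range[2]) *
    dplyr::case_when(genes$class == "induced" ~ 1,
                     genes$class == "repressed" ~ -1,
                     TRUE ~ 0)
  kd_ratio <- ifelse(
    genes$kd_dependent,
    runif(n, .synth$kd_affected_range[1], .synth$kd_affected_range[2]),
    runif(n, .synth$kd_unaffected_range[1], .synth$kd_unaffected_range[2])
  )
  means <- list(
    WT_ESC = base,
    WT_NPC = base * 2^lfc,
    KD_ESC = base,
    KD_NPC = base * 2^(kd_ratio * lfc)
  )
  tpm <- tibble(gene_id = genes$gene_id)
  for (i in seq_len(nrow(sample_sheet))) {
    key <- paste(sample_sheet$genotype[i], sample_sheet$stage[i], sep = "_")
    tpm[[sample_sheet$sample[i]]] <-
      round(means[[key]] * 2^rnorm(n, 0, .synth$tpm_noise_sd), 3)
  }
  list(tpm = tpm, sample_sheet = sample_sheet)
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Fragments as BED3, peaks and TF ChIP as narrowPeak, genes/expression/
#' sample sheet/truth as TSV. Files round-trip losslessly through
#' [read_dataset()].
#'
#' @param dataset a `sim_dataset` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a manifest tibble (`file`, `n_rows`, `md5`).
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    fragments_A.bed = function(p) write_bed3(dataset$fragments$A, p),
    fragments_B.bed = function(p) write_bed3(dataset$fragments$B, p),
    k27ac.bed = function(p) write_bed3(dataset$k27ac, p),
    peaks_A.narrowPeak = function(p) write_narrowpeak(dataset$peaks$A, p),
    peaks_B.narrowPeak = function(p) write_narrowpeak(dataset$peaks$B, p),
    chip.narrowPeak = function(p) write_narrowpeak(dataset$chip, p),
    genes.tsv = function(p) write_genes(dataset$genes, p),
    expression.tsv = function(p) write_expression(dataset$expression, p),
    samples.tsv = function(p) write_sample_sheet(dataset$sample_sheet, p),
    truth_regions.tsv = function(p) readr::write_tsv(dataset$truth$regions, p,
                                                     progress = FALSE),
    truth_genes.tsv = function(p) readr::write_tsv(dataset$truth$genes, p,
                                                   progress = FALSE),
    genome.tsv = function(p) readr::write_tsv(dataset$config$genome, p,
                                              progress = FALSE)
  )
  rows <- c(nrow(dataset$fragments$A), nrow(dataset$fragments$B),
            nrow(dataset$k27ac), nrow(dataset$peaks$A), nrow(dataset$peaks$B),
            nrow(dataset$chip), nrow(dataset$genes), nrow(dataset$expression),
            nrow(dataset$sample_sheet), nrow(dataset$truth$regions),
            nrow(dataset$truth$genes), nrow(dataset$config$genome))
  for (f in names(paths)) paths[[f]](file.path(dir, f))
  manifest <- tibble(
    file = names(paths), n_rows = rows,
    md5 = unname(tools::md5sum(file.path(dir, names(paths))))
  )
  invisible(manifest)
}

#' Read back a dataset written by [write_dataset()]
#'
#' @param dir directory written by [write_dataset()].
#' @return A list with the same tabular components as a `sim_dataset`
#'   (without the `config`, except the genome table).
#' @export
read_dataset <- function(dir) {
  truth_regions <- readr::read_tsv(
    file.path(dir, "truth_regions.tsv"),
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_double(),
      end = readr::col_double(), region_id = readr::col_character(),
      class = readr::col_character(), role = readr::col_character(),
      target_gene = readr::col_character(), tf_bound = readr::col_logical()
    ), progress = FALSE)
  truth_genes <- readr::read_tsv(
    file.path(dir, "truth_genes.tsv"),
    col_types = readr::cols(
      gene_id = readr::col_character(), class = readr::col_character(),
      anchor_region = readr::col_character(),
      kd_dependent = readr::col_logical()
    ), progress = FALSE)
  list(
    fragments = list(A = read_bed3(file.path(dir, "fragments_A.bed")),
                     B = read_bed3(file.path(dir, "fragments_B.bed"))),
    k27ac = read_bed3(file.path(dir, "k27ac.bed")),
    peaks = list(A = read_narrowpeak(file.path(dir, "peaks_A.narrowPeak")),
                 B = read_narrowpeak(file.path(dir, "peaks_B.narrowPeak"))),
    chip = read_narrowpeak(file.path(dir, "chip.narrowPeak")),
    genes = read_genes(file.path(dir, "genes.tsv")),
    expression = read_expression(file.path(dir, "expression.tsv")),
    sample_sheet = read_sample_sheet(file.path(dir, "samples.tsv")),
    truth = list(regions = truth_regions, genes = truth_genes),
    genome = readr::read_tsv(file.path(dir, "genome.tsv"),
                             col_types = readr::cols(
                               chrom = readr::col_character(),
                               length = readr::col_double()
                             ), progress = FALSE)
  )
}
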