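# End-to-end orchestration: one config object with every stage parameter,
# one function that runs the stages in dependency order, writes plain-text
# outputs and a manifest of parameters and checksums.

#' Pipeline configuration
#'
#' All stage parameters with their defaults; unknown names are rejected.
#' When `input_dir` is `NULL` the synthetic generator supplies the inputs
#' (using `sim` or its default configuration with `seed`).
#'
#' @param input_dir optional directory of input files laid out as written
#'   by [write_dataset()]; `NULL` to simulate.
#' @param sim optional [sim_config()] used when simulating; built from
#'   `seed` if omitted.
#' @param width consensus peak width (bp).
#' @param spm_cutoff consensus spm cutoff.
#' @param fdr background FDR for openness thresholding.
#' @param link_window peak-gene link window (bp).
#' @param min_fc signal fold-change filter for specific clusters.
#' @param abc_width candidate element width (bp).
#' @param abc_top_n candidate elements retained.
#' @param abc_threshold minimum reported ABC score.
#' @param gamma contact power-law exponent.
#' @param contact_d0 contact distance floor (bp).
#' @param abc_window ABC scoring window around the TSS (bp).
#' @param promoter_window promoter half-width for TF binding calls (bp).
#' @param lfc expression log2 fold-change threshold (induction and WT
#'   response).
#' @param attenuation KD attenuation cutoff.
#' @param pseudocount pseudocount for all signal and TPM ratios.
#' @param seed integer seed for simulation.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL, sim = NULL,
                            width = 500, spm_cutoff = 2, fdr = 0.005,
                            link_window = 5000, min_fc = 2,
                            abc_width = 250, abc_top_n = 150000,
                            abc_threshold = 0.02, gamma = 1.0,
                            contact_d0 = 5000, abc_window = 5e6,
                            promoter_window = 2000, lfc = 1,
                            attenuation = 0.5, pseudocount = 1,
                            seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(cfg$sim)) cfg$sim <- sim_config(seed = seed, gamma = gamma)
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Stages in dependency order: `simulate` (or load inputs), `merge_peaks`
#' (per-condition calling + consensus), `call_open`, `link_genes`, `abc`,
#' `intersect_tf`, `kd_classify`. Later stages are skipped automatically
#' when a requested set excludes their prerequisites' consumers. Outputs
#' are written under `out_dir` together with `manifest.json` recording
#' every parameter and output checksums; a rerun with the same config and
#' seed reproduces identical files.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param stages character vector of stages to run (default all).
#' @return Invisibly, a list of in-memory stage results plus the manifest.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "merge_peaks", "call_open",
                                    "link_genes", "abc", "intersect_tf",
                                    "kd_classify")) {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate", "merge_peaks", "call_open", "link_genes",
                  "abc", "intersect_tf", "kd_classify")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_stage <- function(name) {
    message(sprintf("[%s] %+6.1fs %s", "chromlink",
                    as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    name))
  }
  res <- list()
  outputs <- character(0)
  save_tsv <- function(x, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(x, p, progress = FALSE)
    outputs <<- c(outputs, p)
    p
  }

  # --- inputs -----------------------------------------------------------
  log_stage("load inputs")
  if (!is.null(config$input_dir)) {
    ds <- read_dataset(config$input_dir)
    genome <- ds$genome
  } else {
    ds <- simulate_dataset(config$sim)
    genome <- config$sim$genome
    if ("simulate" %in% stages) {
      log_stage("simulate: writing synthetic dataset")
      ds_dir <- file.path(out_dir, "dataset")
      write_dataset(ds, ds_dir)
      outputs <- c(outputs, list.files(ds_dir, full.names = TRUE))
    }
  }
  res$dataset <- ds

  # --- consensus + openness --------------------------------------------
  if ("merge_peaks" %in% stages || "call_open" %in% stages) {
    log_stage("merge_peaks/call_open: peak calling and dichotomization")
    open <- call_openness(ds$fragments$A, ds$fragments$B, genome,
                          width = config$width,
                          spm_cutoff = config$spm_cutoff, fdr = config$fdr)
    res$openness <- open
    save_tsv(select(open$consensus, -dplyr::any_of(c("clipped"))),
             "consensus_peaks.tsv")
    save_tsv(tidy(open$calls), "openness_calls.tsv")
    save_tsv(open$summary, "openness_summary.tsv")
  }

  # --- linkage ----------------------------------------------------------
  if ("link_genes" %in% stages && !is.null(res$openness)) {
    log_stage("link_genes: peak-gene linkage and induction genes")
    calls <- res$openness$calls
    links <- link_peaks_to_genes(calls, ds$genes, window = config$link_window)
    links <- fold_change_filter(links, min_fc = config$min_fc,
                                pseudocount = config$pseudocount)
    wt <- ds$sample_sheet[ds$sample_sheet$genotype == "WT", ]
    induced <- induction_genes(
      links, ds$expression,
      samples_a = wt$sample[wt$stage == "ESC"],
      samples_b = wt$sample[wt$stage == "NPC"],
      min_lfc = config$lfc, pseudocount = config$pseudocount)
    primed <- primed_promoter_peaks(calls, links, induced)
    res$links <- links
    res$induced <- induced
    res$primed <- primed
    save_tsv(links, "peak_gene_links.tsv")
    save_tsv(induced, "induction_genes.tsv")
    save_tsv(tidy(primed), "primed_peaks.tsv")
  }

  # --- ABC --------------------------------------------------------------
  if ("abc" %in% stages) {
    log_stage("abc: candidate elements and enhancer-gene scores")
    model <- contact_model("powerlaw", gamma = config$gamma,
                           d0 = config$contact_d0)
    abc <- run_abc(ds$peaks$B, ds$fragments$B, ds$k27ac, ds$genes, genome,
                   model = model, top_n = config$abc_top_n,
                   width = config$abc_width, window = config$abc_window,
                   threshold = config$abc_threshold)
    res$abc <- abc
    bedpe <- pairs_to_bedpe(abc$pairs[!abc$pairs$is_promoter, ])
    res$bedpe <- bedpe
    save_tsv(abc$elements, "abc_elements.tsv")
    p <- file.path(out_dir, "enhancer_gene_pairs.bedpe")
    write_bedpe(bedpe, p)
    outputs <- c(outputs, p)
  }

  # --- TF binding -------------------------------------------------------
  if ("intersect_tf" %in% stages && !is.null(res$bedpe)) {
    log_stage("intersect_tf: TF-bound pairs and promoter binding")
    bound <- intersect_pairs(res$bedpe, ds$chip, anchor = "enhancer")
    prom <- promoter_binding(ds$chip, ds$genes,
                             promoter_window = config$promoter_window)
    targets <- export_target_genes(bound, prom)
    res$bound_pairs <- bound
    res$promoter_bound <- prom
    res$targets <- targets
    save_tsv(bound, "tf_bound_pairs.tsv")
    save_tsv(prom, "tf_promoter_bound.tsv")
    save_tsv(targets, "tf_target_genes.tsv")
  }

  # --- KD response ------------------------------------------------------
  if ("kd_classify" %in% stages) {
    log_stage("kd_classify: knockdown-response clusters")
    wt_resp <- define_wt_response(ds$expression, ds$sample_sheet,
                                  lfc_threshold = config$lfc,
                                  pseudocount = config$pseudocount)
    kd <- classify_kd_effect(wt_resp, ds$expression, ds$sample_sheet,
                             attenuation_cutoff = config$attenuation,
                             pseudocount = config$pseudocount)
    res$kd <- kd
    save_tsv(tidy(kd), "kd_response_calls.tsv")
  }

  # --- manifest ---------------------------------------------------------
  log_stage("manifest")
  params <- unclass(config)
  params$sim <- unclass(params$sim)
  params$sim$genome <- NULL
  params$input_dir <- if (is.null(params$input_dir)) NA else params$input_dir
  manifest <- list(
    package = "chromlink",
    version = as.character(utils::packageVersion("chromlink")),
    stages = stages,
    parameters = params,
    outputs = lapply(
      setNames(sort(unique(outputs)),
               sub("^/?", "", sub(normalizePath(out_dir), "",
                                  normalizePath(sort(unique(outputs))),
                                  fixed = TRUE))),
      function(p) list(md5 = unname(tools::md5sum(p)), bytes = file.size(p))
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  res$manifest <- manifest
  invisible(res)
}
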