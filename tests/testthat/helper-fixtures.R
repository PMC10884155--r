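# Shared fixtures and independent oracles. The default-condition synthetic
# dataset and its derived stages are expensive, so they are computed once
# per test run and memoised in this environment.

fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, force(expr), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

default_sim <- function() {
  memo("sim", simulate_dataset(sim_config(seed = 1)))
}

default_openness <- function() {
  memo("openness", {
    ds <- default_sim()
    call_openness(ds$fragments$A, ds$fragments$B, ds$config$genome)
  })
}

default_abc <- function() {
  memo("abc", {
    ds <- default_sim()
    run_abc(ds$peaks$B, ds$fragments$B, ds$k27ac, ds$genes, ds$config$genome)
  })
}

tiny_genome <- tibble::tibble(chrom = c("chr1", "chr2"),
                              length = c(1e5, 5e4))

# small, fast simulation for structural tests
small_config <- function(seed = 7, ...) {
  args <- list(genome = tibble::tibble(chrom = c("chr1", "chr2"),
                                       length = c(4e5, 2e5)),
               n_common = 6, n_a_specific = 4, n_b_specific = 4,
               n_closed_decoy = 5, n_background_reads = 2e4, n_genes = 20,
               open_rate = 25000, closed_rate = 250, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

random_peakset <- function(n, genome = tiny_genome, width = 500, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ci <- sample.int(nrow(genome), n, replace = TRUE)
  start <- floor(runif(n, 0, genome$length[ci] - width))
  tibble::tibble(chrom = genome$chrom[ci], start = start, end = start + width,
                 spm = round(runif(n, 0, 10), 3))
}

# O(n^2) greedy reference for the iterative overlap-removal merge
greedy_merge_oracle <- function(peaks, spm_cutoff = 2) {
  peaks <- peaks[order(-peaks$spm, peaks$chrom, peaks$start), ]
  kept <- integer(0)
  alive <- rep(TRUE, nrow(peaks))
  overlaps <- function(i, j) {
    peaks$chrom[i] == peaks$chrom[j] &
      peaks$start[i] < peaks$end[j] & peaks$start[j] < peaks$end[i]
  }
  for (i in seq_len(nrow(peaks))) {
    if (!alive[i]) next
    kept <- c(kept, i)
    for (j in seq_len(nrow(peaks))) {
      if (alive[j] && j != i && overlaps(i, j)) alive[j] <- FALSE
    }
    alive[i] <- FALSE
  }
  out <- peaks[kept, ]
  out <- out[out$spm >= spm_cutoff, ]
  out[order(out$chrom, out$start), ]
}

# per-bp bitmap reference for interval union
bitmap_union_oracle <- function(intervals, genome) {
  out <- list()
  for (ci in seq_len(nrow(genome))) {
    len <- genome$length[ci]
    covered <- logical(len)
    x <- intervals[intervals$chrom == genome$chrom[ci], ]
    for (i in seq_len(nrow(x))) {
      covered[seq(x$start[i] + 1, x$end[i])] <- TRUE
    }
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep)) {
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = genome$chrom[ci], start = starts[keep], end = ends[keep])
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(chrom = character(), start = double(),
                          end = double()))
  }
  dplyr::arrange(dplyr::bind_rows(out), chrom, start)
}

# brute-force all-pairs peak-gene linkage
link_oracle <- function(peaks, genes, window = 5000) {
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(genes))) {
      if (peaks$chrom[i] != genes$chrom[j]) next
      d <- max(0, peaks$start[i] - genes$tss[j],
               genes$tss[j] - (peaks$end[i] - 1))
      if (d <= window) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          peak_id = peaks$peak_id[i], gene_id = genes$gene_id[j], distance = d)
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(peak_id = character(), gene_id = character(),
                          distance = double()))
  }
  dplyr::arrange(dplyr::bind_rows(rows), peak_id, gene_id)
}

uniform_frags <- function(n, genome, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ci <- sample.int(nrow(genome), n, replace = TRUE, prob = genome$length)
  mid <- floor(runif(n, 0, genome$length[ci]))
  tibble::tibble(chrom = genome$chrom[ci],
                 start = pmax(0, mid - 50),
                 end = pmin(genome$length[ci], mid + 50))
}

# truth genes that induction_genes() can see: induced genes whose promoter
# is a class-C (primed) region
truth_primed_genes <- function(ds) {
  tg <- ds$truth$genes
  tr <- ds$truth$regions
  cls <- tr$class[match(tg$anchor_region, tr$region_id)]
  tg$gene_id[tg$class == "induced" & !is.na(cls) & cls == "C"]
}
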