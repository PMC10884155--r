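# Peak-recall stage: interval union, pseudo-input, the simplified caller,
# RP10M normalization, the FDR-quantile threshold and dichotomization.

test_that("merging coalesces overlapping and book-ended intervals", {
  x <- tibble::tibble(chrom = "chr1", start = c(100, 150), end = c(200, 250))
  out <- merge_all_peaks(x)
  expect_equal(c(out$start, out$end), c(100, 250))

  disjoint <- tibble::tibble(chrom = c("chr1", "chr1", "chr2"),
                             start = c(0, 1000, 50), end = c(500, 1500, 80))
  expect_equal(merge_all_peaks(disjoint), disjoint)

  booked <- tibble::tibble(chrom = "chr1", start = c(100, 200), end = c(200, 300))
  expect_equal(nrow(merge_all_peaks(booked)), 1)

  expect_equal(nrow(merge_all_peaks(x[0, ])), 0)
})

test_that("interval union equals the per-bp bitmap reference", {
  genome <- tibble::tibble(chrom = c("chr1", "chr2"), length = c(10000, 5000))
  set.seed(4)
  n <- 1000
  ci <- sample.int(2, n, replace = TRUE)
  start <- floor(runif(n, 0, genome$length[ci] - 50))
  x <- tibble::tibble(chrom = genome$chrom[ci], start = start,
                      end = start + sample(1:50, n, replace = TRUE))
  expect_equal(merge_all_peaks(x), bitmap_union_oracle(x, genome))
})

test_that("pseudo-input removes exactly the peak-overlapping fragments", {
  genome <- tiny_genome
  fr <- uniform_frags(5000, genome, seed = 9)
  expect_equal(make_pseudo_input(fr, fr[0, ]), fr)

  whole <- tibble::tibble(chrom = genome$chrom, start = 0, end = genome$length)
  expect_equal(nrow(make_pseudo_input(fr, whole)), 0)

  merged <- merge_all_peaks(random_peakset(20, genome, seed = 10))
  kept <- make_pseudo_input(fr, merged)
  # disjointness and count conservation against a direct overlap check
  overlaps <- rep(FALSE, nrow(fr))
  for (i in seq_len(nrow(merged))) {
    overlaps <- overlaps | (fr$chrom == merged$chrom[i] &
                              fr$start < merged$end[i] &
                              merged$start[i] < fr$end)
  }
  expect_equal(nrow(kept), sum(!overlaps))
  expect_equal(kept, fr[!overlaps, ])
})

test_that("the caller is quiet on uniform background and finds hot windows", {
  genome <- tibble::tibble(chrom = "chr1", length = 1e6)
  total_false <- 0
  for (s in 1:20) {
    fr <- uniform_frags(20000, genome, seed = s)
    total_false <- total_false + nrow(call_peaks_simple(fr, genome))
  }
  expect_lte(total_false, 1)

  # one loaded window over a sparse background: lambda ~ 2, count 60
  set.seed(1)
  mid <- c(floor(runif(2000, 0, 1e6)), floor(runif(60, 5000, 5300)))
  fr <- tibble::tibble(chrom = "chr1", start = pmax(0, mid - 50), end = mid + 50)
  pk <- call_peaks_simple(fr, genome)
  expect_equal(nrow(pk), 1)
  expect_true(pk$start <= 5000 && pk$end >= 5300)
  expect_true(pk$summit >= 5000 && pk$summit < 5300)

  expect_equal(nrow(call_peaks_simple(fr[0, ], genome)), 0)
})

test_that("RP10M normalization matches the scale formula and a recount", {
  regions <- tibble::tibble(chrom = "chr1", start = 1000, end = 2000)
  fr <- tibble::tibble(chrom = "chr1", start = seq(1100, 1900, length.out = 10),
                       end = seq(1100, 1900, length.out = 10) + 10)
  out <- normalize_rp10m(regions, fr, total_unique = 1e7)
  expect_equal(out$rp10m, 10)
  out <- normalize_rp10m(regions, fr, total_unique = 5e6)
  expect_equal(out$rp10m, 20)

  genome <- tiny_genome
  rg <- random_peakset(30, genome, seed = 21)[, c("chrom", "start", "end")]
  fr <- uniform_frags(20000, genome, seed = 22)
  got <- normalize_rp10m(rg, fr)$rp10m
  mids <- floor((fr$start + fr$end) / 2)
  manual <- vapply(seq_len(nrow(rg)), function(i) {
    sum(fr$chrom == rg$chrom[i] & mids >= rg$start[i] & mids < rg$end[i])
  }, numeric(1)) * 1e7 / nrow(fr)
  expect_equal(got, manual)

  expect_error(normalize_rp10m(regions, fr[0, ]), "positive")
})

test_that("the background threshold is the inverse-ECDF quantile", {
  expect_equal(estimate_background_threshold(1:1000, fdr = 0.005), 995)
  expect_equal(sum((1:1000) > 995) / 1000, 0.005)
  expect_equal(estimate_background_threshold(rep(0, 300)), 0)
  expect_equal(estimate_background_threshold(c(5, 1, 9, 300:1), fdr = 0),
               300)
  expect_error(estimate_background_threshold(numeric(0)), "empty")
  expect_warning(estimate_background_threshold(1:50), "200")
})

test_that("lowering the FDR never lowers the threshold", {
  set.seed(8)
  x <- rexp(5000, 1 / 50)
  fdrs <- c(0.1, 0.05, 0.01, 0.005, 0.001, 0)
  th <- vapply(fdrs, function(f) estimate_background_threshold(x, f),
               numeric(1))
  expect_true(all(diff(th) >= 0))
})

test_that("achieved FDR on uniform background stays at or below nominal", {
  genome <- tibble::tibble(chrom = "chr1", length = 2e6)
  for (s in 1:10) {
    fr <- uniform_frags(4e5, genome, seed = 100 + s)
    bg <- call_peaks_simple(fr, genome, window = 500, step = 250,
                            q = 0.05, correct = "none")
    bg <- normalize_rp10m(bg, fr, col = "signal")
    thr <- estimate_background_threshold(bg$signal, fdr = 0.005)
    frac <- mean(bg$signal > thr)
    expect_gte(frac, 0)
    expect_lte(frac, 0.007)
  }
})

test_that("openness labels follow the strict threshold definition", {
  peaks <- tibble::tibble(chrom = "chr1", start = c(0, 1000, 2000, 3000),
                          end = c(500, 1500, 2500, 3500),
                          signal_a = c(10, 10, 1, 1),
                          signal_b = c(10, 1, 10, 1))
  calls <- classify_openness(peaks, threshold = 4)
  expect_equal(calls$label, c("C", "I", "N", "unassigned"))
  s <- openness_summary(calls)
  expect_equal(sum(s$n), nrow(peaks))
  expect_error(classify_openness(peaks[, 1:3], 4), "signal_a")
})

test_that("swapping conditions swaps I and N and fixes C/unassigned", {
  set.seed(13)
  peaks <- tibble::tibble(chrom = "chr1", start = seq(0, 99000, 1000),
                          end = seq(500, 99500, 1000),
                          signal_a = rexp(100, 1 / 8),
                          signal_b = rexp(100, 1 / 8))
  fwd <- classify_openness(peaks, 6)
  swapped <- dplyr::rename(peaks, signal_a = signal_b, signal_b = signal_a)
  rev <- classify_openness(swapped, 6)
  map <- c(C = "C", I = "N", N = "I", unassigned = "unassigned")
  expect_equal(unname(map[fwd$label]), rev$label)
})
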