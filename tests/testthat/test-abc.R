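# Activity-by-Contact scoring: candidate elements, activity, contact decay
# and the normalized per-gene scores.

test_that("candidate elements are ranked, truncated, filtered and merged", {
  genome <- tibble::tibble(chrom = "chr1", length = 1e5)
  set.seed(71)
  peaks <- tibble::tibble(chrom = "chr1",
                          summit = seq(5000, 95000, length.out = 10))
  # plant distinct read loads so the ranking is unambiguous
  fr <- dplyr::bind_rows(lapply(seq_len(10), function(i) {
    m <- rep(peaks$summit[i], i * 5)
    tibble::tibble(chrom = "chr1", start = m - 50, end = m + 50)
  }))
  top3 <- make_candidate_elements(peaks, fr, genome, top_n = 3, width = 250)
  expect_equal(nrow(top3), 3)
  expect_setequal(top3$atac_count, c(40, 45, 50))

  bl <- tibble::tibble(chrom = "chr1", start = 94000, end = 96000)
  no_top <- make_candidate_elements(peaks, fr, genome, top_n = 3, width = 250,
                                    blacklist = bl)
  expect_false(any(no_top$start < bl$end & bl$start < no_top$end))

  near <- tibble::tibble(chrom = "chr1", summit = c(1000, 1150))
  merged <- make_candidate_elements(near, fr, genome, width = 250)
  expect_equal(nrow(merged), 1)
  expect_equal(c(merged$start, merged$end), c(875, 1275))
})

test_that("activity is the geometric mean of ATAC and H3K27ac counts", {
  el <- tibble::tibble(chrom = "chr1", start = 1000, end = 1250)
  atac <- tibble::tibble(chrom = "chr1", start = rep(1100, 4), end = rep(1120, 4))
  k27 <- tibble::tibble(chrom = "chr1", start = rep(1050, 9), end = rep(1070, 9))
  out <- element_activity(el, atac, k27)
  expect_equal(out$activity, 6)
  out <- element_activity(el, atac[0, ], k27)
  expect_equal(out$activity, 0)

  set.seed(72)
  genome <- tiny_genome
  els <- random_peakset(25, genome)[, c("chrom", "start", "end")]
  fa <- uniform_frags(5000, genome)
  fk <- uniform_frags(5000, genome)
  out <- element_activity(els, fa, fk)
  expect_equal(out$activity, sqrt(out$atac_count * out$k27ac_count))
})

test_that("contact decay follows the power law and the binned table", {
  m <- contact_model("powerlaw", gamma = 1, d0 = 5000)
  expect_equal(contact(m, 0) / contact(m, 5000), 2)
  expect_equal(contact(m, c(100, 100)), rep(contact(m, 100), 2))

  m2 <- contact_model("powerlaw", gamma = 1.5, d0 = 2000)
  d <- seq(0, 1e6, length.out = 50)
  expect_true(all(diff(contact(m2, d)) < 0))

  tb <- contact_model("table",
                      table = tibble::tibble(bin_start = c(0, 1e4, 2e4),
                                             contact = c(5, 5, 5)))
  expect_equal(contact(tb, c(0, 9999, 15000, 25000)), rep(5, 4))
  expect_error(contact(tb, 4e4), "beyond")
  expect_error(contact(m, -1), "non-negative")
})

test_that("ABC scores are normalized shares of activity times contact", {
  model <- contact_model("powerlaw")
  gene <- tibble::tibble(chrom = "chr1", tss = 100000, gene_id = "g")

  single <- tibble::tibble(chrom = "chr1", start = 50000, end = 50250,
                           activity = 7)
  pairs <- abc_scores(single, gene, model, threshold = 0.02)
  expect_equal(pairs$abc_score[!pairs$is_promoter], 1.0)

  equal_pair <- tibble::tibble(chrom = "chr1",
                               start = c(50000, 149750), end = c(50250, 150000),
                               activity = c(3, 3))
  pairs <- abc_scores(equal_pair, gene, model, threshold = 0)
  expect_equal(pairs$abc_score[!pairs$is_promoter], c(0.5, 0.5))

  # three elements all 50 kb from the TSS: A = {10, 5, 5} -> {0.5, 0.25, 0.25}
  trio <- tibble::tibble(chrom = "chr1",
                         start = c(49875, 149875, 149875),
                         end = c(50125, 150125, 150125),
                         activity = c(10, 5, 5))
  pairs <- abc_scores(trio, gene, model, threshold = 0.02)
  got <- pairs[!pairs$is_promoter, ]
  expect_equal(sort(got$abc_score, decreasing = TRUE), c(0.5, 0.25, 0.25))
  expect_equal(nrow(got), 3)
})

test_that("per-gene scores sum to one and are scale invariant", {
  genome <- tiny_genome
  set.seed(73)
  els <- random_peakset(40, genome)[, c("chrom", "start", "end")]
  els$activity <- rexp(40, 1 / 5)
  genes <- tibble::tibble(chrom = c("chr1", "chr2"), tss = c(50000, 25000),
                          gene_id = c("g1", "g2"),
                          promoter_activity = c(4, 9))
  model <- contact_model("powerlaw")
  all_pairs <- abc_scores(els, genes, model, threshold = 0)
  sums <- tapply(all_pairs$abc_score, all_pairs$gene_id, sum)
  expect_equal(as.numeric(sums), c(1, 1), tolerance = 1e-9)
  expect_true(all(all_pairs$abc_score >= 0 & all_pairs$abc_score <= 1))

  scaled <- els
  scaled$activity <- scaled$activity * 37
  genes_scaled <- genes
  genes_scaled$promoter_activity <- genes$promoter_activity * 37
  pairs2 <- abc_scores(scaled, genes_scaled, model, threshold = 0)
  expect_equal(pairs2$abc_score, all_pairs$abc_score)
})

test_that("raising one element's activity raises its score, lowers others", {
  model <- contact_model("powerlaw")
  gene <- tibble::tibble(chrom = "chr1", tss = 100000, gene_id = "g")
  els <- tibble::tibble(chrom = "chr1",
                        start = c(49875, 149875, 79875),
                        end = c(50125, 150125, 80125),
                        activity = c(10, 5, 8))
  base <- abc_scores(els, gene, model, threshold = 0)
  base <- base[!base$is_promoter, ]
  els2 <- els
  els2$activity[2] <- 12
  bumped <- abc_scores(els2, gene, model, threshold = 0)
  bumped <- bumped[!bumped$is_promoter, ]
  expect_gt(bumped$abc_score[bumped$start == 149875],
            base$abc_score[base$start == 149875])
  expect_true(all(bumped$abc_score[bumped$start != 149875] <
                    base$abc_score[base$start != 149875]))
})

test_that("all-zero activity windows are flagged and yield no pairs", {
  model <- contact_model("powerlaw")
  gene <- tibble::tibble(chrom = "chr1", tss = 100000, gene_id = "g")
  els <- tibble::tibble(chrom = "chr1", start = 50000, end = 50250,
                        activity = 0)
  expect_warning(pairs <- abc_scores(els, gene, model), "all-zero")
  expect_equal(nrow(pairs), 0)
  expect_equal(attr(pairs, "flagged_genes"), "g")
})

test_that("BEDPE export is well-formed and round-trips", {
  p <- tibble::tibble(chrom = "chr1", start = 50000, end = 50250,
                      element_id = "e1", activity = 5, is_promoter = FALSE,
                      distance = 49875, abc_score = 0.4, gene_id = "g",
                      tss = 100000)
  bedpe <- pairs_to_bedpe(p)
  expect_equal(names(bedpe),
               c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                 "name", "score", "strand1", "strand2"))
  expect_equal(c(bedpe$start2, bedpe$end2), c(99750, 100250))
  expect_false(bedpe$start1 == bedpe$start2 && bedpe$end1 == bedpe$end2)

  path <- withr::local_tempfile(fileext = ".bedpe")
  write_bedpe(bedpe, path)
  expect_equal(read_bedpe(path), bedpe, ignore_attr = TRUE)
  # empty export still yields a valid, readable file with a header comment
  write_bedpe(bedpe[0, ], path)
  expect_equal(substr(readLines(path)[1], 1, 1), "#")
  expect_equal(nrow(read_bedpe(path)), 0)
})

test_that("true enhancer-gene links are recovered on synthetic data", {
  ds <- default_sim()
  abc <- default_abc()
  rec <- abc_link_recall(abc$pairs, ds$truth$regions)
  expect_gte(rec$recall, 0.8)
})
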