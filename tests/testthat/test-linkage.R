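# Peak-gene linkage, fold-change filtering, induction genes, primed peaks
# and the TSS-proximity fraction.

test_that("the 5 kb link boundary is exact", {
  peaks <- tibble::tibble(chrom = "chr1", start = 10000, end = 10500,
                          peak_id = "p1")
  near <- tibble::tibble(chrom = "chr1", tss = 10000 - 4999, gene_id = "near")
  far <- tibble::tibble(chrom = "chr1", tss = 10000 - 5001, gene_id = "far")
  at <- tibble::tibble(chrom = "chr1", tss = 10000 - 5000, gene_id = "at")
  inside <- tibble::tibble(chrom = "chr1", tss = 10250, gene_id = "inside")
  genes <- dplyr::bind_rows(near, far, at, inside)
  links <- link_peaks_to_genes(peaks, genes, window = 5000)
  expect_setequal(links$gene_id, c("near", "at", "inside"))
  expect_equal(links$distance[links$gene_id == "inside"], 0)
  expect_equal(links$distance[links$gene_id == "at"], 5000)
})

test_that("linkage equals the all-pairs distance oracle", {
  genome <- tiny_genome
  set.seed(31)
  for (i in 1:20) {
    peaks <- random_peakset(50, genome)[, c("chrom", "start", "end")]
    peaks$peak_id <- sprintf("p%02d", seq_len(nrow(peaks)))
    ci <- sample.int(2, 30, replace = TRUE)
    genes <- tibble::tibble(chrom = genome$chrom[ci],
                            tss = floor(runif(30, 0, genome$length[ci])),
                            gene_id = sprintf("g%02d", 1:30))
    got <- link_peaks_to_genes(peaks, genes, window = 5000) %>%
      dplyr::select(peak_id, gene_id, distance) %>%
      dplyr::arrange(peak_id, gene_id)
    expect_equal(got, link_oracle(peaks, genes, 5000), ignore_attr = TRUE)
  }
})

test_that("widening the window never loses links", {
  genome <- tiny_genome
  peaks <- random_peakset(40, genome, seed = 41)[, c("chrom", "start", "end")]
  peaks$peak_id <- as.character(seq_len(nrow(peaks)))
  ci <- sample.int(2, 25, replace = TRUE)
  genes <- tibble::tibble(chrom = genome$chrom[ci],
                          tss = floor(runif(25, 0, genome$length[ci])),
                          gene_id = as.character(1:25))
  narrow <- link_peaks_to_genes(peaks, genes, window = 2000)
  wide <- link_peaks_to_genes(peaks, genes, window = 10000)
  key <- function(x) paste(x$peak_id, x$gene_id)
  expect_true(all(key(narrow) %in% key(wide)))
})

test_that("fold-change filter spares Cluster C and tests I/N directionally", {
  links <- tibble::tibble(
    peak_id = c("n", "c", "i"), gene_id = c("g1", "g2", "g3"),
    label = c("N", "C", "I"),
    signal_a = c(1, 5, 3), signal_b = c(10, 5, 2))
  out <- fold_change_filter(links, min_fc = 2, pseudocount = 1)
  # N link: (10+1)/(1+1) = 5.5 > 2 kept; C exempt; I: (3+1)/(2+1) < 2 dropped
  expect_setequal(out$peak_id, c("n", "c"))

  set.seed(51)
  many <- tibble::tibble(
    peak_id = as.character(1:200), gene_id = as.character(1:200),
    label = sample(c("C", "I", "N"), 200, replace = TRUE),
    signal_a = rexp(200, 1 / 10), signal_b = rexp(200, 1 / 10))
  filtered <- fold_change_filter(many)
  expect_equal(sum(filtered$label == "C"), sum(many$label == "C"))
})

test_that("induction genes require a C link and sufficient fold change", {
  links <- tibble::tibble(peak_id = c("p1", "p2", "p3"),
                          gene_id = c("up", "flat", "unmeasured"),
                          label = c("C", "C", "C"))
  expr <- tibble::tibble(gene_id = c("up", "flat"),
                         a1 = c(0, 10), a2 = c(0, 10),
                         b1 = c(10, 10), b2 = c(10, 10))
  expect_warning(
    out <- induction_genes(links, expr, samples_a = c("a1", "a2"),
                           samples_b = c("b1", "b2")),
    "absent")
  expect_equal(out$gene_id, "up")
  expect_equal(out$lfc, log2(11 / 1))
  expect_equal(attr(out, "missing_genes"), "unmeasured")
})

test_that("primed peaks are C peaks whose nearest gene is induced", {
  calls <- classify_openness(
    tibble::tibble(chrom = "chr1", start = c(0, 10000, 20000),
                   end = c(500, 10500, 20500),
                   peak_id = c("pc", "pn", "ptie"),
                   signal_a = c(10, 1, 10), signal_b = c(10, 10, 10)),
    threshold = 4)
  links <- tibble::tibble(
    peak_id = c("pc", "pn", "ptie", "ptie"),
    gene_id = c("ind", "ind", "other", "ind"),
    label = c("C", "N", "C", "C"),
    distance = c(100, 100, 300, 300))
  primed <- primed_promoter_peaks(calls, links, induced = "ind")
  # pc: nearest gene induced -> primed; pn: not C; ptie: tie includes an
  # induced gene -> primed
  expect_setequal(primed$peak_id, c("pc", "ptie"))
  expect_true(all(primed$label == "C"))
})

test_that("tss_fraction matches a brute-force computation", {
  genes <- tibble::tibble(chrom = "chr1", tss = c(1000, 50000),
                          gene_id = c("g1", "g2"))
  on_tss <- tibble::tibble(chrom = "chr1", start = c(900, 49900),
                           end = c(1100, 50100))
  expect_equal(tss_fraction(on_tss, genes), 1)
  off <- tibble::tibble(chrom = "chr1", start = 20000, end = 20500)
  expect_equal(tss_fraction(off, genes), 0)
  expect_error(tss_fraction(off[0, ], genes), "empty")

  genome <- tiny_genome
  set.seed(61)
  peaks <- random_peakset(60, genome)[, c("chrom", "start", "end")]
  ci <- sample.int(2, 15, replace = TRUE)
  rg <- tibble::tibble(chrom = genome$chrom[ci],
                       tss = floor(runif(15, 0, genome$length[ci])),
                       gene_id = as.character(1:15))
  brute <- mean(vapply(seq_len(nrow(peaks)), function(i) {
    any(rg$chrom == peaks$chrom[i] &
          pmax(0, peaks$start[i] - rg$tss, rg$tss - (peaks$end[i] - 1)) <= 5000)
  }, logical(1)))
  expect_equal(tss_fraction(peaks, rg), brute)
  expect_gte(tss_fraction(peaks, rg, window = 20000),
             tss_fraction(peaks, rg, window = 5000))
})
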