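# Readers/writers for the plain-text formats used throughout: BED3 fragments,
# narrowPeak (BED6+4), BEDPE pairs, and the TSV tables (genes, expression,
# sample sheet, truth). Everything is 0-based half-open on disk and in memory.

#' Read/write BED3 intervals
#'
#' @param path file path.
#' @return Tibble with `chrom`, `start`, `end`.
#' @export
read_bed3 <- function(path) {
  readr::read_tsv(path,
    col_names = c("chrom", "start", "end"),
    col_types = readr::cols(
      chrom = readr::col_character(),
      start = readr::col_double(),
      end = readr::col_double()
    ),
    comment = "#", progress = FALSE
  )
}

#' @param x interval tibble.
#' @rdname read_bed3
#' @export
write_bed3 <- function(x, path) {
  readr::write_tsv(x[, c("chrom", "start", "end")], path, col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

narrowpeak_cols <- c("chrom", "start", "end", "name", "score", "strand",
                     "signal", "pvalue", "qvalue", "summit_offset")

#' Read a narrowPeak (BED6+4) file
#'
#' The 10th column is the summit offset from `start`; it is converted to an
#' absolute `summit` coordinate. Files with a column count other than 10
#' raise an error naming the file.
#'
#' @param path file path.
#' @param sample_id optional sample label attached as a column.
#' @return Tibble with `chrom`, `start`, `end`, `name`, `score`, `strand`,
#'   `signal`, `pvalue`, `qvalue`, `summit`.
#' @export
read_narrowpeak <- function(path, sample_id = NULL) {
  first <- readr::read_lines(path, n_max = 1, progress = FALSE)
  if (length(first) > 0) {
    nfield <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
    if (nfield != 10) {
      abort(sprintf("'%s' line 1: expected 10 narrowPeak columns, found %d",
                    path, nfield))
    }
  }
  x <- readr::read_tsv(path,
    col_names = narrowpeak_cols,
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_double(),
      end = readr::col_double(), name = readr::col_character(),
      score = readr::col_double(), strand = readr::col_character(),
      signal = readr::col_double(), pvalue = readr::col_double(),
      qvalue = readr::col_double(), summit_offset = readr::col_double()
    ),
    comment = "#", progress = FALSE
  )
  x <- mutate(x, summit = .data$start + .data$summit_offset) %>%
    select(-"summit_offset")
  if (!is.null(sample_id)) x$sample_id <- sample_id
  x
}

#' @param x peak tibble with at least `chrom`, `start`, `end`; `summit`,
#'   `score`, `name` used when present.
#' @rdname read_narrowpeak
#' @export
write_narrowpeak <- function(x, path) {
  n <- nrow(x)
  out <- tibble(
    chrom = x$chrom, start = x$start, end = x$end,
    name = if ("name" %in% names(x)) x$name else paste0("peak_", seq_len(max(n, 0))),
    score = if ("score" %in% names(x)) x$score else 0,
    strand = ".",
    signal = if ("signal" %in% names(x)) x$signal else
      if ("score" %in% names(x)) x$score else 0,
    pvalue = if ("pvalue" %in% names(x)) x$pvalue else -1,
    qvalue = if ("qvalue" %in% names(x)) x$qvalue else -1,
    summit_offset = if ("summit" %in% names(x)) x$summit - x$start else
      floor((x$end - x$start) / 2)
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

bedpe_cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                "name", "score", "strand1", "strand2")

#' Read/write 10-column BEDPE enhancer-promoter pairs
#'
#' Anchor 1 is the enhancer element, anchor 2 the promoter window, `name` the
#' target gene id and `score` the ABC score. Files carry one `#`-prefixed
#' header comment.
#'
#' @param path file path.
#' @return Tibble with the 10 BEDPE columns.
#' @export
read_bedpe <- function(path) {
  readr::read_tsv(path,
    col_names = bedpe_cols,
    col_types = readr::cols(
      chrom1 = readr::col_character(), start1 = readr::col_double(),
      end1 = readr::col_double(), chrom2 = readr::col_character(),
      start2 = readr::col_double(), end2 = readr::col_double(),
      name = readr::col_character(), score = readr::col_double(),
      strand1 = readr::col_character(), strand2 = readr::col_character()
    ),
    comment = "#", progress = FALSE
  )
}

#' @param x BEDPE tibble (see [pairs_to_bedpe()]).
#' @rdname read_bedpe
#' @export
write_bedpe <- function(x, path) {
  readr::write_lines(paste0("#", paste(bedpe_cols, collapse = "\t")), path)
  if (nrow(x) > 0) {
    readr::write_tsv(x[, bedpe_cols], path, col_names = FALSE, append = TRUE,
                     progress = FALSE)
  }
  invisible(path)
}

#' Read/write the 6-column gene annotation TSV
#'
#' Columns: `chrom`, `tss`, `strand`, `gene_id`, `body_start`, `body_end`.
#'
#' @param path file path.
#' @export
read_genes <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), tss = readr::col_double(),
    strand = readr::col_character(), gene_id = readr::col_character(),
    body_start = readr::col_double(), body_end = readr::col_double()
  ), progress = FALSE)
}

#' @param x gene tibble.
#' @rdname read_genes
#' @export
write_genes <- function(x, path) {
  readr::write_tsv(
    x[, c("chrom", "tss", "strand", "gene_id", "body_start", "body_end")],
    path, progress = FALSE
  )
  invisible(path)
}

#' Read/write an expression matrix TSV (gene_id + one column per sample)
#' @param path file path.
#' @export
read_expression <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
}

#' @param x expression tibble.
#' @rdname read_expression
#' @export
write_expression <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read/write the sample sheet (sample, genotype, stage)
#' @param path file path.
#' @export
read_sample_sheet <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

#' @param x sample sheet tibble.
#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
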