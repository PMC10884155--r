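# broom-style tidiers for the result objects.

#' Tidy openness calls
#'
#' @param x an `openness_calls` tibble.
#' @param ... unused.
#' @return A plain tibble of per-peak calls.
#' @export
tidy.openness_calls <- function(x, ...) {
  class(x) <- setdiff(class(x), "openness_calls")
  attr(x, "threshold") <- NULL
  as_tibble(x)
}

#' One-row summary of openness calls
#'
#' @param x an `openness_calls` tibble.
#' @param ... unused.
#' @return Tibble with the threshold and per-cluster counts.
#' @export
glance.openness_calls <- function(x, ...) {
  s <- openness_summary(x)
  tibble(threshold = attr(x, "threshold"),
         n_peaks = nrow(x),
         n_common = s$n[s$label == "C"],
         n_a_specific = s$n[s$label == "I"],
         n_b_specific = s$n[s$label == "N"],
         n_unassigned = s$n[s$label == "unassigned"])
}

#' Tidy knockdown-response calls
#'
#' @param x a `kd_response_calls` tibble.
#' @param ... unused.
#' @return A plain tibble of per-gene calls.
#' @export
tidy.kd_response_calls <- function(x, ...) {
  class(x) <- setdiff(class(x), "kd_response_calls")
  attr(x, "attenuation_cutoff") <- NULL
  as_tibble(x)
}

#' One-row summary of knockdown-response calls
#'
#' @param x a `kd_response_calls` tibble.
#' @param ... unused.
#' @return Tibble with the cutoff and per-cluster gene counts.
#' @export
glance.kd_response_calls <- function(x, ...) {
  cl <- factor(x$cluster, levels = c("1", "2", "3", "4", "none"))
  counts <- as.integer(table(cl))
  tibble(attenuation_cutoff = attr(x, "attenuation_cutoff"),
         n_genes = nrow(x),
         n_cluster1 = counts[1], n_cluster2 = counts[2],
         n_cluster3 = counts[3], n_cluster4 = counts[4],
         n_flat = counts[5])
}
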