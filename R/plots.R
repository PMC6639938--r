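#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_line
#'   geom_abline labs theme_minimal scale_colour_brewer
#' @export
ggplot2::autoplot

#' Plot a discovery evaluation
#'
#' Bar chart of the planted-insertion classification: detected, FN1
#' (non-unique flank), FN2 (N region), missed for other reasons.
#'
#' @param object An `alu_eval` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot alu_eval
#' @export
autoplot.alu_eval <- function(object, ...) {
  d <- tidy.alu_eval(object) |>
    count(.data$status) |>
    mutate(status = factor(.data$status,
                           levels = c("detected", "FN1", "FN2",
                                      "missed_other")))
  ggplot(d, aes(x = .data$status, y = .data$n, fill = .data$status)) +
    geom_col(show.legend = FALSE) +
    labs(x = NULL, y = "planted insertions",
         title = "Planted-insertion discovery outcome") +
    theme_minimal()
}

#' Plot genotype calls as an allele-count scatter
#'
#' Classic allele-intensity plot: kmerA count against kmerB count, coloured
#' by called genotype. Homozygotes hug the axes, heterozygotes the diagonal.
#'
#' @param object An `alu_calls` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot alu_calls
#' @export
autoplot.alu_calls <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$nA, y = .data$nB, colour = .data$genotype)) +
    geom_point(alpha = 0.7) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    scale_colour_brewer(palette = "Dark2") +
    labs(x = "allele A 32-mer count", y = "allele B 32-mer count",
         colour = "genotype",
         title = "Allele-specific 32-mer counts") +
    theme_minimal()
}

#' Plot sensitivity against sequencing coverage
#'
#' @param data Tibble with columns `coverage` and `sensitivity` (for example
#'   assembled from [glance()] over several evaluations).
#' @return A ggplot.
#' @export
plot_sensitivity_curve <- function(data) {
  stopifnot(all(c("coverage", "sensitivity") %in% names(data)))
  ggplot(data, aes(x = .data$coverage, y = .data$sensitivity)) +
    geom_line() +
    geom_point() +
    labs(x = "depth of coverage", y = "discovery sensitivity",
         title = "REF- discovery sensitivity vs coverage") +
    theme_minimal()
}

#' Plot a filtering cascade
#'
#' @param x An object carrying a `cascade` attribute (see [cascade()]).
#' @return A ggplot of per-stage counts.
#' @export
plot_cascade <- function(x) {
  d <- cascade(x) |>
    mutate(stage = factor(.data$stage, levels = rev(.data$stage)))
  ggplot(d, aes(x = .data$n, y = .data$stage)) +
    geom_col(fill = "steelblue") +
    labs(x = "candidates", y = NULL, title = "Filtering cascade") +
    theme_minimal()
}
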