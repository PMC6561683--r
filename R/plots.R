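#' @importFrom ggplot2 ggplot aes autoplot geom_col geom_point geom_line
#'   geom_hline geom_abline labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot a positional motif distribution
#'
#' @param object A `kferq_position_histogram` from
#'   [positional_distribution()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kferq_position_histogram
#' @export
autoplot.kferq_position_histogram <- function(object, ...) {
  ggplot(object, aes(x = (.data$bin_start + .data$bin_end) / 2,
                     y = .data$count)) +
    geom_col(width = attr(object, "bin_size"), fill = "grey35") +
    labs(x = "relative position (0 = N-terminus, 1 = C-terminus)",
         y = "motif count") +
    theme_minimal()
}

#' Plot a motif-centred solvent-exposure profile
#'
#' @param object A `kferq_exposure_profile` from [exposure_profile()].
#' @param ... Unused.
#' @return A ggplot; the horizontal line is the all-residue baseline.
#' @method autoplot kferq_exposure_profile
#' @export
autoplot.kferq_exposure_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$offset, y = .data$pct_exposed)) +
    geom_line(colour = "grey35") +
    geom_point(size = 0.8) +
    geom_hline(aes(yintercept = .data$baseline), colour = "red",
               linetype = 2) +
    labs(x = "offset from motif centre (residues)", y = "% exposed") +
    theme_minimal()
}

#' Plot the length-model fit
#'
#' @param object A `kferq_length_fit` from [fit_length_model()].
#' @param ... Unused.
#' @return A ggplot of log2 motif count against protein length with the
#'   fitted line.
#' @method autoplot kferq_length_fit
#' @export
autoplot.kferq_length_fit <- function(object, ...) {
  cf <- stats::coef(object$fit)
  ggplot(object$data, aes(x = .data$length, y = .data$log2_count)) +
    geom_point(alpha = 0.4) +
    geom_abline(intercept = cf[["(Intercept)"]], slope = cf[["length"]],
                colour = "blue") +
    labs(x = "protein length (residues)",
         y = paste0("log2 n ", object$motif_class, " motifs")) +
    theme_minimal()
}

#' Bar chart of hierarchy-group percentages
#'
#' @param breakdown Result of [group_percentages()].
#' @return A ggplot.
#' @export
plot_group_percentages <- function(breakdown) {
  ggplot(breakdown, aes(x = .data$hierarchy_group, y = .data$percent)) +
    geom_col(fill = "grey35") +
    labs(x = NULL, y = "% of proteins") +
    theme_minimal()
}

#' Scatterplot of conservation scores, CMA-able vs CMA-unable
#'
#' @param scores Result of [score_conservation()].
#' @return A ggplot; selectively conserved motifs (able > 0, unable <= 0)
#'   are highlighted.
#' @export
plot_conservation <- function(scores) {
  ggplot(scores, aes(x = .data$score_unable, y = .data$score_able,
                     colour = .data$selective)) +
    geom_point(alpha = 0.6) +
    geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    labs(x = "conservation score, CMA-unable species",
         y = "conservation score, CMA-able species",
         colour = "selectively\nconserved") +
    theme_minimal()
}

#' Heat map of amino-acid position frequencies within motifs
#'
#' @param freqs Result of [aa_position_frequencies()].
#' @return A ggplot tile map of percent per (amino acid, position).
#' @export
plot_position_frequencies <- function(freqs) {
  ggplot(freqs, aes(x = factor(.data$position), y = .data$amino_acid,
                    fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    labs(x = "position relative to flanking residue", y = NULL,
         fill = "%") +
    theme_minimal()
}
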