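# ggplot2 helpers for the main result types.

#' @importFrom ggplot2 ggplot aes geom_col geom_point geom_tile geom_histogram
#'   geom_vline labs scale_fill_gradient2 theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot the chromosome distribution of a gene set
#'
#' @param dist Tibble from [chromosome_distribution()].
#' @return A ggplot object.
#' @export
plot_chromosome_distribution <- function(dist) {
  dist$chromosome <- factor(dist$chromosome, levels = CHROMOSOME_LABELS)
  ggplot(dist, aes(x = .data$chromosome, y = .data$n_genes)) +
    geom_col(fill = "steelblue") +
    labs(x = "chromosome", y = "genes", title = "Chromosome distribution") +
    theme_minimal()
}

#' Plot per-chromosome mean expression for the direction sets
#'
#' @param cm Tibble from [chromosome_mean_expression()].
#' @return A ggplot object.
#' @export
plot_chromosome_means <- function(cm) {
  long <- tidyr::pivot_longer(cm[c("chromosome", "mean_up", "mean_down")],
                              -"chromosome", names_to = "set",
                              values_to = "mean_log2_ratio")
  long$chromosome <- factor(long$chromosome, levels = CHROMOSOME_LABELS)
  ggplot(dplyr::filter(long, !is.na(.data$mean_log2_ratio)),
         aes(x = .data$chromosome, y = .data$mean_log2_ratio, fill = .data$set)) +
    geom_col(position = "dodge") +
    labs(x = "chromosome", y = "mean log2 ratio") +
    theme_minimal()
}

#' Plot the incidence ranking
#'
#' @param incidence Tibble from [de_incidence_ranking()].
#' @param top Number of top genes to show.
#' @return A ggplot object.
#' @export
plot_incidence <- function(incidence, top = 20) {
  d <- head(incidence, top)
  d$gene_id <- factor(d$gene_id, levels = rev(d$gene_id))
  ggplot(d, aes(x = .data$n_units_de, y = .data$gene_id)) +
    geom_col(fill = "darkorange") +
    labs(x = "samples called DE", y = "gene",
         title = "Differential-expression incidence") +
    theme_minimal()
}

#' @rdname chromosome_correlation_map
#' @param object A `correlation_map`.
#' @export
autoplot.correlation_map <- function(object, ...) {
  long <- tidy.correlation_map(object)
  ggplot(long, aes(x = .data$sample_a, y = .data$sample_b, fill = .data$r)) +
    geom_tile() +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(title = sprintf("Chromosome %s correlation map (%s)",
                         object$chromosome, object$method)) +
    theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @rdname storey_qvalues
#' @param object A `qvalue_result`.
#' @export
autoplot.qvalue_result <- function(object, ...) {
  ggplot(tibble(q = object$q), aes(x = .data$q)) +
    geom_histogram(bins = 40, fill = "grey40") +
    geom_vline(xintercept = 0.05, linetype = 2) +
    labs(x = "q-value",
         title = sprintf("q-values (pi0 = %.3f)", object$pi0)) +
    theme_minimal()
}

#' @rdname pca_study
#' @param object A `pca_result`.
#' @export
autoplot.pca_result <- function(object, ...) {
  d <- tidy.pca_result(object)
  ggplot(d, aes(x = .data$PC1, y = .data$PC2)) +
    geom_point() +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * object$variance_fraction[1]),
         y = sprintf("PC2 (%.1f%%)", 100 * object$variance_fraction[2])) +
    theme_minimal()
}
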