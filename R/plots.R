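# ggplot2 graphics for scan and variance-partition results.

#' Manhattan plot of an association scan
#'
#' @param object A `qg_gwas`.
#' @param threshold Significance line (default: the scan's Bonferroni
#'   attribute).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot qg_gwas
#' @export
autoplot.qg_gwas <- function(object, threshold = NULL, ...) {
  threshold <- threshold %||% attr(object, "threshold")
  df <- as_tibble(object) %>%
    filter(!is.na(.data$p_value)) %>%
    arrange(.data$chrom, .data$pos) %>%
    group_by(.data$chrom) %>%
    mutate(pos_mb = .data$pos / 1e6) %>%
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos_mb,
                                   y = -log10(.data$p_value),
                                   colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(threshold), linetype = "dashed",
                        colour = "red") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](italic(p))),
                  title = attr(object, "trait")) +
    ggplot2::theme_minimal()
}

#' Quantile-quantile plot of an association scan
#'
#' Observed versus expected -log10 p-values with the genomic inflation
#' factor in the subtitle.
#'
#' @param gwas A `qg_gwas`.
#' @return A ggplot.
#' @export
plot_qq <- function(gwas) {
  p <- sort(gwas$p_value[!is.na(gwas$p_value)])
  n <- length(p)
  df <- tibble(expected = -log10((seq_len(n) - 0.5) / n),
               observed = -log10(p))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::labs(x = expression(expected ~ -log[10](italic(p))),
                  y = expression(observed ~ -log[10](italic(p))),
                  subtitle = sprintf("lambda[GC] = %.3f",
                                     attr(gwas, "lambda_gc"))) +
    ggplot2::theme_minimal()
}

#' Variance-partition bar plot of a GREML fit
#'
#' @param object A `qg_greml`.
#' @param ... Unused.
#' @return A ggplot of the per-component fractions of phenotypic variance
#'   with +/- 1 SE bars.
#' @method autoplot qg_greml
#' @export
autoplot.qg_greml <- function(object, ...) {
  df <- tidy(object) %>% filter(.data$component != "residual")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(0, .data$fraction - .data$fraction_se),
      ymax = .data$fraction + .data$fraction_se), width = 0.2) +
    ggplot2::labs(x = NULL, y = "fraction of phenotypic variance",
                  title = object$model$trait) +
    ggplot2::theme_minimal()
}
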