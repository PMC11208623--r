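#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_abline geom_col
#'   facet_wrap labs theme_bw coord_flip
NULL

#' Scatter plots of method concordance
#'
#' One panel per method pair, raw mtDNAcn on both axes with the identity
#' line and the pair's Pearson r in the panel label.
#'
#' @param object An `mtcn_concordance` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mtcn_concordance <- function(object, ...) {
  rows <- purrr::pmap_dfr(object$pairs, function(method_a, method_b, n,
                                                 pearson_r) {
    ok <- complete.cases(object$wide[c(method_a, method_b)])
    tibble(
      pair = sprintf("%s vs %s (r = %.3f)", method_a, method_b, pearson_r),
      x = object$wide[[method_a]][ok],
      y = object$wide[[method_b]][ok]
    )
  })
  ggplot(rows, aes(x = .data$x, y = .data$y)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey50") +
    geom_point(alpha = 0.7) +
    facet_wrap(~pair, scales = "free") +
    labs(x = "mtDNAcn (first method)", y = "mtDNAcn (second method)") +
    theme_bw()
}

#' Per-contig depth plot
#'
#' @param object An `mtcn_coverage` object.
#' @param ... Unused.
#' @return A ggplot of mean depth per contig, coloured by contig class.
#' @export
autoplot.mtcn_coverage <- function(object, ...) {
  ggplot(object$per_contig,
         aes(x = .data$contig, y = .data$mean_depth, fill = .data$class)) +
    geom_col() +
    labs(x = NULL, y = "Mean depth (X)", fill = "Contig class") +
    theme_bw()
}

#' Bar chart of haplogroup-region counts
#'
#' @param tally Tibble from [region_tally()].
#' @return A ggplot.
#' @export
plot_region_tally <- function(tally) {
  stopifnot(all(c("region", "n") %in% names(tally)))
  tally$region <- factor(tally$region, levels = rev(tally$region))
  ggplot(tally, aes(x = .data$region, y = .data$n)) +
    geom_col(fill = "steelblue") +
    coord_flip() +
    labs(x = NULL, y = "Samples") +
    theme_bw()
}

#' Cohort mtDNAcn distribution plot
#'
#' @param truth Cohort tibble from [simulate_cohort()] (or any table with
#'   `group` and a value column).
#' @param value Column to plot (default `true_mtdnacn`).
#' @return A ggplot of per-group distributions.
#' @export
plot_cohort <- function(truth, value = true_mtdnacn) {
  value <- rlang::enquo(value)
  ggplot(truth, aes(x = .data$group, y = !!value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.4) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5) +
    labs(x = NULL, y = "Relative mtDNAcn") +
    theme_bw()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
ggplot2::autoplot
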