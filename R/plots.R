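#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar plot of per-test rejection rates
#'
#' One bar per individual test plus the combined test, with exact binomial
#' 99% confidence intervals and the nominal level marked; the standard
#' view of a type-I-error or power experiment.
#'
#' @param object A `fam_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fam_experiment
#' @export
autoplot.fam_experiment <- function(object, ...) {
  rates <- object$rates
  rates$test <- factor(rates$test, levels = rates$test)
  rates$role <- ifelse(rates$test == "combined", "combined", "individual")
  ggplot2::ggplot(rates, ggplot2::aes(x = .data$test, y = .data$rate,
                                      fill = .data$role)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lower,
                                        ymax = .data$ci_upper),
                           width = 0.25) +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(individual = "grey60",
                                          combined = "black")) +
    ggplot2::labs(
      x = NULL,
      y = if (object$kind == "level") "rejection rate (type I error)"
          else "rejection rate (power)",
      title = sprintf("%s experiment: %d replicates, m = %d, alpha = %g",
                      if (object$kind == "level") "Level" else "Power",
                      object$replicates, object$m, object$alpha)
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of pairwise p-value correlations
#'
#' @param results As in [pvalue_correlations()].
#' @return A ggplot object.
#' @export
plot_pvalue_correlations <- function(results) {
  cm <- pvalue_correlations(results)
  df <- tibble::as_tibble(as.table(cm), .name_repair = ~ c("test1", "test2", "r"))
  df$test1 <- factor(df$test1, levels = rownames(cm))
  df$test2 <- factor(df$test2, levels = rownames(cm))
  ggplot2::ggplot(df, ggplot2::aes(.data$test1, .data$test2,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                                  mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
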