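#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_boxplot geom_abline geom_step facet_wrap labs theme_minimal
#'   scale_y_continuous coord_cartesian
NULL

#' @export
ggplot2::autoplot

#' Plot perturbation time series
#'
#' One panel per perturbation, one line per observed node.
#'
#' @param object A `pert_ts`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pert_ts <- function(object, ...) {
  ggplot(object$measurements, aes(x = time, y = value, colour = node)) +
    geom_line() +
    geom_point(size = 0.8) +
    facet_wrap(~perturbation) +
    labs(
      x = "time (min)", y = if (object$binarized) "state" else "normalized signal",
      colour = NULL
    ) +
    theme_minimal()
}

#' Hyper-edge frequency profile of a family
#'
#' Horizontal bars of hyper-edge frequencies within a family, the family-level
#' heterogeneity picture.
#'
#' @param family A [bn_family()] (or a precomputed [hyperedge_frequencies()]
#'   tibble).
#' @param min_frequency Hide hyper-edges below this frequency.
#' @return A ggplot.
#' @export
plot_hyperedge_frequencies <- function(family, min_frequency = 0) {
  freq <- if (is.data.frame(family)) family else hyperedge_frequencies(family)
  freq <- freq[freq$frequency >= min_frequency, ]
  freq$hyperedge <- stats::reorder(freq$hyperedge, freq$frequency)
  ggplot(freq, aes(x = frequency, y = hyperedge)) +
    geom_col(fill = "steelblue") +
    coord_cartesian(xlim = c(0, 1)) +
    labs(x = "frequency in family", y = NULL) +
    theme_minimal()
}

#' RMSE-ratio comparison of structured versus random data
#'
#' Boxplot of the random-sample RMSE ratios with the structured-data ratio
#' overlaid, the standard specificity picture: a family that fits its own
#' data exactly (ratio 1) but cannot fit random trajectories shows the random
#' box strictly below the structured point.
#'
#' @param random A [random_validation()] tibble.
#' @param structured Structured-data RMSE ratio(s) to overlay (default 1).
#' @return A ggplot.
#' @export
plot_rmse_ratio <- function(random, structured = 1) {
  rn <- dplyr::mutate(random, dataset = "random")
  st <- tibble(dataset = "structured", ratio = structured)
  ggplot(rn, aes(x = dataset, y = ratio)) +
    geom_boxplot(fill = "indianred", width = 0.4) +
    geom_point(data = st, colour = "dodgerblue3", size = 3) +
    scale_y_continuous(limits = c(0, 1.05)) +
    labs(x = NULL, y = "RMSE ratio (discrete / model)") +
    theme_minimal()
}

#' ROC point cloud of a family with its AUROC
#'
#' @param points Data frame with columns `fpr`, `tpr` (one point per
#'   network), as consumed by [family_auroc()].
#' @return A ggplot.
#' @export
plot_roc <- function(points) {
  auc <- family_auroc(points)
  env <- as_tibble(points) %>%
    group_by(fpr) %>%
    summarise(tpr = max(tpr), .groups = "drop") %>%
    arrange(fpr)
  env <- bind_rows(tibble(fpr = 0, tpr = 0), env, tibble(fpr = 1, tpr = 1))
  ggplot(as_tibble(points), aes(x = fpr, y = tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_line(data = env, colour = "steelblue") +
    geom_point(colour = "steelblue") +
    coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("AUROC = %.2f", auc)
    ) +
    theme_minimal()
}
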