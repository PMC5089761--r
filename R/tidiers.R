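#' Tidy an ROC result
#'
#' @param x An `ms_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A one-row tibble with `auc`, `ci_low`, `ci_high`, `se`,
#'   `n_cases`, `n_controls`, `ci_method`.
#' @method tidy ms_roc
#' @export
tidy.ms_roc <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high, se = x$se,
    n_cases = x$n_cases, n_controls = x$n_controls, ci_method = x$ci_method
  )
}

#' @rdname tidy.ms_roc
#' @method glance ms_roc
#' @export
glance.ms_roc <- function(x, ...) tidy.ms_roc(x, ...)

#' Tidy a group comparison
#'
#' `tidy()` returns the pairwise Welch t-tests with Bonferroni-adjusted
#' p-values; `glance()` the one-way ANOVA summary.
#'
#' @param x An `ms_group_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ms_group_comparison
#' @export
tidy.ms_group_comparison <- function(x, ...) x$pairwise

#' @rdname tidy.ms_group_comparison
#' @method glance ms_group_comparison
#' @export
glance.ms_group_comparison <- function(x, ...) {
  tibble::tibble(
    statistic = x$anova$f,
    df_between = x$anova$df_between,
    df_within = x$anova$df_within,
    p_value = x$anova$p
  )
}

#' Tidy a septile partition
#'
#' @param x An `ms_septiles` from [septile_partition()].
#' @param ... Unused.
#' @return A tibble with one row per septile: `septile`, `count`,
#'   `fraction`, and the interval bounds.
#' @method tidy ms_septiles
#' @export
tidy.ms_septiles <- function(x, ...) {
  bounds <- c(-Inf, x$cutpoints, Inf)
  tibble::tibble(
    septile = 1:7,
    lower = bounds[1:7],
    upper = bounds[2:8],
    count = x$counts,
    fraction = x$counts / x$n
  )
}

#' @rdname tidy.ms_septiles
#' @method glance ms_septiles
#' @export
glance.ms_septiles <- function(x, ...) {
  tibble::tibble(mean = x$mean, sd = x$sd, n = x$n, top_fraction = x$top_fraction)
}

#' Plot an ROC curve
#'
#' Empirical ROC curve (sensitivity vs 1 - specificity over all score
#' thresholds) with the AUC annotated.
#'
#' @param object An `ms_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ms_roc
#' @export
autoplot.ms_roc <- function(object, ...) {
  thr <- sort(unique(c(-Inf, object$case_scores, object$control_scores, Inf)))
  pts <- purrr::map_dfr(thr, function(t) {
    tibble::tibble(
      fpr = mean(object$control_scores >= t),
      tpr = mean(object$case_scores >= t)
    )
  }) %>% dplyr::arrange(.data$fpr, .data$tpr)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC curve (AUC %.2f, %d%% CI %.2f-%.2f)",
                      object$auc, round(100 * object$conf_level),
                      object$ci_low, object$ci_high)
    ) +
    ggplot2::theme_minimal()
}

#' Score distribution by cohort group
#'
#' Box-and-whisker plot with jittered points, one box per group, mirroring
#' the standard presentation of a risk-score distribution across probands,
#' siblings and controls.
#'
#' @param data Scored tibble (e.g. from [score_cohort()]).
#' @param score,group Columns with the score and the group label.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(data, score = score, group = group) {
  ggplot2::ggplot(data, ggplot2::aes(x = {{ group }}, y = {{ score }})) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = NULL, y = "Risk score (log10 odds units)") +
    ggplot2::theme_minimal()
}

#' Plot septile occupancy
#'
#' @param x An `ms_septiles` from [septile_partition()].
#' @return A ggplot object.
#' @export
plot_septiles <- function(x) {
  d <- tidy.ms_septiles(x)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$septile), y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Septile (mean ± 0.25 / 0.75 / 1.25 SD)",
                  y = "Fraction of cohort") +
    ggplot2::theme_minimal()
}
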