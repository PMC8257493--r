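#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a logistic PCA fit
#'
#' @param x A [`logistic_pca`][fit_logistic_pca] object.
#' @param matrix One of `"scores"` (default; one row per individual and
#'   component), `"loadings"` (one row per term and component) or
#'   `"deviance"` (one row per component).
#' @param ... Unused.
#' @return A tibble in long format.
#' @method tidy logistic_pca
#' @export
tidy.logistic_pca <- function(x, matrix = c("scores", "loadings", "deviance"),
                              ...) {
  matrix <- match.arg(matrix)
  if (matrix == "deviance") return(x$deviance_explained)
  m <- x[[matrix]]
  id_col <- if (matrix == "scores") "individual_id" else "term"
  tibble::tibble(
    !!id_col := rep(rownames(m), ncol(m)),
    component = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
}

#' One-row summary of a logistic PCA fit
#'
#' @param x A [`logistic_pca`][fit_logistic_pca] object.
#' @param ... Unused.
#' @method glance logistic_pca
#' @export
glance.logistic_pca <- function(x, ...) {
  tibble::tibble(
    k = x$k, m = x$m,
    deviance = x$deviance, null_deviance = x$null_deviance,
    deviance_explained = max(x$deviance_explained$cumulative),
    iterations = x$iterations, converged = x$converged
  )
}

#' Tidy a classifier evaluation
#'
#' @param x A [`classifier_eval`][evaluate_component] object.
#' @param curve One of `"roc"` (default), `"pr"` or `"ppv"`.
#' @param ... Unused.
#' @method tidy classifier_eval
#' @export
tidy.classifier_eval <- function(x, curve = c("roc", "pr", "ppv"), ...) {
  x[[match.arg(curve)]]
}

#' One-row summary of a classifier evaluation
#'
#' @param x A [`classifier_eval`][evaluate_component] object.
#' @param ... Unused.
#' @method glance classifier_eval
#' @export
glance.classifier_eval <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, cutoff = x$cutoff, sensitivity = x$sensitivity,
    specificity = x$specificity, precision = x$precision, f1 = x$f1,
    n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' Scree plot of a logistic PCA fit
#'
#' @param object A [`logistic_pca`][fit_logistic_pca] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot logistic_pca
#' @export
autoplot.logistic_pca <- function(object, ...) {
  df <- object$deviance_explained
  ggplot2::ggplot(df, ggplot2::aes(.data$component, .data$deviance_explained)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative), colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative), colour = "steelblue") +
    ggplot2::scale_x_continuous(breaks = df$component) +
    ggplot2::labs(x = "component", y = "fraction of deviance explained",
                  title = "Logistic PCA scree") +
    ggplot2::theme_minimal()
}

#' ROC curve of a classifier evaluation
#'
#' @param object A [`classifier_eval`][evaluate_component] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot classifier_eval
#' @export
autoplot.classifier_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc,
                  ggplot2::aes(1 - .data$specificity, .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC (AUC = %.2f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Phenogram scatter plot
#'
#' Plots subgroup term frequency against remainder frequency, highlighting
#' terms with uncorrected p below the threshold used in [phenogram()].
#'
#' @param pheno Output of [phenogram()].
#' @return A ggplot object.
#' @export
plot_phenogram <- function(pheno) {
  ggplot2::ggplot(pheno, ggplot2::aes(.data$freq_rest, .data$freq_group,
                                      colour = .data$highlight)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue",
                                            `TRUE` = "firebrick"),
                                 name = "p < threshold") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "frequency in remainder of cohort",
                  y = "frequency in subgroup") +
    ggplot2::theme_minimal()
}
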