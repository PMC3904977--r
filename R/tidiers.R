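# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' Tidy a PCA projection
#'
#' @param x an `ifr_pca`.
#' @param ... unused.
#' @return tibble per component: `component`, `eigenvalue`,
#'   `variance_fraction`, `cumulative_variance`, `retained`.
#' @method tidy ifr_pca
#' @export
tidy.ifr_pca <- function(x, ...) {
  frac <- x$eigenvalues / sum(x$eigenvalues)
  tibble::tibble(component = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 variance_fraction = frac,
                 cumulative_variance = cumsum(frac),
                 retained = seq_along(x$eigenvalues) <= x$k)
}

#' @method glance ifr_pca
#' @export
glance.ifr_pca <- function(x, ...) {
  tibble::tibble(n_columns = length(x$columns), k = x$k,
                 cum_var = x$cum_var, variance_target = x$variance_target)
}

#' Tidy an LDA model
#'
#' @param x an `ifr_lda`.
#' @param ... unused.
#' @return tibble per feature: class means and discriminant weight.
#' @method tidy ifr_lda
#' @export
tidy.ifr_lda <- function(x, ...) {
  tibble::tibble(feature = seq_along(x$w),
                 mean_fsr = as.numeric(x$mu0), mean_ifr = as.numeric(x$mu1),
                 weight = as.numeric(x$w))
}

#' @method glance ifr_lda
#' @export
glance.ifr_lda <- function(x, ...) {
  tibble::tibble(n_features = length(x$w),
                 n_ifr = unname(x$n["n1"]), n_fsr = unname(x$n["n0"]),
                 prior_ifr = unname(x$priors["p1"]))
}

#' Tidy an ROC analysis
#'
#' @param x an `ifr_roc`.
#' @param ... unused.
#' @return the ROC points tibble (`cutoff`, `fpr`, `tpr`, `precision`,
#'   `mcc`).
#' @method tidy ifr_roc
#' @export
tidy.ifr_roc <- function(x, ...) x$points

#' @method glance ifr_roc
#' @export
glance.ifr_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, max_mcc = x$max_mcc,
                 max_mcc_cutoff = x$max_mcc_cutoff,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Tidy a classifier bundle
#'
#' @param x an `ifr_bundle`.
#' @param ... unused.
#' @return tibble per amino-acid type: retained columns/components and
#'   training sizes.
#' @method tidy ifr_bundle
#' @export
tidy.ifr_bundle <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$models), function(tp) {
    m <- x$models[[tp]]
    tibble::tibble(res_type = tp, n_columns = length(m$columns),
                   n_removed = length(m$removed), k = m$pca$k,
                   cum_var = m$pca$cum_var,
                   n_ifr = unname(m$lda$n["n1"]), n_fsr = unname(m$lda$n["n0"]))
  }))
}

#' @method glance ifr_bundle
#' @export
glance.ifr_bundle <- function(x, ...) {
  tibble::tibble(n_models = length(x$models), cutoff = x$cutoff,
                 seed = x$seed %||% NA_integer_)
}

#' ROC curve plot
#'
#' @param object an `ifr_roc`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot ifr_roc
#' @export
autoplot.ifr_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("AUC = %.3f, max MCC = %.3f",
                                  object$auc, object$max_mcc)) +
    ggplot2::theme_minimal()
}

#' Cutoff-screen plot
#'
#' Accuracy, precision, sensitivity and MCC as functions of the decision
#' cutoff.
#'
#' @param object an `ifr_cutoff_screen`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot ifr_cutoff_screen
#' @export
autoplot.ifr_cutoff_screen <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("cutoff", "accuracy", "precision",
                                  "sensitivity", "mcc")],
    -"cutoff", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cutoff, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Decision cutoff", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
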