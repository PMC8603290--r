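#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PCA result
#'
#' @param x An `expr_pca` object.
#' @param ... Unused.
#' @return The sample-by-component score tibble.
#' @method tidy expr_pca
#' @export
tidy.expr_pca <- function(x, ...) x$scores

#' One-row PCA summary
#'
#' @param x An `expr_pca` object.
#' @param ... Unused.
#' @return Tibble with `n_samples`, `n_genes_used`, `n_components`,
#'   `pc1_variance_fraction`, `total_variance`.
#' @method glance expr_pca
#' @export
glance.expr_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_genes_used = x$n_genes_used,
    n_components = x$n_components,
    pc1_variance_fraction = x$explained_variance_fraction[1],
    total_variance = x$total_variance
  )
}

#' Tidy a ROC cut-off result
#'
#' @param x A `roc_cutoff` object.
#' @param ... Unused.
#' @return The ROC curve tibble (`threshold`, `sensitivity`,
#'   `specificity`, `youden_j`).
#' @method tidy roc_cutoff
#' @export
tidy.roc_cutoff <- function(x, ...) x$curve

#' One-row ROC cut-off summary
#'
#' @param x A `roc_cutoff` object.
#' @param ... Unused.
#' @return Tibble with `cutoff`, `youden_j`, `auc`, `n`, `direction`.
#' @method glance roc_cutoff
#' @export
glance.roc_cutoff <- function(x, ...) {
  tibble::tibble(cutoff = x$cutoff, youden_j = x$youden_j, auc = x$auc,
                 n = x$n, direction = x$direction)
}

#' Per-group observed/expected table of a log-rank test
#'
#' @param x A `logrank_test` object.
#' @param ... Unused.
#' @return The per-group tibble (`group`, `n`, `observed`, `expected`).
#' @method tidy logrank_test
#' @export
tidy.logrank_test <- function(x, ...) x$groups

#' One-row log-rank summary
#'
#' @param x A `logrank_test` object.
#' @param ... Unused.
#' @return Tibble with `chi_square`, `df`, `p_value`, `n`.
#' @method glance logrank_test
#' @export
glance.logrank_test <- function(x, ...) {
  tibble::tibble(chi_square = x$chi_square, df = x$df,
                 p_value = x$p_value, n = x$n)
}
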