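#' Tidy a ROC curve
#'
#' @param x An `fh_roc` object.
#' @param ... Ignored.
#' @return Tibble of swept thresholds with `sens`, `spec` and Youden `j`.
#' @export
tidy.fh_roc <- function(x, ...) {
  dplyr::mutate(x$curve, j = .data$sens + .data$spec - 1)
}

#' @rdname tidy.fh_roc
#' @return `glance()`: one-row tibble with `auc`, `n_case`, `n_control`,
#'   `degenerate`.
#' @export
glance.fh_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_case = x$n_case, n_control = x$n_control,
                 degenerate = x$degenerate)
}

#' Tidy a group comparison
#'
#' @param x An `fh_group_compare` object.
#' @param ... Ignored.
#' @return Pairwise comparison tibble (`group1`, `group2`, `p_value`,
#'   `method`).
#' @export
tidy.fh_group_compare <- function(x, ...) {
  x$pairwise
}

#' @rdname tidy.fh_group_compare
#' @return `glance()`: one-row tibble with the chosen `method`, `overall_p`
#'   and number of groups.
#' @export
glance.fh_group_compare <- function(x, ...) {
  tibble::tibble(method = x$method, overall_p = x$overall_p,
                 n_groups = nrow(x$summary))
}
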