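#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a ROC curve
#'
#' @param object An [roc_curve()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.fh_roc <- function(object, ...) {
  dat <- dplyr::arrange(object$curve, 1 - .data$spec, .data$sens)
  ggplot2::ggplot(dat, ggplot2::aes(x = 1 - .data$spec, y = .data$sens)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC = %.3f (%d cases vs %d controls)",
                                  object$auc, object$n_case,
                                  object$n_control)) +
    ggplot2::theme_minimal()
}

#' Score distributions by group
#'
#' Density plot of one panel's weighted gene score per cohort group, with the
#' control 75th percentile marked.
#'
#' @param scores Long score tibble (`sample_id`, `panel`, `wgs`).
#' @param cohort Cohort tibble.
#' @param panel Panel to plot.
#' @param control_group Group whose 75th percentile is marked.
#' @return A ggplot.
#' @export
plot_score_distributions <- function(scores, cohort, panel = "wGS8",
                                     control_group = "EUR") {
  dat <- dplyr::inner_join(scores[scores$panel == panel, ],
                           cohort[c("sample_id", "group")], by = "sample_id")
  dat <- dat[!is.na(dat$wgs), ]
  p75 <- percentile_cutoff(dat$wgs[dat$group == control_group], 75)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$wgs, fill = .data$group)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::geom_vline(xintercept = p75, linetype = "dashed") +
    ggplot2::labs(x = sprintf("%s (mmol/L-weighted units)", panel),
                  y = "Density", fill = "Group",
                  title = sprintf("%s by group (dashed: control p75 = %.3f)",
                                  panel, p75)) +
    ggplot2::theme_minimal()
}

#' Effect-allele frequencies by group
#'
#' Bar chart of per-SNP effect-allele frequencies per cohort group, the usual
#' companion to the panel-refinement step.
#'
#' @param genotypes Genotype tibble.
#' @param cohort Cohort tibble.
#' @return A ggplot.
#' @export
plot_allele_frequencies <- function(genotypes, cohort) {
  rsids <- setdiff(names(genotypes), "sample_id")
  dat <- dplyr::inner_join(genotypes, cohort[c("sample_id", "group")],
                           by = "sample_id") |>
    tidyr::pivot_longer(dplyr::all_of(rsids), names_to = "rsid",
                        values_to = "dosage") |>
    dplyr::filter(!is.na(.data$dosage)) |>
    dplyr::group_by(.data$rsid, .data$group) |>
    dplyr::summarise(freq = sum(.data$dosage) / (2 * dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$rsid, y = .data$freq,
                                    fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Effect-allele frequency", fill = "Group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
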