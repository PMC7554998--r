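#' Percentile cutoff from a control score distribution
#'
#' Empirical quantile of the control scores (linear-interpolation "type 7"
#' convention, declared in reports). A sensible percentile needs a reasonable
#' control sample; fewer than 20 controls is an error.
#'
#' @param control_scores Numeric control scores (`NA` dropped).
#' @param q Percentile in (0, 100); classification uses 75, 90 or 95.
#' @return Threshold (numeric scalar).
#' @examples
#' percentile_cutoff(1:100, 75)
#' @export
percentile_cutoff <- function(control_scores, q) {
  x <- control_scores[!is.na(control_scores)]
  if (length(x) < 20) {
    stop("percentile cutoffs need at least 20 control scores (got ",
         length(x), ")", call. = FALSE)
  }
  stopifnot(length(q) == 1, q > 0, q < 100)
  unname(stats::quantile(x, q / 100, type = 7))
}

#' Count and proportion of scores above a threshold
#'
#' "Above the top quartile" is read strictly (`score > threshold`) by
#' default; set `strict = FALSE` for `>=`. Samples with missing scores are
#' excluded from the denominator.
#'
#' @param scores Numeric scores.
#' @param threshold Threshold.
#' @param strict Strict inequality (default `TRUE`).
#' @return One-row tibble: `n_above`, `n_total`, `proportion`.
#' @examples
#' proportion_above(c(rep(1, 216), rep(2, 187)), 1.5)
#' @export
proportion_above <- function(scores, threshold, strict = TRUE) {
  x <- scores[!is.na(scores)]
  if (!length(x)) stop("no non-missing scores", call. = FALSE)
  n_above <- if (strict) sum(x > threshold) else sum(x >= threshold)
  tibble::tibble(n_above = n_above, n_total = length(x),
                 proportion = n_above / length(x))
}

#' ROC curve of case vs control scores
#'
#' Sweeps sensitivity and specificity over thresholds placed at midpoints
#' between adjacent distinct pooled scores (plus sentinels below the minimum
#' and above the maximum; positive = score strictly above threshold). The
#' area under the curve is computed by the trapezoid rule and cross-checked
#' against the tie-corrected Mann-Whitney identity
#' `AUC = U / (n_case * n_control)`; a disagreement beyond 1e-10 aborts.
#' Constant scores in both groups yield AUC 0.5 with a degeneracy flag.
#'
#' @param case_scores,control_scores Numeric scores (`NA` dropped).
#' @return Object of class `fh_roc`: `curve` tibble (`threshold`, `sens`,
#'   `spec`), `auc`, `n_case`, `n_control`, `degenerate`.
#' @export
roc_curve <- function(case_scores, control_scores) {
  case <- case_scores[!is.na(case_scores)]
  control <- control_scores[!is.na(control_scores)]
  if (!length(case) || !length(control)) {
    stop("both case and control scores must be non-empty", call. = FALSE)
  }
  # Scores that are mathematically equal sums of betas can differ by ~1e-16
  # depending on summation order; snap to 10 decimals so ties are ties.
  case <- round(case, 10)
  control <- round(control, 10)
  pooled <- sort(unique(c(case, control)))
  degenerate <- length(pooled) == 1
  thresholds <- if (degenerate) {
    pooled
  } else {
    c(pooled[1] - 1, (pooled[-1] + pooled[-length(pooled)]) / 2,
      pooled[length(pooled)] + 1)
  }
  sens <- vapply(thresholds, function(t) mean(case > t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(control <= t), numeric(1))
  fpr <- 1 - spec
  ord <- order(fpr, sens)     # increasing false-positive rate
  auc_trap <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(sens)]) / 2)
  if (degenerate) auc_trap <- 0.5
  r <- rank(c(case, control), ties.method = "average")
  u <- sum(r[seq_along(case)]) - length(case) * (length(case) + 1) / 2
  auc_mw <- u / (length(case) * length(control))
  if (abs(auc_trap - auc_mw) > 1e-10) {
    stop("internal error: trapezoid AUC and Mann-Whitney AUC disagree (",
         auc_trap, " vs ", auc_mw, ")", call. = FALSE)
  }
  structure(list(
    curve = tibble::tibble(threshold = thresholds, sens = sens, spec = spec),
    auc = auc_mw, n_case = length(case), n_control = length(control),
    degenerate = degenerate,
    case_scores = case, control_scores = control
  ), class = "fh_roc")
}

#' @export
print.fh_roc <- function(x, ...) {
  cat("<fh_roc> AUC =", format(x$auc, digits = 4),
      sprintf("(%d cases vs %d controls, %d thresholds)%s\n", x$n_case,
              x$n_control, nrow(x$curve),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Youden-optimal cutoff from a ROC curve
#'
#' Maximizes Youden's J = sensitivity + specificity - 1 over the swept
#' thresholds; ties are broken towards the higher threshold (higher
#' specificity).
#'
#' @param roc An [roc_curve()] object.
#' @param panel_name Label carried into the report.
#' @return One-row cutoff-report tibble: `panel`, `cutoff_type = "youden"`,
#'   `threshold`, `sens`, `spec`, `youden_j`.
#' @export
youden_optimal <- function(roc, panel_name = NA_character_) {
  stopifnot(inherits(roc, "fh_roc"))
  j <- roc$curve$sens + roc$curve$spec - 1
  best <- which(j >= max(j) - 1e-12)
  pick <- best[which.max(roc$curve$threshold[best])]
  tibble::tibble(panel = panel_name, cutoff_type = "youden",
                 threshold = roc$curve$threshold[pick],
                 sens = roc$curve$sens[pick], spec = roc$curve$spec[pick],
                 youden_j = j[pick])
}

#' Paired comparison of two AUCs (DeLong)
#'
#' Compares the AUCs of two scores measured on the same case and control
#' samples using the DeLong covariance of placement values. Two-sided p from
#' the normal reference.
#'
#' @param case_a,case_b Scores of the case samples under score A and B
#'   (aligned sample-by-sample).
#' @param control_a,control_b Scores of the control samples (aligned).
#' @return One-row tibble: `auc_a`, `auc_b`, `delta`, `z`, `p_value`.
#' @export
compare_auc <- function(case_a, control_a, case_b, control_b) {
  if (length(case_a) != length(case_b) ||
      length(control_a) != length(control_b)) {
    stop("paired comparison requires both scores on the same samples",
         call. = FALSE)
  }
  keep_case <- !is.na(case_a) & !is.na(case_b)
  keep_ctrl <- !is.na(control_a) & !is.na(control_b)
  placements <- function(case, control) {
    psi <- outer(case, control, function(x, y) (x > y) + 0.5 * (x == y))
    list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
  }
  pa <- placements(case_a[keep_case], control_a[keep_ctrl])
  pb <- placements(case_b[keep_case], control_b[keep_ctrl])
  m <- length(pa$v10); n <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- pa$auc - pb$auc
  if (var_delta <= 0) {
    z <- 0
    p <- 1
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  tibble::tibble(auc_a = pa$auc, auc_b = pb$auc, delta = delta, z = z,
                 p_value = p)
}

#' Full panel-by-cutoff classification suite
#'
#' For every panel: derives the 75th/90th/95th percentile thresholds from the
#' control group and the Youden-optimal threshold from the case-vs-control
#' ROC, then reports the count and proportion of samples above each threshold
#' within every group, with the operating characteristics (sensitivity on the
#' case group, specificity on the control group, Youden J).
#'
#' @param scores Long score tibble from [score_panels()] (`sample_id`,
#'   `panel`, `wgs`).
#' @param cohort Cohort tibble (`sample_id`, `group`).
#' @param cutoffs Subset of `c("p75", "p90", "p95", "youden")`.
#' @param case_group,control_group Group labels used to derive thresholds.
#' @param strict Strict "above" (default `TRUE`).
#' @return Cutoff-report tibble: one row per panel x cutoff x group with
#'   `threshold`, `n_above`, `n_total`, `proportion_above`, `sens`, `spec`,
#'   `youden_j`, `auc`.
#' @export
panel_cutoff_suite <- function(scores, cohort,
                               cutoffs = c("p75", "p90", "p95", "youden"),
                               case_group = "FH_Mneg", control_group = "EUR",
                               strict = TRUE) {
  cutoffs <- match.arg(cutoffs, several.ok = TRUE)
  joined <- dplyr::inner_join(scores, cohort[c("sample_id", "group")],
                              by = "sample_id")
  if (!control_group %in% joined$group) {
    stop("control group ", control_group, " not present", call. = FALSE)
  }
  purrr::map_dfr(unique(joined$panel), function(pn) {
    sub <- joined[joined$panel == pn, ]
    ctrl <- sub$wgs[sub$group == control_group & !is.na(sub$wgs)]
    case <- sub$wgs[sub$group == case_group & !is.na(sub$wgs)]
    roc <- if (length(case)) roc_curve(case, ctrl) else NULL
    purrr::map_dfr(cutoffs, function(ct) {
      if (ct == "youden") {
        if (is.null(roc)) return(NULL)
        y <- youden_optimal(roc, pn)
        thr <- y$threshold
      } else {
        thr <- percentile_cutoff(ctrl, as.numeric(sub("p", "", ct)))
      }
      per_group <- purrr::map_dfr(unique(sub$group), function(gr) {
        pa <- proportion_above(sub$wgs[sub$group == gr], thr, strict = strict)
        tibble::tibble(group = gr, n_above = pa$n_above,
                       n_total = pa$n_total, proportion_above = pa$proportion)
      })
      sens <- if (length(case)) {
        proportion_above(case, thr, strict = strict)$proportion
      } else {
        NA_real_
      }
      spec <- 1 - proportion_above(ctrl, thr, strict = strict)$proportion
      dplyr::mutate(per_group, panel = pn, cutoff_type = ct, threshold = thr,
                    sens = sens, spec = spec, youden_j = sens + spec - 1,
                    auc = if (is.null(roc)) NA_real_ else roc$auc,
                    .before = 1)
    })
  })
}
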