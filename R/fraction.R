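#' Monogenic percentage of an FH cohort
#'
#' Percentage of FH patients (control samples excluded) carrying an
#' identified pathogenic variant, within a DLCN stratum:
#' `100 * n(FH_Mpos) / n(FH patients)`.
#'
#' @param cohort Cohort tibble.
#' @param stratum `"all"`, `"definite"` (DLCN > 8), `"probable"` (6-8) or
#'   `"probable+definite"` (DLCN >= 6).
#' @return Percentage in \[0, 100\] (full precision; round at report time).
#' @examples
#' coh <- tibble::tibble(
#'   sample_id = as.character(1:670),
#'   group = rep(c("FH_Mpos", "FH_Mneg"), c(250, 420))
#' )
#' round(monogenic_pct(coh), 1)  # 37.3
#' @export
monogenic_pct <- function(cohort, stratum = c("all", "definite", "probable",
                                              "probable+definite")) {
  stratum <- match.arg(stratum)
  fh <- cohort[cohort$group %in% c("FH_Mneg", "FH_Mpos"), ]
  fh <- filter_stratum(fh, stratum)
  if (!nrow(fh)) stop("stratum `", stratum, "` is empty", call. = FALSE)
  100 * mean(fh$group == "FH_Mpos")
}

filter_stratum <- function(cohort, stratum) {
  if (stratum == "all") return(cohort)
  keep <- switch(stratum,
    "definite" = cohort$dlcn_class == "definite",
    "probable" = cohort$dlcn_class == "probable",
    "probable+definite" = cohort$dlcn_class %in% c("probable", "definite")
  )
  cohort[!is.na(keep) & keep, ]
}

#' Combined monogenic + polygenic genetic assignment
#'
#' The headline estimator: given the monogenic percentage `M` and the
#' polygenic rate `r` (percentage of mutation-negative patients whose score
#' exceeds the cutoff), the percentage of patients with an identified genetic
#' cause is `M + (100 - M) * r / 100`. Both arguments are percentages;
#' precision is kept in full and rounded only when reported.
#'
#' @param M Monogenic percentage in \[0, 100\].
#' @param r Polygenic rate among mutation-negative patients, in \[0, 100\].
#' @return Combined percentage in \[M, 100\].
#' @examples
#' round(combined_assignment(37.3, 46.4), 1)  # 66.4
#' round(combined_assignment(50.7, 51.1), 1)  # 75.9
#' @export
combined_assignment <- function(M, r) {
  if (any(M < 0 | M > 100) || any(r < 0 | r > 100)) {
    stop("M and r must be percentages in [0, 100]", call. = FALSE)
  }
  M + (100 - M) * r / 100
}

#' Fraction-of-genetic-cause table across DLCN strata
#'
#' For each stratum: the monogenic percentage, the polygenic rate among
#' mutation-negative patients with a non-missing score (strictly above
#' `threshold`), the combined percentage, and the underlying counts
#' (`combined_count = n_mpos + n_above` supports exact recomposition across
#' partitioning strata).
#'
#' @param scores Score tibble for one panel (`sample_id`, `wgs`).
#' @param cohort Cohort tibble.
#' @param threshold Score cutoff.
#' @param strata Character vector of strata (see [monogenic_pct()]).
#' @param strict Strict "above" (default `TRUE`).
#' @return Tibble: `stratum`, `n_fh`, `n_mpos`, `n_mneg_scored`, `n_above`,
#'   `monogenic_pct`, `polygenic_rate`, `combined_pct`, `combined_count`.
#' @export
fraction_table <- function(scores, cohort, threshold,
                           strata = c("all", "definite"), strict = TRUE) {
  joined <- dplyr::left_join(cohort, scores[c("sample_id", "wgs")],
                             by = "sample_id")
  purrr::map_dfr(strata, function(st) {
    fh <- filter_stratum(joined[joined$group %in% c("FH_Mneg", "FH_Mpos"), ],
                         st)
    if (!nrow(fh)) stop("stratum `", st, "` is empty", call. = FALSE)
    n_mpos <- sum(fh$group == "FH_Mpos")
    mneg_scores <- fh$wgs[fh$group == "FH_Mneg" & !is.na(fh$wgs)]
    pa <- proportion_above(mneg_scores, threshold, strict = strict)
    M <- 100 * n_mpos / nrow(fh)
    r <- 100 * pa$proportion
    tibble::tibble(
      stratum = st, n_fh = nrow(fh), n_mpos = n_mpos,
      n_mneg_scored = pa$n_total, n_above = pa$n_above,
      monogenic_pct = M, polygenic_rate = r,
      combined_pct = combined_assignment(M, r),
      combined_count = n_mpos + pa$n_above
    )
  })
}

#' Run the full simulated-study pipeline
#'
#' Simulates (or accepts) a study, then runs every stage: weighted scores for
#' all three panels, per-SNP Hardy-Weinberg tests by group, control-vs-case
#' allele-frequency tests, stepwise logistic panel refinement, the
#' panel-by-cutoff classification suite, group score comparisons, and the
#' combined genetic-assignment table. Fixed seed and config give byte-
#' identical reports.
#'
#' @param config [sim_config()] used when `study` is `NULL`.
#' @param weights Weight table.
#' @param seed Integer seed (defaults to `config$seed`).
#' @param study Optional pre-built `fh_study` (skips simulation).
#' @param refine Run the stepwise refinement stage (default `TRUE`); when
#'   disabled the configured wGS8 panel is used as-is.
#' @param strata Strata for the fraction table.
#' @param out_path Optional path: write the JSON + text report via
#'   [write_report()].
#' @return List of class `fh_report` with sections `panels`, `score_summary`,
#'   `pairwise`, `hwe`, `association`, `cutoffs`, `fractions`, `meta`.
#' @export
run_pipeline <- function(config = sim_config(), weights = default_weights(),
                         seed = config$seed, study = NULL, refine = TRUE,
                         strata = c("all", "probable", "definite"),
                         out_path = NULL) {
  if (is.null(study)) {
    study <- simulate_study(config, weights = weights, seed = seed)
  }
  genotypes <- study$genotypes
  cohort <- study$cohort

  scores <- score_panels(genotypes, weights)
  joined <- dplyr::inner_join(scores, cohort[c("sample_id", "group")],
                              by = "sample_id")
  score_summary <- joined |>
    dplyr::filter(!is.na(.data$wgs)) |>
    dplyr::group_by(.data$panel, .data$group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$wgs),
                     sd = stats::sd(.data$wgs), .groups = "drop")
  pairwise <- purrr::map_dfr(unique(scores$panel), function(pn) {
    gc <- group_compare(joined[joined$panel == pn & !is.na(joined$wgs), ])
    dplyr::mutate(gc$pairwise, panel = pn, .before = 1)
  })

  hwe <- hwe_scan(genotypes, cohort)

  case_ids <- cohort$sample_id[cohort$group == "FH_Mneg"]
  ctrl_ids <- cohort$sample_id[cohort$group == "EUR"]
  assoc_input <- genotypes[genotypes$sample_id %in% c(case_ids, ctrl_ids), ]
  labels <- assoc_input$sample_id %in% case_ids
  association <- if (refine && length(ctrl_ids) && length(case_ids)) {
    stepwise_logistic(assoc_input, labels)
  } else {
    NULL
  }

  cutoffs <- panel_cutoff_suite(scores, cohort)

  wgs8 <- scores[scores$panel == "wGS8", ]
  p75 <- cutoffs$threshold[cutoffs$panel == "wGS8" &
                             cutoffs$cutoff_type == "p75"][1]
  fractions <- fraction_table(wgs8, cohort, p75, strata = strata)

  report <- structure(list(
    panels = lapply(fh_panels, as.list),
    score_summary = score_summary,
    pairwise = pairwise,
    hwe = hwe,
    association = association,
    cutoffs = cutoffs,
    fractions = fractions,
    meta = list(seed = study$seed, mode = config$mode,
                config_hash = rlang::hash(config),
                n = dplyr::count(cohort, .data$group),
                missing_policy = "exclude",
                quantile_convention = "type 7 (linear interpolation)",
                above_rule = "strict (score > threshold)")
  ), class = "fh_report")
  if (!is.null(out_path)) write_report(report, out_path)
  report
}

#' @export
print.fh_report <- function(x, ...) {
  cat(format_report_text(x), sep = "\n")
  invisible(x)
}
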