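#' Compute weighted LDL-c gene scores
#'
#' The weighted gene score of a sample is the sum over panel SNPs of the
#' number of effect-allele copies times the per-allele beta,
#' `wGS = sum_i c_i * beta_i` (mmol/L-weighted units). In `diplotype` panels
#' the two additive APOE terms are replaced by a single epsilon-diplotype
#' contribution (see [apoe_diplotype()]).
#'
#' Missing dosages follow `missing_policy`: `"exclude"` (default) leaves the
#' sample's score `NA` and flags it incomplete, so downstream denominators
#' drop it; `"renormalize"` scales the partial score by
#' `panel size / n_snps_used` as a sensitivity analysis.
#'
#' @param genotypes Genotype tibble (`sample_id` + dosage columns).
#' @param weights `fh_weights` table.
#' @param panel Panel name (`"wGS11"`, `"wGS8"`, `"wGS6"`) or an
#'   [score_panel()] object.
#' @param missing_policy `"exclude"` or `"renormalize"`.
#' @param apoe_weights Named diplotype weights; defaults to the table attached
#'   to `weights`, else [default_apoe_diplotype_weights()]. Diplotype panels
#'   only.
#' @return Tibble: `sample_id`, `panel`, `wgs`, `n_snps_used`, `complete`.
#' @examples
#' w <- default_weights()
#' g <- simulate_genotypes_hwe(5, stats::setNames(w$ref_freq, w$rsid), seed = 1)
#' compute_wgs(g, w, "wGS8")
#' @export
compute_wgs <- function(genotypes, weights, panel = "wGS11",
                        missing_policy = c("exclude", "renormalize"),
                        apoe_weights = NULL) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(weights, "fh_weights"))
  panel <- as_panel(panel)
  panel_check_weights(panel, weights)
  absent <- setdiff(panel$members, names(genotypes))
  if (length(absent)) {
    stop("panel SNP(s) absent from the genotype table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  dose <- as.matrix(genotypes[panel$members])
  if (!all(is.na(dose) | dose %in% 0:2)) {
    stop("dosages must be 0, 1, 2 or missing", call. = FALSE)
  }
  beta <- stats::setNames(weights$beta, weights$rsid)[panel$members]
  p_size <- length(panel$members)

  if (panel$apoe_mode == "diplotype") {
    if (is.null(apoe_weights)) {
      apoe_weights <- attr(weights, "apoe_diplotype_weights") %||%
        default_apoe_diplotype_weights()
    }
    dip <- apoe_diplotype(genotypes[["rs429358"]], genotypes[["rs7412"]])
    apoe_term <- unname(apoe_weights[dip])      # NA when indeterminate
    non_apoe <- setdiff(panel$members, APOE_SNPS)
    contrib <- sweep(dose[, non_apoe, drop = FALSE], 2, beta[non_apoe], `*`)
    used <- rowSums(!is.na(dose[, non_apoe, drop = FALSE])) +
      2L * !is.na(apoe_term)
    partial <- rowSums(contrib, na.rm = TRUE) +
      ifelse(is.na(apoe_term), 0, apoe_term)
  } else {
    contrib <- sweep(dose, 2, beta, `*`)
    used <- rowSums(!is.na(dose))
    partial <- rowSums(contrib, na.rm = TRUE)
  }
  complete <- used == p_size
  wgs <- if (missing_policy == "exclude") {
    ifelse(complete, partial, NA_real_)
  } else {
    ifelse(used > 0, partial * p_size / used, NA_real_)
  }
  tibble::tibble(sample_id = genotypes$sample_id, panel = panel$name,
                 wgs = wgs, n_snps_used = as.integer(used),
                 complete = complete)
}

#' APOE epsilon diplotype from the two defining SNPs
#'
#' rs429358-C and rs7412-T define the epsilon4 and epsilon2 haplotypes
#' (epsilon3 carries neither). With dosages counting the C allele at rs429358
#' and the T allele at rs7412, the diplotype is read off the pair of counts
#' under the no-recombinant assumption: the double heterozygote is phased as
#' E2/E4 (the epsilon1 recombinant is rare). Pairs implying a recombinant
#' (counts summing past two) and pairs with a missing site return
#' `"indeterminate"`.
#'
#' @param rs429358_dosage Copies of the rs429358 C allele (0/1/2 or `NA`).
#' @param rs7412_dosage Copies of the rs7412 T allele (0/1/2 or `NA`).
#' @return Character vector over `E2/E2`, `E2/E3`, `E2/E4`, `E3/E3`, `E3/E4`,
#'   `E4/E4`, `indeterminate`.
#' @examples
#' apoe_diplotype(0, 2)  # E2/E2
#' apoe_diplotype(1, 1)  # E2/E4
#' @export
apoe_diplotype <- function(rs429358_dosage, rs7412_dosage) {
  n4 <- rs429358_dosage
  n2 <- rs7412_dosage
  ok <- !is.na(n4) & !is.na(n2)
  if (any(ok & (!(n4 %in% 0:2) | !(n2 %in% 0:2)))) {
    stop("dosages must be 0, 1, 2 or missing", call. = FALSE)
  }
  out <- rep("indeterminate", length(n4))
  valid <- ok & (n4 + n2 <= 2)
  n3 <- 2L - n4 - n2
  key <- paste(n2, n3, n4)                # counts of e2, e3, e4 haplotypes
  map <- c("2 0 0" = "E2/E2", "1 1 0" = "E2/E3", "1 0 1" = "E2/E4",
           "0 2 0" = "E3/E3", "0 1 1" = "E3/E4", "0 0 2" = "E4/E4")
  out[valid] <- map[key[valid]]
  out
}

#' Per-sample score difference between nested panels
#'
#' For panels with `panel_b` nested inside `panel_a` (same APOE mode,
#' additive), the per-sample difference `wGS_a - wGS_b` equals the score of
#' the set-difference SNPs; this is the arithmetic behind dropping
#' non-informative SNPs from a score.
#'
#' @param genotypes Genotype tibble.
#' @param weights `fh_weights` table.
#' @param panel_a,panel_b Panels with `panel_b` a subset of `panel_a`.
#' @return Tibble `sample_id`, `wgs_a`, `wgs_b`, `difference` (`NA` unless the
#'   sample is complete on `panel_a`).
#' @export
score_difference <- function(genotypes, weights, panel_a, panel_b) {
  panel_a <- as_panel(panel_a)
  panel_b <- as_panel(panel_b)
  if (!all(panel_b$members %in% panel_a$members)) {
    stop("panel_b must be nested inside panel_a", call. = FALSE)
  }
  if (panel_a$apoe_mode != panel_b$apoe_mode) {
    stop("panels must share the same APOE mode", call. = FALSE)
  }
  a <- compute_wgs(genotypes, weights, panel_a)
  b <- compute_wgs(genotypes, weights, panel_b)
  tibble::tibble(sample_id = a$sample_id, wgs_a = a$wgs, wgs_b = b$wgs,
                 difference = ifelse(a$complete & b$complete,
                                     a$wgs - b$wgs, NA_real_))
}

#' Analytic score bounds of a panel
#'
#' The additive score lies in `[sum_i min(0, 2 beta_i), sum_i max(0, 2 beta_i)]`
#' over the panel members.
#'
#' @inheritParams score_difference
#' @param panel Panel name or object.
#' @return Numeric `c(lower, upper)`.
#' @export
wgs_bounds <- function(weights, panel) {
  panel <- as_panel(panel)
  panel_check_weights(panel, weights)
  beta <- weights$beta[match(panel$members, weights$rsid)]
  c(lower = sum(pmin(0, 2 * beta)), upper = sum(pmax(0, 2 * beta)))
}

#' Score all panels for a study
#'
#' Convenience wrapper computing every panel in `panels` and stacking the
#' results in long form.
#'
#' @inheritParams compute_wgs
#' @param panels Character vector of panel names or list of panel objects.
#' @return Long tibble of [compute_wgs()] results.
#' @export
score_panels <- function(genotypes, weights, panels = names(fh_panels),
                         missing_policy = "exclude") {
  purrr::map_dfr(panels, function(p) {
    compute_wgs(genotypes, weights, p, missing_policy = missing_policy)
  })
}
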