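#' Hardy-Weinberg equilibrium test
#'
#' Chi-square goodness-of-fit (1 df) of the observed genotype counts against
#' the counts expected from the observed allele frequency; when any expected
#' count falls below 5 the exact conditional test is used instead (summing,
#' over all heterozygote counts compatible with the observed allele counts,
#' the probabilities no larger than that of the observed table).
#'
#' @param counts Genotype counts `c(n0, n1, n2)` of effect-allele dosage
#'   0/1/2.
#' @param rsid,group Optional labels carried into the result.
#' @return One-row tibble: `rsid`, `group`, `n0`, `n1`, `n2`, `chi2`,
#'   `p_value`, `method` (`"chi-square"` or `"exact"`).
#' @examples
#' hwe_test(c(25, 50, 25))
#' @export
hwe_test <- function(counts, rsid = NA_character_, group = NA_character_) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("all genotype counts are zero", call. = FALSE)
  n0 <- counts[1]; n1 <- counts[2]; n2 <- counts[3]
  p <- (2 * n2 + n1) / (2 * n)
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chi2 <- sum((counts - expected)^2 / ifelse(expected > 0, expected, 1) *
                (expected > 0))
  if (any(expected < 5)) {
    method <- "exact"
    p_value <- hwe_exact_p(n1, n_a = 2 * n2 + n1, n = n)
  } else {
    method <- "chi-square"
    p_value <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  tibble::tibble(rsid = rsid, group = group, n0 = n0, n1 = n1, n2 = n2,
                 chi2 = chi2, p_value = p_value, method = method)
}

# Exact HWE p: conditional distribution of the heterozygote count given the
# minor-allele count, P(n1 | n, nA) proportional to
# n! / (n0! n1! n2!) * 2^n1; p = sum of probabilities <= P(observed).
hwe_exact_p <- function(n1_obs, n_a, n) {
  n_b <- 2 * n - n_a
  n_minor <- min(n_a, n_b)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  logp <- vapply(hets, function(h) {
    hom_minor <- (n_minor - h) / 2
    hom_major <- n - h - hom_minor
    lgamma(n + 1) - lgamma(hom_minor + 1) - lgamma(h + 1) -
      lgamma(hom_major + 1) + h * log(2) +
      lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  obs <- probs[hets == n1_obs]
  min(1, sum(probs[probs <= obs * (1 + 1e-12)]))
}

#' Hardy-Weinberg tests for a genotype table
#'
#' Applies [hwe_test()] to every SNP, optionally within cohort groups.
#'
#' @param genotypes Genotype tibble.
#' @param cohort Optional cohort tibble; when given, tests run per group.
#' @return Tibble of per-SNP (x group) results.
#' @export
hwe_scan <- function(genotypes, cohort = NULL) {
  rsids <- setdiff(names(genotypes), "sample_id")
  geno_counts <- function(x) tabulate(factor(x, levels = 0:2), nbins = 3)
  if (is.null(cohort)) {
    return(purrr::map_dfr(rsids, function(rs) {
      hwe_test(geno_counts(genotypes[[rs]]), rsid = rs)
    }))
  }
  joined <- dplyr::inner_join(genotypes, cohort[c("sample_id", "group")],
                              by = "sample_id")
  purrr::map_dfr(unique(joined$group), function(g) {
    sub <- joined[joined$group == g, ]
    purrr::map_dfr(rsids, function(rs) {
      hwe_test(geno_counts(sub[[rs]]), rsid = rs, group = g)
    })
  })
}

#' Two-group allele-frequency test
#'
#' Compares effect-allele counts between two groups on the 2x2 allele-count
#' table: Pearson chi-square without continuity correction by default,
#' switching to Fisher's exact test whenever any expected cell is 5 or below.
#'
#' @param counts_a,counts_b `c(effect_count, other_count)` allele counts, or
#'   dosage vectors (alleles are then counted as `2n` per group).
#' @return One-row tibble: effect-allele frequencies, `statistic` (chi-square,
#'   `NA` under Fisher), `p_value`, `method`.
#' @export
allele_freq_test <- function(counts_a, counts_b) {
  as_allele_counts <- function(x) {
    if (length(x) == 2 && all(x == round(x)) && !anyNA(x)) return(as.numeric(x))
    x <- x[!is.na(x)]
    c(sum(x), 2 * length(x) - sum(x))
  }
  a <- as_allele_counts(counts_a)
  b <- as_allele_counts(counts_b)
  tab <- rbind(a, b)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("allele table has an empty margin", call. = FALSE)
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 5)) {
    ft <- stats::fisher.test(tab)
    out <- tibble::tibble(statistic = NA_real_, p_value = ft$p.value,
                          method = "fisher")
  } else {
    ct <- stats::chisq.test(tab, correct = FALSE)
    out <- tibble::tibble(statistic = unname(ct$statistic),
                          p_value = ct$p.value, method = "chi-square")
  }
  dplyr::bind_cols(
    tibble::tibble(freq_a = a[1] / sum(a), freq_b = b[1] / sum(b)), out
  )
}

#' Stepwise logistic panel refinement
#'
#' Bidirectional stepwise selection of panel SNPs in an additive-dosage
#' logistic model of case status. The default criterion is p-based (a
#' candidate enters when its Wald p-value in the current model is the
#' smallest below `p_enter`; a retained term leaves when its Wald p-value
#' exceeds `p_remove`); `criterion = "aic"` delegates to [stats::step()].
#' Retained SNPs are reported with per-allele odds ratios, Wald 95% CIs and
#' p-values. Complete separation is flagged, not silently ignored.
#'
#' @param genotypes Genotype tibble restricted to the candidate SNPs (plus
#'   `sample_id`).
#' @param labels Logical or 0/1 vector (`TRUE` = case), aligned with
#'   `genotypes` rows.
#' @param criterion `"p"` or `"aic"`.
#' @param p_enter,p_remove Entry/removal thresholds for the p-based mode.
#' @return Tibble of class `fh_assoc`: `rsid`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `model`; attributes `selected` (rsids) and
#'   `separation` (logical).
#' @export
stepwise_logistic <- function(genotypes, labels, criterion = c("p", "aic"),
                              p_enter = 0.05, p_remove = 0.10) {
  criterion <- match.arg(criterion)
  rsids <- setdiff(names(genotypes), "sample_id")
  if (length(rsids) < 2) stop("need at least 2 candidate SNPs", call. = FALSE)
  y <- as.integer(labels)
  if (length(unique(y[!is.na(y)])) < 2) {
    stop("both case and control labels must be present", call. = FALSE)
  }
  dat <- as.data.frame(genotypes[rsids])
  dat$.y <- y
  dat <- dat[stats::complete.cases(dat), ]
  separation <- FALSE
  fit_glm <- function(formula) {
    fit <- withCallingHandlers(
      stats::glm(formula, family = stats::binomial(), data = dat),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) {
          separation <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    # glm can converge quietly under separation; runaway log-odds per allele
    # (|coef| > 15, i.e. OR beyond ~3e6) are a reliable tell.
    slopes <- stats::coef(fit)[-1]
    if (length(slopes) && any(abs(slopes) > 15, na.rm = TRUE)) {
      separation <<- TRUE
    }
    fit
  }
  if (criterion == "aic") {
    base <- fit_glm(.y ~ 1)
    full_scope <- stats::reformulate(rsids, response = ".y")
    fit <- suppressWarnings(stats::step(
      base, scope = list(lower = .y ~ 1, upper = full_scope),
      direction = "both", trace = 0
    ))
    selected <- setdiff(names(stats::coef(fit)), "(Intercept)")
  } else {
    selected <- character()
    repeat {
      changed <- FALSE
      remaining <- setdiff(rsids, selected)
      if (length(remaining)) {
        pvals <- vapply(remaining, function(rs) {
          f <- stats::reformulate(c(selected, rs), response = ".y")
          cf <- summary(fit_glm(f))$coefficients
          cf[rs, "Pr(>|z|)"]
        }, numeric(1))
        if (min(pvals) < p_enter) {
          selected <- c(selected, remaining[which.min(pvals)])
          changed <- TRUE
        }
      }
      if (length(selected) > 1) {
        f <- stats::reformulate(selected, response = ".y")
        cf <- summary(fit_glm(f))$coefficients
        pv <- cf[selected, "Pr(>|z|)"]
        if (max(pv) > p_remove) {
          selected <- setdiff(selected, selected[which.max(pv)])
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    fit <- if (length(selected)) {
      fit_glm(stats::reformulate(selected, response = ".y"))
    } else {
      fit_glm(.y ~ 1)
    }
  }
  out <- if (length(selected)) {
    cf <- summary(fit)$coefficients[selected, , drop = FALSE]
    tibble::tibble(
      rsid = selected,
      odds_ratio = exp(cf[, "Estimate"]),
      ci_low = exp(cf[, "Estimate"] - 1.96 * cf[, "Std. Error"]),
      ci_high = exp(cf[, "Estimate"] + 1.96 * cf[, "Std. Error"]),
      p_value = cf[, "Pr(>|z|)"],
      model = "additive"
    )
  } else {
    tibble::tibble(rsid = character(), odds_ratio = numeric(),
                   ci_low = numeric(), ci_high = numeric(),
                   p_value = numeric(), model = character())
  }
  out <- dplyr::arrange(out, .data$p_value)
  attr(out, "selected") <- out$rsid
  attr(out, "separation") <- separation
  class(out) <- c("fh_assoc", class(out))
  out
}

#' Compare score distributions between groups
#'
#' Two groups: Student's t-test unless either group departs from normality
#' (Shapiro-Wilk at alpha = 0.05), in which case the Wilcoxon-Mann-Whitney
#' test is used. More than two groups: one-way ANOVA or Kruskal-Wallis under
#' the same gate, with pairwise post-hoc tests (unadjusted, mirroring a
#' pairwise comparison matrix of means and p-values).
#'
#' @param data Data frame with one score and one group column.
#' @param score,group Column names (strings).
#' @return Object of class `fh_group_compare`: `summary` (group, n, mean, sd),
#'   `pairwise` (group1, group2, p_value, method), `overall_p` (> 2 groups),
#'   `method`.
#' @export
group_compare <- function(data, score = "wgs", group = "group") {
  x <- data[[score]]
  g <- as.character(data[[group]])
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- g[keep]
  groups <- unique(g)
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2)) stop("every group needs n >= 2", call. = FALSE)
  summary_tab <- tibble::tibble(
    group = groups,
    n = vapply(groups, function(k) sum(g == k), integer(1)),
    mean = vapply(groups, function(k) mean(x[g == k]), numeric(1)),
    sd = vapply(groups, function(k) stats::sd(x[g == k]), numeric(1))
  )
  normal <- all(vapply(groups, function(k) {
    xs <- x[g == k]
    if (stats::sd(xs) == 0) return(FALSE)        # degenerate: rank-based path
    if (length(xs) > 4999) xs <- sample(xs, 4999)
    stats::shapiro.test(xs)$p.value >= 0.05
  }, logical(1)))
  pair_test <- function(a, b) {
    if (length(unique(c(a, b))) == 1) {
      return(list(p = 1, method = "wilcoxon"))   # complete ties
    }
    if (normal) {
      list(p = stats::t.test(a, b)$p.value, method = "t")
    } else {
      list(p = suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))$p.value,
           method = "wilcoxon")
    }
  }
  combos <- utils::combn(groups, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(combos, function(cp) {
    res <- pair_test(x[g == cp[1]], x[g == cp[2]])
    tibble::tibble(group1 = cp[1], group2 = cp[2], p_value = res$p,
                   method = res$method)
  })
  overall_p <- NA_real_
  method <- if (normal) "t" else "wilcoxon"
  if (length(groups) > 2) {
    if (normal) {
      overall_p <- summary(stats::aov(x ~ factor(g)))[[1]][["Pr(>F)"]][1]
      method <- "anova"
    } else {
      overall_p <- stats::kruskal.test(x, factor(g))$p.value
      method <- "kruskal-wallis"
    }
  }
  structure(list(summary = summary_tab, pairwise = pairwise,
                 overall_p = overall_p, method = method),
            class = "fh_group_compare")
}

#' @export
print.fh_group_compare <- function(x, ...) {
  cat("<fh_group_compare> method:", x$method, "\n")
  print(x$summary)
  print(x$pairwise)
  if (!is.na(x$overall_p)) cat("overall p =", format(x$overall_p), "\n")
  invisible(x)
}

#' Cochran-Armitage trend test
#'
#' Tests for a linear trend in a proportion across ordered categories using
#' the standard trend statistic with integer scores `1..K` (any affine
#' re-scoring gives the same statistic). Two-sided p from the normal
#' reference distribution.
#'
#' @param successes Count above threshold per ordered category.
#' @param totals Category totals.
#' @param scores Category scores (default `1..K`).
#' @return One-row tibble: `z`, `chi2`, `p_value`.
#' @export
cochran_armitage <- function(successes, totals, scores = seq_along(successes)) {
  stopifnot(length(successes) == length(totals),
            length(scores) == length(totals), all(successes <= totals))
  if (length(totals) < 2) {
    stop("need at least 2 ordered categories", call. = FALSE)
  }
  n <- sum(totals)
  pbar <- sum(successes) / n
  if (pbar <= 0 || pbar >= 1) {
    stop("overall proportion is degenerate (0 or 1)", call. = FALSE)
  }
  sbar <- sum(totals * scores) / n
  num <- sum(successes * scores) - pbar * sum(totals * scores)
  den <- sqrt(pbar * (1 - pbar) * (sum(totals * scores^2) - n * sbar^2))
  z <- num / den
  tibble::tibble(z = z, chi2 = z^2,
                 p_value = 2 * stats::pnorm(-abs(z)))
}

#' Age- and sex-adjusted association of a score with a clinical component
#'
#' Logistic regression `component ~ score + age + sex`, reporting the score
#' coefficient as an odds ratio per score unit with Wald CI and p-value.
#' Complete separation is flagged.
#'
#' @param data Data frame containing the columns below (rows with missing
#'   covariates are dropped).
#' @param component Binary outcome column name (DLCN component flag).
#' @param score,age,sex Covariate column names.
#' @return One-row tibble: `term`, `estimate` (log-OR), `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`, `n`, `separation`.
#' @export
adjusted_component_assoc <- function(data, component, score = "wgs",
                                     age = "age", sex = "sex") {
  dat <- data.frame(y = as.integer(data[[component]]),
                    score = data[[score]], age = data[[age]],
                    sex = factor(data[[sex]]))
  dat <- dat[stats::complete.cases(dat), ]
  if (length(unique(dat$y)) < 2) {
    stop("component must take both values", call. = FALSE)
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ score + age + sex, family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- summary(fit)$coefficients["score", ]
  tibble::tibble(term = component, estimate = unname(cf["Estimate"]),
                 odds_ratio = exp(unname(cf["Estimate"])),
                 ci_low = exp(unname(cf["Estimate"] - 1.96 * cf["Std. Error"])),
                 ci_high = exp(unname(cf["Estimate"] + 1.96 * cf["Std. Error"])),
                 p_value = unname(cf["Pr(>|z|)"]), n = nrow(dat),
                 separation = separation)
}
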