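test_that("percentile cutoffs follow the declared convention", {
  thr <- percentile_cutoff(1:100, 75)
  expect_gte(thr, 75)
  expect_lte(thr, 76)
  expect_equal(thr, unname(stats::quantile(1:100, 0.75, type = 7)))
  # monotone in q
  x <- stats::rnorm(200)
  expect_true(percentile_cutoff(x, 75) <= percentile_cutoff(x, 90))
  expect_true(percentile_cutoff(x, 90) <= percentile_cutoff(x, 95))
  # degenerate scores: threshold is the common value, strict proportion 0
  same <- rep(2.5, 30)
  expect_equal(percentile_cutoff(same, 75), 2.5)
  expect_equal(proportion_above(same, 2.5)$proportion, 0)
  expect_error(percentile_cutoff(1:10, 75), "at least 20")
})

test_that("control p75 estimates track the Gaussian quantile at study size", {
  # control distribution with mean 0.732, SD 0.21: p75 = mu + 0.6745 sigma
  thr <- vapply(1:30, function(s) {
    withr::with_seed(s, percentile_cutoff(stats::rnorm(503, 0.732, 0.21), 75))
  }, numeric(1))
  expect_lt(abs(mean(thr) - (0.732 + stats::qnorm(0.75) * 0.21)), 0.02)
})

test_that("proportion_above counts match a brute-force loop and printed-count arithmetic", {
  withr::with_seed(50, {
    x <- stats::rnorm(400)
    x[sample(400, 20)] <- NA
    thr <- 0.3
    got <- proportion_above(x, thr)
    count <- 0L; total <- 0L
    for (v in x) {
      if (!is.na(v)) {
        total <- total + 1L
        if (v > thr) count <- count + 1L
      }
    }
    expect_equal(got$n_above, count)
    expect_equal(got$n_total, total)
    expect_equal(got$proportion, count / total)
  })
  # 187 above among 403 -> 46.4%
  scores <- c(rep(1, 403 - 187), rep(2, 187))
  expect_equal(round(100 * proportion_above(scores, 1.5)$proportion, 1), 46.4)
  expect_equal(proportion_above(c(1, 2, 3), 0)$proportion, 1)
  # strict vs non-strict at a tied threshold
  expect_equal(proportion_above(c(1, 1, 2), 1, strict = FALSE)$n_above, 3)
  expect_equal(proportion_above(c(1, 1, 2), 1, strict = TRUE)$n_above, 1)
})

test_that("ROC endpoints behave: separation, exchangeability, swapping", {
  sep <- roc_curve(c(3, 4, 5), c(0, 1, 2))
  expect_equal(sep$auc, 1)
  expect_equal(youden_optimal(sep)$youden_j, 1)

  withr::with_seed(51, {
    x <- stats::rnorm(400)
    same <- roc_curve(x[1:200], x[201:400])
    expect_lt(abs(same$auc - 0.5), 0.1)
    # swapping case and control maps AUC to 1 - AUC
    a <- roc_curve(x[1:200] + 0.3, x[201:400])
    b <- roc_curve(x[201:400], x[1:200] + 0.3)
    expect_equal(a$auc, 1 - b$auc, tolerance = 1e-12)
  })

  const <- roc_curve(rep(1, 5), rep(1, 7))
  expect_true(const$degenerate)
  expect_equal(const$auc, 0.5)
})

test_that("trapezoid AUC equals the Mann-Whitney identity and pROC agrees", {
  withr::with_seed(52, {
    for (i in 1:20) {
      case <- round(stats::rnorm(40, 0.3), 1)     # coarse: many ties
      ctrl <- round(stats::rnorm(60), 1)
      roc <- roc_curve(case, ctrl)                # internal 1e-10 cross-check
      ref <- suppressMessages(pROC::auc(
        pROC::roc(response = rep(c(1, 0), c(40, 60)),
                  predictor = c(case, ctrl), quiet = TRUE,
                  direction = "<", levels = c(0, 1))
      ))
      expect_equal(roc$auc, as.numeric(ref), tolerance = 1e-10)
    }
  })
})

test_that("ROC sens and 1-spec are monotone along the threshold sweep", {
  withr::with_seed(53, {
    roc <- roc_curve(stats::rnorm(80, 0.4), stats::rnorm(120))
    ord <- order(roc$curve$threshold)
    expect_true(all(diff(roc$curve$sens[ord]) <= 1e-12))
    expect_true(all(diff(1 - roc$curve$spec[ord]) <= 1e-12))
  })
})

test_that("simulated scores at the study's moments hit the binormal AUC", {
  withr::with_seed(54, {
    closed_form <- stats::pnorm((0.836 - 0.732) / sqrt(0.18^2 + 0.21^2))
    aucs <- vapply(1:10, function(i) {
      roc_curve(stats::rnorm(403, 0.836, 0.18),
                stats::rnorm(503, 0.732, 0.21))$auc
    }, numeric(1))
    expect_lt(abs(mean(aucs) - closed_form), 0.03)
  })
})

test_that("the Youden threshold equals an exhaustive scan", {
  withr::with_seed(55, {
    for (i in 1:10) {
      case <- round(stats::rnorm(30, 0.5), 1)
      ctrl <- round(stats::rnorm(40), 1)
      roc <- roc_curve(case, ctrl)
      y <- youden_optimal(roc)
      # brute force over every candidate threshold in the sweep
      j_scan <- vapply(roc$curve$threshold, function(t) {
        mean(case > t) + mean(ctrl <= t) - 1
      }, numeric(1))
      expect_equal(y$youden_j, max(j_scan), tolerance = 1e-12)
      best <- roc$curve$threshold[j_scan >= max(j_scan) - 1e-12]
      expect_equal(y$threshold, max(best))   # tie-break to higher threshold
      expect_equal(y$youden_j, y$sens + y$spec - 1)
    }
  })
  ident <- roc_curve(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_lt(abs(youden_optimal(ident)$youden_j), 1e-12)
})

test_that("DeLong AUC comparison matches pROC and is sane at the extremes", {
  withr::with_seed(56, {
    n1 <- 80; n0 <- 120
    base_case <- stats::rnorm(n1, 0.5)
    base_ctrl <- stats::rnorm(n0)
    noisy_case <- base_case + stats::rnorm(n1, 0, 0.8)
    noisy_ctrl <- base_ctrl + stats::rnorm(n0, 0, 0.8)
    got <- compare_auc(base_case, base_ctrl, noisy_case, noisy_ctrl)
    ref <- pROC::roc.test(
      pROC::roc(rep(c(1, 0), c(n1, n0)), c(base_case, base_ctrl), quiet = TRUE),
      pROC::roc(rep(c(1, 0), c(n1, n0)), c(noisy_case, noisy_ctrl), quiet = TRUE),
      method = "delong", paired = TRUE
    )
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-8)
    expect_equal(got$auc_a - got$auc_b,
                 as.numeric(ref$estimate[1] - ref$estimate[2]),
                 tolerance = 1e-10)
  })
  # identical scores -> p = 1
  same <- compare_auc(c(1, 2, 3), c(0, 1), c(1, 2, 3), c(0, 1))
  expect_equal(same$p_value, 1)
  expect_error(compare_auc(1:3, 1:4, 1:2, 1:4), "same samples")
})

test_that("a dominating score is declared better at moderate size", {
  hits <- vapply(1:10, function(s) {
    withr::with_seed(400 + s, {
      n1 <- 400; n0 <- 500
      signal <- c(stats::rnorm(n1, 1), stats::rnorm(n0))
      strong <- signal
      weak <- 0.35 * signal + stats::rnorm(n1 + n0, 0, 1)
      compare_auc(strong[1:n1], strong[-(1:n1)],
                  weak[1:n1], weak[-(1:n1)])$p_value < 0.05
    })
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("the cutoff suite is internally consistent across panels and groups", {
  study <- simulate_study(sim_config(n_eur = 300, n_mneg = 250, n_mpos = 150),
                          seed = 57)
  scores <- score_panels(study$genotypes, default_weights())
  suite <- panel_cutoff_suite(scores, study$cohort)
  expect_setequal(unique(suite$panel), c("wGS11", "wGS8", "wGS6"))
  expect_setequal(unique(suite$cutoff_type), c("p75", "p90", "p95", "youden"))
  for (pn in unique(suite$panel)) {
    sub <- suite[suite$panel == pn, ]
    thr <- function(ct) sub$threshold[sub$cutoff_type == ct][1]
    expect_true(thr("p75") <= thr("p90"))
    expect_true(thr("p90") <= thr("p95"))
    for (gr in unique(sub$group)) {
      props <- vapply(c("p75", "p90", "p95"), function(ct) {
        sub$proportion_above[sub$cutoff_type == ct & sub$group == gr]
      }, numeric(1))
      expect_true(all(diff(props) <= 1e-12))
    }
    # strict proportion above the control's own p75 is at most 25%
    ctrl75 <- sub[sub$cutoff_type == "p75" & sub$group == "EUR", ]
    expect_lte(ctrl75$proportion_above, 0.25 + 1e-12)
    expect_true(all(sub$youden_j >= -1 & sub$youden_j <= 1))
  }
})

test_that("roc tidiers expose the curve and the headline numbers", {
  roc <- roc_curve(c(2, 3, 4), c(1, 2))
  td <- tidy(roc)
  expect_true(all(c("threshold", "sens", "spec", "j") %in% names(td)))
  gl <- glance(roc)
  expect_equal(gl$n_case, 3)
  expect_equal(gl$auc, roc$auc)
})
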