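test_that("HWE chi-square matches the textbook formula", {
  perfect <- hwe_test(c(25, 50, 25))
  expect_equal(perfect$chi2, 0)
  expect_equal(perfect$p_value, 1)
  expect_equal(perfect$method, "chi-square")

  # no heterozygotes at p = 0.5, n = 100: expected (25, 50, 25)
  extreme <- hwe_test(c(50, 0, 50))
  expect_equal(extreme$chi2, 100)

  # random tables against (obs - exp)^2 / exp computed by hand
  withr::with_seed(8, {
    for (i in 1:20) {
      counts <- as.vector(stats::rmultinom(1, 400, c(0.3, 0.5, 0.2)))
      res <- hwe_test(counts)
      n <- sum(counts)
      p <- (2 * counts[3] + counts[2]) / (2 * n)
      expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
      expect_equal(res$chi2, sum((counts - expected)^2 / expected))
    }
  })
  expect_error(hwe_test(c(0, 0, 0)), "zero")
})

test_that("the exact HWE path equals full enumeration for small tables", {
  small_tables <- list(c(4, 1, 0), c(2, 2, 1), c(7, 1, 2), c(3, 3, 3),
                       c(10, 0, 1), c(0, 1, 6))
  for (tab in small_tables) {
    res <- hwe_test(tab)
    expect_equal(res$method, "exact")
    expect_equal(res$p_value, hwe_enumeration_p(tab[1], tab[2], tab[3]),
                 tolerance = 1e-10, info = paste(tab, collapse = ","))
    expect_gte(res$p_value, 0)
    expect_lte(res$p_value, 1)
  }
})

test_that("allele tests pick chi-square or Fisher appropriately", {
  big <- allele_freq_test(c(300, 700), c(300, 700))
  expect_equal(big$method, "chi-square")
  expect_equal(big$statistic, 0, tolerance = 1e-12)
  expect_equal(big$p_value, 1)

  # sparse table takes the Fisher path; p equals hypergeometric enumeration
  sparse <- allele_freq_test(c(10, 0), c(0, 10))
  expect_equal(sparse$method, "fisher")
  enum_p <- sum(vapply(0:10, function(k) {
    pr <- choose(10, k) * choose(10, 10 - k) / choose(20, 10)
    obs <- choose(10, 10) * choose(10, 0) / choose(20, 10)
    if (pr <= obs + 1e-12) pr else 0
  }, numeric(1)))
  expect_equal(sparse$p_value, enum_p, tolerance = 1e-10)

  expect_error(allele_freq_test(c(0, 0), c(1, 1)), "margin")
})

test_that("the SNP with the largest configured shift is detected at study size", {
  freqs <- default_group_freqs()
  hits <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      eur <- stats::rbinom(503, 2, freqs$eur[freqs$rsid == "rs4299376"])
      cas <- stats::rbinom(420, 2, freqs$fh_mneg[freqs$rsid == "rs4299376"])
      allele_freq_test(eur, cas)$p_value < 0.05
    })
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("stepwise logistic recovers a causal SNP and rejects null data", {
  # one causal SNP among ten, OR 1.5 per allele, n = 2000
  withr::with_seed(31, {
    n <- 2000
    g <- tibble::tibble(sample_id = as.character(1:n))
    for (i in 1:10) g[[paste0("rs", i)]] <- stats::rbinom(n, 2, 0.3)
    eta <- log(1.5) * g$rs1
    y <- stats::rbinom(n, 1, stats::plogis(eta - mean(eta)))
    res <- stepwise_logistic(g, y)
    expect_true("rs1" %in% res$rsid)
    expect_gt(res$odds_ratio[res$rsid == "rs1"], 1)
    expect_true(all(res$ci_low <= res$odds_ratio &
                      res$odds_ratio <= res$ci_high))
  })
  # balanced null data with zero coefficients -> empty selection
  g0 <- tibble::tibble(sample_id = as.character(1:8),
                       rs1 = rep(0:1, 4), rs2 = rep(c(0, 0, 1, 1), 2))
  y0 <- rep(0:1, each = 4)
  res0 <- stepwise_logistic(g0, y0)
  expect_equal(nrow(res0), 0)
  expect_error(stepwise_logistic(g0["sample_id"], y0), "2 candidate")
  expect_error(stepwise_logistic(g0, rep(1, 8)), "both case and control")
})

test_that("AIC-mode stepwise also recovers the causal SNP", {
  withr::with_seed(32, {
    n <- 1500
    g <- tibble::tibble(sample_id = as.character(1:n))
    for (i in 1:6) g[[paste0("rs", i)]] <- stats::rbinom(n, 2, 0.3)
    y <- stats::rbinom(n, 1, stats::plogis(log(1.6) * (g$rs2 - 0.6)))
    res <- stepwise_logistic(g, y, criterion = "aic")
    expect_true("rs2" %in% res$rsid)
  })
})

test_that("separation is flagged, not silently swallowed", {
  g <- tibble::tibble(sample_id = as.character(1:40),
                      rs1 = rep(c(0L, 2L), each = 20),
                      rs2 = stats::rbinom(40, 2, 0.5))
  y <- rep(0:1, each = 20)
  res <- suppressWarnings(stepwise_logistic(g, y))
  expect_true(attr(res, "separation"))
})

test_that("logistic score equations hold at convergence and a single binary predictor matches the cross-product OR", {
  withr::with_seed(33, {
    n <- 600
    x <- stats::rbinom(n, 1, 0.4)
    y <- stats::rbinom(n, 1, stats::plogis(-0.5 + 0.8 * x))
    fit <- stats::glm(y ~ x, family = stats::binomial())
    mu <- stats::fitted(fit)
    grad <- crossprod(cbind(1, x), y - mu)
    expect_lt(max(abs(grad)), 1e-6)
    tab <- table(x, y)
    or_table <- (tab["1", "1"] * tab["0", "0"]) /
      (tab["1", "0"] * tab["0", "1"])
    expect_equal(exp(stats::coef(fit)[["x"]]), or_table, tolerance = 1e-8)
  })
})

test_that("group comparisons gate on normality and handle ties", {
  # identical tied samples -> Wilcoxon path, p = 1
  d <- tibble::tibble(wgs = rep(1, 20), group = rep(c("a", "b"), 10))
  gc <- group_compare(d)
  expect_equal(gc$pairwise$method, "wilcoxon")
  expect_equal(gc$pairwise$p_value, 1)

  # two Gaussians at the study's moments -> decisive t-test
  withr::with_seed(1, {
    d2 <- tibble::tibble(
      wgs = c(stats::rnorm(403, 0.836, 0.18), stats::rnorm(503, 0.732, 0.21)),
      group = rep(c("case", "control"), c(403, 503))
    )
    gc2 <- group_compare(d2)
    expect_equal(gc2$pairwise$method, "t")
    expect_lt(gc2$pairwise$p_value, 1e-8)
  })

  # skewed data routes to the rank-based test
  withr::with_seed(35, {
    d3 <- tibble::tibble(wgs = c(stats::rexp(80), stats::rexp(80) + 0.1),
                         group = rep(c("a", "b"), each = 80))
    expect_equal(group_compare(d3)$pairwise$method, "wilcoxon")
  })
  expect_error(group_compare(d[d$group == "a", ]), "2 groups")
})

test_that("three-group comparisons report an overall test and pairwise matrix", {
  withr::with_seed(36, {
    d <- tibble::tibble(
      wgs = stats::rnorm(300),
      group = rep(c("EUR", "FH_Mneg", "FH_Mpos"), each = 100)
    )
    gc <- group_compare(d)
    expect_true(gc$method %in% c("anova", "kruskal-wallis"))
    expect_gt(gc$overall_p, 0.001)   # null data
    expect_equal(nrow(gc$pairwise), 3)
    expect_equal(nrow(tidy(gc)), 3)
    expect_equal(glance(gc)$n_groups, 3)
  })
})

test_that("the trend test matches its permutation null and collapses to chi-square at K = 2", {
  flat <- cochran_armitage(c(10, 10, 10), c(50, 50, 50))
  expect_lt(abs(flat$z), 1e-12)

  # increasing proportions: z against a permutation reference
  succ <- round(c(0.1, 0.3, 0.5, 0.7, 0.9) * 50)
  tot <- rep(50, 5)
  res <- cochran_armitage(succ, tot)
  expect_gt(res$z, 0)
  expect_lt(res$p_value, 1e-10)
  perm_p <- withr::with_seed(37, {
    y <- rep(rep(1:0, 5), times = as.vector(rbind(succ, tot - succ)))
    sc <- rep(1:5, tot)
    obs <- sum(sc * y)
    perms <- vapply(1:2000, function(i) sum(sc[sample.int(length(sc))] * y),
                    numeric(1))
    mean(abs(perms - mean(perms)) >= abs(obs - mean(perms)) - 1e-9)
  })
  # both declare an overwhelming trend
  expect_lt(perm_p, 0.01)

  # K = 2 equals the uncorrected 2x2 chi-square
  res2 <- cochran_armitage(c(12, 30), c(40, 60))
  tab <- rbind(c(12, 28), c(30, 30))
  expect_equal(res2$chi2,
               unname(stats::chisq.test(tab, correct = FALSE)$statistic),
               tolerance = 1e-10)

  # affine re-scoring leaves the statistic unchanged
  res3 <- cochran_armitage(succ, tot, scores = 10 + 3 * (1:5))
  expect_equal(res3$z, res$z, tolerance = 1e-12)

  # agreement with the standard trend test
  ptt <- suppressWarnings(stats::prop.trend.test(succ, tot))
  expect_equal(res$chi2, unname(ptt$statistic), tolerance = 1e-10)

  expect_error(cochran_armitage(5, 10), "2 ordered categories")
})

test_that("adjusted component associations recover signs and nulls", {
  withr::with_seed(38, {
    n <- 600
    d <- tibble::tibble(
      wgs = stats::rnorm(n, 0.8, 0.2),
      age = stats::rnorm(n, 45, 12),
      sex = sample(c("M", "F"), n, replace = TRUE)
    )
    # component independent of score
    d$flag <- stats::rbinom(n, 1, 0.4)
    null_fit <- adjusted_component_assoc(d, "flag")
    expect_gt(null_fit$p_value, 0.001)
    # strong negative dependence (logit slope -2 per score unit)
    signs <- vapply(1:10, function(s) {
      withr::with_seed(100 + s, {
        d$flag <- stats::rbinom(n, 1, stats::plogis(1.2 - 2 * d$wgs))
        adjusted_component_assoc(d, "flag")$estimate < 0
      })
    }, logical(1))
    expect_gte(mean(signs), 0.95)
    # age/sex confounding only: score coefficient stays near zero
    d$flag <- stats::rbinom(n, 1, stats::plogis(-2 + 0.04 * d$age))
    conf_fit <- adjusted_component_assoc(d, "flag")
    expect_gt(conf_fit$p_value, 0.001)
  })
})

test_that("hwe_scan covers every SNP within every group", {
  study <- simulate_study(sim_config(n_eur = 150, n_mneg = 100, n_mpos = 60),
                          seed = 40)
  res <- hwe_scan(study$genotypes, study$cohort)
  expect_equal(nrow(res), 3 * 11)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_true(all(res$n0 + res$n1 + res$n2 > 0))
})
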