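#' Default group-specific effect-allele frequencies for simulation
#'
#' Reads the synthetic frequency table shipped with the package: approximate
#' European control frequencies plus enriched mutation-negative and mildly
#' enriched mutation-positive case frequencies for the panel SNPs. These are
#' simulation defaults, not estimates from any cohort.
#'
#' @return Tibble with columns `rsid`, `eur`, `fh_mneg`, `fh_mpos`.
#' @export
default_group_freqs <- function() {
  readr::read_tsv(system.file("extdata", "group_freqs_synthetic.tsv",
                              package = "polyfh"),
                  comment = "#", show_col_types = FALSE)
}

#' Simulation configuration
#'
#' Bundles everything the cohort generator needs. Defaults emulate the study
#' design the pipeline targets: 503 European controls, 420 mutation-negative
#' and 250 mutation-positive FH patients; Hardy-Weinberg genotypes in every
#' group; a 231:19 LDLR:APOB split among carriers; DLCN component margins and
#' categorized-LDL band probabilities typical of an FH referral cohort.
#'
#' @param n_eur,n_mneg,n_mpos Group sizes.
#' @param freqs Tibble `rsid`/`eur`/`fh_mneg`/`fh_mpos` of effect-allele
#'   frequencies (default [default_group_freqs()]).
#' @param mode `"frequency-shift"` draws case genotypes in HWE at the
#'   group-specific frequencies; `"liability-threshold"` draws candidates at
#'   control frequencies, forms a latent LDL-c liability (weighted score plus
#'   Gaussian residual) and keeps the top tail, producing risk-allele
#'   enrichment endogenously.
#' @param residual_sd Residual SD of the latent liability (mmol/L), liability
#'   mode only.
#' @param selection_quantile Upper tail kept in liability mode (e.g. 0.05
#'   keeps the top 5% of candidates).
#' @param monogenic_split Named counts or proportions for `LDLR` and `APOB`
#'   among mutation-positive patients.
#' @param dlcn_margins Tibble `component`/`fh_mneg`/`fh_mpos` of per-component
#'   presence probabilities for the eight DLCN items.
#' @param ldl_band_probs List with `fh_mneg` and `fh_mpos` probability vectors
#'   over the five categorized LDL-c bands (1 = lowest).
#' @param seed Integer seed stored with the config; [simulate_study()] uses it
#'   when no explicit seed is passed.
#' @return List of class `fh_sim_config`.
#' @export
sim_config <- function(n_eur = 503, n_mneg = 420, n_mpos = 250,
                       freqs = default_group_freqs(),
                       mode = c("frequency-shift", "liability-threshold"),
                       residual_sd = 0.9,
                       selection_quantile = 0.05,
                       monogenic_split = c(LDLR = 231, APOB = 19),
                       dlcn_margins = default_dlcn_margins(),
                       ldl_band_probs = default_ldl_band_probs(),
                       seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_eur >= 0, n_mneg >= 0, n_mpos >= 0)
  fcols <- c("eur", "fh_mneg", "fh_mpos")
  stopifnot(all(c("rsid", fcols) %in% names(freqs)))
  fv <- unlist(freqs[fcols])
  if (any(fv <= 0 | fv >= 1)) {
    stop("all effect-allele frequencies must lie strictly in (0, 1)",
         call. = FALSE)
  }
  if (residual_sd <= 0) stop("residual_sd must be positive", call. = FALSE)
  if (selection_quantile <= 0 || selection_quantile >= 1) {
    stop("selection_quantile must lie in (0, 1)", call. = FALSE)
  }
  if (!all(c("LDLR", "APOB") %in% names(monogenic_split)) ||
      any(monogenic_split < 0) || sum(monogenic_split) <= 0) {
    stop("monogenic_split needs non-negative LDLR and APOB weights",
         call. = FALSE)
  }
  monogenic_split <- monogenic_split / sum(monogenic_split)
  structure(list(
    n_eur = as.integer(n_eur), n_mneg = as.integer(n_mneg),
    n_mpos = as.integer(n_mpos), freqs = tibble::as_tibble(freqs),
    mode = mode, residual_sd = residual_sd,
    selection_quantile = selection_quantile,
    monogenic_split = monogenic_split, dlcn_margins = dlcn_margins,
    ldl_band_probs = ldl_band_probs, seed = as.integer(seed)
  ), class = "fh_sim_config")
}

# DLCN component presence probabilities by patient group (FH referral cohort
# scale: family history common, personal premature CVD ~5-10%, xanthomata
# uncommon; mutation carriers skew towards childhood high LDL-c).
default_dlcn_margins <- function() {
  tibble::tibble(
    component = DLCN_FLAGS,
    fh_mneg = c(0.435, 0.603, 0.051, 0.208, 0.096, 0.049, 0.137, 0.184),
    fh_mpos = c(0.396, 0.685, 0.094, 0.373, 0.089, 0.044, 0.182, 0.200)
  )
}

# Categorized LDL-c band probabilities, bands 1 (<155 mg/dL) to 5 (>330).
default_ldl_band_probs <- function() {
  list(fh_mneg = c(0.148, 0.038, 0.405, 0.371, 0.038),
       fh_mpos = c(0.112, 0.020, 0.216, 0.440, 0.212))
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Draws each SNP's effect-allele dosage independently as Binomial(2, p), the
#' random-mating genotype distribution, so the control generator satisfies
#' the Hardy-Weinberg condition the analysis later tests.
#'
#' @param n Number of samples (>= 1).
#' @param freqs Named numeric vector of effect-allele frequencies, strictly
#'   inside (0, 1); names are rsids.
#' @param seed Optional integer seed (local to this call).
#' @param sample_prefix Prefix for generated sample ids.
#' @return Genotype tibble.
#' @export
simulate_genotypes_hwe <- function(n, freqs, seed = NULL,
                                   sample_prefix = "S") {
  stopifnot(n >= 1)
  if (is.null(names(freqs)) || any(!nzchar(names(freqs)))) {
    stop("`freqs` must be named by rsid", call. = FALSE)
  }
  if (any(freqs <= 0 | freqs >= 1)) {
    stop("frequencies must lie strictly in (0, 1)", call. = FALSE)
  }
  draw <- function() {
    out <- tibble::tibble(
      sample_id = sprintf("%s%05d", sample_prefix, seq_len(n))
    )
    for (rs in names(freqs)) {
      out[[rs]] <- stats::rbinom(n, 2L, freqs[[rs]])
    }
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate an FH case group
#'
#' Generates genotypes and cohort metadata for a mutation-negative or
#' mutation-positive patient group. In `frequency-shift` mode genotypes are
#' drawn in HWE at the group-specific frequencies. In `liability-threshold`
#' mode candidates are drawn at control frequencies, a latent LDL-c liability
#' (weighted score over all weight-table SNPs plus a Gaussian residual) is
#' computed, and the top `selection_quantile` tail is kept, so risk-allele
#' enrichment emerges from selection rather than being hard-coded.
#' Mutation-positive samples receive a mutation gene per the configured
#' LDLR:APOB split (largest-remainder allocation, then shuffled); DLCN
#' components are drawn independently from the group margins, the categorized
#' LDL-c band from the group band probabilities, and the DLCN total score,
#' age and sex from group-typical distributions.
#'
#' @param n Group size.
#' @param config An [sim_config()] object.
#' @param group `"FH_Mneg"` or `"FH_Mpos"`.
#' @param weights Weight table; required in liability mode (the betas define
#'   the liability).
#' @param seed Optional integer seed (local to this call).
#' @return List with `genotypes` and `cohort` tibbles.
#' @export
simulate_case_group <- function(n, config, group = c("FH_Mneg", "FH_Mpos"),
                                weights = NULL, seed = NULL) {
  group <- match.arg(group)
  stopifnot(inherits(config, "fh_sim_config"))
  run <- function() simulate_case_group_impl(n, config, group, weights)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

simulate_case_group_impl <- function(n, config, group, weights) {
  prefix <- if (group == "FH_Mneg") "MNEG" else "MPOS"
  gcol <- if (group == "FH_Mneg") "fh_mneg" else "fh_mpos"
  if (n == 0L) {
    geno <- tibble::tibble(sample_id = character())
    for (rs in config$freqs$rsid) geno[[rs]] <- integer()
    return(list(genotypes = geno, cohort = empty_cohort()))
  }
  if (config$mode == "frequency-shift") {
    freqs <- stats::setNames(config$freqs[[gcol]], config$freqs$rsid)
    geno <- simulate_genotypes_hwe(n, freqs, sample_prefix = prefix)
  } else {
    if (is.null(weights)) {
      stop("liability-threshold mode requires `weights` (betas define the ",
           "liability)", call. = FALSE)
    }
    q <- config$selection_quantile
    m <- ceiling(n / q)
    freqs <- stats::setNames(config$freqs$eur, config$freqs$rsid)
    pool <- simulate_genotypes_hwe(m, freqs, sample_prefix = prefix)
    common <- intersect(names(pool), weights$rsid)
    beta <- stats::setNames(weights$beta, weights$rsid)[common]
    burden <- as.matrix(pool[common]) %*% beta
    latent <- as.numeric(burden) + stats::rnorm(m, 0, config$residual_sd)
    keep <- order(latent, decreasing = TRUE)[seq_len(n)]
    geno <- pool[sort(keep), ]
    geno$sample_id <- sprintf("%s%05d", prefix, seq_len(n))
  }
  margins <- stats::setNames(config$dlcn_margins[[gcol]],
                             config$dlcn_margins$component)
  cohort <- tibble::tibble(sample_id = geno$sample_id, group = group)
  cohort$mutation_gene <- if (group == "FH_Mpos") {
    allocate_genes(n, config$monogenic_split)
  } else {
    "none"
  }
  for (comp in DLCN_FLAGS) {
    cohort[[comp]] <- stats::rbinom(n, 1L, margins[[comp]])
  }
  cohort$ldl_category <- sample(1:5, n, replace = TRUE,
                                prob = config$ldl_band_probs[[gcol]])
  mu <- if (group == "FH_Mneg") c(7.09, 2.6) else c(9.09, 4.1)
  cohort$dlcn_score <- pmin(pmax(round(stats::rnorm(n, mu[1], mu[2])), 0), 25)
  cohort$dlcn_class <- dlcn_class(cohort$dlcn_score)
  am <- if (group == "FH_Mneg") c(46.4, 12.4) else c(42.3, 13.7)
  cohort$age <- round(pmin(pmax(stats::rnorm(n, am[1], am[2]), 18), 95), 1)
  p_female <- if (group == "FH_Mneg") 0.536 else 0.548
  cohort$sex <- ifelse(stats::runif(n) < p_female, "F", "M")
  list(genotypes = geno, cohort = cohort)
}

# Largest-remainder integer allocation of mutation genes, then a random
# shuffle so gene labels are not ordered by sample id.
allocate_genes <- function(n, split) {
  counts <- floor(n * split)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(n * split - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  sample(rep(names(split), times = counts))
}

empty_cohort <- function() {
  out <- tibble::tibble(sample_id = character(), group = character(),
                        mutation_gene = character())
  for (comp in DLCN_FLAGS) out[[comp]] <- integer()
  out$ldl_category <- integer()
  out$dlcn_score <- numeric()
  out$dlcn_class <- character()
  out$age <- numeric()
  out$sex <- character()
  out
}

#' Simulate the full three-group study
#'
#' Composes a European control group (HWE genotypes at control frequencies,
#' no clinical fields), a mutation-negative and a mutation-positive FH group,
#' and optionally writes them in the package's TSV dialects (`genotypes.tsv`,
#' `cohort.tsv`) so they can be re-read unchanged by [read_genotypes_tsv()]
#' and [read_cohort_tsv()].
#'
#' @param config An [sim_config()].
#' @param weights Weight table (needed in liability mode; defaults to the
#'   shipped synthetic table).
#' @param seed Integer seed; defaults to `config$seed`. The same seed and
#'   config always yield identical output.
#' @param out_dir Optional directory for TSV output.
#' @return List of class `fh_study`: `genotypes`, `cohort`, `config`, `seed`.
#' @examples
#' study <- simulate_study(sim_config(n_eur = 50, n_mneg = 40, n_mpos = 20))
#' dplyr::count(study$cohort, group)
#' @export
simulate_study <- function(config = sim_config(), weights = default_weights(),
                           seed = config$seed, out_dir = NULL) {
  stopifnot(inherits(config, "fh_sim_config"))
  parts <- withr::with_seed(seed, {
    eur_freqs <- stats::setNames(config$freqs$eur, config$freqs$rsid)
    eur_geno <- if (config$n_eur > 0) {
      simulate_genotypes_hwe(config$n_eur, eur_freqs, sample_prefix = "EUR")
    } else {
      g <- tibble::tibble(sample_id = character())
      for (rs in config$freqs$rsid) g[[rs]] <- integer()
      g
    }
    eur_cohort <- empty_cohort()
    if (config$n_eur > 0) {
      eur_cohort <- tibble::add_row(
        eur_cohort, sample_id = eur_geno$sample_id, group = "EUR",
        mutation_gene = "none",
        sex = ifelse(stats::runif(config$n_eur) < 0.5, "F", "M")
      )
    }
    mneg <- simulate_case_group(config$n_mneg, config, "FH_Mneg", weights)
    mpos <- simulate_case_group(config$n_mpos, config, "FH_Mpos", weights)
    list(
      genotypes = dplyr::bind_rows(eur_geno, mneg$genotypes, mpos$genotypes),
      cohort = dplyr::bind_rows(eur_cohort, mneg$cohort, mpos$cohort)
    )
  })
  study <- structure(list(genotypes = parts$genotypes, cohort = parts$cohort,
                          config = config, seed = as.integer(seed)),
                     class = "fh_study")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_genotypes_tsv(study$genotypes, file.path(out_dir, "genotypes.tsv"))
    write_cohort_tsv(study$cohort, file.path(out_dir, "cohort.tsv"))
  }
  study
}

#' @export
print.fh_study <- function(x, ...) {
  cat("<fh_study> ", nrow(x$genotypes), " samples x ",
      ncol(x$genotypes) - 1L, " SNPs (mode: ", x$config$mode,
      ", seed: ", x$seed, ")\n", sep = "")
  print(dplyr::count(x$cohort, .data$group))
  invisible(x)
}
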