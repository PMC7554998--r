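# Small in-code fixtures shared across the suite.

# Two-SNP weight table matching the orientation used in reader tests
# (rs6511720 carried on its T allele here, unlike the shipped table, so
# orientation handling is actually exercised).
mini_weights <- function() {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c(
    "rsid\tgene\teffect_allele\tother_allele\tbeta\tref_freq",
    "rs6511720\tLDLR\tT\tG\t0.18\t0.11",
    "rs629301\tCELSR2-SORT1\tT\tG\t0.15\t0.78"
  ), path)
  read_weights(path)
}

# Dosage TSV with mixed cell styles: numeric, allele pairs, missing.
write_mixed_tsv <- function(path) {
  writeLines(c(
    "sample_id\trs6511720\trs629301",
    "S1\tTT\tGG",
    "S2\t1\tTG",
    "S3\t.\t2"
  ), path)
  path
}

# Minimal VCF paired with a dosage TSV carrying the same genotypes.
write_paired_vcf_tsv <- function(vcf_path, tsv_path, weights) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", sep = "\t"),
    paste("19", "1000", "rs6511720", "G", "T", ".", "PASS", ".", "GT",
          "1/1", "0/1", "./.", sep = "\t"),
    paste("1", "2000", "rs629301", "T", "G", ".", "PASS", ".", "GT",
          "1/1", "0|1", "0/0", sep = "\t")
  ), vcf_path)
  # rs629301: ALT (G) is the OTHER allele, so GT "1/1" is zero effect copies.
  writeLines(c(
    "sample_id\trs6511720\trs629301",
    "S1\t2\t0",
    "S2\t1\t1",
    "S3\t.\t2"
  ), tsv_path)
  invisible(list(vcf = vcf_path, tsv = tsv_path))
}

# Random dosage table over the full shipped panel.
random_genotypes <- function(n, weights, seed, missing_rate = 0) {
  withr::with_seed(seed, {
    out <- tibble::tibble(sample_id = sprintf("R%04d", seq_len(n)))
    for (rs in weights$rsid) {
      d <- sample(0:2, n, replace = TRUE)
      if (missing_rate > 0) {
        d[stats::runif(n) < missing_rate] <- NA_integer_
      }
      out[[rs]] <- d
    }
    out
  })
}

# Independent exact HWE oracle: direct factorial formula over all
# heterozygote counts compatible with the observed allele counts.
hwe_enumeration_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  na <- 2 * n2 + n1
  nb <- 2 * n - na
  n_minor <- min(na, nb)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  prob <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    (factorial(n) / (factorial(hom_min) * factorial(h) * factorial(hom_maj))) *
      2^h * factorial(na) * factorial(nb) / factorial(2 * n)
  }, numeric(1))
  obs <- prob[hets == n1]
  sum(prob[prob <= obs + 1e-12])
}

# Published epsilon-haplotype table for the 3x3 two-site genotype grid,
# written out by hand (rows: rs429358 C copies 0..2, cols: rs7412 T copies
# 0..2); recombinant cells are indeterminate.
apoe_truth_table <- function() {
  matrix(c(
    "E3/E3", "E2/E3", "E2/E2",
    "E3/E4", "E2/E4", "indeterminate",
    "E4/E4", "indeterminate", "indeterminate"
  ), nrow = 3, byrow = TRUE)
}
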