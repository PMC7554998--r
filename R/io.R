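#' Read a dosage TSV into a genotype table
#'
#' The genotype table is a tibble with a `sample_id` column and one integer
#' column per rsid holding copies of the effect allele (0/1/2, `NA` missing).
#' Cells in the file may be numeric dosages (`0`,`1`,`2`), unphased allele
#' pairs (e.g. `"AG"`), or the missing token `"."`. Allele pairs are oriented
#' against the weight table: the dosage is the number of effect-allele
#' characters in the cell. Alleles outside the SNP's effect/other pair are a
#' data error, never guessed through a strand flip.
#'
#' @param path Dosage TSV: header `sample_id<TAB>rsid1<TAB>...`, one row per
#'   sample.
#' @param weights An `fh_weights` table (see [read_weights()]) providing the
#'   effect/other orientation for every rsid column.
#' @return Genotype tibble (`sample_id` + one integer column per rsid).
#' @export
read_genotypes_tsv <- function(path, weights) {
  stopifnot(inherits(weights, "fh_weights"))
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"),
                         na = character())
  if (!"sample_id" %in% names(raw)) {
    stop("dosage TSV must have a `sample_id` column", call. = FALSE)
  }
  if (anyDuplicated(raw$sample_id)) {
    stop("duplicate sample_id in ", path, call. = FALSE)
  }
  rsids <- setdiff(names(raw), "sample_id")
  unknown <- setdiff(rsids, weights$rsid)
  if (length(unknown)) {
    stop("genotype column(s) not in the weight table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(sample_id = raw$sample_id)
  for (rs in rsids) {
    w <- weights[weights$rsid == rs, ]
    out[[rs]] <- parse_dosage_cells(raw[[rs]], rs, w$effect_allele,
                                    w$other_allele)
  }
  out
}

parse_dosage_cells <- function(cells, rsid, effect, other) {
  cells <- trimws(cells)
  out <- rep(NA_integer_, length(cells))
  is_missing <- cells == "." | cells == "" | toupper(cells) == "NA"
  is_numeric <- cells %in% c("0", "1", "2")
  out[is_numeric] <- as.integer(cells[is_numeric])
  is_pair <- !is_missing & !is_numeric
  if (any(is_pair)) {
    pairs <- toupper(cells[is_pair])
    if (any(nchar(pairs) != 2L)) {
      stop("unparseable genotype cell(s) for ", rsid, ": ",
           paste(unique(pairs[nchar(pairs) != 2L]), collapse = ", "),
           call. = FALSE)
    }
    a1 <- substr(pairs, 1, 1)
    a2 <- substr(pairs, 2, 2)
    ok <- a1 %in% c(effect, other) & a2 %in% c(effect, other)
    if (!all(ok)) {
      stop("allele mismatch at ", rsid, " (expected ", effect, "/", other,
           "): ", paste(unique(pairs[!ok]), collapse = ", "), call. = FALSE)
    }
    out[is_pair] <- (a1 == effect) + (a2 == effect)
  }
  out
}

#' Write a genotype table as a dosage TSV
#'
#' Inverse of [read_genotypes_tsv()] for numeric dosages: missing values are
#' written as `"."`.
#'
#' @param genotypes Genotype tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  out <- genotypes
  for (rs in setdiff(names(out), "sample_id")) {
    out[[rs]] <- ifelse(is.na(out[[rs]]), ".", as.character(out[[rs]]))
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read panel genotypes from a VCF
#'
#' Minimal VCF v4.x support: records are matched to the panel by ID (rsid),
#' REF/ALT must equal the SNP's effect/other pair in either order, and the GT
#' field is converted to an effect-allele dosage. `./.` or `.` genotypes are
#' missing. Strand flips are not auto-resolved: an incompatible REF/ALT pair
#' is an error naming the record. CHROM/POS are ignored (matching is by rsid).
#'
#' @inheritParams read_genotypes_tsv
#' @param path VCF file (uncompressed or bgzipped).
#' @return Genotype tibble with one column per panel record found in the VCF.
#' @export
read_genotypes_vcf <- function(path, weights) {
  stopifnot(inherits(weights, "fh_weights"))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  keep <- which(ids %in% weights$rsid)
  if (!length(keep)) {
    stop("no VCF record matches a weight-table rsid", call. = FALSE)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  out <- tibble::tibble(sample_id = samples)
  for (i in keep) {
    rs <- ids[i]
    w <- weights[weights$rsid == rs, ]
    ref <- unname(fix[i, "REF"])
    alt <- unname(fix[i, "ALT"])
    if (!setequal(c(ref, alt), c(w$effect_allele, w$other_allele))) {
      stop("allele mismatch at VCF record ", rs, ": REF/ALT ", ref, "/", alt,
           " incompatible with ", w$effect_allele, "/", w$other_allele,
           call. = FALSE)
    }
    effect_idx <- if (alt == w$effect_allele) "1" else "0"
    calls <- gt[i, , drop = TRUE]
    out[[rs]] <- vapply(calls, function(g) {
      if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
      alleles <- strsplit(g, "[/|]")[[1]]
      if (any(alleles == ".")) return(NA_integer_)
      if (!all(alleles %in% c("0", "1"))) {
        stop("non-biallelic GT at ", rs, ": ", g, call. = FALSE)
      }
      sum(alleles == effect_idx)
    }, integer(1), USE.NAMES = FALSE)
  }
  out
}

#' Read and write cohort metadata
#'
#' The cohort table holds one row per sample: `sample_id`, `group` (`EUR`
#' control, `FH_Mneg` mutation-negative patient, `FH_Mpos` mutation-positive
#' patient), `mutation_gene` (`none`/`LDLR`/`APOB`), the eight DLCN component
#' flags `dlcn_1a` ... `dlcn_4b`, the categorized LDL-c band `ldl_category`
#' (1-5), `dlcn_score`, `age`, `sex`, and the derived `dlcn_class`. Clinical
#' fields are `NA` for the control group.
#'
#' @param path TSV path.
#' @return A validated cohort tibble.
#' @export
read_cohort_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, na = c("", "NA", "."))
  validate_cohort(tab)
}

#' @rdname read_cohort_tsv
#' @param cohort Cohort tibble.
#' @export
write_cohort_tsv <- function(cohort, path) {
  readr::write_tsv(cohort, path, na = ".")
  invisible(path)
}

DLCN_FLAGS <- paste0("dlcn_", c("1a", "1b", "2a", "2b", "3a", "3b", "4a", "4b"))

#' Map a DLCN score to its diagnostic class
#'
#' @param score Numeric DLCN point total.
#' @return Character: `"<3"`, `"possible"` (3-5), `"probable"` (6-8) or
#'   `"definite"` (>8); `NA` passes through.
#' @export
dlcn_class <- function(score) {
  dplyr::case_when(
    is.na(score) ~ NA_character_,
    score < 3 ~ "<3",
    score <= 5 ~ "possible",
    score <= 8 ~ "probable",
    TRUE ~ "definite"
  )
}

validate_cohort <- function(tab) {
  tab <- tibble::as_tibble(tab)
  required <- c("sample_id", "group")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("cohort table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$sample_id)) {
    stop("duplicate sample_id in cohort table", call. = FALSE)
  }
  ok_group <- tab$group %in% c("EUR", "FH_Mneg", "FH_Mpos")
  if (!all(ok_group)) {
    stop("unknown group label(s): ",
         paste(unique(tab$group[!ok_group]), collapse = ", "), call. = FALSE)
  }
  if (!"mutation_gene" %in% names(tab)) tab$mutation_gene <- "none"
  tab$mutation_gene[is.na(tab$mutation_gene)] <- "none"
  bad_mut <- (tab$group == "FH_Mpos") != (tab$mutation_gene != "none")
  if (any(bad_mut)) {
    stop("mutation_gene must be none exactly for non-FH_Mpos samples",
         call. = FALSE)
  }
  if ("ldl_category" %in% names(tab)) {
    bad_ldl <- !is.na(tab$ldl_category) & !tab$ldl_category %in% 1:5
    if (any(bad_ldl)) stop("ldl_category must be in 1..5", call. = FALSE)
  }
  if ("dlcn_score" %in% names(tab)) {
    tab$dlcn_class <- dlcn_class(tab$dlcn_score)
  }
  tab
}

#' Write the pipeline report
#'
#' Emits a machine-readable JSON document (panel definitions, per-group score
#' moments, Hardy-Weinberg results, association/refinement results, cutoff
#' reports, fraction estimates, seed and config hash) plus a human-readable
#' text table of the pairwise group-comparison matrix. Sections that were not
#' computed are listed under `sections_absent` and written as `null`.
#'
#' @param results An `fh_report` from [run_pipeline()], or a bare named list
#'   with any of its sections.
#' @param path Output path for the JSON document; the text table is written
#'   next to it with extension `.txt`.
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(results, path) {
  sections <- c("panels", "score_summary", "hwe", "association", "cutoffs",
                "fractions", "meta")
  doc <- lapply(stats::setNames(sections, sections), function(s) results[[s]])
  doc$sections_absent <- sections[vapply(doc, is.null, logical(1))]
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  txt_path <- sub("\\.json$", ".txt", path)
  if (identical(txt_path, path)) txt_path <- paste0(path, ".txt")
  writeLines(format_report_text(results), txt_path)
  invisible(c(json = path, text = txt_path))
}

format_report_text <- function(results) {
  lines <- c("polyfh pipeline report", strrep("=", 40))
  if (is.null(results$score_summary)) {
    lines <- c(lines, "", "[score comparison section absent]")
  } else {
    for (pn in unique(results$score_summary$panel)) {
      sub <- results$score_summary[results$score_summary$panel == pn, ]
      lines <- c(lines, "", paste0("Weighted gene score ", pn,
                                   " by group: mean (SD)"))
      lines <- c(lines, sprintf("  %-10s %8.3f (%.2f)  n=%d",
                                sub$group, sub$mean, sub$sd, sub$n))
      pw <- results$pairwise
      if (!is.null(pw)) {
        pws <- pw[pw$panel == pn, ]
        lines <- c(lines, "  pairwise p-values:",
                   sprintf("    %-10s vs %-10s p = %.3g",
                           pws$group1, pws$group2, pws$p_value))
      }
    }
  }
  if (!is.null(results$fractions)) {
    fr <- results$fractions
    lines <- c(lines, "", "Combined genetic assignment (%):",
               sprintf("  %-18s monogenic %5.1f + polygenic rate %5.1f -> %5.1f",
                       fr$stratum, fr$monogenic_pct, fr$polygenic_rate,
                       fr$combined_pct))
  } else {
    lines <- c(lines, "", "[fraction section absent]")
  }
  lines
}
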