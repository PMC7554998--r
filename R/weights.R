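#' The 11-SNP LDL-c-raising panel and its nested refinements
#'
#' Panel membership for the three weighted gene scores: `wGS11` is the full
#' 11-SNP assay (one SNP per locus, plus both APOE sites rs429358/rs7412 so
#' that epsilon genotypes are representable); `wGS8` keeps the SNPs that
#' associate with mutation-negative FH plus rs429358; `wGS6` is the classical
#' six-SNP refinement. The panels are strictly nested: wGS6 < wGS8 < wGS11.
#'
#' @format Named list of character vectors of rsids.
#' @export
fh_panels <- list(
  wGS11 = c("rs2479409", "rs629301", "rs1367117", "rs4299376", "rs1564348",
            "rs1800562", "rs3757354", "rs8017377", "rs6511720", "rs429358",
            "rs7412"),
  wGS8 = c("rs2479409", "rs629301", "rs1367117", "rs4299376", "rs3757354",
           "rs6511720", "rs429358", "rs7412"),
  wGS6 = c("rs629301", "rs1367117", "rs4299376", "rs6511720", "rs429358",
           "rs7412")
)

APOE_SNPS <- c("rs429358", "rs7412")

#' Construct a score panel
#'
#' A panel is a named, ordered set of rsids plus a rule for handling the two
#' APOE sites: `"additive"` scores rs429358 and rs7412 like any other SNP
#' (signed per-allele betas), `"diplotype"` replaces their additive terms with
#' a single contribution looked up from an epsilon-diplotype weight table.
#'
#' @param name Panel name: `"wGS11"`, `"wGS8"`, `"wGS6"` (members filled in
#'   from [fh_panels]) or `"custom"` (supply `members`).
#' @param members Character vector of rsids; required when `name = "custom"`.
#' @param apoe_mode `"additive"` or `"diplotype"`.
#' @return An object of class `fh_panel` (list with `name`, `members`,
#'   `apoe_mode`).
#' @examples
#' score_panel("wGS8")
#' @export
score_panel <- function(name = c("wGS11", "wGS8", "wGS6", "custom"),
                        members = NULL,
                        apoe_mode = c("additive", "diplotype")) {
  name <- match.arg(name)
  apoe_mode <- match.arg(apoe_mode)
  if (name == "custom") {
    if (is.null(members)) {
      stop("a custom panel requires `members`", call. = FALSE)
    }
  } else {
    members <- fh_panels[[name]]
  }
  members <- as.character(members)
  if (anyDuplicated(members)) {
    stop("panel members must be unique rsids", call. = FALSE)
  }
  n_apoe <- sum(APOE_SNPS %in% members)
  if (n_apoe == 1L) {
    stop("rs429358 and rs7412 must both be present whenever either is ",
         "(epsilon genotypes need both sites)", call. = FALSE)
  }
  if (apoe_mode == "diplotype" && n_apoe == 0L) {
    stop("diplotype mode requires rs429358 and rs7412 in the panel",
         call. = FALSE)
  }
  structure(list(name = name, members = members, apoe_mode = apoe_mode),
            class = "fh_panel")
}

#' @export
print.fh_panel <- function(x, ...) {
  cat("<fh_panel> ", x$name, " (", length(x$members), " SNPs, APOE ",
      x$apoe_mode, ")\n  ", paste(x$members, collapse = ", "), "\n", sep = "")
  invisible(x)
}

as_panel <- function(panel, apoe_mode = NULL) {
  if (inherits(panel, "fh_panel")) {
    return(panel)
  }
  if (is.character(panel) && length(panel) == 1 && panel %in% names(fh_panels)) {
    if (is.null(apoe_mode)) apoe_mode <- "additive"
    return(score_panel(panel, apoe_mode = apoe_mode))
  }
  stop("`panel` must be an fh_panel or one of ",
       paste(names(fh_panels), collapse = ", "), call. = FALSE)
}

#' Read a SNP weight table
#'
#' Reads the per-SNP effect-allele weights used to build scores. Each row
#' carries the rsid, gene label, effect allele (the LDL-c-raising allele,
#' except where a lowering allele is carried with a negative beta), other
#' allele, the signed per-allele beta (mmol/L), and optionally a reference
#' effect-allele frequency used as a simulator default. JSON files may also
#' carry an `apoe_diplotype_weights` block mapping the six epsilon diplotypes
#' to a score contribution.
#'
#' @param path Path to a TSV (columns `rsid`, `gene`, `effect_allele`,
#'   `other_allele`, `beta`, optional `ref_freq`; `#` comments allowed) or a
#'   JSON file (array `snps` of the same records, optional
#'   `apoe_diplotype_weights`).
#' @param format `"auto"` (by extension), `"tsv"` or `"json"`.
#' @return A tibble of class `fh_weights`, one row per SNP, with an
#'   `apoe_diplotype_weights` attribute (named numeric or `NULL`).
#' @examples
#' read_weights(system.file("extdata", "glgc_weights_synthetic.tsv",
#'                          package = "polyfh"))
#' @export
read_weights <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (!file.exists(path)) {
    stop("weight file not found: ", path, call. = FALSE)
  }
  apoe_weights <- NULL
  if (format == "tsv") {
    tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  } else {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    tab <- if (is.data.frame(doc)) doc else doc$snps
    if (is.null(tab)) {
      stop("JSON weight file must contain a `snps` array", call. = FALSE)
    }
    tab <- tibble::as_tibble(tab)
    if (!is.data.frame(doc) && !is.null(doc$apoe_diplotype_weights)) {
      apoe_weights <- unlist(doc$apoe_diplotype_weights)
    }
  }
  validate_weights(tab, apoe_weights)
}

#' @rdname read_weights
#' @details `default_weights()` returns the synthetic placeholder table
#'   shipped with the package (approximate GLGC orientations and magnitudes;
#'   intended for simulation and as a template, not for clinical scoring).
#' @export
default_weights <- function() {
  read_weights(system.file("extdata", "glgc_weights_synthetic.tsv",
                           package = "polyfh"))
}

validate_weights <- function(tab, apoe_weights = NULL) {
  required <- c("rsid", "effect_allele", "other_allele", "beta")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("weight table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"gene" %in% names(tab)) tab$gene <- NA_character_
  if (!"ref_freq" %in% names(tab)) tab$ref_freq <- NA_real_
  tab <- tibble::as_tibble(tab)[, c("rsid", "gene", "effect_allele",
                                    "other_allele", "beta", "ref_freq")]
  if (anyDuplicated(tab$rsid)) {
    stop("duplicate rsid in weight table: ",
         paste(unique(tab$rsid[duplicated(tab$rsid)]), collapse = ", "),
         call. = FALSE)
  }
  beta <- suppressWarnings(as.numeric(tab$beta))
  if (anyNA(beta) || any(!is.finite(beta))) {
    stop("non-numeric or non-finite beta in weight table", call. = FALSE)
  }
  tab$beta <- beta
  tab$ref_freq <- suppressWarnings(as.numeric(tab$ref_freq))
  bad_freq <- !is.na(tab$ref_freq) & (tab$ref_freq < 0 | tab$ref_freq > 1)
  if (any(bad_freq)) {
    stop("ref_freq outside [0, 1] for: ",
         paste(tab$rsid[bad_freq], collapse = ", "), call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  ok_alleles <- tab$effect_allele %in% bases & tab$other_allele %in% bases &
    tab$effect_allele != tab$other_allele
  if (!all(ok_alleles)) {
    stop("invalid allele pair for: ",
         paste(tab$rsid[!ok_alleles], collapse = ", "), call. = FALSE)
  }
  if (!is.null(apoe_weights)) {
    needed <- c("E2/E2", "E2/E3", "E2/E4", "E3/E3", "E3/E4", "E4/E4")
    if (!all(needed %in% names(apoe_weights))) {
      stop("apoe_diplotype_weights must cover all six diplotypes",
           call. = FALSE)
    }
    apoe_weights <- vapply(apoe_weights[needed], as.numeric, numeric(1))
  }
  attr(tab, "apoe_diplotype_weights") <- apoe_weights
  class(tab) <- c("fh_weights", class(tab))
  tab
}

#' Epsilon-diplotype score contributions
#'
#' A conventional set of joint APOE epsilon-genotype weights (mmol/L relative
#' to E3/E3) for use with diplotype-mode scoring, in the style used by the
#' small-scale LDL-c score literature.
#'
#' @return Named numeric vector over the six diplotypes.
#' @export
default_apoe_diplotype_weights <- function() {
  c("E2/E2" = -0.9, "E2/E3" = -0.4, "E2/E4" = -0.2,
    "E3/E3" = 0.0, "E3/E4" = 0.1, "E4/E4" = 0.2)
}

panel_check_weights <- function(panel, weights) {
  absent <- setdiff(panel$members, weights$rsid)
  if (length(absent)) {
    stop("panel SNP(s) absent from the weight table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
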