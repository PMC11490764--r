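#' Default thresholds of the LoF target-discovery cascade
#'
#' All boundary values are inclusive on the "keep" side: discarding variants
#' with allele frequency `< 0.005` or `> 0.995` keeps the closed band
#' `[0.005, 0.995]`, and likewise for the 10–90% heterozygosity and
#' protein-position bands, the `< 300 AU` expression cut and the `< 15%`
#' LOH cut.
#'
#' @param ... Named overrides of any threshold.
#' @return Named list of thresholds.
#' @export
lof_thresholds <- function(...) {
  defaults <- list(
    af_min = 0.005, af_max = 0.995,
    het_min = 0.10, het_max = 0.90,
    pos_min = 0.10, pos_max = 0.90,
    expr_min = 300,
    loh_min = 0.15
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad)) abort(paste0("unknown threshold(s): ",
                                  paste(bad, collapse = ", ")))
    defaults <- modifyList(defaults, overrides)
  }
  defaults
}

# gene families excluded a priori from target discovery
EXCLUDED_FAMILIES <- c("olfactory_receptor", "taste_receptor",
                       "opioid_receptor", "keratin", "keratin_associated")

#' Allele-frequency filter
#'
#' Keeps common variants: alternate allele frequency within
#' `[af_min, af_max]` (default `[0.005, 0.995]`).
#'
#' @param af Alternate allele frequency in `[0, 1]` (vectorized).
#' @param thresholds See [lof_thresholds()].
#' @return Logical vector, `TRUE` = keep.
#' @export
filter_af <- function(af, thresholds = lof_thresholds()) {
  if (any(af < 0 | af > 1, na.rm = TRUE)) abort("allele frequency outside [0, 1]")
  !is.na(af) & af >= thresholds$af_min & af <= thresholds$af_max
}

#' Heterozygosity filter
#'
#' Keeps variants whose observed heterozygous-sample fraction lies within
#' `[het_min, het_max]` (default 10–90%, inclusive).
#'
#' @param het Fraction of genotyped samples heterozygous (vectorized).
#' @inheritParams filter_af
#' @return Logical vector, `TRUE` = keep.
#' @export
filter_het <- function(het, thresholds = lof_thresholds()) {
  if (any(het < 0 | het > 1, na.rm = TRUE)) abort("heterozygosity outside [0, 1]")
  !is.na(het) & het >= thresholds$het_min & het <= thresholds$het_max
}

#' Protein-position filter
#'
#' Removes truncating lesions in the outer 10% of the coding sequence, where
#' alternative start sites or short C-terminal truncations may leave a
#' near-functional protein. Splice mechanisms bypass this filter (pass `NA`
#' to keep).
#'
#' @param f First-affected-codon fraction in (0, 1], or `NA` for mechanisms
#'   the filter does not apply to (vectorized).
#' @inheritParams filter_af
#' @return Logical vector, `TRUE` = keep.
#' @export
filter_position <- function(f, thresholds = lof_thresholds()) {
  is.na(f) | (f >= thresholds$pos_min & f <= thresholds$pos_max)
}

#' Expression filter
#'
#' Keeps genes expressed at `>= expr_min` arbitrary units in \emph{both}
#' normal and cancer tissue ("either below" is discarded). Missing values
#' fail the filter.
#'
#' @param expression_normal,expression_cancer Expression in arbitrary units
#'   (vectorized).
#' @inheritParams filter_af
#' @return Logical vector, `TRUE` = keep.
#' @export
filter_expression <- function(expression_normal, expression_cancer,
                              thresholds = lof_thresholds()) {
  keep <- !is.na(expression_normal) & !is.na(expression_cancer) &
    expression_normal >= thresholds$expr_min &
    expression_cancer >= thresholds$expr_min
  keep
}

#' LOH filter
#'
#' Keeps genes whose locus undergoes loss of heterozygosity in at least
#' `loh_min` (default 15%) of cases in at least one common cancer type, and
#' reports which cancer types reach the threshold.
#'
#' @param loh_by_cancer Named numeric vector (or single-gene tibble with
#'   `cancer_type`, `loh_fraction`) of per-cancer LOH fractions.
#' @inheritParams filter_af
#' @return List with `keep` (logical) and `supporting_cancers` (character).
#' @export
filter_loh <- function(loh_by_cancer, thresholds = lof_thresholds()) {
  if (is.data.frame(loh_by_cancer)) {
    loh_by_cancer <- setNames(loh_by_cancer$loh_fraction,
                              loh_by_cancer$cancer_type)
  }
  if (length(loh_by_cancer) == 0) {
    abort("filter_loh: empty LOH map for gene")
  }
  supporting <- names(loh_by_cancer)[loh_by_cancer >= thresholds$loh_min]
  list(keep = length(supporting) > 0, supporting_cancers = supporting)
}

#' Gene-family filter
#'
#' Discards variants residing in gene families a priori unexploitable in an
#' LOH-therapy context: olfactory, taste and opioid receptors, keratins and
#' keratin-associated proteins.
#'
#' @param family_tags Character vector of family tags for one gene (possibly
#'   empty), or a list of such vectors.
#' @return Logical, `TRUE` = keep.
#' @export
filter_family <- function(family_tags) {
  if (is.list(family_tags)) {
    return(purrr::map_lgl(family_tags, filter_family))
  }
  !any(family_tags %in% EXCLUDED_FAMILIES)
}

#' All-transcripts filter
#'
#' A truncating or splice variant is retained only when it yields a LoF
#' mechanism in \emph{every} known transcript of the gene; a variant that is,
#' e.g., intronic in one isoform is discarded.
#'
#' @param v Variant (list/one-row data frame with `pos`, `ref`, `alt`).
#' @param transcripts List of `transcript_model` objects of one gene.
#' @return Logical, `TRUE` = keep.
#' @export
filter_all_transcripts <- function(v, transcripts) {
  stopifnot(length(transcripts) >= 1)
  mechs <- purrr::map_chr(transcripts, function(tx) {
    span <- tx_span(tx)
    pos0 <- as.integer(as.list(v)$pos) - 1L
    if (pos0 < span[1] || pos0 >= span[2]) return("none")
    annotate_consequence(v, tx)$mechanism
  })
  all(mechs != "none")
}

#' Default gene-family tag table
#'
#' Heuristic symbol-prefix table mapping obvious olfactory (`OR*`), taste
#' (`TAS2R*`), opioid (`OPR*`) receptor and keratin (`KRT*`, `KRTAP*`)
#' symbols to their exclusion tags. Intended as a convenience default; the
#' cascade takes an explicit user table.
#'
#' @param genes Character vector of gene symbols.
#' @return Tibble with `gene`, `family_tag` (only rows with a matched tag).
#' @export
default_family_table <- function(genes) {
  tag <- dplyr::case_when(
    stringr::str_detect(genes, "^OR\\d")     ~ "olfactory_receptor",
    stringr::str_detect(genes, "^TAS2R")     ~ "taste_receptor",
    stringr::str_detect(genes, "^OPR[MKDL]") ~ "opioid_receptor",
    stringr::str_detect(genes, "^KRTAP")     ~ "keratin_associated",
    stringr::str_detect(genes, "^KRT\\d")    ~ "keratin",
    TRUE ~ NA_character_
  )
  tibble(gene = genes, family_tag = tag) |> filter(!is.na(.data$family_tag))
}
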