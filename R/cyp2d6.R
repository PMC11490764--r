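#' CYP2D6 star-allele activity table
#'
#' The shipped table maps star alleles to activity levels (`full`, `semi`,
#' `null`) and, for the alleles callable from a single diagnostic SNV, their
#' defining rsIDs (`*4` via rs3892097, `*33` via rs28371717). Two alleles are
#' listed under two activity levels in the underlying nomenclature lists
#' (`*53` full/semi, `*41` semi/null); the first listing is retained and a
#' warning is emitted unless suppressed. Users may pass their own table
#' (columns `allele`, `activity`, `defining_rsids` ';'-joined) anywhere this
#' one is accepted.
#'
#' @param warn_conflicts Warn about the dual-listed alleles (default `TRUE`).
#' @return Tibble with columns `allele`, `activity`, `defining_rsids`.
#' @export
cyp2d6_allele_table <- function(warn_conflicts = TRUE) {
  path <- system.file("extdata", "cyp2d6_alleles.tsv",
                      package = "lohtarget", mustWork = TRUE)
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = "cccc")
  if (warn_conflicts) {
    dual <- tbl$allele[!is.na(tbl$note) & grepl("first listing", tbl$note)]
    if (length(dual)) {
      warn(paste0("alleles listed under two activity levels; first listing ",
                  "retained: ", paste(dual, collapse = ", ")))
    }
  }
  tbl |>
    mutate(defining_rsids = dplyr::coalesce(.data$defining_rsids, "")) |>
    select("allele", "activity", "defining_rsids")
}

#' QC filter for variant calls
#'
#' Keeps calls with Phred quality `>= qual_min` (default 20; "quality score
#' <20 excluded") and strand bias `<= sb_max` (default 0.90; "strand bias
#' >90% excluded"). Both boundaries inclusive on the keep side, as the strict
#' inequalities of the exclusion rules imply.
#'
#' @param qual Phred-scaled quality (vectorized).
#' @param strand_bias Max(forward, reverse) alt-read fraction in `[0.5, 1]`
#'   (vectorized). See [strand_bias_from_counts()].
#' @param qual_min,sb_max Thresholds.
#' @return Logical vector, `TRUE` = keep.
#' @export
qc_filter <- function(qual, strand_bias, qual_min = 20, sb_max = 0.90) {
  if (any(qual < 0, na.rm = TRUE)) abort("negative quality score")
  if (any(strand_bias < 0.5 - 1e-9 | strand_bias > 1, na.rm = TRUE)) {
    abort("strand bias outside [0.5, 1]")
  }
  !is.na(qual) & !is.na(strand_bias) & qual >= qual_min & strand_bias <= sb_max
}

#' Strand bias from alt-supporting read counts
#'
#' @param fwd,rev Alt-supporting read counts on each strand.
#' @return `max(fwd, rev) / (fwd + rev)`, in `[0.5, 1]`.
#' @export
strand_bias_from_counts <- function(fwd, rev) {
  tot <- fwd + rev
  if (any(tot <= 0)) abort("no alt-supporting reads")
  pmax(fwd, rev) / tot
}

#' Assign a star-allele multiset from QC-retained calls
#'
#' Each allele-defining rsID contributes one allele copy when its variant
#' allele fraction is consistent with heterozygosity (VAF in
#' `[vaf_het_min, vaf_hom_min]`, default `[0.2, 0.8]`) and two copies when
#' VAF exceeds `vaf_hom_min`; calls below `vaf_het_min` are treated as
#' absent. Unfilled positions default to the reference allele `*1`. More
#' than two total copies is an ambiguity error naming the conflicting
#' alleles.
#'
#' @param calls Tibble of QC-retained calls with columns `rsid`, `vaf`.
#' @param allele_table See [cyp2d6_allele_table()].
#' @param vaf_het_min,vaf_hom_min VAF thresholds for one/two copies.
#' @return Character vector of star alleles, length >= 2, sorted.
#' @export
assign_alleles <- function(calls, allele_table = cyp2d6_allele_table(FALSE),
                           vaf_het_min = 0.2, vaf_hom_min = 0.8) {
  calls <- as_tibble(calls)
  defin <- allele_table |> filter(.data$defining_rsids != "")
  rs_map <- setNames(defin$allele, defin$defining_rsids)
  alleles <- character()
  if (nrow(calls) > 0) {
    hits <- calls |> filter(.data$rsid %in% names(rs_map))
    for (i in seq_len(nrow(hits))) {
      a <- rs_map[[hits$rsid[i]]]
      v <- hits$vaf[i]
      copies <- if (v > vaf_hom_min) 2L else if (v >= vaf_het_min) 1L else 0L
      alleles <- c(alleles, rep(a, copies))
    }
  }
  if (length(alleles) > 2) {
    abort(paste0("ambiguous diplotype: defining variants imply more than two ",
                 "allele copies (", paste(alleles, collapse = ", "), ")"),
          class = "lohtarget_ambiguity")
  }
  sort(c(alleles, rep("*1", 2L - length(alleles))))
}

# phenotype from activity-level counts; 'extrapolated' marks multisets not
# covered verbatim by the published rule text
predict_from_activities <- function(acts) {
  f <- sum(acts == "full"); s <- sum(acts == "semi"); n <- sum(acts == "null")
  phen <-
    if (f > 2) "UM"
    else if (f == 2) "EM"
    else if (f == 1 && s >= 1) "EM"
    else if (f == 1) "IM"                 # remaining alleles are null
    else if (s >= 2) "IM"
    else if (s == 1) "IM"                 # {semi, null...}: extrapolated
    else "PM"                             # no activity-bearing allele
  quoted <- (f > 2) ||
    (f == 2 && s == 0 && n == 0) ||
    (f == 1 && s == 1 && n == 0) ||
    (f == 1 && s == 0 && n == 1) ||
    (f == 0 && s == 2 && n == 0) ||
    (f == 0 && s == 0 && n == 2)
  list(phenotype = phen, extrapolated = !quoted)
}

#' Metabolizer phenotype from a star-allele multiset
#'
#' Counts fully functional (F), semi-functional (S) and null (N) alleles and
#' applies, in precedence order UM > EM > IM > PM: UM if F > 2; EM if F = 2,
#' or F = 1 with a semi-active allele; IM if F = 1 with only null partners,
#' or two (or more) semi-functional alleles; PM if no activity-bearing
#' allele remains. Multisets outside the published diplotype rules (e.g.
#' \{semi, null\}) are classified by the same counting logic and flagged via
#' the `"extrapolated"` attribute.
#'
#' @param alleles Character vector (length >= 2) of star alleles, e.g.
#'   `c("*1", "*4")`, or of activity levels (`"full"`, `"semi"`, `"null"`).
#' @param allele_table See [cyp2d6_allele_table()].
#' @return Character scalar `"UM"`, `"EM"`, `"IM"` or `"PM"` with logical
#'   attribute `extrapolated`.
#' @examples
#' predict_phenotype(c("*4", "*4"))  # PM
#' predict_phenotype(c("*1", "*4"))  # IM
#' predict_phenotype(c("*1", "*10")) # EM
#' @export
predict_phenotype <- function(alleles,
                              allele_table = cyp2d6_allele_table(FALSE)) {
  if (length(alleles) < 2) abort("a diplotype carries at least two alleles")
  if (all(alleles %in% c("full", "semi", "null"))) {
    acts <- alleles
  } else {
    acts <- allele_table$activity[match(alleles, allele_table$allele)]
    if (any(is.na(acts))) {
      abort(paste0("allele(s) without an activity level: ",
                   paste(alleles[is.na(acts)], collapse = ", ")))
    }
  }
  res <- predict_from_activities(acts)
  structure(res$phenotype, extrapolated = res$extrapolated)
}

#' Call diplotypes and metabolizer phenotypes for a set of samples
#'
#' Applies [qc_filter()], [assign_alleles()] and [predict_phenotype()] per
#' sample. Ambiguous samples get a `status` describing the conflict instead
#' of a crash.
#'
#' @param calls Tibble with columns `sample`, `rsid`, `qual`, `strand_bias`,
#'   `vaf`.
#' @param allele_table See [cyp2d6_allele_table()].
#' @param qual_min,sb_max QC thresholds, see [qc_filter()].
#' @return Tibble with `sample`, `diplotype` (e.g. `"*1/*4"`), `phenotype`,
#'   `status` (`"ok"` or the ambiguity message), `extrapolated`, `evidence`
#'   (retained defining rsIDs, ';'-joined), `n_retained`.
#' @export
call_samples <- function(calls, allele_table = cyp2d6_allele_table(FALSE),
                         qual_min = 20, sb_max = 0.90) {
  calls <- as_tibble(calls)
  stopifnot(all(c("sample", "rsid", "qual", "strand_bias", "vaf") %in%
                  names(calls)))
  defin_rs <- allele_table$defining_rsids[allele_table$defining_rsids != ""]
  purrr::map_dfr(split(calls, calls$sample), function(sub) {
    kept <- sub[qc_filter(sub$qual, sub$strand_bias, qual_min, sb_max), ]
    res <- tryCatch({
      alleles <- assign_alleles(kept, allele_table)
      phen <- predict_phenotype(alleles, allele_table)
      tibble(diplotype = paste(alleles, collapse = "/"),
             phenotype = as.character(phen),
             status = "ok",
             extrapolated = attr(phen, "extrapolated"))
    }, lohtarget_ambiguity = function(e) {
      tibble(diplotype = NA_character_, phenotype = NA_character_,
             status = conditionMessage(e), extrapolated = NA)
    })
    bind_cols(tibble(sample = sub$sample[1]), res,
              tibble(evidence = paste(intersect(kept$rsid, defin_rs),
                                      collapse = ";"),
                     n_retained = nrow(kept)))
  })
}
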