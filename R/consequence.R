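#' Loss-of-function consequence annotation
#'
#' Classifies a variant against one transcript model into one of four LoF
#' mechanisms or `none`:
#' \itemize{
#'   \item `splice_snv` / `splice_indel` — the variant alters a canonical
#'     splice donor or acceptor dinucleotide (strand-aware; a variant spans
#'     the site if its reference interval intersects the 2-bp window, an
#'     insertion if its insertion point falls strictly inside it);
#'   \item `stop_snv` — an exonic substitution creates an in-frame stop codon
#'     (TAA/TAG/TGA on the coding strand);
#'   \item `frameshift_indel` — an exonic indel whose net length change is not
#'     divisible by 3.
#' }
#' In-frame exonic indels, deep-intronic variants and substitutions that do
#' not create a stop are `none`. Indel alleles are minimalized (shared
#' prefix/suffix trimmed) before any coordinate logic.
#'
#' @param v Variant: list or one-row data frame with `pos` (1-based), `ref`,
#'   `alt` (and optionally `chrom`).
#' @param tx A [transcript_model()].
#' @return One-row tibble with `mechanism` and `protein_fraction` (NA for
#'   splice mechanisms and `none`).
#' @examples
#' tx <- transcript_model("G", "G.t1", "chr1", "+",
#'                        data.frame(start = c(0, 30), end = c(12, 42)),
#'                        region_seq = paste0("ATGAAATACGGG",
#'                                            "GTAAGTCCCCCCCCCCCCAG",
#'                                            "CCCTACAAATAA"),
#'                        region_start = 0)
#' # G>A in the last base of the intron disrupts the acceptor dinucleotide
#' annotate_consequence(list(pos = 30, ref = "G", alt = "A"), tx)
#' @export
annotate_consequence <- function(v, tx) {
  v <- as.list(v)
  pos0 <- as.integer(v$pos) - 1L
  tr <- trim_alleles(pos0, toupper(v$ref), toupper(v$alt))
  span <- tx_span(tx)
  v_end <- max(tr$pos0 + max(nchar(tr$ref), 1L), pos0 + nchar(toupper(v$ref)))
  if (v_end <= span[1] || tr$pos0 >= span[2]) {
    abort(sprintf("variant at %d does not overlap transcript '%s'",
                  pos0 + 1L, tx$tx_id))
  }
  iv <- affected_interval(tr)
  ss <- splice_sites(tx)
  splice_hit <- FALSE
  if (nrow(ss) > 0) {
    splice_hit <- if (iv$width == 0L) {
      any(ss$start < iv$start & iv$start < ss$end)
    } else {
      any(ss$start < iv$start + iv$width & iv$start < ss$end)
    }
  }
  is_snv <- nchar(tr$ref) == 1L && nchar(tr$alt) == 1L
  is_indel <- nchar(tr$ref) != nchar(tr$alt)
  if (splice_hit) {
    mech <- if (is_snv) "splice_snv" else "splice_indel"
    return(tibble(mechanism = mech, protein_fraction = NA_real_))
  }
  ex <- tx$exons
  exonic <- if (iv$width == 0L) {
    any(ex$start < iv$start & iv$start < ex$end)
  } else {
    any(ex$start < iv$start + iv$width & iv$start < ex$end)
  }
  if (!exonic) return(tibble(mechanism = "none", protein_fraction = NA_real_))
  if (is_indel) {
    shift <- abs(nchar(tr$alt) - nchar(tr$ref))
    if (shift %% 3L != 0L) {
      return(tibble(mechanism = "frameshift_indel",
                    protein_fraction = first_affected_fraction(tr, tx)))
    }
    return(tibble(mechanism = "none", protein_fraction = NA_real_))
  }
  # substitution (possibly multi-base after trimming; only SNVs can gain stops here)
  cds <- cds_sequence(tx)
  if (is.null(cds)) {
    abort(sprintf("cds_sequence required to call stop-gain in '%s'", tx$tx_id))
  }
  if (is_snv) {
    idx <- genomic_to_cds(tx, iv$start)
    if (is.na(idx)) return(tibble(mechanism = "none", protein_fraction = NA_real_))
    alt_coding <- if (tx$strand == "+") tr$alt else complement_base(tr$alt)
    k0 <- idx %/% 3L
    codon <- substr(cds, 3L * k0 + 1L, 3L * k0 + 3L)
    within <- idx %% 3L
    substr(codon, within + 1L, within + 1L) <- alt_coding
    if (codon %in% STOP_CODONS) {
      K <- nchar(cds) %/% 3L
      return(tibble(mechanism = "stop_snv",
                    protein_fraction = (k0 + 1L) / K))
    }
  }
  tibble(mechanism = "none", protein_fraction = NA_real_)
}

# minimal allele representation; pos0 advances over the trimmed prefix
trim_alleles <- function(pos0, ref, alt) {
  # shared suffix
  while (nchar(ref) > 0 && nchar(alt) > 0 &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt)) &&
         !(nchar(ref) == 1 && nchar(alt) == 1)) {
    ref <- substr(ref, 1, nchar(ref) - 1L)
    alt <- substr(alt, 1, nchar(alt) - 1L)
  }
  # shared prefix
  while (nchar(ref) > 0 && nchar(alt) > 0 &&
         substr(ref, 1, 1) == substr(alt, 1, 1) &&
         !(nchar(ref) == 1 && nchar(alt) == 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos0 <- pos0 + 1L
  }
  list(pos0 = as.integer(pos0), ref = ref, alt = alt)
}

# reference interval touched by the trimmed variant; width 0 = insertion point
affected_interval <- function(tr) {
  if (nchar(tr$ref) == 0L || (nchar(tr$alt) > nchar(tr$ref) &&
                              substr(tr$ref, 1, 1) == substr(tr$alt, 1, 1))) {
    # pure insertion (possibly still carrying a VCF anchor base)
    anchor <- nchar(tr$ref)
    list(start = tr$pos0 + anchor, width = 0L)
  } else {
    list(start = tr$pos0, width = nchar(tr$ref))
  }
}

# first affected codon (translation order) / total codons, for truncating variants
first_affected_fraction <- function(tr, tx) {
  K <- cds_length(tx) %/% 3L
  if (K == 0L) return(NA_real_)
  iv <- affected_interval(tr)
  pts <- if (iv$width == 0L) c(iv$start - 1L, iv$start)
         else seq(iv$start, iv$start + iv$width - 1L)
  idx <- purrr::map_int(pts, function(p) genomic_to_cds(tx, p))
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) return(NA_real_)
  (min(idx) %/% 3L + 1L) / K
}

#' Relative protein position of a truncating variant
#'
#' Index of the first affected codon, counted in translation order, divided
#' by the total codon count. Used by the positional filter that removes
#' lesions in the outer 10% of the coding sequence.
#'
#' @inheritParams annotate_consequence
#' @return Fraction in (0, 1].
#' @export
protein_fraction <- function(v, tx) {
  cc <- annotate_consequence(v, tx)
  if (!cc$mechanism %in% c("stop_snv", "frameshift_indel")) {
    abort(sprintf(
      "protein_fraction is defined for truncating mechanisms, not '%s'",
      cc$mechanism))
  }
  cc$protein_fraction
}
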