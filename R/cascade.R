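#' Five-class LoF mechanism classification of a gene
#'
#' Genes retaining a single LoF mechanism among their surviving variants are
#' classed 1 (premature-stop SNV), 2 (splice-site SNV), 3 (frameshift indel)
#' or 4 (splice-site indel); genes with two or more distinct mechanisms are
#' class 5.
#'
#' @param mechanisms Character vector of mechanisms of one gene's retained
#'   variants (values in `stop_snv`, `splice_snv`, `frameshift_indel`,
#'   `splice_indel`).
#' @return Integer class 1–5.
#' @export
classify_gene <- function(mechanisms) {
  if (length(mechanisms) == 0) abort("classify_gene: empty mechanism list")
  valid <- c(stop_snv = 1L, splice_snv = 2L, frameshift_indel = 3L,
             splice_indel = 4L)
  if (any(!mechanisms %in% names(valid))) {
    abort(paste0("classify_gene: invalid mechanism(s): ",
                 paste(setdiff(mechanisms, names(valid)), collapse = ", ")))
  }
  u <- unique(mechanisms)
  if (length(u) >= 2) 5L else valid[[u]]
}

MECHANISM_LEVELS <- c("stop_snv", "splice_snv", "frameshift_indel", "splice_indel")

CASCADE_STAGES <- c("annotated", "family", "af", "het", "position",
                    "expression", "loh", "all_transcripts", "validation")

#' Run the full LoF target-discovery cascade
#'
#' Annotates each variant's consequence against the transcript models, then
#' applies the filter stages in order: gene-family exclusion, allele
#' frequency, heterozygosity, protein position, expression, LOH,
#' all-transcripts concordance and (when rsID sets are supplied) independent
#' validation. Survivors are grouped by gene and given a five-class LoF
#' mechanism classification.
#'
#' @param variants Tibble with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `rsid`, `af`, `het` (as from [read_vcf()]).
#' @param transcripts Named list of [transcript_model()] objects.
#' @param expression Tibble `gene`, `expression_normal`, `expression_cancer`.
#' @param loh Tibble `gene`, `cancer_type`, `loh_fraction`.
#' @param families Tibble `gene`, `family_tag` (genes absent from the table
#'   carry no tags). `NULL` = no exclusions.
#' @param validation List of character vectors of rsIDs with independent
#'   support; a variant is kept if present in at least one set. Empty list =
#'   stage skipped.
#' @param het_from_af Approximate missing heterozygosity as `2*af*(1-af)`
#'   (logged); otherwise missing het fails the het filter.
#' @param thresholds See [lof_thresholds()].
#' @return A `lof_cascade` object: list with `candidates` (gene, rsid,
#'   mechanism, lof_class, het, af, protein_fraction, supporting_cancers),
#'   `stage_summary` (per-stage retained counts by mechanism), `variants`
#'   (per-variant annotation incl. `stage_dropped`), `thresholds`.
#' @export
run_cascade <- function(variants, transcripts, expression, loh,
                        families = NULL, validation = list(),
                        het_from_af = FALSE,
                        thresholds = lof_thresholds()) {
  variants <- as_tibble(variants)
  empty <- empty_cascade(thresholds)
  if (nrow(variants) == 0) return(empty)

  by_gene <- transcripts_by_gene(transcripts)
  ann <- purrr::pmap_dfr(variants, function(...) {
    v <- list(...)
    annotate_variant(v, by_gene)
  })
  variants <- bind_cols(variants[, setdiff(names(variants),
                                           c("gene", "mechanism",
                                             "protein_fraction",
                                             "in_all_transcripts"))], ann)
  variants <- filter(variants, .data$mechanism != "none")
  if (nrow(variants) == 0) return(empty)

  if (het_from_af && any(is.na(variants$het))) {
    inform("approximating missing heterozygosity as 2*af*(1-af)")
    variants <- mutate(variants, het = if_else(is.na(.data$het),
                                               2 * .data$af * (1 - .data$af),
                                               .data$het))
  }

  expr <- as_tibble(expression)
  lohm <- as_tibble(loh)
  fam_tags <- family_tags_for(variants$gene, families)
  loh_res <- purrr::map(variants$gene, function(g) {
    sub <- filter(lohm, .data$gene == g)
    if (nrow(sub) == 0) {
      abort(sprintf("filter_loh: no LOH annotation for gene '%s'", g))
    }
    filter_loh(sub, thresholds)
  })
  ev <- left_join(tibble(gene = variants$gene), expr, by = "gene")

  pass <- tibble(
    family = filter_family(fam_tags),
    af = filter_af(variants$af, thresholds),
    het = filter_het(dplyr::coalesce(variants$het, -1), thresholds),
    position = filter_position(variants$protein_fraction, thresholds),
    expression = filter_expression(ev$expression_normal,
                                   ev$expression_cancer, thresholds),
    loh = purrr::map_lgl(loh_res, "keep"),
    all_transcripts = variants$in_all_transcripts,
    validation = if (length(validation) == 0) TRUE
                 else variants$rsid %in% unique(unlist(validation))
  )
  filter_stages <- names(pass)
  stage_dropped <- apply(!as.matrix(pass), 1, function(fails) {
    if (any(fails)) filter_stages[which(fails)[1]] else NA_character_
  })
  variants$stage_dropped <- stage_dropped
  variants$supporting_cancers <- purrr::map_chr(
    loh_res, function(x) paste(x$supporting_cancers, collapse = ";"))

  # retained counts after each stage, by mechanism
  stage_summary <- purrr::map_dfr(seq_along(CASCADE_STAGES), function(i) {
    st <- CASCADE_STAGES[i]
    later <- CASCADE_STAGES[-seq_len(i)]
    keep <- is.na(stage_dropped) | stage_dropped %in% later
    counts <- table(factor(variants$mechanism[keep], levels = MECHANISM_LEVELS))
    bind_cols(tibble(stage = st), as_tibble(as.list(counts)))
  })
  stage_summary <- stage_counts(stage_summary)

  survivors <- filter(variants, is.na(.data$stage_dropped))
  candidates <- survivors |>
    group_by(.data$gene) |>
    mutate(lof_class = classify_gene(.data$mechanism)) |>
    ungroup() |>
    select("gene", "rsid", "mechanism", "lof_class", "het", "af",
           "protein_fraction", "supporting_cancers") |>
    arrange(.data$lof_class, .data$gene)

  structure(list(candidates = candidates, stage_summary = stage_summary,
                 variants = variants, thresholds = thresholds),
            class = "lof_cascade")
}

empty_cascade <- function(thresholds) {
  zero <- as_tibble(setNames(as.list(rep(0L, 4)), MECHANISM_LEVELS))
  stage_summary <- bind_cols(tibble(stage = CASCADE_STAGES),
                             zero[rep(1, length(CASCADE_STAGES)), ])
  structure(list(
    candidates = tibble(gene = character(), rsid = character(),
                        mechanism = character(), lof_class = integer(),
                        het = double(), af = double(),
                        protein_fraction = double(),
                        supporting_cancers = character()),
    stage_summary = stage_counts(stage_summary),
    variants = tibble(), thresholds = thresholds),
    class = "lof_cascade")
}

# annotate one variant against all genes whose transcripts it overlaps
annotate_variant <- function(v, transcripts_by_gene) {
  pos0 <- as.integer(v$pos) - 1L
  for (g in names(transcripts_by_gene)) {
    txs <- transcripts_by_gene[[g]]
    hit <- purrr::keep(txs, function(tx) {
      span <- tx_span(tx)
      tx$chrom == v$chrom && pos0 >= span[1] && pos0 < span[2]
    })
    if (length(hit) == 0) next
    calls <- purrr::map_dfr(hit, function(tx) annotate_consequence(v, tx))
    lof <- filter(calls, .data$mechanism != "none")
    if (nrow(lof) == 0) {
      return(tibble(gene = g, mechanism = "none",
                    protein_fraction = NA_real_, in_all_transcripts = FALSE))
    }
    return(tibble(gene = g, mechanism = lof$mechanism[1],
                  protein_fraction = lof$protein_fraction[1],
                  in_all_transcripts = filter_all_transcripts(v, txs)))
  }
  tibble(gene = NA_character_, mechanism = "none",
         protein_fraction = NA_real_, in_all_transcripts = FALSE)
}

family_tags_for <- function(genes, families) {
  if (is.null(families) || nrow(families) == 0) {
    return(purrr::map(genes, function(g) character()))
  }
  families <- as_tibble(families)
  purrr::map(genes, function(g) {
    families$family_tag[families$gene == g]
  })
}

#' Add row totals to a mechanism count table
#'
#' Utility behind the cascade stage summary: sums all numeric count columns
#' of a per-stage (or per-category) table into a `total` column.
#'
#' @param df Data frame with one or more numeric count columns.
#' @return Tibble with a `total` column appended (recomputed if present).
#' @export
stage_counts <- function(df) {
  df <- as_tibble(df)
  df$total <- NULL
  num <- purrr::map_lgl(df, is.numeric)
  df$total <- as.integer(rowSums(df[, num, drop = FALSE]))
  df
}

#' @export
print.lof_cascade <- function(x, ...) {
  cat("<lof_cascade>\n")
  cat(sprintf("  %d candidate variant(s) in %d gene(s)\n",
              nrow(x$candidates), dplyr::n_distinct(x$candidates$gene)))
  print(x$stage_summary)
  invisible(x)
}

#' @export
tidy.lof_cascade <- function(x, ...) x$candidates

#' @export
glance.lof_cascade <- function(x, ...) {
  tibble(n_input = nrow(x$variants),
         n_candidates = nrow(x$candidates),
         n_genes = dplyr::n_distinct(x$candidates$gene))
}

#' @export
autoplot.lof_cascade <- function(object, ...) {
  long <- tidyr::pivot_longer(object$stage_summary,
                              dplyr::all_of(MECHANISM_LEVELS),
                              names_to = "mechanism", values_to = "n")
  long$stage <- factor(long$stage, levels = CASCADE_STAGES)
  ggplot(long, aes(x = .data$stage, y = .data$n, fill = .data$mechanism)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "cascade stage", y = "variants retained",
                  title = "LoF discovery cascade attrition") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' The published 60-gene LoF target table
#'
#' The final variant set of the discovery cascade as printed in the source
#' study: 60 genes (63 variant records; class-5 genes carry two mechanisms),
#' with heterozygote percentage, LoF mechanism, relative protein position of
#' truncating lesions and supporting cancer-type LOH fractions. Shipped as a
#' plain-text fixture and used to exercise the classifier on real published
#' values.
#'
#' @return Tibble with columns `class_printed`, `gene`, `locus`, `rsid`,
#'   `het_pct`, `mechanism`, `protein_pct`, `loh`.
#' @export
lof_table2 <- function() {
  path <- system.file("extdata", "table2_lof_variants.tsv",
                      package = "lohtarget", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    class_printed = readr::col_integer(),
                    gene = readr::col_character(),
                    locus = readr::col_character(),
                    rsid = readr::col_character(),
                    het_pct = readr::col_double(),
                    mechanism = readr::col_character(),
                    protein_pct = readr::col_double(),
                    loh = readr::col_character()
                  ))
}

#' Classify a printed variant table into the five LoF classes
#'
#' Groups records by gene, applies [classify_gene()] to each gene's
#' mechanisms and tabulates genes per class.
#'
#' @param records Tibble with at least `gene` and `mechanism` columns, e.g.
#'   [lof_table2()].
#' @return List with `per_gene` (gene, lof_class) and `class_counts`
#'   (lof_class 1–5, n_genes).
#' @export
classify_records <- function(records) {
  per_gene <- as_tibble(records) |>
    group_by(.data$gene) |>
    summarise(lof_class = classify_gene(.data$mechanism), .groups = "drop")
  counts <- per_gene |>
    count(.data$lof_class, name = "n_genes") |>
    tidyr::complete(lof_class = 1:5, fill = list(n_genes = 0L))
  list(per_gene = per_gene, class_counts = counts)
}
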