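#' Read a VCF into a variant tibble
#'
#' Parses a VCF v4.2 (via vcfR). Allele frequency is taken from the INFO AF
#' field when present and computed from GT otherwise; heterozygosity (the
#' fraction of genotyped samples heterozygous) is computed from GT when
#' genotype columns are present.
#'
#' @param path VCF file.
#' @return Tibble with `chrom`, `pos` (1-based), `rsid`, `ref`, `alt`, `af`,
#'   `het`, `n_samples`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(sprintf("VCF not found: %s", path))
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) {
                  abort(sprintf("failed to parse VCF '%s': %s", path,
                                conditionMessage(e)))
                })
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) {
    fixm <- matrix(fixm, nrow = 1, dimnames = list(NULL, names(fixm)))
  }
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(chrom = character(), pos = integer(), rsid = character(),
                  ref = character(), alt = character(), af = double(),
                  het = double(), n_samples = integer()))
  }
  af_info <- suppressWarnings(
    as.numeric(vcfR::extract.info(v, element = "AF")))
  het <- rep(NA_real_, nrow(fix))
  af_gt <- rep(NA_real_, nrow(fix))
  n_samp <- 0L
  if (ncol(v@gt) > 1) {
    gt <- vcfR::extract.gt(v, element = "GT")
    if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
    n_samp <- ncol(gt)
    alleles <- function(g) strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)
    for (i in seq_len(nrow(fix))) {
      g <- gt[i, ]
      g <- g[!is.na(g) & g != "./."]
      if (length(g) == 0) next
      al <- alleles(g)
      is_het <- purrr::map_lgl(al, function(a) length(unique(a)) > 1)
      het[i] <- mean(is_het)
      dose <- purrr::map_int(al, function(a) sum(a != "0"))
      af_gt[i] <- sum(dose) / (2 * length(g))
    }
  }
  af <- ifelse(!is.na(af_info), af_info, af_gt)
  tibble(chrom = fix$CHROM, pos = as.integer(fix$POS),
         rsid = if_else(is.na(fix$ID) | fix$ID == ".", NA_character_, fix$ID),
         ref = fix$REF, alt = fix$ALT, af = af, het = het,
         n_samples = n_samp)
}

#' Write a variant table (and optional genotypes) as VCF v4.2
#'
#' @param variants Tibble with `chrom`, `pos`, `rsid`, `ref`, `alt`, `af`.
#' @param genotypes Optional integer matrix (variants x samples) of
#'   alt-allele dosages 0/1/2.
#' @param samples Sample names (required with `genotypes`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, genotypes = NULL, samples = NULL, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=lohtarget",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alternate allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  has_gt <- !is.null(genotypes) && nrow(variants) > 0
  if (has_gt) {
    stopifnot(!is.null(samples), ncol(genotypes) == length(samples))
    cols <- c(cols, "FORMAT", samples)
  } else if (!is.null(samples)) {
    cols <- c(cols, "FORMAT", samples)
  }
  body <- character()
  if (nrow(variants) > 0) {
    gt_str <- c("0/0", "0/1", "1/1")
    body <- purrr::map_chr(seq_len(nrow(variants)), function(i) {
      r <- variants[i, ]
      fields <- c(r$chrom, r$pos, r$rsid %||% ".", r$ref, r$alt, ".", "PASS",
                  sprintf("AF=%.6g", r$af))
      if (has_gt) {
        fields <- c(fields, "GT", gt_str[genotypes[i, ] + 1L])
      }
      paste(fields, collapse = "\t")
    })
  }
  writeLines(c(header, paste(cols, collapse = "\t"), body), path)
  invisible(path)
}

#' Read a screening plate TSV
#'
#' Accepts raw-signal plates (`compound`, `line`, `concentration_nM`,
#' `signal`, `background`, `dmso_signal`) or pre-normalized plates
#' (`compound`, `line`, `concentration_nM`, `viability_pct`).
#'
#' @param path Plate TSV.
#' @return Tibble; attribute `pre_normalized` records which layout was read.
#' @export
read_plate <- function(path) {
  if (!file.exists(path)) abort(sprintf("plate file not found: %s", path))
  d <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("compound", "line", "concentration_nM")
  if (!all(need %in% names(d))) {
    abort(sprintf("plate '%s' lacks required columns: %s", path,
                  paste(setdiff(need, names(d)), collapse = ", ")))
  }
  pre <- "viability_pct" %in% names(d)
  if (!pre && !all(c("signal", "background", "dmso_signal") %in% names(d))) {
    abort(sprintf("plate '%s' has neither raw-signal nor viability_pct columns",
                  path))
  }
  structure(as_tibble(d), pre_normalized = pre)
}

#' Read per-sample variant-call tables
#'
#' TSV with columns `sample`, `rsid`, `qual`, and either `strand_bias` or
#' raw strand counts `alt_fwd`/`alt_rev` (converted via
#' [strand_bias_from_counts()]), plus `vaf`.
#'
#' @param path Calls TSV.
#' @return Tibble with `sample`, `rsid`, `qual`, `strand_bias`, `vaf`.
#' @export
read_calls <- function(path) {
  if (!file.exists(path)) abort(sprintf("calls file not found: %s", path))
  d <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"strand_bias" %in% names(d) &&
      all(c("alt_fwd", "alt_rev") %in% names(d))) {
    d$strand_bias <- strand_bias_from_counts(d$alt_fwd, d$alt_rev)
  }
  need <- c("sample", "rsid", "qual", "strand_bias", "vaf")
  if (!all(need %in% names(d))) {
    abort(sprintf("calls '%s' lacks required columns: %s", path,
                  paste(setdiff(need, names(d)), collapse = ", ")))
  }
  as_tibble(d)[, need]
}

#' Read a gene annotation table
#'
#' @param path TSV with a header row.
#' @param kind `"expression"` (gene, expression_normal, expression_cancer),
#'   `"loh"` (gene, cancer_type, loh_fraction) or `"families"`
#'   (gene, family_tag).
#' @return Tibble with the kind's columns.
#' @export
read_annotation <- function(path, kind = c("expression", "loh", "families")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    abort(sprintf("annotation file not found: %s", path))
  }
  d <- readr::read_tsv(path, show_col_types = FALSE)
  need <- switch(kind,
    expression = c("gene", "expression_normal", "expression_cancer"),
    loh = c("gene", "cancer_type", "loh_fraction"),
    families = c("gene", "family_tag"))
  if (!all(need %in% names(d))) {
    abort(sprintf("%s table '%s' lacks columns: %s", kind, path,
                  paste(setdiff(need, names(d)), collapse = ", ")))
  }
  as_tibble(d)[, need]
}

#' Write a reproducibility manifest
#'
#' Records the package version, R version, seed, configuration and MD5
#' checksums of the input files as JSON in `out_dir`. Contains no
#' timestamps, so repeated runs with the same inputs are byte-identical.
#'
#' @param out_dir Output directory.
#' @param config Named list of configuration values.
#' @param seed Integer seed used for the run (or `NULL`).
#' @param inputs Character vector of input file paths to checksum.
#' @return Path of the manifest, invisibly.
#' @export
write_manifest <- function(out_dir, config = list(), seed = NULL,
                           inputs = character()) {
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    package = "lohtarget",
    version = as.character(utils::packageVersion("lohtarget")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config = config,
    input_md5 = as.list(tools::md5sum(inputs)))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
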