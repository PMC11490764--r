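#' Simulate Hardy-Weinberg genotypes
#'
#' Draws alt-allele dosages (0/1/2) i.i.d. with P(het) = 2p(1-p) and
#' P(hom-alt) = p^2. A fixture-level stand-in for a population cohort; real
#' cohorts need not be in Hardy-Weinberg equilibrium.
#'
#' @param p Alternate allele frequency in `[0, 1]`.
#' @param n Number of samples (>= 1).
#' @param seed Optional integer seed for reproducible draws.
#' @return Integer vector of length `n` with values in `{0, 1, 2}`.
#' @export
simulate_genotypes <- function(p, n, seed = NULL) {
  if (p < 0 || p > 1) abort("allele frequency p must lie in [0, 1]")
  if (n < 1) abort("n must be >= 1")
  draw <- function() rbinom(n, 2L, p)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

SAFE_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

random_cds <- function(n_codons) {
  paste(sample(SAFE_CODONS, n_codons, replace = TRUE), collapse = "")
}

# Build one toy gene transcript: exon lengths are multiples of 3 so codons
# never span junctions; introns carry canonical GT...AG in coding orientation.
simulate_transcript <- function(gene, tx_id, chrom, strand, region_start,
                                exon_lens = c(120L, 240L, 120L),
                                intron_len = 200L) {
  stopifnot(all(exon_lens %% 3L == 0L), intron_len >= 20L)
  exon_seqs <- purrr::map_chr(exon_lens, function(l) random_cds(l %/% 3L))
  intron_seqs <- purrr::map_chr(seq_len(length(exon_lens) - 1L), function(i) {
    paste0("GT", random_cds((intron_len - 4L) %/% 3L + 2L) |>
             substr(1, intron_len - 4L), "AG")
  })
  types <- c(rbind(rep("exon", length(exon_lens)),
                   c(rep("intron", length(intron_seqs)), NA)))
  seqs <- c(rbind(exon_seqs, c(intron_seqs, NA)))
  keep <- !is.na(seqs)
  segs <- tibble(type = types[keep], seq = seqs[keep],
                 len = nchar(seqs[keep]))
  pre_mrna <- paste(segs$seq, collapse = "")
  if (strand == "+") {
    region_seq <- pre_mrna
    gsegs <- segs
  } else {
    region_seq <- revcomp(pre_mrna)
    gsegs <- segs[rev(seq_len(nrow(segs))), ]
  }
  starts <- region_start + cumsum(c(0L, gsegs$len[-nrow(gsegs)]))
  gsegs$start <- starts
  gsegs$end <- starts + gsegs$len
  ex <- filter(gsegs, .data$type == "exon")[, c("start", "end")]
  transcript_model(gene = gene, tx_id = tx_id, chrom = chrom, strand = strand,
                   exons = ex, region_seq = region_seq,
                   region_start = region_start)
}

# overwrite codon k (1-based) of the CDS in the genomic region sequence
set_cds_codon <- function(tx, k, codon) {
  stopifnot(nchar(codon) == 3)
  for (j in 0:2) {
    idx <- 3L * (k - 1L) + j
    g <- cds_to_genomic(tx, idx)
    b <- substr(codon, j + 1L, j + 1L)
    if (tx$strand == "-") b <- complement_base(b)
    substr(tx$region_seq, g - tx$region_start + 1L,
           g - tx$region_start + 1L) <- b
  }
  tx
}

region_base <- function(tx, g) {
  substr(tx$region_seq, g - tx$region_start + 1L, g - tx$region_start + 1L)
}

# Plant one variant of the requested mechanism into a transcript.
# Returns list(tx = possibly rewritten transcript, pos/ref/alt = VCF fields).
plant_variant <- function(tx, mechanism, protein_fraction = 0.5) {
  K <- cds_length(tx) %/% 3L
  k <- max(2L, min(K - 1L, as.integer(round(protein_fraction * K))))
  if (mechanism == "stop_snv") {
    tx <- set_cds_codon(tx, k, "TAC")
    g <- cds_to_genomic(tx, 3L * (k - 1L) + 2L)
    alt <- if (tx$strand == "+") "A" else "T"
    list(tx = tx, pos = g + 1L, ref = region_base(tx, g), alt = alt)
  } else if (mechanism == "benign") {
    tx <- set_cds_codon(tx, k, "GCC")
    g <- cds_to_genomic(tx, 3L * (k - 1L) + 2L)
    alt <- if (tx$strand == "+") "T" else "A"
    list(tx = tx, pos = g + 1L, ref = region_base(tx, g), alt = alt)
  } else if (mechanism == "frameshift_indel") {
    g <- cds_to_genomic(tx, 3L * (k - 1L))
    a <- g - 1L
    ref <- paste0(region_base(tx, a), region_base(tx, g))
    list(tx = tx, pos = a + 1L, ref = ref, alt = region_base(tx, a))
  } else if (mechanism == "splice_snv") {
    ss <- splice_sites(tx)
    acc <- filter(ss, .data$intron == 1L, .data$type == "acceptor")
    g <- if (tx$strand == "+") acc$end - 1L else acc$start
    alt <- if (tx$strand == "+") "A" else "T"
    list(tx = tx, pos = g + 1L, ref = region_base(tx, g), alt = alt)
  } else if (mechanism == "splice_indel") {
    ss <- splice_sites(tx)
    acc <- filter(ss, .data$intron == 1L, .data$type == "acceptor")
    a <- acc$start - 1L
    ref <- paste0(region_base(tx, a), region_base(tx, a + 1L),
                  region_base(tx, a + 2L))
    list(tx = tx, pos = a + 1L, ref = ref, alt = region_base(tx, a))
  } else {
    abort(sprintf("unknown mechanism '%s'", mechanism))
  }
}

PLANT_FATES <- c("pass_all", "fail_af", "fail_het", "fail_position",
                 "fail_expression", "fail_loh", "fail_family",
                 "fail_transcripts")

#' Specify a synthetic population cohort
#'
#' Each planted variant carries a LoF mechanism, a target allele frequency
#' and a `designed_fate` describing which cascade filter (if any) it is
#' built to violate. Fate-specific defaults: `fail_af` plants at p = 5e-4
#' (which under Hardy-Weinberg also implies sub-threshold heterozygosity —
#' the variant still drops at the earlier AF stage), `fail_het` at p = 0.02
#' (het ~ 4%, AF passing), `fail_position` at protein fraction 0.05,
#' `fail_expression`/`fail_loh`/`fail_family` tweak the gene annotations and
#' `fail_transcripts` adds a second isoform skipping the variant's exon.
#'
#' @param variants Tibble with columns `gene`, `mechanism` (`stop_snv`,
#'   `frameshift_indel`, `splice_snv`, `splice_indel`, `benign`), and
#'   optionally `af`, `protein_fraction`, `designed_fate`.
#' @param n_samples Cohort size (default 1000).
#' @param seed Integer RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(variants, n_samples = 1000L, seed = 1L) {
  if (n_samples < 1) abort("n_samples must be >= 1")
  v <- as_tibble(variants)
  if (!"designed_fate" %in% names(v)) v$designed_fate <- "pass_all"
  if (!"af" %in% names(v)) v$af <- NA_real_
  if (!"protein_fraction" %in% names(v)) v$protein_fraction <- NA_real_
  bad <- setdiff(v$designed_fate, PLANT_FATES)
  if (length(bad)) abort(paste0("unknown designed_fate: ",
                                paste(unique(bad), collapse = ", ")))
  v <- v |> mutate(
    af = dplyr::case_when(
      !is.na(af) ~ af,
      designed_fate == "fail_af" ~ 0.0005,
      designed_fate == "fail_het" ~ 0.02,
      TRUE ~ 0.2),
    protein_fraction = dplyr::case_when(
      !is.na(protein_fraction) ~ protein_fraction,
      designed_fate == "fail_position" ~ 0.05,
      TRUE ~ 0.5))
  if (any(v$af < 0 | v$af > 1)) abort("allele frequency outside [0, 1]")
  trunc_only <- v$designed_fate == "fail_position" &
    !v$mechanism %in% c("stop_snv", "frameshift_indel")
  if (any(trunc_only)) {
    abort("fail_position requires a truncating mechanism")
  }
  structure(list(variants = v, n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort with planted LoF variants
#'
#' Builds one toy gene locus per planted variant (alternating strands,
#' 3-exon transcripts with canonical splice dinucleotides), plants the
#' variant, draws Hardy-Weinberg genotypes for `n_samples` samples and
#' assembles the annotation tables the cascade consumes, with each
#' `designed_fate` realized by the appropriate allele frequency or
#' annotation tweak.
#'
#' @param spec A [cohort_spec()].
#' @return List with `variants` (VCF-like tibble incl. observed `af`,
#'   `het`), `genotypes` (variants x samples integer matrix), `transcripts`,
#'   `expression`, `loh`, `families`, `truth` (per-variant design and
#'   realized values), `samples`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, simulate_cohort_impl(spec))
}

simulate_cohort_impl <- function(spec) {
  v <- spec$variants
  n <- spec$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  transcripts <- list()
  expression <- list(); lohl <- list(); families <- list()
  rows <- list(); gts <- list(); truth <- list()
  for (i in seq_len(nrow(v))) {
    gene <- v$gene[i]
    fate <- v$designed_fate[i]
    strand <- if (i %% 2L == 1L) "+" else "-"
    tx <- simulate_transcript(gene, paste0(gene, ".t1"), "chr1",
                              strand, (i - 1L) * 10000L)
    pl <- plant_variant(tx, v$mechanism[i], v$protein_fraction[i])
    txs <- list(pl$tx)
    if (fate == "fail_transcripts") {
      # isoform skipping the middle exon: the variant (planted there) is
      # deep-intronic in this transcript
      ex <- pl$tx$exons
      tx2 <- transcript_model(gene, paste0(gene, ".t2"), "chr1", strand,
                              exons = ex[c(1, nrow(ex)), ],
                              region_seq = pl$tx$region_seq,
                              region_start = pl$tx$region_start)
      txs <- c(txs, list(tx2))
    }
    names(txs) <- purrr::map_chr(txs, "tx_id")
    transcripts <- c(transcripts, txs)

    gt <- rbinom(n, 2L, v$af[i])
    af_obs <- mean(gt) / 2
    het_obs <- mean(gt == 1L)
    rsid <- sprintf("rs9%06d", i)
    rows[[i]] <- tibble(chrom = "chr1", pos = pl$pos, rsid = rsid,
                        ref = pl$ref, alt = pl$alt,
                        af = af_obs, het = het_obs)
    gts[[i]] <- gt
    expression[[i]] <- tibble(
      gene = gene,
      expression_normal = 1000,
      expression_cancer = if (fate == "fail_expression") 200 else 800)
    lohl[[i]] <- if (fate == "fail_loh") {
      tibble(gene = gene, cancer_type = c("Lung", "Ovarian"),
             loh_fraction = c(0.05, 0.04))
    } else {
      tibble(gene = gene, cancer_type = c("Lung", "Ovarian"),
             loh_fraction = c(0.28, 0.25))
    }
    if (fate == "fail_family") {
      families[[length(families) + 1]] <-
        tibble(gene = gene, family_tag = "olfactory_receptor")
    }
    truth[[i]] <- tibble(gene = gene, rsid = rsid,
                         mechanism = v$mechanism[i], designed_fate = fate,
                         af_target = v$af[i], af_obs = af_obs,
                         het_obs = het_obs,
                         protein_fraction = v$protein_fraction[i])
  }
  gt_mat <- do.call(rbind, gts)
  if (is.null(gt_mat)) gt_mat <- matrix(integer(), 0, n)
  colnames(gt_mat) <- samples
  list(variants = bind_rows(rows), genotypes = gt_mat,
       transcripts = transcripts,
       expression = bind_rows(expression),
       loh = bind_rows(lohl),
       families = if (length(families)) bind_rows(families)
                  else tibble(gene = character(), family_tag = character()),
       truth = bind_rows(truth), samples = samples)
}

#' Write a simulated cohort to disk (VCF + annotation tables)
#'
#' Emits `cohort.vcf` (v4.2, GT per sample, INFO AF), `transcripts.bed`
#' (BED12), `cds.fasta`, `expression.tsv`, `loh.tsv`, `families.tsv` and
#' `truth.tsv` into `out_dir`. Output is byte-identical under a fixed spec
#' seed.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, list with `paths` and the simulated `cohort`.
#' @export
generate_cohort_vcf <- function(spec, out_dir) {
  cohort <- simulate_cohort(spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    vcf = file.path(out_dir, "cohort.vcf"),
    transcripts = file.path(out_dir, "transcripts.bed"),
    cds = file.path(out_dir, "cds.fasta"),
    expression = file.path(out_dir, "expression.tsv"),
    loh = file.path(out_dir, "loh.tsv"),
    families = file.path(out_dir, "families.tsv"),
    truth = file.path(out_dir, "truth.tsv"))
  write_vcf(cohort$variants, cohort$genotypes, cohort$samples, paths$vcf)
  write_bed12(cohort$transcripts, paths$transcripts)
  write_cds_fasta(cohort$transcripts, paths$cds)
  readr::write_tsv(cohort$expression, paths$expression)
  readr::write_tsv(cohort$loh, paths$loh)
  readr::write_tsv(cohort$families, paths$families)
  readr::write_tsv(cohort$truth, paths$truth)
  invisible(list(paths = paths, cohort = cohort))
}

#' Specify a synthetic two-line viability screen
#'
#' Defaults mirror the screening design the pipeline targets: a 10-point
#' concentration grid of 0-10,000 nM, planted differential-toxicity hits
#' with a wild-type/LoF IC50 ratio of 4 (LoF-line IC50 1 µM) and
#' equally-toxic non-hits, additive Gaussian noise of 2 viability points,
#' three technical replicates.
#'
#' @param n_compounds,n_hits Screen size and number of planted hits.
#' @param ic50_lof_um LoF-line IC50 of planted hits (µM).
#' @param ic50_ratio Wild-type / LoF IC50 ratio of planted hits (>= 2).
#' @param ic50_null_um IC50 of non-hits, both lines (µM).
#' @param hill Hill slope of all generated curves.
#' @param noise_sd Gaussian noise SD in viability percent (>= 0).
#' @param concentrations_nM Concentration grid, must include 0.
#' @param n_replicates Technical replicates per well.
#' @param seed Integer RNG seed.
#' @return A `screen_spec` list.
#' @export
screen_spec <- function(n_compounds = 525L, n_hits = 12L,
                        ic50_lof_um = 1, ic50_ratio = 4, ic50_null_um = 1,
                        hill = 1, noise_sd = 2,
                        concentrations_nM = c(0, 40, 80, 160, 315, 625,
                                              1250, 2500, 5000, 10000),
                        n_replicates = 3L, seed = 1L) {
  if (n_hits > n_compounds) abort("n_hits must be <= n_compounds")
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  if (any(concentrations_nM < 0)) abort("concentrations must be non-negative")
  if (!any(concentrations_nM == 0)) abort("grid must include 0 (DMSO control)")
  if (n_hits > 0 && ic50_ratio < 2) abort("planted hits require ic50_ratio >= 2")
  structure(list(n_compounds = as.integer(n_compounds),
                 n_hits = as.integer(n_hits),
                 ic50_lof_um = ic50_lof_um, ic50_ratio = ic50_ratio,
                 ic50_null_um = ic50_null_um, hill = hill,
                 noise_sd = noise_sd,
                 concentrations_nM = sort(concentrations_nM),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "screen_spec")
}

#' Generate a synthetic screening plate
#'
#' Signals follow a logistic dose-response per line with additive Gaussian
#' noise on the percent-viability scale (truncated at 0); DMSO wells define
#' 100%. Raw signals are emitted so the pipeline's own normalization is
#' exercised.
#'
#' @param spec A [screen_spec()].
#' @param out_dir Optional directory; writes `plate.tsv` and
#'   `screen_truth.tsv` when given.
#' @return List with `plate` (compound, line, concentration_nM, replicate,
#'   signal, background, dmso_signal) and `truth` (compound, is_hit,
#'   ic50_wt_um, ic50_lof_um).
#' @export
generate_screen <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "screen_spec"))
  res <- withr::with_seed(spec$seed, generate_screen_impl(spec))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(res$plate, file.path(out_dir, "plate.tsv"))
    readr::write_tsv(res$truth, file.path(out_dir, "screen_truth.tsv"))
  }
  res
}

generate_screen_impl <- function(spec) {
  if (spec$n_compounds == 0L) {
    return(list(plate = tibble(compound = character(), line = character(),
                               concentration_nM = double(),
                               replicate = integer(), signal = double(),
                               background = double(), dmso_signal = double()),
                truth = tibble(compound = character(), is_hit = logical(),
                               ic50_wt_um = double(), ic50_lof_um = double())))
  }
  compounds <- sprintf("cmp%04d", seq_len(spec$n_compounds))
  hit_idx <- if (spec$n_hits > 0) {
    sort(sample(spec$n_compounds, spec$n_hits))
  } else integer()
  is_hit <- seq_len(spec$n_compounds) %in% hit_idx
  ic50_lof <- ifelse(is_hit, spec$ic50_lof_um, spec$ic50_null_um)
  ic50_wt <- ifelse(is_hit, spec$ic50_lof_um * spec$ic50_ratio,
                    spec$ic50_null_um)
  truth <- tibble(compound = compounds, is_hit = is_hit,
                  ic50_wt_um = ic50_wt, ic50_lof_um = ic50_lof)
  background <- 500; dmso <- 10000
  grid <- tidyr::expand_grid(
    compound = compounds,
    line = c("line_wt", "line_lof"),
    concentration_nM = spec$concentrations_nM,
    replicate = seq_len(spec$n_replicates))
  grid <- left_join(grid, truth, by = "compound")
  x_um <- grid$concentration_nM / 1000
  ic50 <- if_else(grid$line == "line_wt", grid$ic50_wt_um, grid$ic50_lof_um)
  v <- if_else(x_um == 0, 100, 100 / (1 + (x_um / ic50)^spec$hill))
  if (spec$noise_sd > 0) v <- v + rnorm(length(v), 0, spec$noise_sd)
  v <- pmax(v, 0)
  grid$signal <- background + (dmso - background) * v / 100
  grid$background <- background
  grid$dmso_signal <- dmso
  list(plate = grid[, c("compound", "line", "concentration_nM", "replicate",
                        "signal", "background", "dmso_signal")],
       truth = truth)
}

#' Generate synthetic organoid variant-call sets
#'
#' For each requested diplotype, emits the defining SNVs of its non-reference
#' alleles at a variant allele fraction drawn from a Beta distribution
#' centered on copies/2 (concentration k = 50; homozygous calls centered just
#' below 1), with clean QC fields, plus `n_decoys` decoy calls per sample of
#' which a fraction `qc_decoy_rate` carries a QC-failing quality (< 20) or
#' strand bias (> 0.90).
#'
#' @param diplotypes List of character vectors of star alleles (length >= 2
#'   each), e.g. `list(c("*1", "*4"), c("*1", "*1"))`. Names become sample
#'   IDs; unnamed lists get `HCCO01`, `HCCO02`, ...
#' @param qc_decoy_rate Fraction of injected decoys that fail QC.
#' @param n_decoys Decoy calls per sample.
#' @param seed Integer RNG seed.
#' @param allele_table See [cyp2d6_allele_table()].
#' @param out_dir Optional directory; writes `organoid_calls.tsv` and
#'   `organoid_truth.tsv` when given.
#' @return List with `calls` (sample, rsid, qual, strand_bias, vaf) and
#'   `truth` (per planted/decoy call and per-sample planted diplotype and
#'   phenotype).
#' @export
generate_organoid_calls <- function(diplotypes, qc_decoy_rate = 0.25,
                                    n_decoys = 4L, seed = 1L,
                                    allele_table = cyp2d6_allele_table(FALSE),
                                    out_dir = NULL) {
  stopifnot(qc_decoy_rate >= 0, qc_decoy_rate <= 1)
  known <- allele_table$allele
  unknown <- setdiff(unique(unlist(diplotypes)), known)
  if (length(unknown)) {
    abort(paste0("unknown star allele(s): ", paste(unknown, collapse = ", ")))
  }
  if (is.null(names(diplotypes))) {
    names(diplotypes) <- sprintf("HCCO%02d", seq_along(diplotypes))
  }
  defin <- allele_table |> filter(.data$defining_rsids != "")
  res <- withr::with_seed(seed, {
    calls <- list(); truth <- list()
    for (s in names(diplotypes)) {
      dip <- diplotypes[[s]]
      stopifnot(length(dip) >= 2)
      counts <- table(dip[dip != "*1"])
      for (a in names(counts)) {
        j <- match(a, defin$allele)
        if (is.na(j)) next  # allele without a single defining SNV: silent
        copies <- as.integer(counts[[a]])
        cfrac <- min(copies / 2, 0.97)
        vaf <- stats::rbeta(1, 50 * cfrac, 50 * (1 - cfrac))
        calls[[length(calls) + 1]] <- tibble(
          sample = s, rsid = defin$defining_rsids[j],
          qual = runif(1, 30, 60), strand_bias = runif(1, 0.5, 0.75),
          vaf = vaf)
        truth[[length(truth) + 1]] <- tibble(
          sample = s, rsid = defin$defining_rsids[j], is_decoy = FALSE,
          fails_qc = FALSE, allele = a, copies = copies)
      }
      if (n_decoys > 0) {
        n_fail <- round(qc_decoy_rate * n_decoys)
        for (d in seq_len(n_decoys)) {
          fails <- d <= n_fail
          qual <- if (fails && d %% 2L == 1L) runif(1, 0, 19.5)
                  else runif(1, 25, 60)
          sb <- if (fails && d %% 2L == 0L) runif(1, 0.905, 1)
                else runif(1, 0.5, 0.85)
          rs <- sprintf("rs7%05d", sample.int(99999, 1))
          calls[[length(calls) + 1]] <- tibble(
            sample = s, rsid = rs, qual = qual, strand_bias = sb,
            vaf = runif(1, 0.2, 0.6))
          truth[[length(truth) + 1]] <- tibble(
            sample = s, rsid = rs, is_decoy = TRUE, fails_qc = fails,
            allele = NA_character_, copies = NA_integer_)
        }
      }
    }
    dip_truth <- purrr::imap_dfr(diplotypes, function(dip, s) {
      phen <- predict_phenotype(sort(dip), allele_table)
      tibble(sample = s, diplotype = paste(sort(dip), collapse = "/"),
             phenotype = as.character(phen))
    })
    list(calls = bind_rows(calls), truth = bind_rows(truth),
         diplotype_truth = dip_truth)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(res$calls, file.path(out_dir, "organoid_calls.tsv"))
    readr::write_tsv(left_join(res$truth, res$diplotype_truth, by = "sample"),
                     file.path(out_dir, "organoid_truth.tsv"))
  }
  res
}
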