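# Hand-constructed toy transcripts with fully known coordinates.

# Plus-strand two-exon gene:
#   exon1 [0,12) | intron [12,32) GT....AG | exon2 [32,44)
# CDS = ATGAAATACGGG CCCTACAAATAA (24 nt, 8 codons)
toy_tx_plus <- function() {
  transcript_model(
    gene = "TOYP", tx_id = "TOYP.t1", chrom = "chr1", strand = "+",
    exons = data.frame(start = c(0, 32), end = c(12, 44)),
    region_seq = paste0("ATGAAATACGGG", "GT", strrep("C", 16), "AG",
                        "CCCTACAAATAA"),
    region_start = 0)
}

# Minus-strand two-exon gene on genomic [100,122):
#   coding order: exon1 ATGAAA | intron GTCCCCCCAG | exon2 TTTTAA
#   genomic: exon2_g [100,106) | intron_g [106,116) | exon1_g [116,122)
# splice dinucleotides (genomic): acceptor [106,108), donor [114,116)
toy_tx_minus <- function() {
  pre_mrna <- paste0("ATGAAA", "GTCCCCCCAG", "TTTTAA")
  transcript_model(
    gene = "TOYM", tx_id = "TOYM.t1", chrom = "chr1", strand = "-",
    exons = data.frame(start = c(100, 116), end = c(106, 122)),
    region_seq = lohtarget:::revcomp(pre_mrna),
    region_start = 100)
}

# Single-exon plus-strand gene with K codons, all GGG except codon k = TAC
# (mutable to a TAA stop at its third base).
toy_tx_single_exon <- function(K, k) {
  codons <- rep("GGG", K)
  codons[k] <- "TAC"
  transcript_model(
    gene = "TOYS", tx_id = "TOYS.t1", chrom = "chr1", strand = "+",
    exons = data.frame(start = 0, end = 3 * K),
    region_seq = paste(codons, collapse = ""), region_start = 0)
}

# stop-gain SNV at codon k of toy_tx_single_exon(K, k)
toy_stop_variant <- function(k) {
  list(pos = 3 * (k - 1) + 3, ref = "C", alt = "A")
}

# expected drop stage for each designed fate
FATE_STAGE <- c(fail_af = "af", fail_het = "het", fail_position = "position",
                fail_expression = "expression", fail_loh = "loh",
                fail_family = "family", fail_transcripts = "all_transcripts")

# independent per-variant re-evaluation of all cascade predicates, built
# directly from the exported filter functions and the raw annotation tables
brute_force_survivors <- function(cohort, thresholds = lof_thresholds()) {
  txs_by_gene <- split(cohort$transcripts,
                       purrr::map_chr(cohort$transcripts, "gene"))
  keep <- purrr::map_lgl(seq_len(nrow(cohort$variants)), function(i) {
    v <- as.list(cohort$variants[i, ])
    gene <- cohort$truth$gene[match(v$rsid, cohort$truth$rsid)]
    txs <- txs_by_gene[[gene]]
    calls <- purrr::map_chr(txs, function(tx) {
      span <- lohtarget:::tx_span(tx)
      if (v$pos - 1 < span[1] || v$pos - 1 >= span[2]) return("none")
      annotate_consequence(v, tx)$mechanism
    })
    mech <- setdiff(calls, "none")
    if (length(mech) == 0) return(FALSE)
    pf <- if (mech[1] %in% c("stop_snv", "frameshift_indel")) {
      protein_fraction(v, txs[[which(calls != "none")[1]]])
    } else NA_real_
    fam <- cohort$families$family_tag[cohort$families$gene == gene]
    ex <- cohort$expression[cohort$expression$gene == gene, ]
    lo <- cohort$loh[cohort$loh$gene == gene, ]
    filter_family(fam) &&
      filter_af(v$af, thresholds) &&
      filter_het(v$het, thresholds) &&
      filter_position(pf, thresholds) &&
      filter_expression(ex$expression_normal[1], ex$expression_cancer[1],
                        thresholds) &&
      filter_loh(lo, thresholds)$keep &&
      filter_all_transcripts(v, txs)
  })
  cohort$variants$rsid[keep]
}
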