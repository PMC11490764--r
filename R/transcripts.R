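#' Transcript models with canonical splice dinucleotides
#'
#' A `transcript_model` holds the exon structure of one transcript together
#' with its strand, an optional genomic region sequence and/or spliced CDS
#' sequence. All internal coordinates are 0-based half-open on the genome;
#' conversion from 1-based formats (VCF, GFF3) happens at the I/O boundary.
#'
#' @param gene Gene identifier.
#' @param tx_id Transcript identifier (unique within a set).
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with columns `start`, `end` (0-based half-open,
#'   ascending genomic order, non-overlapping).
#' @param region_seq Optional plus-strand genomic sequence covering
#'   `[region_start, region_start + nchar(region_seq))`.
#' @param region_start 0-based genomic start of `region_seq`.
#' @param cds_sequence Optional spliced coding sequence (coding strand,
#'   length divisible by 3). Derived from `region_seq` when absent.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(gene, tx_id, chrom, strand, exons,
                             region_seq = NULL, region_start = 0L,
                             cds_sequence = NULL) {
  stopifnot(strand %in% c("+", "-"))
  exons <- as_tibble(exons)[, c("start", "end")]
  exons <- arrange(exons, .data$start)
  if (any(exons$end <= exons$start)) {
    abort("transcript_model: empty or inverted exon interval")
  }
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)])) {
    abort(sprintf("transcript_model: overlapping exons in transcript '%s'", tx_id))
  }
  tx <- structure(
    list(gene = gene, tx_id = tx_id, chrom = chrom, strand = strand,
         exons = exons, region_seq = region_seq,
         region_start = as.integer(region_start),
         cds_sequence = cds_sequence),
    class = "transcript_model"
  )
  cds <- cds_sequence(tx)
  if (!is.null(cds) && nchar(cds) %% 3L != 0L) {
    abort(sprintf("transcript_model: CDS length of '%s' not divisible by 3", tx_id))
  }
  tx
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s%s, %d exon(s), span %d-%d\n",
              x$tx_id, x$gene, x$chrom, x$strand, nrow(x$exons),
              min(x$exons$start), max(x$exons$end)))
  invisible(x)
}

tx_span <- function(tx) c(min(tx$exons$start), max(tx$exons$end))

complement_base <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(complement_base(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

region_subseq <- function(tx, start0, end0) {
  if (is.null(tx$region_seq)) return(NULL)
  i <- start0 - tx$region_start
  j <- end0 - tx$region_start
  if (i < 0 || j > nchar(tx$region_seq)) return(NULL)
  substr(tx$region_seq, i + 1L, j)
}

#' Spliced coding sequence of a transcript
#'
#' Returns the supplied CDS when present, otherwise splices it from the
#' genomic region sequence (reverse-complemented for minus-strand models).
#' `NULL` when neither source is available.
#'
#' @param tx A `transcript_model`.
#' @return Character scalar or `NULL`.
#' @export
cds_sequence <- function(tx) {
  if (!is.null(tx$cds_sequence)) return(toupper(tx$cds_sequence))
  if (is.null(tx$region_seq)) return(NULL)
  pieces <- purrr::map2_chr(tx$exons$start, tx$exons$end,
                            function(s, e) region_subseq(tx, s, e))
  plus <- paste(pieces, collapse = "")
  if (tx$strand == "+") toupper(plus) else toupper(revcomp(plus))
}

cds_length <- function(tx) {
  cds <- cds_sequence(tx)
  if (!is.null(cds)) return(nchar(cds))
  sum(tx$exons$end - tx$exons$start)
}

#' Canonical splice dinucleotide intervals of a transcript
#'
#' For every intron, the donor site is the first two intronic bases and the
#' acceptor the last two, in the transcript's reading direction: on the minus
#' strand the donor lies at the genomically-high end of the intron.
#'
#' @param tx A `transcript_model`.
#' @return Tibble with columns `intron`, `type` (`"donor"`/`"acceptor"`),
#'   `start`, `end` (0-based half-open genomic 2-bp intervals).
#' @export
splice_sites <- function(tx) {
  ne <- nrow(tx$exons)
  if (ne < 2) {
    return(tibble(intron = integer(), type = character(),
                  start = integer(), end = integer()))
  }
  int_start <- tx$exons$end[-ne]
  int_end <- tx$exons$start[-1]
  low <- tibble(intron = seq_len(ne - 1L), start = int_start,
                end = int_start + 2L)
  high <- tibble(intron = seq_len(ne - 1L), start = int_end - 2L,
                 end = int_end)
  if (tx$strand == "+") {
    low$type <- "donor"; high$type <- "acceptor"
  } else {
    low$type <- "acceptor"; high$type <- "donor"
  }
  arrange(bind_rows(low, high)[, c("intron", "type", "start", "end")],
          .data$intron, .data$start)
}

# 0-based genomic position -> 0-based index into the spliced CDS, NA if intronic
genomic_to_cds <- function(tx, pos0) {
  ex <- tx$exons
  cum <- cumsum(c(0L, ex$end - ex$start))
  hit <- which(pos0 >= ex$start & pos0 < ex$end)
  if (length(hit) == 0) return(NA_integer_)
  idx_plus <- cum[hit] + (pos0 - ex$start[hit])
  if (tx$strand == "+") as.integer(idx_plus)
  else as.integer(sum(ex$end - ex$start) - 1L - idx_plus)
}

# inverse of genomic_to_cds
cds_to_genomic <- function(tx, idx0) {
  ex <- tx$exons
  total <- sum(ex$end - ex$start)
  stopifnot(idx0 >= 0, idx0 < total)
  idx_plus <- if (tx$strand == "+") idx0 else total - 1L - idx0
  cum <- cumsum(c(0L, ex$end - ex$start))
  hit <- max(which(cum <= idx_plus))
  as.integer(ex$start[hit] + (idx_plus - cum[hit]))
}

#' Write transcript models as BED12
#'
#' One line per transcript; the name field is `gene:tx_id`. Coordinates are
#' written 0-based half-open as BED requires.
#'
#' @param transcripts List of `transcript_model` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(transcripts, path) {
  lines <- purrr::map_chr(transcripts, function(tx) {
    span <- tx_span(tx)
    sizes <- paste0(paste(tx$exons$end - tx$exons$start, collapse = ","), ",")
    starts <- paste0(paste(tx$exons$start - span[1], collapse = ","), ",")
    paste(tx$chrom, span[1], span[2], paste0(tx$gene, ":", tx$tx_id), 0,
          tx$strand, span[1], span[2], "0,0,0", nrow(tx$exons), sizes, starts,
          sep = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Write transcript models as GFF3
#'
#' Emits `mRNA` and `exon` features (1-based closed coordinates) with
#' `ID`/`Parent` attributes and a `gene_id` attribute on the mRNA.
#'
#' @inheritParams write_bed12
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(transcripts, path) {
  rows <- purrr::map(transcripts, function(tx) {
    span <- tx_span(tx)
    mrna <- sprintf("%s\tlohtarget\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;gene_id=%s",
                    tx$chrom, span[1] + 1L, span[2], tx$strand, tx$tx_id, tx$gene)
    ex <- sprintf("%s\tlohtarget\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
                  tx$chrom, tx$exons$start + 1L, tx$exons$end, tx$strand,
                  tx$tx_id, seq_len(nrow(tx$exons)), tx$tx_id)
    c(mrna, ex)
  })
  writeLines(c("##gff-version 3", unlist(rows)), path)
  invisible(path)
}

#' Read transcript models from BED12 or GFF3
#'
#' The format is auto-detected from the file extension (`.bed` vs
#' `.gff`/`.gff3`). BED blocks or GFF3 exon features become exons; splice
#' dinucleotides are derived, not read. CDS sequences can be attached from a
#' FASTA whose headers are transcript IDs.
#'
#' @param path Transcript file (BED12 or GFF3).
#' @param cds_fasta Optional FASTA of spliced CDS sequences, headers matching
#'   transcript IDs.
#' @return Named list of `transcript_model` objects (names = transcript IDs).
#' @export
read_transcripts <- function(path, cds_fasta = NULL) {
  if (!file.exists(path)) abort(sprintf("transcript file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  txs <- if (ext == "bed") read_transcripts_bed12(path)
         else if (ext %in% c("gff", "gff3")) read_transcripts_gff3(path)
         else abort(sprintf("unsupported transcript format: .%s", ext))
  if (!is.null(cds_fasta)) {
    seqs <- Biostrings::readDNAStringSet(cds_fasta)
    nm <- sub("\\s.*$", "", names(seqs))
    for (i in seq_along(txs)) {
      j <- match(txs[[i]]$tx_id, nm)
      if (!is.na(j)) {
        txs[[i]]$cds_sequence <- as.character(seqs[[j]])
        if (nchar(txs[[i]]$cds_sequence) %% 3L != 0L) {
          abort(sprintf("CDS of '%s' not divisible by 3", txs[[i]]$tx_id))
        }
      }
    }
  }
  txs
}

read_transcripts_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  txs <- purrr::map(seq_along(gr), function(i) {
    g <- gr[i]
    blocks <- S4Vectors::mcols(g)$blocks[[1]]
    # blocks are 1-based closed relative to chromStart+1
    chrom_start <- BiocGenerics::start(g) - 1L  # back to 0-based
    ex <- tibble(start = chrom_start + BiocGenerics::start(blocks) - 1L,
                 end = chrom_start + BiocGenerics::end(blocks))
    nm <- S4Vectors::mcols(g)$name
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    gene <- parts[1]
    tx_id <- if (length(parts) > 1) parts[2] else parts[1]
    transcript_model(gene = gene, tx_id = tx_id,
                     chrom = as.character(GenomeInfoDb::seqnames(g)),
                     strand = as.character(BiocGenerics::strand(g)),
                     exons = ex)
  })
  setNames(txs, purrr::map_chr(txs, "tx_id"))
}

read_transcripts_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ftype <- as.character(S4Vectors::mcols(gr)$type)
  mrna <- gr[ftype %in% c("mRNA", "transcript")]
  exons <- gr[ftype == "exon"]
  txs <- purrr::map(seq_along(mrna), function(i) {
    m <- mrna[i]
    id <- S4Vectors::mcols(m)$ID
    gene <- S4Vectors::mcols(m)$gene_id %||% id
    parent <- purrr::map_chr(as.list(S4Vectors::mcols(exons)$Parent),
                             function(p) if (length(p)) p[[1]] else NA_character_)
    ex_gr <- exons[parent == id]
    ex <- tibble(start = BiocGenerics::start(ex_gr) - 1L,
                 end = BiocGenerics::end(ex_gr))
    transcript_model(gene = as.character(gene), tx_id = as.character(id),
                     chrom = as.character(GenomeInfoDb::seqnames(m)),
                     strand = as.character(BiocGenerics::strand(m)),
                     exons = ex)
  })
  setNames(txs, purrr::map_chr(txs, "tx_id"))
}

#' Write spliced CDS sequences to FASTA
#'
#' @param transcripts List of `transcript_model` objects with available CDS.
#' @param path Output FASTA.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(transcripts, path) {
  seqs <- purrr::map_chr(transcripts, function(tx) {
    cds <- cds_sequence(tx)
    if (is.null(cds)) abort(sprintf("no CDS available for '%s'", tx$tx_id))
    cds
  })
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- purrr::map_chr(transcripts, "tx_id")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# group a transcript list by gene -> named list of lists
transcripts_by_gene <- function(transcripts) {
  genes <- purrr::map_chr(transcripts, "gene")
  split(transcripts, genes)
}
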