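# Plain-text readers/writers for the package's tabular interchange formats.
# Annotation and read tables are TSV with "." for absent fields; sequences
# travel as FASTA via Biostrings.

dot_na <- function(x) ifelse(is.na(x), ".", as.character(x))
undot <- function(x, as = as.integer) ifelse(x == ".", NA, x) %>% as()

#' Write transcript sequences as FASTA
#'
#' @param genes Transcriptome tibble with `gene_id` and `sequence`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_transcriptome_fasta <- function(genes, path) {
  seqs <- Biostrings::DNAStringSet(genes$sequence)
  names(seqs) <- genes$gene_id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read transcript sequences from FASTA
#'
#' @param path FASTA file.
#' @return A tibble `gene_id`, `sequence`.
#' @export
read_transcriptome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  tibble::tibble(gene_id = names(seqs),
                 sequence = unname(as.character(seqs)))
}

#' Write/read the BED-like annotation table
#'
#' Columns: transcript_id, length, cds_start, cds_end, coding_flag,
#' intron_start, intron_end, family_id; 0-based half-open coordinates;
#' "." marks absent fields.
#'
#' @param genes Transcriptome/annotation tibble.
#' @param path File path.
#' @return `path` invisibly (writer); annotation tibble (reader).
#' @export
write_annotation <- function(genes, path) {
  out <- tibble::tibble(
    transcript_id = genes$gene_id,
    length = genes$length,
    cds_start = genes$cds_start,
    cds_end = genes$cds_end,
    coding_flag = as.integer(genes$coding),
    intron_start = dot_na(genes$intron_start),
    intron_end = dot_na(genes$intron_end),
    family_id = dot_na(genes$family_id))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  tibble::tibble(
    gene_id = df$transcript_id,
    length = as.integer(df$length),
    cds_start = as.integer(df$cds_start),
    cds_end = as.integer(df$cds_end),
    coding = as.integer(df$coding_flag) == 1L,
    intron_start = undot(df$intron_start),
    intron_end = undot(df$intron_end),
    family_id = undot(df$family_id, as.character))
}

#' Write/read annotation as GFF3
#'
#' Transcript-space GFF3: one `mRNA` (or `ncRNA`) feature per transcript on
#' its own seqid, with child `CDS` and `intron` features.  Coordinates are
#' converted between the package's 0-based half-open convention and GFF3's
#' 1-based closed intervals.
#'
#' @param genes Annotation tibble.
#' @param path File path.
#' @return `path` invisibly (writer); annotation tibble (reader).
#' @export
write_annotation_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    type <- if (g$coding) "mRNA" else "ncRNA"
    attrs <- sprintf("ID=%s", g$gene_id)
    if (!is.na(g$family_id)) attrs <- paste0(attrs, ";family_id=", g$family_id)
    lines <- c(lines, paste(g$gene_id, "riboage", type, 1, g$length, ".",
                            "+", ".", attrs, sep = "\t"))
    if (g$coding) {
      lines <- c(lines, paste(g$gene_id, "riboage", "CDS", g$cds_start + 1L,
                              g$cds_end, ".", "+", "0",
                              sprintf("ID=%s.cds;Parent=%s", g$gene_id,
                                      g$gene_id), sep = "\t"))
    }
    if (!is.na(g$intron_start)) {
      lines <- c(lines, paste(g$gene_id, "riboage", "intron",
                              g$intron_start + 1L, g$intron_end, ".", "+",
                              ".", sprintf("ID=%s.intron;Parent=%s",
                                           g$gene_id, g$gene_id),
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_annotation_gff3
#' @export
read_annotation_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("read_annotation_gff3() requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- tibble::as_tibble(as.data.frame(gr))
  tx <- dplyr::filter(df, .data$type %in% c("mRNA", "ncRNA"))
  cds <- dplyr::filter(df, .data$type == "CDS")
  intr <- dplyr::filter(df, .data$type == "intron")
  ids <- as.character(tx$ID)
  key <- as.character(tx$seqnames)
  fam <- if ("family_id" %in% names(tx)) as.character(tx$family_id) else
    rep(NA_character_, nrow(tx))
  tibble::tibble(
    gene_id = ids,
    length = as.integer(tx$end),
    cds_start = as.integer(cds$start[match(key,
                                           as.character(cds$seqnames))]) - 1L,
    cds_end = as.integer(cds$end[match(key, as.character(cds$seqnames))]),
    coding = tx$type == "mRNA",
    intron_start = as.integer(
      intr$start[match(key, as.character(intr$seqnames))]) - 1L,
    intron_end = as.integer(
      intr$end[match(key, as.character(intr$seqnames))]),
    family_id = fam) %>%
    dplyr::mutate(
      cds_start = ifelse(.data$coding, .data$cds_start, 0L),
      cds_end = ifelse(.data$coding, .data$cds_end, .data$length))
}

#' Write/read aligned reads in the package TSV dialect
#'
#' Columns: transcript_id, five_prime (0-based), length, sample_id, assay,
#' spans_intron_junction (0/1).
#'
#' @param reads Read tibble.
#' @param path File path.
#' @return `path` invisibly (writer); read tibble (reader).
#' @export
write_reads <- function(reads, path) {
  out <- dplyr::mutate(reads,
    spans_intron_junction = as.integer(.data$spans_intron_junction))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_reads
#' @export
read_reads <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    transcript_id = "c", five_prime = "i", length = "i",
    sample_id = "c", assay = "c", spans_intron_junction = "i")) %>%
    dplyr::mutate(spans_intron_junction = .data$spans_intron_junction == 1L)
}

#' Emit reads as transcript-space SAM
#'
#' Minimal unspliced SAM records against the transcript sequences: POS is
#' 1-based per the SAM spec, CIGAR is full-length match, sequences are
#' taken from the transcript (or `*` when absent).  Junction-flagged reads
#' are skipped (their transcript-space interval is not contiguous).
#'
#' @param reads Read tibble.
#' @param genes Transcriptome tibble (needs `gene_id`, `length`; `sequence`
#'   optional).
#' @param path Output SAM file.
#' @return `path`, invisibly.
#' @export
write_reads_sam <- function(reads, genes, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", genes$gene_id, genes$length))
  reads <- dplyr::filter(reads, !.data$spans_intron_junction)
  seq_of <- if ("sequence" %in% names(genes)) {
    stats::setNames(genes$sequence, genes$gene_id)
  } else NULL
  seqs <- if (is.null(seq_of)) rep("*", nrow(reads)) else {
    substr(seq_of[reads$transcript_id], reads$five_prime + 1L,
           reads$five_prime + reads$length)
  }
  body <- sprintf("r%06d\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                  seq_len(nrow(reads)), reads$transcript_id,
                  reads$five_prime + 1L, reads$length, seqs)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write/read the ground-truth table
#'
#' @param truth Truth tibble from [simulate_truth()].
#' @param path File path.
#' @return `path` invisibly (writer); truth tibble (reader).
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", condition = "c", baseline = "d", txn_log2fc = "d",
    te_log2fc = "d", te_class = "c"))
}

#' Write/read an offset table
#'
#' @param offsets Offset tibble (`length`, `offset`, `provenance`).
#' @param path File path.
#' @return `path` invisibly (writer); offset tibble (reader).
#' @export
write_offsets <- function(offsets, path) {
  readr::write_tsv(as_offset_table(offsets), path)
  invisible(path)
}

#' @rdname write_offsets
#' @export
read_offsets <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    length = "i", offset = "i", .default = "c"))
}

#' Write/read a gene x sample count table
#'
#' @param counts A `count_table`.
#' @param path File path.
#' @return `path` invisibly (writer); `count_table` (reader).
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(tibble::as_tibble(counts), path)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", .default = "i"))
  new_count_table(df)
}

#' Write/read a sample design sheet
#'
#' @param design Design tibble.
#' @param path File path.
#' @return `path` invisibly (writer); design tibble (reader).
#' @export
write_design <- function(design, path) {
  readr::write_tsv(design, path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", assay = "c", condition = "c", replicate = "i",
    .default = "d"))
}
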