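# Gene x sample count tables: a wide tibble (gene_id + one column per
# sample) with the sample design and a per-sample read-accounting sidecar
# stored as attributes.

new_count_table <- function(tbl, design = NULL, sidecar = NULL) {
  structure(tbl, class = unique(c("count_table", class(tbl))),
            design = design, sidecar = sidecar)
}

#' Extract the numeric matrix from a count table
#'
#' @param counts A `count_table` (or any gene-by-sample wide tibble whose
#'   first column is `gene_id`).
#' @return An integer matrix with gene ids as rownames.
#' @export
count_matrix <- function(counts) {
  m <- as.matrix(counts[, setdiff(names(counts), "gene_id"), drop = FALSE])
  rownames(m) <- counts$gene_id
  storage.mode(m) <- "double"
  m
}

#' Read-accounting sidecar of a count table
#'
#' Per-sample tallies of where every input read went: `ncrna_filtered`,
#' `no_offset_length`, `outside_cds`, `edge_excluded`, `counted`.  These
#' categories partition the input reads exactly.
#'
#' @param counts A `count_table` from [count_cds()].
#' @return The sidecar tibble (or NULL when counts were simulated directly).
#' @export
sidecar <- function(counts) attr(counts, "sidecar")

#' Remove reads mapped to non-coding transcripts
#'
#' @param reads Read tibble.
#' @param genes Annotation tibble; every read's transcript must be present.
#' @return The reads on coding transcripts, with attribute `n_removed`
#'   holding the number filtered out.
#' @export
filter_ncrna <- function(reads, genes) {
  unknown <- setdiff(unique(reads$transcript_id), genes$gene_id)
  if (length(unknown)) {
    abort(sprintf("reads reference unknown transcript(s): %s",
                  paste(sort(unknown), collapse = ", ")))
  }
  coding_ids <- genes$gene_id[genes$coding]
  keep <- reads$transcript_id %in% coding_ids
  out <- reads[keep, ]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Count A-sites per gene with edge-codon exclusion
#'
#' Assigns each read to the transcript position `five_prime + offset` (the
#' first nucleotide of the A-site codon for Ribo-seq; a fixed 15-nt offset
#' for RNA-Seq) and counts it for its gene when that site lies within the
#' CDS and outside the first and last `exclude_codons` codons.  Reads on
#' non-coding transcripts, reads of a length with no defined offset, sites
#' outside the CDS, and sites on excluded edge codons are each tallied to a
#' sidecar category, so the categories partition the input exactly.
#'
#' @param reads Read tibble; rows of other assays are ignored if an `assay`
#'   column is present.
#' @param genes Annotation tibble.
#' @param offsets Offset table; defaults to [rna_offsets()] when
#'   `assay = "rna"`, otherwise required.
#' @param assay `"ribo"` or `"rna"`.
#' @param exclude_codons Number of codons masked at each CDS edge
#'   (default 5).
#' @param samples Optional sample ordering; defaults to sorted unique
#'   sample ids in `reads`.
#' @return A `count_table` tibble (one row per coding gene, one column per
#'   sample) with the accounting sidecar attached; see [sidecar()].
#' @export
count_cds <- function(reads, genes, offsets = NULL,
                      assay = c("ribo", "rna"), exclude_codons = 5L,
                      samples = NULL) {
  assay <- match.arg(assay)
  if (length(exclude_codons) != 1 || is.na(exclude_codons) ||
      exclude_codons < 0) {
    abort("`exclude_codons` must be a non-negative integer")
  }
  exclude_codons <- as.integer(exclude_codons)
  if (is.null(offsets)) {
    if (assay == "rna") offsets <- rna_offsets() else
      abort("`offsets` is required for assay = \"ribo\"")
  }
  if ("assay" %in% names(reads)) {
    reads <- dplyr::filter(reads, .data$assay == .env$assay)
  }
  unknown <- setdiff(unique(reads$transcript_id), genes$gene_id)
  if (length(unknown)) {
    abort(sprintf("reads reference unknown transcript(s): %s",
                  paste(sort(unknown), collapse = ", ")))
  }
  coding <- dplyr::filter(genes, .data$coding)
  n_codons <- (coding$cds_end - coding$cds_start) %/% 3L
  short <- coding$gene_id[n_codons < 2L * exclude_codons + 1L]
  if (length(short)) {
    warn(sprintf(
      "gene(s) with CDS shorter than %d codons are fully edge-excluded: %s",
      2L * exclude_codons + 1L, paste(short, collapse = ", ")))
  }
  samples <- samples %||% sort(unique(reads$sample_id))

  gi <- match(reads$transcript_id, coding$gene_id)   # NA for non-coding
  off <- lookup_offsets(reads$length, offsets)
  site <- reads$five_prime + off
  cds_s <- coding$cds_start[gi]
  cds_e <- coding$cds_end[gi]
  codon <- (site - cds_s) %/% 3L
  ncod <- n_codons[gi]

  category <- dplyr::case_when(
    is.na(gi) ~ "ncrna_filtered",
    is.na(off) ~ "no_offset_length",
    site < cds_s | site >= cds_e ~ "outside_cds",
    codon < exclude_codons | codon > ncod - 1L - exclude_codons ~
      "edge_excluded",
    TRUE ~ "counted")

  counted <- tibble::tibble(gene_id = coding$gene_id[gi],
                            sample_id = reads$sample_id)[
                              category == "counted", ]
  wide <- counted %>%
    dplyr::count(.data$gene_id, .data$sample_id) %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "n",
                       values_fill = 0L)
  out <- tibble::tibble(gene_id = coding$gene_id) %>%
    dplyr::left_join(wide, by = "gene_id")
  for (s in samples) if (!s %in% names(out)) out[[s]] <- 0L
  out <- out[, c("gene_id", samples)]
  out <- dplyr::mutate(out, dplyr::across(-"gene_id",
                                          ~ as.integer(dplyr::coalesce(., 0L))))

  side <- tibble::tibble(sample_id = reads$sample_id, category = category) %>%
    dplyr::count(.data$sample_id, .data$category) %>%
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L)
  for (cat in c("ncrna_filtered", "no_offset_length", "outside_cds",
                "edge_excluded", "counted")) {
    if (!cat %in% names(side)) side[[cat]] <- 0L
  }
  side <- side %>%
    dplyr::mutate(total = .data$ncrna_filtered + .data$no_offset_length +
                    .data$outside_cds + .data$edge_excluded + .data$counted) %>%
    dplyr::select("sample_id", "total", "ncrna_filtered", "no_offset_length",
                  "outside_cds", "edge_excluded", "counted")
  new_count_table(out, sidecar = side)
}

#' Count intron-containing and junction-spanning reads for one gene
#'
#' `intron_containing` counts reads that are not junction-flagged and meet
#' the intron rule: overlap of at least 1 nt with the intron interval
#' (`mode = "overlap"`, the default) or full containment of the read within
#' the intron (`mode = "contained"`).  `junction_spanning` counts reads
#' flagged `spans_intron_junction` (spliced-template reads crossing the
#' junction).  All intervals are 0-based half-open, so a read abutting the
#' intron start does not overlap it.
#'
#' @param reads Read tibble.
#' @param genes Annotation tibble.
#' @param gene_id Gene to quantify; must carry an intron. Defaults to the
#'   single intron-bearing gene in `genes`.
#' @param mode Intron rule, `"overlap"` or `"contained"`.
#' @return A tibble `sample_id`, `intron_containing`, `junction_spanning`.
#' @export
count_intron_reads <- function(reads, genes, gene_id = NULL,
                               mode = c("overlap", "contained")) {
  mode <- match.arg(mode)
  with_intron <- genes$gene_id[!is.na(genes$intron_start)]
  gene_id <- gene_id %||% {
    if (length(with_intron) != 1) {
      abort("specify `gene_id`: annotation has no unique intron-bearing gene")
    }
    with_intron
  }
  g <- genes[genes$gene_id == gene_id, ]
  if (nrow(g) != 1 || is.na(g$intron_start)) {
    abort(sprintf("gene '%s' has no annotated intron", gene_id))
  }
  df <- dplyr::filter(reads, .data$transcript_id == .env$gene_id)
  if (!"spans_intron_junction" %in% names(df)) {
    df$spans_intron_junction <- FALSE
  }
  df$spans_intron_junction[is.na(df$spans_intron_junction)] <- FALSE
  hit <- if (mode == "overlap") {
    interval_overlap(df$five_prime, df$five_prime + df$length,
                     g$intron_start, g$intron_end) >= 1L
  } else {
    df$five_prime >= g$intron_start & df$five_prime + df$length <= g$intron_end
  }
  df$.hit <- hit
  df %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::summarise(
      intron_containing = sum(.data$.hit & !.data$spans_intron_junction),
      junction_spanning = sum(.data$spans_intron_junction),
      .groups = "drop")
}

#' Reading-frame composition of A-sites in a transcript window
#'
#' Used to verify programmed frameshifts: A-sites are computed from
#' `five_prime + offset`, restricted to `[window[1], window[2])`, and their
#' frames reported relative to `anchor` (default: the gene's CDS start, so
#' a +1 frameshift downstream of the shift site shows up as dominant
#' frame 1).
#'
#' @inheritParams count_intron_reads
#' @param offsets Offset table.
#' @param window 0-based half-open transcript interval.
#' @param anchor Reference position defining frame 0; defaults to the
#'   gene's `cds_start`.
#' @return A tibble `frame`, `n`, `fraction` (frames 0..2 always present).
#' @export
frame_in_window <- function(reads, genes, gene_id, offsets, window,
                            anchor = NULL) {
  if (length(window) != 2 || window[1] >= window[2]) {
    abort("`window` must be a non-empty half-open interval")
  }
  g <- genes[genes$gene_id == gene_id, ]
  if (nrow(g) != 1) abort(sprintf("unknown gene '%s'", gene_id))
  if (window[1] < 0 || window[2] > g$length) {
    abort("`window` must lie within the transcript")
  }
  anchor <- anchor %||% g$cds_start
  df <- dplyr::filter(reads, .data$transcript_id == .env$gene_id)
  off <- lookup_offsets(df$length, offsets)
  a_site <- df$five_prime + off
  keep <- !is.na(a_site) & a_site >= window[1] & a_site < window[2]
  frames <- (a_site[keep] - anchor) %% 3L
  out <- tibble::tibble(frame = 0:2,
                        n = as.integer(tabulate(frames + 1L, nbins = 3L)))
  out$fraction <- if (sum(out$n) > 0) out$n / sum(out$n) else rep(NA_real_, 3)
  out
}
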