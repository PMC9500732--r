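#' Majority-rule consensus from a multiple sequence alignment
#'
#' Columns whose gap fraction exceeds `max_gap_frac` are dropped; every
#' retained column emits its modal non-gap base.  Ties go to the
#' lexicographically smallest base, except that `N` never wins a tie against
#' a concrete base (A/C/G/T).  The alignment itself is an input — typically
#' the output of an external aligner over a repeat family — and must be
#' flush (all rows the same length; alphabet A, C, G, T, N, `-`).
#'
#' @param aln Named character vector of aligned sequences, or a
#'   `Biostrings::DNAStringSet` (gaps as `-`).
#' @param max_gap_frac Columns with a gap fraction strictly above this are
#'   dropped (default 0.5).
#' @return The consensus sequence as a single string; attribute `columns`
#'   holds the 1-based indices of the retained alignment columns.
#' @export
#' @examples
#' consensus_from_msa(c(a = "ACGT", b = "ACGA", c = "ACG-"))
consensus_from_msa <- function(aln, max_gap_frac = 0.5) {
  if (methods::is(aln, "DNAStringSet")) aln <- as.character(aln)
  aln <- toupper(as.character(aln))
  if (length(aln) < 2) abort("consensus needs at least 2 aligned sequences")
  widths <- nchar(aln)
  if (length(unique(widths)) != 1) {
    abort("ragged alignment: rows have differing lengths")
  }
  mat <- do.call(rbind, strsplit(aln, ""))
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad)) {
    abort(sprintf("alignment contains invalid symbol(s): %s",
                  paste(bad, collapse = ", ")))
  }
  keep <- logical(ncol(mat))
  out <- character(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    if (mean(col == "-") > max_gap_frac) next
    tab <- table(col[col != "-"])
    top <- names(tab)[tab == max(tab)]
    concrete <- setdiff(top, "N")
    out[j] <- if (length(concrete)) sort(concrete)[1] else "N"
    keep[j] <- TRUE
  }
  structure(paste(out[keep], collapse = ""), columns = which(keep))
}

#' Count A-sites per ORF of an overlapping ORF pair
#'
#' Partitions A-sites (`five_prime + offset`) on a consensus transcript into
#' ORF-A-only, ORF-B-only, the ORF overlap, and outside.  With
#' `exclude_overlap = TRUE` (default) overlap A-sites are excluded from both
#' ORF counts and reported in `overlap_excluded`, so `orf_a + orf_b +
#' overlap_excluded + outside + no_offset` equals the number of input reads
#' per sample.  With `exclude_overlap = FALSE` the overlap is credited to
#' both ORFs (and still reported).
#'
#' @param reads Read tibble aligned to the consensus transcript.
#' @param orf_a,orf_b 0-based half-open intervals on the consensus.
#' @param offsets Offset table.
#' @param exclude_overlap Mask the ORF intersection? Default TRUE.
#' @return A tibble per sample: `sample_id`, `orf_a`, `orf_b`,
#'   `overlap_excluded`, `outside`, `no_offset`, `total`.
#' @export
count_family <- function(reads, orf_a, orf_b, offsets,
                         exclude_overlap = TRUE) {
  ov <- c(max(orf_a[1], orf_b[1]), min(orf_a[2], orf_b[2]))
  has_ov <- ov[1] < ov[2]
  off <- lookup_offsets(reads$length, offsets)
  site <- reads$five_prime + off
  in_a <- !is.na(site) & site >= orf_a[1] & site < orf_a[2]
  in_b <- !is.na(site) & site >= orf_b[1] & site < orf_b[2]
  in_ov <- if (has_ov) in_a & in_b else rep(FALSE, length(site))
  cat <- tibble::tibble(
    sample_id = reads$sample_id,
    no_offset = is.na(site),
    orf_a = in_a & (!exclude_overlap | !in_ov),
    orf_b = in_b & (!exclude_overlap | !in_ov),
    overlap = in_ov,
    outside = !is.na(site) & !in_a & !in_b)
  cat %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::summarise(orf_a = sum(.data$orf_a), orf_b = sum(.data$orf_b),
                     overlap_excluded = sum(.data$overlap),
                     outside = sum(.data$outside),
                     no_offset = sum(.data$no_offset),
                     total = dplyr::n(), .groups = "drop")
}

#' Relabel element-family reads onto the family consensus
#'
#' Synthetic family copies are indel-free point mutants of one ancestor, so
#' copy coordinates and consensus coordinates coincide; mapping family reads
#' to the consensus reduces to reassigning their transcript id.
#'
#' @param reads Read tibble.
#' @param genes Annotation tibble (uses `family_id`).
#' @param family_id Family to project (default: the single family present).
#' @param consensus_id Transcript id given to projected reads.
#' @return The reads of the family, relabelled to `consensus_id`.
#' @export
project_family_reads <- function(reads, genes, family_id = NULL,
                                 consensus_id = "consensus") {
  fams <- unique(genes$family_id[!is.na(genes$family_id)])
  family_id <- family_id %||% {
    if (length(fams) != 1) abort("specify `family_id`")
    fams
  }
  members <- genes$gene_id[!is.na(genes$family_id) &
                             genes$family_id == family_id]
  out <- dplyr::filter(reads, .data$transcript_id %in% members)
  out$transcript_id <- consensus_id
  out
}
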