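#' Footprint length histogram
#'
#' @param reads Read tibble (needs a `length` column).
#' @return A tibble with columns `length` and `n`, one row per observed
#'   length, sorted by length.  Empty input gives an empty tibble.
#' @export
length_histogram <- function(reads) {
  if (nrow(reads) == 0) {
    return(tibble::tibble(length = integer(), n = integer()))
  }
  reads %>%
    dplyr::count(.data$length) %>%
    dplyr::arrange(.data$length)
}

#' 5'-end metagene profile around the start or stop codon
#'
#' Tallies, per footprint length, the signed position of each read's 5' end
#' relative to the anchor: position 0 is the first nucleotide of the start
#' codon (`anchor = "start"`) or of the stop codon (`anchor = "stop"`).
#' Only reads on coding transcripts contribute; reads outside `window` are
#' tallied separately so that mass is conserved.
#'
#' @param reads Read tibble (`transcript_id`, `five_prime`, `length`).
#' @param genes Annotation tibble with `gene_id`, `cds_start`, `cds_end`,
#'   `coding`.
#' @param anchor `"start"` or `"stop"`.
#' @param window Signed integer pair, inclusive bounds of the tallied
#'   positions.
#' @return A `metagene_profile` tibble (`length`, `position`, `count`) with
#'   every in-window position present (zero-filled).  Attributes: `anchor`,
#'   `window`, `n_reads` (reads considered), `out_of_window`.
#' @export
metagene_profile <- function(reads, genes, anchor = c("start", "stop"),
                             window = c(-30L, 30L)) {
  anchor <- match.arg(anchor)
  if (window[1] > window[2]) abort("`window` bounds must be ordered")
  assert_cols(genes, c("gene_id", "cds_start", "cds_end", "coding"),
              "annotation")
  coding <- genes %>%
    dplyr::filter(.data$coding) %>%
    dplyr::select("gene_id", "cds_start", "cds_end")
  df <- dplyr::inner_join(reads, coding, by = c(transcript_id = "gene_id"))
  anchor_pos <- if (anchor == "start") df$cds_start else df$cds_end - 3L
  pos <- df$five_prime - anchor_pos
  inside <- pos >= window[1] & pos <= window[2]
  tallied <- tibble::tibble(length = df$length[inside], position = pos[inside])
  grid <- tidyr::expand_grid(length = sort(unique(df$length)),
                             position = seq.int(window[1], window[2]))
  prof <- tallied %>%
    dplyr::count(.data$length, .data$position, name = "count") %>%
    dplyr::right_join(grid, by = c("length", "position")) %>%
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) %>%
    dplyr::arrange(.data$length, .data$position)
  structure(prof,
            class = c("metagene_profile", class(prof)),
            anchor = anchor, window = window,
            n_reads = nrow(df), out_of_window = sum(!inside))
}

#' Calibrate A-site offsets from the initiation peak
#'
#' At initiation the ribosome sits with its P-site on the AUG and its A-site
#' on codon 2, i.e. +3 nt from the start.  The dominant 5'-end peak of a
#' footprint length at signed position `p*` upstream of the start codon
#' therefore implies an A-site offset of `3 - p*` (e.g. a peak at -12 gives
#' offset 15; at -10, offset 13).  The peak is searched within
#' `search_window`; ties are broken toward the smaller `|p*|`, then the
#' smaller `p*`.
#'
#' @param profile A start-anchored [metagene_profile()].
#' @param lengths Footprint lengths to calibrate (default: all in profile).
#' @param search_window Signed interval searched for the peak.
#' @param min_reads Minimum reads per length; lengths below it are omitted
#'   with a warning.
#' @return An offset table tibble: `length`, `offset`,
#'   `provenance = "calibrated"`, `peak_position`, `n_reads`.
#' @export
calibrate_offsets <- function(profile, lengths = NULL,
                              search_window = c(-18L, -6L),
                              min_reads = 500L) {
  if (!inherits(profile, "metagene_profile") ||
      !identical(attr(profile, "anchor"), "start")) {
    abort("`profile` must be a start-anchored metagene_profile")
  }
  if (nrow(profile) == 0 || sum(profile$count) == 0) {
    abort("empty metagene profile: nothing to calibrate")
  }
  lengths <- lengths %||% sort(unique(profile$length))
  rows <- purrr::map(lengths, function(l) {
    sub <- dplyr::filter(profile, .data$length == l)
    n_l <- sum(sub$count)
    if (n_l < min_reads) {
      warn(sprintf("length %d: %d reads < min_reads = %d; omitted",
                   l, n_l, min_reads))
      return(NULL)
    }
    win <- dplyr::filter(sub, .data$position >= search_window[1],
                         .data$position <= search_window[2])
    if (nrow(win) == 0 || sum(win$count) == 0) {
      warn(sprintf("length %d: no reads in search window; omitted", l))
      return(NULL)
    }
    win <- dplyr::arrange(win, dplyr::desc(.data$count),
                          abs(.data$position), .data$position)
    p_star <- win$position[1]
    tibble::tibble(length = l, offset = 3L - p_star,
                   provenance = "calibrated",
                   peak_position = p_star, n_reads = n_l)
  })
  proto <- tibble::tibble(length = integer(), offset = integer(),
                          provenance = character(),
                          peak_position = integer(), n_reads = integer())
  dplyr::bind_rows(proto, rows)
}

#' Reading-frame report over A-sites
#'
#' Translates each read 5' end to its A-site (`five_prime + offset`) and,
#' for A-sites strictly inside the CDS of a coding transcript, tallies the
#' frame `(a_site - cds_start) mod 3` per footprint length.  Reads whose
#' length has no offset are dropped with a warning.
#'
#' @inheritParams metagene_profile
#' @param offsets Offset table ([standard_offsets()], [calibrate_offsets()]
#'   output, or a named vector length -> offset).
#' @return A tibble `length`, `frame` (0/1/2), `n`, `fraction` with the
#'   three frames present for every length.  Attribute `empty` is TRUE when
#'   no read fell inside a CDS.
#' @export
frame_report <- function(reads, genes, offsets) {
  coding <- genes %>%
    dplyr::filter(.data$coding) %>%
    dplyr::select("gene_id", "cds_start", "cds_end")
  df <- dplyr::inner_join(reads, coding, by = c(transcript_id = "gene_id"))
  off <- lookup_offsets(df$length, offsets)
  if (anyNA(off) && nrow(df) > 0) {
    dropped <- sort(unique(df$length[is.na(off)]))
    warn(sprintf("dropping reads of length(s) %s: no offset defined",
                 paste(dropped, collapse = ", ")))
  }
  keep <- !is.na(off)
  df <- df[keep, ]
  a_site <- df$five_prime + off[keep]
  in_cds <- a_site >= df$cds_start & a_site < df$cds_end
  df <- df[in_cds, ]
  a_site <- a_site[in_cds]
  if (nrow(df) == 0) {
    out <- tibble::tibble(length = integer(), frame = integer(),
                          n = integer(), fraction = double())
    attr(out, "empty") <- TRUE
    return(out)
  }
  out <- tibble::tibble(length = df$length,
                        frame = (a_site - df$cds_start) %% 3L) %>%
    dplyr::count(.data$length, .data$frame) %>%
    tidyr::complete(length = unique(df$length), frame = 0:2,
                    fill = list(n = 0L)) %>%
    dplyr::group_by(.data$length) %>%
    dplyr::mutate(fraction = .data$n / sum(.data$n)) %>%
    dplyr::ungroup()
  attr(out, "empty") <- FALSE
  out
}
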