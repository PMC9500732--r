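#' Published A-site offset table for yeast ribosome footprints
#'
#' Distance, in nt, from a footprint's 5' end to the first nucleotide of the
#' A-site codon, for the footprint lengths with a defined offset: 13 for
#' 26 nt, 14 for 27 nt, 15 for 21--22 nt and 28--29 nt, and 16 for
#' 30--31 nt.  These are the fixed offsets used when calibration is skipped
#' (`provenance = "fixed"`).
#'
#' @return A tibble with columns `length`, `offset` and `provenance`.
#' @seealso [calibrate_offsets()] for data-driven offsets,
#'   [rna_offsets()] for the RNA-Seq counterpart.
#' @export
#' @examples
#' standard_offsets()
standard_offsets <- function() {
  tibble::tibble(
    length = c(21L, 22L, 26L, 27L, 28L, 29L, 30L, 31L),
    offset = c(15L, 15L, 13L, 14L, 15L, 15L, 16L, 16L),
    provenance = "fixed"
  )
}

#' Fixed offset table for RNA-Seq fragments
#'
#' RNA-Seq fragments carry no ribosome, so a single fixed offset (15 nt by
#' convention) assigns every fragment to the transcript position 15 nt
#' downstream of its 5' end, regardless of fragment length.  The returned
#' table uses `length = NA` as a wildcard matching any read length.
#'
#' @param offset Offset in nt applied to every fragment length. Default 15.
#' @return A one-row tibble with columns `length` (NA wildcard), `offset`,
#'   `provenance`.
#' @export
rna_offsets <- function(offset = 15L) {
  tibble::tibble(length = NA_integer_, offset = as.integer(offset),
                 provenance = "fixed")
}

# Normalize an offset input (tibble with length/offset, or a named vector
# mapping length -> offset) into the tibble form used internally.
as_offset_table <- function(offsets) {
  if (is.data.frame(offsets)) {
    assert_cols(offsets, c("length", "offset"), "offset table")
    out <- tibble::as_tibble(offsets[, intersect(
      c("length", "offset", "provenance"), names(offsets))])
  } else if (is.numeric(offsets) && !is.null(names(offsets))) {
    out <- tibble::tibble(length = as.integer(names(offsets)),
                          offset = as.integer(unname(offsets)))
  } else {
    abort("offsets must be a data frame (length, offset) or a named vector")
  }
  if (!"provenance" %in% names(out)) out$provenance <- "fixed"
  bad <- !is.na(out$length) &
    (out$offset <= 0 | out$offset >= out$length)
  if (any(bad)) {
    abort(sprintf(
      "invalid offsets (must satisfy 0 < offset < length): lengths %s",
      paste(out$length[bad], collapse = ", ")))
  }
  out
}

# Map read lengths to offsets; NA-length rows act as a wildcard for any
# length.  Returns an integer vector with NA where no offset is defined.
lookup_offsets <- function(lengths, offsets) {
  offsets <- as_offset_table(offsets)
  wild <- offsets$offset[is.na(offsets$length)]
  spec <- offsets[!is.na(offsets$length), ]
  out <- spec$offset[match(lengths, spec$length)]
  if (length(wild)) out[is.na(out)] <- wild[1]
  out
}
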