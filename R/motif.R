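#' Locate the K-helix ExxR motif
#'
#' Scans a window of the sequence for the conserved E-x-x-R pattern of the
#' P450 K-helix and returns the first hit. In the canonical P450 fold the
#' K-helix follows the I-helix, so the default window starts just after
#' the end of SRS4 (when an annotation or projection is supplied) and runs
#' to the end of the sequence.
#'
#' @param record [protein_record()] to scan.
#' @param search_start,search_end 1-based closed window bounds; defaults
#'   derived from `srs` or the whole sequence.
#' @param srs Optional [srs_annotation()] or `srs_projection` on `record`;
#'   when given and `search_start` is missing, the window starts at
#'   SRS4 end + 1.
#' @return Object of class `motif_hit` with `sequence_id`, `pattern`
#'   ("ExxR"), `found` (logical), `start` (position of the E) and
#'   `matched` text. When no match exists, `found` is `FALSE` and `start`
#'   is `NA` -- an explicit miss rather than an error, so callers can
#'   degrade gracefully.
#' @examples
#' find_exxr(protein_record("x", "AAEKLRAA"))
#' @export
find_exxr <- function(record, search_start = NULL, search_end = NULL,
                      srs = NULL) {
  len <- record_length(record)
  if (is.null(search_start)) {
    search_start <- if (!is.null(srs)) {
      iv <- srs_intervals_of(srs, record$id)
      e4 <- iv$end[iv$label == "SRS4"]
      if (is.na(e4)) 1L else e4 + 1L
    } else 1L
  }
  if (is.null(search_end)) search_end <- len
  search_start <- max(1L, as.integer(search_start))
  search_end <- min(len, as.integer(search_end))
  miss <- structure(
    list(sequence_id = record$id, pattern = "ExxR", found = FALSE,
         start = NA_integer_, matched = NA_character_),
    class = "motif_hit"
  )
  if (search_end - search_start + 1L < 4L) return(miss)
  window <- substr(record$residues, search_start, search_end)
  m <- regexpr("E..R", window)
  if (m == -1L) return(miss)
  start <- search_start + as.integer(m) - 1L
  structure(
    list(sequence_id = record$id, pattern = "ExxR", found = TRUE,
         start = start,
         matched = substr(record$residues, start, start + 3L)),
    class = "motif_hit"
  )
}

#' @export
print.motif_hit <- function(x, ...) {
  if (x$found) {
    cat("<motif_hit> ", x$pattern, " in ", x$sequence_id, " at ",
        x$start, " (", x$matched, ")\n", sep = "")
  } else {
    cat("<motif_hit> ", x$pattern, " not found in ", x$sequence_id, "\n",
        sep = "")
  }
  invisible(x)
}
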