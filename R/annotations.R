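#' Substrate recognition site (SRS) annotations
#'
#' An `srs_annotation` records the six substrate recognition sites
#' (SRS1..SRS6) of a P450 sequence as closed 1-based residue intervals,
#' ordered along the sequence and non-overlapping.
#'
#' @param sequence_id Id of the annotated sequence.
#' @param starts,ends Integer vectors of length 6, 1-based inclusive, in
#'   SRS1..SRS6 order.
#' @param sequence_length Optional known length of the sequence; when given,
#'   intervals must not extend past it.
#' @return Object of class `srs_annotation` with fields `sequence_id` and
#'   `intervals` (a data.frame with columns `label`, `start`, `end`).
#' @export
srs_annotation <- function(sequence_id, starts, ends, sequence_length = NULL) {
  stopifnot(length(starts) == 6L, length(ends) == 6L)
  starts <- as.integer(starts)
  ends <- as.integer(ends)
  for (i in 1:6) {
    lab <- SRS_LABELS[i]
    if (is.na(starts[i]) || is.na(ends[i]) || starts[i] < 1L ||
        starts[i] > ends[i]) {
      stop(sequence_id, " ", lab, ": invalid interval [", starts[i], ", ",
           ends[i], "]", call. = FALSE)
    }
    if (i > 1L && starts[i] <= ends[i - 1L]) {
      stop(sequence_id, ": ", SRS_LABELS[i - 1L], " and ", lab,
           " overlap or are out of order", call. = FALSE)
    }
    if (!is.null(sequence_length) && ends[i] > sequence_length) {
      stop(sequence_id, " ", lab, ": end ", ends[i],
           " exceeds sequence length ", sequence_length, call. = FALSE)
    }
  }
  structure(
    list(sequence_id = sequence_id,
         intervals = data.frame(label = SRS_LABELS, start = starts,
                                end = ends, stringsAsFactors = FALSE)),
    class = "srs_annotation"
  )
}

#' Canonical SRS interval labels, in sequence order
#' @format Character vector of length 6: "SRS1".."SRS6".
#' @export
SRS_LABELS <- paste0("SRS", 1:6)

#' @export
print.srs_annotation <- function(x, ...) {
  cat("<srs_annotation> ", x$sequence_id, "\n", sep = "")
  print(x$intervals, row.names = FALSE)
  invisible(x)
}

#' Residues covered by each SRS interval
#' @param annotation An [srs_annotation()].
#' @return Named integer vector (SRS1..SRS6) of interval widths.
#' @export
srs_widths <- function(annotation) {
  with(annotation$intervals,
       stats::setNames(end - start + 1L, label))
}

#' Read SRS annotations from TSV
#'
#' Expects a tab-separated file with a header row and columns
#' `sequence_id`, `srs_label`, `start`, `end`; coordinates 1-based
#' inclusive. Every sequence must carry exactly the six labels SRS1..SRS6.
#'
#' @param path Path to the TSV file.
#' @param records Optional named list of [protein_record()]s used to check
#'   interval ends against sequence lengths.
#' @return Named list of [srs_annotation()] objects keyed by sequence id.
#' @export
read_srs_annotations <- function(path, records = NULL) {
  if (!file.exists(path)) {
    stop("annotation file not found: ", path, call. = FALSE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sequence_id", "srs_label", "start", "end")
  if (!all(need %in% names(tab))) {
    stop("annotation TSV must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  out <- lapply(split(tab, tab$sequence_id), function(d) {
    missing <- setdiff(SRS_LABELS, d$srs_label)
    if (length(missing) > 0L) {
      stop(d$sequence_id[1], ": missing ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    extra <- setdiff(d$srs_label, SRS_LABELS)
    if (length(extra) > 0L || nrow(d) != 6L) {
      stop(d$sequence_id[1], ": unexpected or duplicated SRS labels",
           call. = FALSE)
    }
    d <- d[match(SRS_LABELS, d$srs_label), ]
    len <- if (!is.null(records) && d$sequence_id[1] %in% names(records)) {
      record_length(records[[d$sequence_id[1]]])
    }
    srs_annotation(d$sequence_id[1], d$start, d$end, sequence_length = len)
  })
  out[unique(tab$sequence_id)]
}

#' Write SRS annotations to TSV
#' @param annotations Named list of [srs_annotation()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_srs_annotations <- function(annotations, path) {
  rows <- do.call(rbind, lapply(annotations, function(a) {
    data.frame(sequence_id = a$sequence_id, srs_label = a$intervals$label,
               start = a$intervals$start, end = a$intervals$end,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
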