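#' Project SRS intervals from an annotated reference onto a query
#'
#' Each reference SRS interval is carried through the alignment column map
#' to query coordinates. A reference boundary that lands on a query gap is
#' moved inward to the nearest aligned query residue (the projection
#' shrinks, never grows: residues outside the aligned region are never
#' claimed as SRS). An interval whose every column is gapped in the query
#' becomes empty with residue count 0.
#'
#' @param reference_annotation [srs_annotation()] on the reference.
#' @param alignment `pairwise_alignment` involving the reference and the
#'   query (either orientation).
#' @param query [protein_record()] for the query side.
#' @return Object of class `srs_projection`: fields `query_id`,
#'   `reference_id`, `intervals` (data.frame `label`, `start`, `end`,
#'   `residue_count`; `NA` start/end for an empty interval) and
#'   `total_residues`.
#' @export
project_srs <- function(reference_annotation, alignment, query) {
  ref_id <- reference_annotation$sequence_id
  ids <- c(alignment$id_a, alignment$id_b)
  if (!(ref_id %in% ids)) {
    stop("annotated sequence '", ref_id, "' absent from alignment ",
         ids[1], " vs ", ids[2], call. = FALSE)
  }
  aln <- orient_alignment(alignment, ref_id)
  if (aln$id_b != query$id) {
    stop("query '", query$id, "' absent from alignment", call. = FALSE)
  }
  cols <- aln$columns  # pos_a = reference, pos_b = query
  rows <- lapply(1:6, function(i) {
    s <- reference_annotation$intervals$start[i]
    e <- reference_annotation$intervals$end[i]
    in_iv <- !is.na(cols$pos_a) & cols$pos_a >= s & cols$pos_a <= e
    qpos <- cols$pos_b[in_iv]
    qpos <- qpos[!is.na(qpos)]
    if (length(qpos) == 0L) {
      data.frame(label = SRS_LABELS[i], start = NA_integer_,
                 end = NA_integer_, residue_count = 0L,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(label = SRS_LABELS[i], start = min(qpos), end = max(qpos),
                 residue_count = max(qpos) - min(qpos) + 1L,
                 stringsAsFactors = FALSE)
    }
  })
  intervals <- do.call(rbind, rows)
  structure(
    list(query_id = query$id, reference_id = ref_id, intervals = intervals,
         total_residues = sum(intervals$residue_count)),
    class = "srs_projection"
  )
}

#' @export
print.srs_projection <- function(x, ...) {
  cat("<srs_projection> ", x$query_id, " (from ", x$reference_id, "), ",
      x$total_residues, " SRS residues\n", sep = "")
  print(x$intervals, row.names = FALSE)
  invisible(x)
}

#' Convert a projection (or its consensus) to an srs_annotation
#'
#' Fails if any interval is empty, since an annotation requires six
#' non-empty intervals.
#' @param projection An `srs_projection`.
#' @return An [srs_annotation()] on the query.
#' @export
projection_to_annotation <- function(projection) {
  iv <- projection$intervals
  if (anyNA(iv$start)) {
    stop("projection for '", projection$query_id,
         "' has an empty SRS interval; cannot form an annotation",
         call. = FALSE)
  }
  srs_annotation(projection$query_id, iv$start, iv$end)
}

#' Consensus SRS projection from several annotated references
#'
#' The study design aligns a query against multiple reference P450s with
#' established SRS intervals. Each reference yields one projection; the
#' consensus interval per SRS is the intersection of the per-reference
#' intervals (conservative: a residue is called SRS only if every
#' reference supports it). Per-reference projections are returned
#' alongside.
#'
#' @param query [protein_record()].
#' @param references Named list of [protein_record()]s.
#' @param annotations Named list of [srs_annotation()]s covering the
#'   references.
#' @param params [align_params()].
#' @return List with `consensus` (an `srs_projection` with
#'   `reference_id = "consensus"`) and `per_reference` (list of
#'   projections).
#' @export
project_srs_consensus <- function(query, references, annotations,
                                  params = align_params()) {
  stopifnot(length(references) >= 1L)
  projections <- lapply(references, function(ref) {
    ann <- annotations[[ref$id]]
    if (is.null(ann)) stop("no annotation for reference '", ref$id, "'",
                           call. = FALSE)
    project_srs(ann, global_align(ref, query, params), query)
  })
  rows <- lapply(1:6, function(i) {
    starts <- vapply(projections, function(p) p$intervals$start[i],
                     integer(1))
    ends <- vapply(projections, function(p) p$intervals$end[i], integer(1))
    if (anyNA(starts) || max(starts) > min(ends)) {
      data.frame(label = SRS_LABELS[i], start = NA_integer_,
                 end = NA_integer_, residue_count = 0L,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(label = SRS_LABELS[i], start = max(starts),
                 end = min(ends),
                 residue_count = min(ends) - max(starts) + 1L,
                 stringsAsFactors = FALSE)
    }
  })
  intervals <- do.call(rbind, rows)
  consensus <- structure(
    list(query_id = query$id, reference_id = "consensus",
         intervals = intervals,
         total_residues = sum(intervals$residue_count)),
    class = "srs_projection"
  )
  list(consensus = consensus, per_reference = projections)
}
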