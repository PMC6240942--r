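#' Per-SRS identity profile for a pair of sequences
#'
#' Computes percent identity per SRS region, pooled over all six regions,
#' and over the full alignment, from one shared global alignment. The
#' denominator for a region is the number of alignment columns whose
#' residue (on either side) falls in that region's interval;
#' gap-containing columns count as mismatches. Percentages are reported
#' unrounded; use [round_identity_profile()] for the integer rendering
#' used in reports.
#'
#' @param alignment `pairwise_alignment` between the two sequences.
#' @param srs_a,srs_b SRS intervals for side a / side b: an
#'   [srs_annotation()] or `srs_projection` on the respective sequence.
#' @return Object of class `identity_profile`: `id_a`, `id_b`, `per_srs`
#'   (named numeric, SRS1..SRS6), `total_srs`, `full_length`.
#' @export
srs_identity <- function(alignment, srs_a, srs_b) {
  iv_a <- srs_intervals_of(srs_a, alignment$id_a)
  iv_b <- srs_intervals_of(srs_b, alignment$id_b)
  cols <- alignment$columns
  ca <- strsplit(alignment$aligned_a, "")[[1]]
  cb <- strsplit(alignment$aligned_b, "")[[1]]
  match_col <- ca == cb & ca != "-"
  in_region <- function(iv_row_a, iv_row_b) {
    ina <- !is.na(cols$pos_a) & !is.na(iv_row_a$start) &
      cols$pos_a >= iv_row_a$start & cols$pos_a <= iv_row_a$end
    inb <- !is.na(cols$pos_b) & !is.na(iv_row_b$start) &
      cols$pos_b >= iv_row_b$start & cols$pos_b <= iv_row_b$end
    ina | inb
  }
  per_srs <- vapply(1:6, function(i) {
    sel <- in_region(iv_a[i, ], iv_b[i, ])
    if (!any(sel)) return(NA_real_)
    100 * sum(match_col[sel]) / sum(sel)
  }, numeric(1))
  names(per_srs) <- SRS_LABELS
  pooled <- Reduce(`|`, lapply(1:6, function(i) in_region(iv_a[i, ],
                                                          iv_b[i, ])))
  total_srs <- if (any(pooled)) 100 * sum(match_col[pooled]) / sum(pooled)
               else NA_real_
  structure(
    list(id_a = alignment$id_a, id_b = alignment$id_b, per_srs = per_srs,
         total_srs = total_srs,
         full_length = 100 * sum(match_col) / length(match_col)),
    class = "identity_profile"
  )
}

# accept an annotation or a projection and return its intervals data.frame
srs_intervals_of <- function(x, expected_id) {
  if (inherits(x, "srs_annotation")) {
    if (x$sequence_id != expected_id) {
      stop("annotation is for '", x$sequence_id, "', expected '",
           expected_id, "'", call. = FALSE)
    }
    cbind(x$intervals, residue_count = x$intervals$end -
            x$intervals$start + 1L)
  } else if (inherits(x, "srs_projection")) {
    if (x$query_id != expected_id) {
      stop("projection is for '", x$query_id, "', expected '",
           expected_id, "'", call. = FALSE)
    }
    x$intervals
  } else {
    stop("expected an srs_annotation or srs_projection", call. = FALSE)
  }
}

#' @export
print.identity_profile <- function(x, ...) {
  cat("<identity_profile> ", x$id_a, " vs ", x$id_b, "\n", sep = "")
  v <- round(c(x$per_srs, `Total SRS` = x$total_srs,
               `Full length` = x$full_length))
  print(v)
  invisible(x)
}

#' Integer rendering of an identity profile
#' @param profile An `identity_profile`.
#' @return Named numeric vector rounded to the nearest integer.
#' @export
round_identity_profile <- function(profile) {
  round(c(profile$per_srs, total_srs = profile$total_srs,
          full_length = profile$full_length))
}

#' Identity profiles for a set of sequence pairs
#'
#' For each requested pair, aligns the two sequences, obtains SRS
#' intervals for each side (a native annotation when one is supplied for
#' that id, otherwise a consensus projection from the annotated
#' references), and computes the identity profile.
#'
#' @param records Named list of [protein_record()]s (queries and
#'   references).
#' @param annotations Named list of [srs_annotation()]s for the annotated
#'   (reference) sequences.
#' @param pairs List of length-2 character vectors of record ids, or a
#'   2-column matrix/data.frame.
#' @param params [align_params()].
#' @return `tbl_df` with one row per pair: ids, unrounded SRS1..SRS6,
#'   total_srs and full_length percentages, plus the profile objects in a
#'   list-column.
#' @export
identity_matrix <- function(records, annotations, pairs,
                            params = align_params()) {
  if (is.matrix(pairs) || is.data.frame(pairs)) {
    pairs <- lapply(seq_len(nrow(pairs)),
                    function(i) as.character(unlist(pairs[i, 1:2])))
  }
  ids <- unique(unlist(pairs))
  unknown <- setdiff(ids, names(records))
  if (length(unknown) > 0L) {
    stop("unknown sequence id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  reference_ids <- intersect(names(annotations), names(records))
  srs_for <- function(id) {
    if (id %in% names(annotations)) return(annotations[[id]])
    refs <- records[setdiff(reference_ids, id)]
    if (length(refs) == 0L) {
      stop("no annotated reference available to project SRS onto '", id,
           "'", call. = FALSE)
    }
    project_srs_consensus(records[[id]], refs, annotations, params)$consensus
  }
  srs_cache <- stats::setNames(lapply(ids, srs_for), ids)
  rows <- lapply(pairs, function(p) {
    aln <- global_align(records[[p[1]]], records[[p[2]]], params)
    prof <- srs_identity(aln, srs_cache[[p[1]]], srs_cache[[p[2]]])
    tibble::tibble(
      id_a = p[1], id_b = p[2],
      !!!stats::setNames(as.list(prof$per_srs), SRS_LABELS),
      total_srs = prof$total_srs, full_length = prof$full_length,
      profile = list(prof)
    )
  })
  dplyr::bind_rows(rows)
}

#' Write an identity report
#'
#' TSV with integer-rounded percentages (columns pair, SRS1..SRS6,
#' Total SRS, Total sequence) plus an optional JSON sidecar carrying the
#' unrounded values.
#'
#' @param profiles Output of [identity_matrix()].
#' @param path Output TSV path.
#' @param json_path Optional path for the unrounded JSON variant.
#' @return `path`, invisibly.
#' @export
write_identity_report <- function(profiles, path, json_path = NULL) {
  rounded <- data.frame(
    pair = paste(profiles$id_a, "and", profiles$id_b),
    round(as.data.frame(profiles[, SRS_LABELS])),
    `Total SRS` = round(profiles$total_srs),
    `Total sequence` = round(profiles$full_length),
    check.names = FALSE
  )
  utils::write.table(rounded, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      profiles[, c("id_a", "id_b", SRS_LABELS, "total_srs", "full_length")],
      json_path, digits = NA, auto_unbox = TRUE
    )
  }
  invisible(path)
}
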