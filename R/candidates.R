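#' Mutation candidate tables
#'
#' All candidate enumerators return a tibble with one row per candidate:
#' `target_id`, `rule` (one of `hotspot_srs5`, `reciprocal`,
#' `equivalent_position`, `indel_swap`), `position` (1-based on the
#' target), `variant_text` (canonical notation, see [parse_variant()])
#' and `provenance` (free text naming the donor position or motif
#' offset).
#'
#' @name mutation_candidates
NULL

candidate_row <- function(target_id, rule, position, variant_text,
                          provenance) {
  tibble::tibble(target_id = target_id, rule = rule, position = position,
                 variant_text = variant_text, provenance = provenance)
}

#' SRS5 mutagenesis hotspots at fixed offsets from the ExxR motif
#'
#' The residues 5 and 9 positions from the glutamate of the K-helix ExxR
#' motif are recurrent substrate-specificity hotspots in plant P450s.
#' Offsets are counted downstream of the E (towards the C terminus): with
#' the E at position p, offset k names residue p + k. The replacement
#' residue is left open (placeholder `X`) unless a replacement panel is
#' supplied, in which case one candidate per (offset, replacement) pair
#' is emitted.
#'
#' @param record Target [protein_record()].
#' @param exxr A found `motif_hit` from [find_exxr()].
#' @param offsets Non-negative integer offsets from the E (default
#'   `c(5, 9)`).
#' @param replacements Optional character vector of replacement residues.
#' @return Candidate tibble (see [mutation_candidates]); rule
#'   `hotspot_srs5`.
#' @export
srs5_hotspots <- function(record, exxr, offsets = c(5L, 9L),
                          replacements = NULL) {
  stopifnot(inherits(exxr, "motif_hit"))
  if (!exxr$found) stop("ExxR motif was not found for '", record$id, "'",
                        call. = FALSE)
  if (length(offsets) == 0L) {
    return(candidate_row(character(), character(), integer(), character(),
                         character()))
  }
  stopifnot(all(offsets >= 0L))
  rows <- lapply(sort(unique(as.integer(offsets))), function(k) {
    pos <- exxr$start + k
    if (pos > record_length(record)) {
      warning("offset ", k, " from ExxR at ", exxr$start,
              " falls beyond the end of '", record$id, "'; skipped",
              call. = FALSE)
      return(NULL)
    }
    wt <- residue_at(record, pos)
    newres <- if (is.null(replacements)) "X" else replacements
    candidate_row(record$id, "hotspot_srs5", pos,
                  paste0(wt, pos, newres),
                  paste0("ExxR@", exxr$start, " + ", k))
  })
  dplyr::bind_rows(rows)
}

#' Reciprocal mutagenesis candidates between two homologues
#'
#' Walks the alignment columns that intersect the target's SRS intervals
#' (on either side of the alignment). Columns where both residues are
#' present and differ yield one substitution candidate each, replacing
#' the target residue with the donor's at the target coordinate. Columns
#' gapped in either sequence are merged into maximal runs and reported as
#' indel-swap candidates; each run is left-anchored on the preceding
#' aligned column (VCF-style) so both segments are non-empty and the
#' candidate is expressible in the canonical swap notation.
#'
#' @param target,donor [protein_record()]s.
#' @param target_srs SRS intervals on the target ([srs_annotation()] or
#'   `srs_projection`).
#' @param alignment `pairwise_alignment` between target and donor (either
#'   orientation).
#' @param donor_srs Optional SRS intervals on the donor, used only to
#'   include columns that are SRS on the donor side but gapped on the
#'   target.
#' @return Candidate tibble; rules `reciprocal` and `indel_swap`.
#' @export
reciprocal_candidates <- function(target, donor, target_srs, alignment,
                                  donor_srs = NULL) {
  aln <- orient_alignment(alignment, target$id)
  if (aln$id_b != donor$id) stop("donor '", donor$id,
                                 "' absent from alignment", call. = FALSE)
  cols <- aln$columns
  ra <- strsplit(aln$aligned_a, "")[[1]]
  rb <- strsplit(aln$aligned_b, "")[[1]]
  iv_t <- srs_intervals_of(target_srs, target$id)
  sel <- rep(FALSE, nrow(cols))
  for (i in 1:6) {
    if (!is.na(iv_t$start[i])) {
      sel <- sel | (!is.na(cols$pos_a) & cols$pos_a >= iv_t$start[i] &
                      cols$pos_a <= iv_t$end[i])
    }
  }
  if (!is.null(donor_srs)) {
    iv_d <- srs_intervals_of(donor_srs, donor$id)
    for (i in 1:6) {
      if (!is.na(iv_d$start[i])) {
        sel <- sel | (!is.na(cols$pos_b) & cols$pos_b >= iv_d$start[i] &
                        cols$pos_b <= iv_d$end[i])
      }
    }
  }
  subs <- which(sel & ra != "-" & rb != "-" & ra != rb)
  sub_rows <- lapply(subs, function(j) {
    candidate_row(target$id, "reciprocal", cols$pos_a[j],
                  paste0(ra[j], cols$pos_a[j], rb[j]),
                  paste0(donor$id, ":", cols$pos_b[j], ra[j], ">", rb[j]))
  })
  gap <- sel & (ra == "-" | rb == "-")
  runs <- rle(gap)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  swap_rows <- lapply(which(runs$values), function(k) {
    j0 <- run_start[k]; j1 <- run_end[k]
    # left anchor: nearest earlier column aligned in both sequences
    anchor <- j0 - 1L
    while (anchor >= 1L && (ra[anchor] == "-" || rb[anchor] == "-")) {
      anchor <- anchor - 1L
    }
    if (anchor < 1L) return(NULL)  # run at alignment start: inexpressible
    ref_seg <- paste(ra[anchor:j1][ra[anchor:j1] != "-"], collapse = "")
    new_seg <- paste(rb[anchor:j1][rb[anchor:j1] != "-"], collapse = "")
    pos <- cols$pos_a[anchor]
    candidate_row(target$id, "indel_swap", pos,
                  paste0(pos, ref_seg, "::", new_seg),
                  paste0(donor$id, ": gap run, alignment columns ", j0,
                         "-", j1))
  })
  out <- dplyr::bind_rows(c(sub_rows, swap_rows))
  if (nrow(out) == 0L) {
    return(candidate_row(character(), character(), integer(), character(),
                         character()))
  }
  dplyr::arrange(out, .data$rule, .data$position)
}

#' Map a residue position onto a homologue through an alignment
#'
#' Transfers a position of interest (e.g. a hotspot identified in another
#' P450) onto the query: the query residue aligned to
#' `homolog_position`, or an explicit miss when that column is a query
#' gap.
#'
#' @param query,homolog [protein_record()]s.
#' @param homolog_position 1-based position on the homologue.
#' @param alignment `pairwise_alignment` between the two (either
#'   orientation). When omitted, computed with default parameters.
#' @param params [align_params()] used when `alignment` is missing.
#' @return List: `found` (logical), `query_position`, `query_residue`,
#'   `homolog_residue`.
#' @export
map_equivalent_position <- function(query, homolog, homolog_position,
                                    alignment = NULL,
                                    params = align_params()) {
  if (homolog_position < 1L || homolog_position > record_length(homolog)) {
    stop("position ", homolog_position, " out of range for '",
         homolog$id, "'", call. = FALSE)
  }
  if (is.null(alignment)) alignment <- global_align(homolog, query, params)
  aln <- orient_alignment(alignment, homolog$id)
  if (aln$id_b != query$id) stop("query '", query$id,
                                 "' absent from alignment", call. = FALSE)
  j <- which(aln$columns$pos_a == homolog_position)
  qpos <- aln$columns$pos_b[j]
  if (length(qpos) == 0L || is.na(qpos)) {
    return(list(found = FALSE, query_position = NA_integer_,
                query_residue = NA_character_,
                homolog_residue = residue_at(homolog, homolog_position)))
  }
  list(found = TRUE, query_position = qpos,
       query_residue = residue_at(query, qpos),
       homolog_residue = residue_at(homolog, homolog_position))
}

#' Write a candidate report
#' @param candidates Candidate tibble (see [mutation_candidates]).
#' @param path Output TSV path.
#' @param json_path Optional JSON sidecar path.
#' @return `path`, invisibly.
#' @export
write_candidate_report <- function(candidates, path, json_path = NULL) {
  utils::write.table(
    candidates[, c("target_id", "rule", "variant_text", "provenance")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  if (!is.null(json_path)) {
    jsonlite::write_json(candidates, json_path, digits = NA,
                         auto_unbox = TRUE)
  }
  invisible(path)
}
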