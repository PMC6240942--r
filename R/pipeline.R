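#' Pipeline drivers
#'
#' Thin, file-oriented entry points tying the analysis stages together:
#' each reads the standard input formats, calls the module functions and
#' writes TSV/JSON reports plus a small run log (package version, config
#' hash, seed) into `out_dir`. They are what the numbered scripts under
#' `analysis/` call; all computation lives in the module functions.
#'
#' @name pipeline
NULL

write_run_log <- function(out_dir, config) {
  log <- list(
    tool = paste0("srsmut ",
                  as.character(utils::packageVersion("srsmut"))),
    timestamp = format(Sys.time(), tz = "UTC"),
    config_hash = sum(utf8ToInt(paste(deparse(config), collapse = ""))),
    config = config
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(log)
}

#' Map SRS intervals and report identity profiles
#'
#' @param fasta Path to query + reference FASTA.
#' @param annotations Path to SRS annotation TSV for the reference
#'   sequences.
#' @param out_dir Output directory (created if missing).
#' @param pairs Optional list of id pairs for the identity report;
#'   default all unordered pairs of sequences in the FASTA.
#' @param params [align_params()].
#' @return Invisibly, list with the identity tibble and the per-query
#'   consensus projections.
#' @export
run_map_srs <- function(fasta, annotations, out_dir,
                        pairs = NULL, params = align_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_fasta(fasta)
  anns <- read_srs_annotations(annotations, records)
  if (is.null(pairs)) {
    ids <- names(records)
    pairs <- if (length(ids) >= 2L) utils::combn(ids, 2L, simplify = FALSE)
             else list(c(ids, ids))
  }
  profiles <- identity_matrix(records, anns, pairs, params)
  write_identity_report(profiles, file.path(out_dir, "identity.tsv"),
                        file.path(out_dir, "identity.json"))
  queries <- setdiff(names(records), names(anns))
  projections <- lapply(queries, function(q) {
    project_srs_consensus(records[[q]], records[names(anns)], anns,
                          params)$consensus
  })
  names(projections) <- queries
  proj_rows <- dplyr::bind_rows(lapply(projections, function(p) {
    tibble::tibble(query_id = p$query_id, srs = p$intervals$label,
                   start = p$intervals$start, end = p$intervals$end,
                   residue_count = p$intervals$residue_count)
  }))
  utils::write.table(proj_rows, file.path(out_dir, "srs_projections.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_log(out_dir, list(stage = "map_srs", fasta = fasta,
                              annotations = annotations, params = params))
  invisible(list(identity = profiles, projections = projections))
}

#' Propose mutation candidates for a target sequence
#'
#' Emits SRS5 ExxR-offset hotspots, reciprocal candidates from a donor
#' homologue, and (optionally) equivalent-position transfers, in
#' deterministic order (rule, then position). When the ExxR motif is not
#' found the hotspot section is empty and a warning is raised; the
#' report is still written.
#'
#' @param fasta FASTA containing target, donor and reference sequences.
#' @param annotations SRS annotation TSV for the references.
#' @param target_id,donor_id Sequence ids.
#' @param out_dir Output directory.
#' @param offsets ExxR hotspot offsets (default `c(5, 9)`).
#' @param equivalents Optional data.frame with columns `homolog_id`,
#'   `position` for equivalent-position mapping.
#' @param params [align_params()].
#' @return Invisibly, the candidate tibble.
#' @export
run_propose <- function(fasta, annotations, target_id, donor_id, out_dir,
                        offsets = c(5L, 9L), equivalents = NULL,
                        params = align_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_fasta(fasta)
  anns <- read_srs_annotations(annotations, records)
  target <- records[[target_id]]
  donor <- records[[donor_id]]
  if (is.null(target) || is.null(donor)) {
    stop("target or donor id absent from ", fasta, call. = FALSE)
  }
  srs_of <- function(rec) {
    if (rec$id %in% names(anns)) return(anns[[rec$id]])
    project_srs_consensus(rec, records[names(anns)], anns,
                          params)$consensus
  }
  target_srs <- srs_of(target)
  donor_srs <- srs_of(donor)
  exxr <- find_exxr(target, srs = target_srs)
  hot <- if (exxr$found) {
    srs5_hotspots(target, exxr, offsets)
  } else {
    warning("ExxR motif not found in '", target_id,
            "'; hotspot section empty", call. = FALSE)
    NULL
  }
  rec <- reciprocal_candidates(target, donor, target_srs,
                               global_align(target, donor, params),
                               donor_srs = donor_srs)
  eq <- NULL
  if (!is.null(equivalents)) {
    eq <- dplyr::bind_rows(lapply(seq_len(nrow(equivalents)), function(i) {
      hid <- equivalents$homolog_id[i]
      hpos <- equivalents$position[i]
      m <- map_equivalent_position(target, records[[hid]], hpos,
                                   params = params)
      if (!m$found) return(NULL)
      candidate_row(target_id, "equivalent_position", m$query_position,
                    paste0(m$query_residue, m$query_position, "X"),
                    paste0(hid, ":", m$homolog_residue, hpos))
    }))
  }
  out <- dplyr::bind_rows(hot, rec, eq)
  out <- dplyr::arrange(out, .data$rule, .data$position)
  write_candidate_report(out, file.path(out_dir, "candidates.tsv"),
                         file.path(out_dir, "candidates.json"))
  write_run_log(out_dir, list(stage = "propose", fasta = fasta,
                              target = target_id, donor = donor_id,
                              offsets = offsets))
  invisible(out)
}

#' Quantify a variant screen from a peak table
#'
#' Relative yields always; absolute titers and per-strain specificity
#' metrics when a calibration CSV is supplied (relative-only mode
#' otherwise). Writes yield, titer/metrics and fold-change reports.
#'
#' @param peaks_csv Peak table CSV (see [read_peak_table()]).
#' @param out_dir Output directory.
#' @param calibration_csv Optional calibration CSV with columns
#'   `compound`, `concentration_mg_per_L`, `area`, `is_area`.
#' @param reference_strain Strain used as fold-change denominator
#'   (default the first strain in the table).
#' @param quantified_set Compounds pooled into totals (default
#'   `c("1","2","3","7")`).
#' @param response_map Compound -> curve mapping; default
#'   [absolute_titer()]'s.
#' @param timepoint_h Timepoint used for metrics (default the latest).
#' @return Invisibly, list with `yields`, `titers` (or NULL), `metrics`
#'   (tibble or NULL), `fold_changes`.
#' @export
run_quantify <- function(peaks_csv, out_dir, calibration_csv = NULL,
                         reference_strain = NULL,
                         quantified_set = c("1", "2", "3", "7"),
                         response_map = NULL, timepoint_h = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  peaks <- read_peak_table(peaks_csv)
  yields <- relative_yield(peaks)
  utils::write.table(yields, file.path(out_dir, "relative_yields.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (is.null(timepoint_h)) timepoint_h <- max(yields$timepoint_h)
  yt <- yields[yields$timepoint_h == timepoint_h, ]
  if (is.null(reference_strain)) reference_strain <- peaks$strain[1]

  titers <- NULL
  metrics_tab <- NULL
  if (!is.null(calibration_csv)) {
    cal <- tibble::as_tibble(utils::read.csv(calibration_csv,
                                             stringsAsFactors = FALSE))
    curves <- lapply(split(cal, cal$compound), fit_standard_curve)
    titers <- if (is.null(response_map)) absolute_titer(yt, curves)
              else absolute_titer(yt, curves, response_map)
    utils::write.table(titers, file.path(out_dir, "titers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ref_vec <- titer_vector(titers, reference_strain)
    metrics_tab <- dplyr::bind_rows(lapply(unique(titers$strain),
                                           function(s) {
      m <- strain_metrics(titer_vector(titers, s), ref_vec,
                          quantified_set)
      tibble::tibble(
        strain = s, total_mg_per_L = round(m$total, 1),
        oxygenated_pct = round(m$oxygenated_pct),
        content2_pct = round(m$content_target_pct),
        !!!stats::setNames(as.list(round(m$titers, 1)),
                           paste0("titer_", names(m$titers)))
      )
    }))
    utils::write.table(metrics_tab, file.path(out_dir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  fc_value_tab <- if (!is.null(titers)) {
    dplyr::rename(titers, value = "titer_mg_per_L")
  } else {
    dplyr::rename(yt, value = "mean_response")
  }
  combos <- expand.grid(strain = unique(fc_value_tab$strain),
                        compound = unique(fc_value_tab$compound),
                        stringsAsFactors = FALSE)
  fcs <- dplyr::bind_rows(lapply(seq_len(nrow(combos)), function(i) {
    s <- combos$strain[i]; cmp <- combos$compound[i]
    has <- function(st) any(fc_value_tab$strain == st &
                              fc_value_tab$compound == cmp)
    if (!has(s) || !has(reference_strain)) return(NULL)
    tibble::tibble(
      strain = s, compound = cmp, reference = reference_strain,
      fold_change = round(
        fold_change(fc_value_tab, s, reference_strain, cmp,
                    value = "value", timepoint_h = timepoint_h), 1)
    )
  }))
  utils::write.table(fcs, file.path(out_dir, "fold_changes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_log(out_dir, list(stage = "quantify", peaks = peaks_csv,
                              calibration = calibration_csv,
                              reference = reference_strain,
                              quantified_set = quantified_set,
                              timepoint_h = timepoint_h))
  invisible(list(yields = yields, titers = titers, metrics = metrics_tab,
                 fold_changes = fcs))
}

#' Extract one strain's titer vector from an absolute_titer table
#' @param titers Output of [absolute_titer()].
#' @param strain Strain name.
#' @return Named numeric vector keyed by compound.
#' @export
titer_vector <- function(titers, strain) {
  d <- titers[titers$strain == strain, ]
  stats::setNames(d$titer_mg_per_L, d$compound)
}

#' Write simulated inputs to disk
#'
#' Materialises a simulated family (FASTA + annotation TSV + edit log)
#' and a simulated screen (peak CSV + calibration CSV + truth JSON) so
#' the other drivers can be run end to end without external data.
#'
#' @param out_dir Output directory.
#' @param family_config A [family_sim_config()].
#' @param screen_config A [screen_sim_config()].
#' @return Invisibly, list of the two simulation objects.
#' @export
run_simulate <- function(out_dir, family_config = family_sim_config(),
                         screen_config = screen_sim_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fam <- simulate_family(family_config)
  write_fasta(c(list(ancestor = fam$ancestor), fam$descendants),
              file.path(out_dir, "family.fasta"))
  write_srs_annotations(list(fam$annotation),
                        file.path(out_dir, "family_srs.tsv"))
  utils::write.table(fam$edit_log, file.path(out_dir, "edit_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  scr <- simulate_screen(screen_config)
  utils::write.csv(scr$peaks, file.path(out_dir, "peaks.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(scr$calibration, file.path(out_dir, "calibration.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(scr$truth, file.path(out_dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  write_run_log(out_dir, list(stage = "simulate",
                              family_seed = family_config$seed,
                              screen_seed = screen_config$seed))
  invisible(list(family = fam, screen = scr))
}
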