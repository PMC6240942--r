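#' Configuration for simulating a homologous CYP family
#'
#' Generates a star-shaped family: one ancestor, `n_sequences`
#' descendants mutated residue-wise at region-specific rates. The
#' defaults emulate the layout and divergence structure of a CYP76AH-like
#' subfamily: a 500-residue protein, six SRS intervals totalling 78
#' residues, a K-helix ExxR motif planted between SRS4 and SRS5, SRS
#' regions diverging slightly faster than the background, and an optional
#' single-residue deletion inside SRS6 (the 78-vs-77 SRS residue
#' contrast seen among natural paralogues).
#'
#' @param seed Integer seed; all randomness in [simulate_family()] flows
#'   from it.
#' @param n_sequences Number of descendants (default 4).
#' @param length Ancestor length (default 500).
#' @param srs_starts,srs_ends SRS1..SRS6 intervals (defaults: 95-114,
#'   150-159, 230-239, 280-296, 362-372, 470-479; 78 residues in total).
#' @param p_sub_srs Per-residue substitution probability inside SRS
#'   regions (default 0.18).
#' @param p_sub_nonsrs Background substitution probability (default
#'   0.12).
#' @param exxr_position Position of the planted E of the ExxR motif
#'   (default 357); the E and R residues are kept invariant in all
#'   descendants.
#' @param indel_prob Probability that a descendant carries the SRS6
#'   deletion (default 0).
#' @param indel_start,indel_length Start (ancestor coordinates, inside
#'   SRS6) and length of the planted deletion (defaults 473, 1).
#' @return List of class `family_sim_config`.
#' @export
family_sim_config <- function(seed = 1L, n_sequences = 4L, length = 500L,
                              srs_starts = c(95L, 150L, 230L, 280L, 362L,
                                             470L),
                              srs_ends = c(114L, 159L, 239L, 296L, 372L,
                                           479L),
                              p_sub_srs = 0.18, p_sub_nonsrs = 0.12,
                              exxr_position = 357L, indel_prob = 0,
                              indel_start = 473L, indel_length = 1L) {
  ann <- srs_annotation("ancestor", srs_starts, srs_ends,
                        sequence_length = length)
  stopifnot(p_sub_srs >= 0, p_sub_srs <= 1, p_sub_nonsrs >= 0,
            p_sub_nonsrs <= 1, n_sequences >= 1L, indel_prob >= 0,
            indel_prob <= 1, indel_length >= 1L)
  if (exxr_position < 1L || exxr_position + 3L > length) {
    stop("ExxR motif does not fit at position ", exxr_position,
         call. = FALSE)
  }
  if (indel_prob > 0) {
    s6 <- ann$intervals[6, ]
    if (indel_start < s6$start || indel_start + indel_length - 1L > s6$end) {
      stop("planted indel must lie inside SRS6", call. = FALSE)
    }
    if (indel_start <= exxr_position + 3L &&
        indel_start + indel_length - 1L >= exxr_position) {
      stop("planted indel overlaps the ExxR motif", call. = FALSE)
    }
  }
  structure(
    list(seed = as.integer(seed), n_sequences = as.integer(n_sequences),
         length = as.integer(length), annotation = ann,
         p_sub_srs = p_sub_srs, p_sub_nonsrs = p_sub_nonsrs,
         exxr_position = as.integer(exxr_position),
         indel_prob = indel_prob, indel_start = as.integer(indel_start),
         indel_length = as.integer(indel_length)),
    class = "family_sim_config"
  )
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulate a homologous protein family with planted SRS structure
#'
#' Draws a uniform-random ancestor (ExxR planted at the configured
#' position), then mutates each descendant residue-wise: substitution
#' probability `p_sub_srs` inside SRS intervals, `p_sub_nonsrs` outside;
#' replacement drawn uniformly from the 19 other residues. The E and R
#' of the motif are invariant. With probability `indel_prob` a descendant
#' additionally carries the configured SRS6 deletion. Deterministic under
#' the config seed.
#'
#' @param config A [family_sim_config()].
#' @return List: `ancestor` ([protein_record()]), `descendants` (named
#'   list of records), `annotation` (true [srs_annotation()] on ancestor
#'   coordinates), `descendant_annotations` (true annotations per
#'   descendant, indel-adjusted), `edit_log` (tibble: `sequence_id`,
#'   `type`, `position` in ancestor coordinates, `ref`, `new`,
#'   `in_srs`), `config`.
#' @export
simulate_family <- function(config = family_sim_config()) {
  stopifnot(inherits(config, "family_sim_config"))
  set.seed(config$seed)
  len <- config$length
  anc <- sample(AA20, len, replace = TRUE)
  anc[config$exxr_position] <- "E"
  anc[config$exxr_position + 3L] <- "R"
  iv <- config$annotation$intervals
  in_srs <- rep(FALSE, len)
  for (i in 1:6) in_srs[iv$start[i]:iv$end[i]] <- TRUE
  invariant <- c(config$exxr_position, config$exxr_position + 3L)
  p <- ifelse(in_srs, config$p_sub_srs, config$p_sub_nonsrs)
  p[invariant] <- 0
  logs <- list()
  descendants <- list()
  desc_ann <- list()
  for (d in seq_len(config$n_sequences)) {
    id <- sprintf("desc%d", d)
    res <- anc
    hit <- which(stats::runif(len) < p)
    for (j in hit) res[j] <- sample(setdiff(AA20, anc[j]), 1L)
    log_d <- if (length(hit) > 0L) {
      tibble::tibble(sequence_id = id, type = "sub", position = hit,
                     ref = anc[hit], new = res[hit], in_srs = in_srs[hit])
    } else {
      tibble::tibble(sequence_id = character(), type = character(),
                     position = integer(), ref = character(),
                     new = character(), in_srs = logical())
    }
    starts <- iv$start
    ends <- iv$end
    if (config$indel_prob > 0 &&
        stats::runif(1) < config$indel_prob) {
      del <- config$indel_start:(config$indel_start + config$indel_length
                                 - 1L)
      log_d <- dplyr::bind_rows(
        log_d,
        tibble::tibble(sequence_id = id, type = "del",
                       position = config$indel_start,
                       ref = paste(res[del], collapse = ""), new = "",
                       in_srs = TRUE)
      )
      res <- res[-del]
      # indel sits in SRS6, downstream of every other interval
      ends[6] <- ends[6] - config$indel_length
    }
    descendants[[id]] <- protein_record(id, paste(res, collapse = ""))
    desc_ann[[id]] <- srs_annotation(id, starts, ends,
                                     sequence_length = length(res))
    logs[[id]] <- log_d
  }
  list(
    ancestor = protein_record("ancestor", paste(anc, collapse = "")),
    descendants = descendants,
    annotation = config$annotation,
    descendant_annotations = desc_ann,
    edit_log = dplyr::bind_rows(logs),
    config = config
  )
}

#' Configuration for simulating a variant screen
#'
#' Emulates the replicate structure of an in vivo P450 variant screen
#' read out by GC-MS: strains with known true per-compound titers,
#' compound-specific response factors (normalised response per mg/L),
#' multiplicative log-normal noise on every peak area, and noiseless (or
#' optionally noisy) calibration points for the compounds with authentic
#' standards. The default strains reproduce the shake-flask conditions
#' of a wild-type-like producer and a high-specificity variant with
#' three biological replicates and 10% CV.
#'
#' @param seed Integer seed.
#' @param strains Named list of named numeric vectors: true titers mg/L
#'   per compound.
#' @param response_factors Named numeric: normalised response per mg/L
#'   per compound.
#' @param replicates Replicate count (default 3).
#' @param cv Coefficient of variation of the multiplicative noise on the
#'   linear scale (default 0.1); log-sd is `log(1 + cv)`.
#' @param is_area True internal-standard area (default 5e5).
#' @param timepoints_h Sampling times in hours (default 72).
#' @param calibration_concentrations mg/L levels for the standard curves
#'   (default 1, 2, 5, 10, 25, 50, 100).
#' @param curve_compounds Compounds with authentic standards (default
#'   `c("1", "2")`).
#' @param calibration_cv Noise CV on calibration responses (default 0).
#' @return List of class `screen_sim_config`.
#' @export
screen_sim_config <- function(
    seed = 1L,
    strains = list(
      "WT" = c("1" = 15.9, "2" = 23.4, "3" = 0.2, "7" = 4.3),
      "A99I" = c("1" = 0.9, "2" = 86.4, "3" = 0.4, "7" = 0)
    ),
    response_factors = c("1" = 0.09, "2" = 0.11, "3" = 0.11, "7" = 0.11),
    replicates = 3L, cv = 0.1, is_area = 5e5, timepoints_h = 72,
    calibration_concentrations = c(1, 2, 5, 10, 25, 50, 100),
    curve_compounds = c("1", "2"), calibration_cv = 0) {
  stopifnot(replicates >= 1L, cv >= 0, calibration_cv >= 0, is_area > 0)
  for (s in names(strains)) {
    if (any(strains[[s]] < 0)) stop("negative titer in strain ", s,
                                    call. = FALSE)
    if (!all(names(strains[[s]]) %in% names(response_factors))) {
      stop("strain ", s, " has a compound without a response factor",
           call. = FALSE)
    }
  }
  structure(
    list(seed = as.integer(seed), strains = strains,
         response_factors = response_factors,
         replicates = as.integer(replicates), cv = cv, is_area = is_area,
         timepoints_h = timepoints_h,
         calibration_concentrations = calibration_concentrations,
         curve_compounds = curve_compounds,
         calibration_cv = calibration_cv),
    class = "screen_sim_config"
  )
}

#' Simulate a variant-screening peak table with known ground truth
#'
#' Every peak area is
#' `titer * response_factor * is_area * exp(noise)` with
#' `noise ~ Normal(0, log(1 + cv))`; the internal-standard row of each
#' replicate carries its own independent noise of the same magnitude.
#' Calibration responses are `response_factor * concentration`, with
#' optional noise. Deterministic under the config seed.
#'
#' @param config A [screen_sim_config()].
#' @return List: `peaks` (peak-table tibble, see [read_peak_table()]),
#'   `calibration` (tibble `compound`, `concentration_mg_per_L`, `area`,
#'   `is_area`), `truth` (tibble of true titers with
#'   `true_fold_change_vs_ref` against the first strain), `config`.
#' @export
simulate_screen <- function(config = screen_sim_config()) {
  stopifnot(inherits(config, "screen_sim_config"))
  set.seed(config$seed)
  sdlog <- log(1 + config$cv)
  noise <- function(n) if (sdlog == 0) rep(1, n)
                       else exp(stats::rnorm(n, 0, sdlog))
  rows <- list()
  for (strain in names(config$strains)) {
    titers <- config$strains[[strain]]
    for (tp in config$timepoints_h) {
      for (r in seq_len(config$replicates)) {
        is_obs <- config$is_area * noise(1)
        areas <- titers * config$response_factors[names(titers)] *
          is_obs * noise(length(titers))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          strain = strain, variant = strain, replicate = r,
          timepoint_h = tp,
          compound = c(names(titers), "IS"),
          area = c(unname(areas), is_obs)
        )
      }
    }
  }
  peaks <- dplyr::bind_rows(rows)
  cal <- do.call(rbind, lapply(config$curve_compounds, function(cmp) {
    conc <- config$calibration_concentrations
    resp_noise <- if (config$calibration_cv == 0) rep(1, length(conc))
                  else exp(stats::rnorm(length(conc), 0,
                                        log(1 + config$calibration_cv)))
    data.frame(compound = cmp, concentration_mg_per_L = conc,
               area = config$response_factors[[cmp]] * conc *
                 config$is_area * resp_noise,
               is_area = config$is_area, stringsAsFactors = FALSE)
  }))
  ref <- names(config$strains)[1]
  truth <- dplyr::bind_rows(lapply(names(config$strains), function(s) {
    t <- config$strains[[s]]
    tr <- config$strains[[ref]]
    tibble::tibble(
      strain = s, compound = names(t), true_titer_mg_per_L = unname(t),
      true_fold_change_vs_ref = ifelse(
        unname(tr[names(t)]) == 0,
        ifelse(unname(t) == 0, 1, Inf),
        unname(t) / unname(tr[names(t)])
      )
    )
  }))
  list(peaks = peaks, calibration = tibble::as_tibble(cal), truth = truth,
       config = config)
}
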