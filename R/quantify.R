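#' Read a peak table CSV
#'
#' Columns: `strain`, `variant`, `replicate`, `timepoint_h`, `compound`,
#' `area`. One row per integrated peak; the internal standard is the
#' compound `"IS"`. Every (strain, replicate, timepoint) group must
#' contain exactly one IS row with positive area.
#'
#' @param path CSV path (header required, UTF-8).
#' @return Validated tibble.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop("peak table not found: ", path,
                               call. = FALSE)
  peaks <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_peak_table(peaks)
}

#' Validate a peak table
#' @param peaks Data frame of peak records.
#' @return The table, as a tibble, invisibly usable downstream.
#' @export
validate_peak_table <- function(peaks) {
  need <- c("strain", "variant", "replicate", "timepoint_h", "compound",
            "area")
  miss <- setdiff(need, names(peaks))
  if (length(miss) > 0L) {
    stop("peak table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(peaks$area < 0)) stop("negative peak area(s)", call. = FALSE)
  peaks <- tibble::as_tibble(peaks)
  is_counts <- peaks |>
    dplyr::group_by(.data$strain, .data$replicate, .data$timepoint_h) |>
    dplyr::summarise(
      n_is = sum(.data$compound == "IS"),
      is_pos = any(.data$compound == "IS" & .data$area > 0),
      .groups = "drop"
    )
  bad <- is_counts[is_counts$n_is != 1L | !is_counts$is_pos, ]
  if (nrow(bad) > 0L) {
    stop("internal-standard violation in group(s): ",
         paste(sprintf("%s/rep%s/%sh", bad$strain, bad$replicate,
                       bad$timepoint_h), collapse = "; "),
         call. = FALSE)
  }
  peaks
}

#' Internal-standard normalised relative yields
#'
#' For every (strain, compound, timepoint): each replicate's analyte area
#' is divided by the same replicate's internal-standard area, then
#' replicates are averaged. The replicate standard deviation is reported
#' alongside (the error bars of a typical screening figure).
#'
#' @param peaks Peak table (see [read_peak_table()]).
#' @param group_by Extra grouping columns beyond
#'   `strain, compound, timepoint_h` (default none).
#' @return Tibble with `strain`, `variant`, `timepoint_h`, `compound`,
#'   `mean_response`, `sd_response`, `n`.
#' @export
relative_yield <- function(peaks, group_by = character()) {
  peaks <- validate_peak_table(peaks)
  is_tab <- peaks |>
    dplyr::filter(.data$compound == "IS") |>
    dplyr::select("strain", "replicate", "timepoint_h",
                  is_area = "area")
  norm <- peaks |>
    dplyr::filter(.data$compound != "IS") |>
    dplyr::inner_join(is_tab, by = c("strain", "replicate",
                                     "timepoint_h")) |>
    dplyr::mutate(response = .data$area / .data$is_area)
  norm |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("strain", "variant", "timepoint_h", "compound", group_by)
    ))) |>
    dplyr::summarise(
      mean_response = mean(.data$response),
      sd_response = stats::sd(.data$response),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Fold change of a compound between two strains
#'
#' Ratio of mean normalised responses (or of titers, when a titer table
#' is supplied) for `strain` over `reference`. A zero reference mean
#' yields `Inf` (flagged, not an error). `fold_change(x, x)` is exactly 1.
#'
#' @param yields Output of [relative_yield()], or any tibble with
#'   `strain`, `compound` and a value column.
#' @param strain,reference Strain names.
#' @param compound Compound id.
#' @param value Name of the value column (default `mean_response`).
#' @param timepoint_h Optional timepoint filter.
#' @return Single numeric fold change (unrounded; reports round to 1
#'   decimal).
#' @export
fold_change <- function(yields, strain, reference, compound,
                        value = "mean_response", timepoint_h = NULL) {
  pick <- function(s) {
    d <- yields[yields$strain == s & yields$compound == compound, ]
    if (!is.null(timepoint_h)) d <- d[d$timepoint_h == timepoint_h, ]
    if (nrow(d) != 1L) {
      stop("expected one row for strain '", s, "', compound '", compound,
           "'; found ", nrow(d), call. = FALSE)
    }
    d[[value]]
  }
  num <- pick(strain)
  den <- pick(reference)
  if (identical(strain, reference)) return(1)
  if (den == 0) {
    warning("reference mean is zero; fold change undefined (Inf)",
            call. = FALSE)
    return(Inf)
  }
  num / den
}

#' Fit a linear standard curve
#'
#' Ordinary least squares of internal-standard normalised response on
#' concentration (mg/L), via [stats::lm()].
#'
#' @param calibration Data frame with columns `compound`,
#'   `concentration_mg_per_L`, `area`, `is_area` (or a precomputed
#'   `response` column).
#' @param compound Optional compound filter when the table holds several.
#' @return Object of class `standard_curve`: `compound`, `slope`,
#'   `intercept`, `r_squared`, `range` (min/max concentration), `n`.
#' @export
fit_standard_curve <- function(calibration, compound = NULL) {
  if (!is.null(compound)) {
    calibration <- calibration[calibration$compound == compound, ]
  }
  if (!("response" %in% names(calibration))) {
    calibration$response <- calibration$area / calibration$is_area
  }
  conc <- calibration$concentration_mg_per_L
  if (length(unique(conc)) < 2L) {
    stop("standard curve needs >= 2 distinct concentrations",
         call. = FALSE)
  }
  fit <- stats::lm(response ~ concentration_mg_per_L, data = calibration)
  # R^2 computed directly so a perfect (noiseless) calibration is silent
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((calibration$response - mean(calibration$response))^2)
  structure(
    list(compound = if (is.null(compound)) unique(calibration$compound)
                    else compound,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
         range = range(conc), n = nrow(calibration)),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("<standard_curve> ", x$compound, ": response = ",
      format(x$slope, digits = 4), " * conc + ",
      format(x$intercept, digits = 4), " (R2 = ",
      format(x$r_squared, digits = 4), ", n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Absolute titers from relative yields and standard curves
#'
#' Inverts each compound's mapped curve:
#' `titer = (response - intercept) / slope`, floored at 0. Compounds
#' without a curve of their own are quantified through the curve named in
#' `response_map` (identical-response-factor assumption); compounds
#' mapped to no curve at all are dropped with a message.
#'
#' @param yields Output of [relative_yield()].
#' @param curves Named list of `standard_curve` objects, keyed by
#'   compound.
#' @param response_map Named character vector compound -> curve compound.
#'   Default maps each curve compound to itself plus `3 -> "2"` and
#'   `7 -> "2"` (oxygenated manoyl-oxide derivatives read off the
#'   11-oxo curve).
#' @return `yields` with added columns `curve_compound` and
#'   `titer_mg_per_L`, rows restricted to mapped compounds.
#' @export
absolute_titer <- function(yields, curves,
                           response_map = default_response_map(curves)) {
  mapped <- yields[yields$compound %in% names(response_map), ]
  dropped <- setdiff(unique(yields$compound), names(response_map))
  if (length(dropped) > 0L) {
    message("no standard curve mapped for compound(s): ",
            paste(dropped, collapse = ", "), "; excluded from titers")
  }
  mapped$curve_compound <- unname(response_map[mapped$compound])
  unknown <- setdiff(unique(mapped$curve_compound), names(curves))
  if (length(unknown) > 0L) {
    stop("response_map names missing curve(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  mapped$titer_mg_per_L <- vapply(seq_len(nrow(mapped)), function(i) {
    cu <- curves[[mapped$curve_compound[i]]]
    max(0, (mapped$mean_response[i] - cu$intercept) / cu$slope)
  }, numeric(1))
  mapped
}

default_response_map <- function(curves) {
  m <- stats::setNames(names(curves), names(curves))
  if ("2" %in% names(curves)) {
    extra <- stats::setNames(c("2", "2"), c("3", "7"))
    m <- c(m, extra[setdiff(names(extra), names(m))])
  }
  m
}

#' Per-strain production and specificity metrics
#'
#' From per-compound titers of one strain: total production over the
#' quantified compound set, the share of total that is oxygenated
#' (everything except the unmodified substrate, compound 1) and the
#' share that is the target product (compound 2). Zero-total strains
#' report 0% for both. Optionally computes per-compound fold changes
#' against a reference strain's titers.
#'
#' @param titers Named numeric vector of titers (mg/L) keyed by compound
#'   id; compound `"1"` (the substrate) must be present, possibly 0.
#' @param reference_titers Optional named titer vector of the reference
#'   strain for fold changes.
#' @param quantified_set Compound ids summed into the total (default
#'   `c("1","2","3","7")`).
#' @param substrate,target Compound ids of the unmodified substrate and
#'   the target product (defaults `"1"`, `"2"`).
#' @return Object of class `strain_metrics`: `titers`, `total`,
#'   `oxygenated_pct`, `content_target_pct` (unrounded; reports round to
#'   integers) and, when a reference is given, `fold_change` (named
#'   vector, `Inf` where the reference titer is 0 and the strain's is
#'   not, 1 where both are 0).
#' @export
strain_metrics <- function(titers, reference_titers = NULL,
                           quantified_set = c("1", "2", "3", "7"),
                           substrate = "1", target = "2") {
  if (!(substrate %in% names(titers))) {
    stop("substrate compound '", substrate, "' missing from titers",
         call. = FALSE)
  }
  use <- intersect(quantified_set, names(titers))
  total <- sum(titers[use])
  oxy <- if (total == 0) 0 else
    100 * (total - titers[[substrate]]) / total
  content <- if (total == 0 || !(target %in% names(titers))) 0 else
    100 * titers[[target]] / total
  fc <- NULL
  if (!is.null(reference_titers)) {
    shared <- intersect(use, names(reference_titers))
    fc <- vapply(shared, function(k) {
      if (reference_titers[[k]] == 0) {
        if (titers[[k]] == 0) 1 else Inf
      } else titers[[k]] / reference_titers[[k]]
    }, numeric(1))
  }
  structure(
    list(titers = titers[use], total = total, oxygenated_pct = oxy,
         content_target_pct = content, fold_change = fc,
         quantified_set = use, substrate = substrate, target = target),
    class = "strain_metrics"
  )
}

#' @export
print.strain_metrics <- function(x, ...) {
  cat("<strain_metrics> total ", round(x$total, 1), " mg/L, oxygenated ",
      round(x$oxygenated_pct), "%, content of target ",
      round(x$content_target_pct), "%\n", sep = "")
  invisible(x)
}

#' Welch two-sample comparison
#'
#' Two-sided Welch t-test via [stats::t.test()]. Degenerate input (zero
#' variance in both groups) returns p = 1 when the means are equal and
#' p = 0 when they are not, by convention, instead of erroring.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return p-value.
#' @export
compare_groups <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    return(if (mean(group_a) == mean(group_b)) 1 else 0)
  }
  stats::t.test(group_a, group_b, var.equal = FALSE)$p.value
}

#' Time-course summary with stagnation flag
#'
#' Per (strain, compound) series over timepoints; production is flagged
#' as stagnated when the increase over the final interval is less than
#' `threshold` (default 10%) of the final value.
#'
#' @param series Tibble with columns `strain`, `compound`,
#'   `timepoint_h` and a value column.
#' @param value Name of the value column (default `titer_mg_per_L`).
#' @param threshold Fraction of the final value (default 0.1).
#' @return Tibble with one row per (strain, compound): `final_value`,
#'   `final_increase`, `stagnated`.
#' @export
timecourse_summary <- function(series, value = "titer_mg_per_L",
                               threshold = 0.1) {
  series |>
    dplyr::group_by(.data$strain, .data$compound) |>
    dplyr::arrange(.data$timepoint_h, .by_group = TRUE) |>
    dplyr::summarise(
      n_timepoints = dplyr::n(),
      final_value = dplyr::last(.data[[value]]),
      final_increase = dplyr::last(.data[[value]]) -
        dplyr::nth(.data[[value]], dplyr::n() - 1L),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      stagnated = dplyr::if_else(
        .data$n_timepoints < 2L, NA,
        .data$final_increase < threshold * .data$final_value
      )
    )
}
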