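#' Published CYP76AH15 variant screening results, transcribed as fixtures
#'
#' Typed records of the published in vivo screening results for
#' CYP76AH15 and its SRS variants in engineered yeast, used as regression
#' fixtures for the quantification arithmetic. Three tables are bundled:
#'
#' * `shake_flask_titers`: per-strain production titers (mg/L) of
#'   13R-manoyl oxide (compound 1), 11-oxo-13R-manoyl oxide (2) and
#'   11-hydroxy-13R-manoyl oxide (3) after 72 h in shake-flasks, with the
#'   printed derived columns (total mg/L, % oxygenated, % content of 2).
#'   The unquantified oxo-hydroxy derivative (compound 7) is not printed
#'   per strain; its titer is recovered as
#'   `total - (titer1 + titer2 + titer3)`, floored at 0, in column
#'   `titer_7`.
#' * `microtiter_fold_changes`: fold changes of products 2 and 3 versus
#'   native CYP76AH15 from the microtiter screen (raw areas were not
#'   published; these are fixture constants, not recomputable).
#' * `forskolin_relative_yields`: relative diterpene yields (fold vs the
#'   native-enzyme strain) in full forskolin-pathway strains; `NA` marks
#'   "not detected" or not reported.
#'
#' Each row carries a `provenance` string (`<table>/<row label>`).
#'
#' @return Named list of three tibbles: `shake_flask_titers`,
#'   `microtiter_fold_changes`, `forskolin_relative_yields`.
#' @export
reference_tables <- function() {
  sf <- tibble::tribble(
    ~strain,                     ~total, ~oxygenated_pct, ~titer_1, ~titer_2, ~titer_3, ~content2_pct,
    "MO (-)",                      43.8,               0,     43.8,      0.0,      0.0,             0,
    "WT CYP76AH15",                43.8,              64,     15.9,     23.4,      0.2,            53,
    "A99I",                        87.7,              99,      0.9,     86.4,      0.4,            99,
    "S235G Y236F",                 73.5,              94,      4.1,     68.6,      0.8,            93,
    "L366F",                       68.2,              96,      3.1,     64.7,      0.5,            95,
    "L366E",                       69.2,              90,      7.0,     61.2,      1.0,            88,
    "A99I S235G Y236F",            83.4,              97,      2.2,     79.8,      1.4,            96,
    "A99I L366F",                  75.8,              96,      2.8,     72.6,      0.4,            96,
    "S235G Y236F L366E",           47.1,              80,      9.6,     34.2,      3.3,            73,
    "A99I S235G Y236F L366F",      59.6,              83,     10.2,     44.2,      5.1,            74
  )
  sf$titer_7 <- pmax(0, sf$total - (sf$titer_1 + sf$titer_2 + sf$titer_3))
  sf$provenance <- paste0("shake_flask/", sf$strain)

  mt <- tibble::tribble(
    ~variant,                     ~srs_sites, ~fold_2, ~fold_3,
    "Native CYP76AH15",           "-",            1,       1,
    "A99I",                       "1",            5.6,     3.0,
    "S235G Y236F",                "3",            5.1,     7.3,
    "L366F",                      "5",            2.9,     4.2,
    "L366E",                      "5",            3.7,     6.2,
    "A99I S235G Y236F",           "1+3",          6.5,    14.2,
    "A99I L366F",                 "1+5",          6.2,     4.9,
    "S235G Y236F L366E",          "3+5",          3.1,    16.5,
    "A99I S235G Y236F L366F",     "1+3+5",        3.2,    31.4
  )
  mt$provenance <- paste0("microtiter/", mt$variant)

  fk <- tibble::tribble(
    ~strain,       ~`1`, ~`2`, ~`3`, ~`8`, ~`9`,  ~a,   ~b,   ~c,
    "MO (-)",       4.1,   NA,   NA,   NA,   NA,  NA,   NA,   NA,
    "FORSK AH15",     1,    1,   NA,    1,    1,   1,    1,    1,
    "FORSK A99I",   0.5,  2.1,   NA,  0.2,  0.5, 0.3,  3.3, 22.7
  )
  fk$provenance <- paste0("forskolin/", fk$strain)

  list(shake_flask_titers = sf, microtiter_fold_changes = mt,
       forskolin_relative_yields = fk)
}

#' Identity percentages reported for the natural CYP76AH subfamily
#'
#' The published per-SRS / total-SRS / full-length identity comparisons
#' for six CYP76AH pairs, kept as a fixture for report formatting and for
#' the optional integration check against user-supplied sequences (the
#' full-length sequences themselves are not redistributed here).
#'
#' @return Tibble with columns `pair`, `SRS1`..`SRS6`, `total_srs`,
#'   `full_length` (integer percent).
#' @export
reference_identity_table <- function() {
  tibble::tribble(
    ~pair,            ~SRS1, ~SRS2, ~SRS3, ~SRS4, ~SRS5, ~SRS6, ~total_srs, ~full_length,
    "AH15 and AH8",      79,    88,    75,    89,   100,    50,         82,           87,
    "AH15 and AH17",     75,    88,    75,    89,   100,    50,         81,           80,
    "AH8 and AH17",      96,   100,   100,   100,   100,   100,         99,           88,
    "AH11 and AH16",     54,    88,    50,    89,    82,    63,         71,           76,
    "AH15 and AH11",     46,    25,    50,    42,    82,    25,         46,           51,
    "AH15 and AH16",     50,    25,    25,    47,    82,    25,         46,           54
  )
}
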