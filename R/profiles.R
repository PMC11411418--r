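#' Dye response profiles for the synthetic-data generator
#'
#' A response profile gives, for each sensing element, the mean corrected
#' color change (dR, dG, dB, in 8-bit color units) it shows toward each
#' analyte class, plus two per-element trend parameters:
#'
#' * `chain_slope` — signed per-carbon trend: the class mean triplet is
#'   scaled by `1 + chain_slope * (carbon_count - class_min_carbon)`, so
#'   longer-chain homologues strengthen or fade the spot response.
#' * `severity_slope` — gain on the `urine_severity` increment: an injured
#'   subject at ordinal grade g gets
#'   `urine_injured + severity_slope * g * urine_severity` as mean triplet,
#'   so elements with a nonzero `urine_severity` row respond linearly in
#'   injury severity and are silent in controls when their `urine_control`
#'   and `urine_injured` rows are zero.
#'
#' The defaults encode the qualitative selectivity structure of the dye
#' panel: alizarin red S (S1) and toluidine blue (S3) respond mainly to
#' alcohols; phenol red (S6), pararosaniline (S7) and bromopyrogallol red
#' (S8) to aldehydes; malachite green (S4) to esters; eriochrome black T
#' (S12) strongly to all three classes; every element shows at least a
#' weak response to every vapor. In urine mode S4 and S8 respond in both
#' cohorts while S3 and S7 respond only in injured subjects, scaled by
#' severity grade. Aldehyde-selective spots carry carbon-chain trends
#' (S6 strengthens, S7 and S8 fade with chain length).
#'
#' @return A tibble with columns `element`, `class`, `dR`, `dG`, `dB`,
#'   `chain_slope`, `severity_slope`; one row per element x class.
#' @export
#' @examples
#' default_profiles() |> dplyr::filter(element == "S3")
default_profiles <- function() {
  # element, class, dR, dG, dB (corrected deltas, 8-bit units)
  m <- tibble::tribble(
    ~element, ~class,     ~dR, ~dG, ~dB,
    "S1",  "alcohol",  -60, -20,  30,
    "S1",  "aldehyde",  -8,  -3,   4,
    "S1",  "ester",    -10,  -4,   5,
    "S2",  "alcohol",  -35, -10,  20,
    "S2",  "aldehyde",  -5,  -2,   3,
    "S2",  "ester",    -30, -12,  18,
    "S3",  "alcohol",  -55,  25, -15,
    "S3",  "aldehyde",  -6,   3,  -2,
    "S3",  "ester",     -8,   4,  -3,
    "S4",  "alcohol",   -6,  -2,   3,
    "S4",  "aldehyde",  -8,  -3,   4,
    "S4",  "ester",    -50, -30,  25,
    "S5",  "alcohol",   -5,   2,  -3,
    "S5",  "aldehyde", -40, -15,  20,
    "S5",  "ester",    -28, -10,  14,
    "S6",  "alcohol",   -4,  -2,   2,
    "S6",  "aldehyde",  45, -35, -20,
    "S6",  "ester",     -6,  -4,   3,
    "S7",  "alcohol",   -5,  -2,   2,
    "S7",  "aldehyde", -55,  30,  20,
    "S7",  "ester",     -7,   3,   3,
    "S8",  "alcohol",   -6,   2,  -2,
    "S8",  "aldehyde", -45, -25,  35,
    "S8",  "ester",     -7,  -4,   5,
    "S9",  "alcohol",   -8,  -3,   4,
    "S9",  "aldehyde", -10,  -4,   5,
    "S9",  "ester",     -9,  -3,   4,
    "S10", "alcohol",   -6,  -2,   3,
    "S10", "aldehyde", -35, -18,  15,
    "S10", "ester",    -30, -15,  12,
    "S11", "alcohol",   -5,  -2,   2,
    "S11", "aldehyde",  -7,  -3,   3,
    "S11", "ester",    -38, -20,  16,
    "S12", "alcohol",  -50, -25,  30,
    "S12", "aldehyde", -45, -20,  28,
    "S12", "ester",    -40, -18,  24,
    # urine cohorts: S4/S8 (+ weak S12) respond in both groups; S3/S7
    # respond only through the severity increment
    "S3",  "urine_severity", -18,   9,  -6,
    "S7",  "urine_severity", -16,   9,   7,
    "S4",  "urine_control",  -25, -15,  12,
    "S4",  "urine_injured",  -38, -23,  18,
    "S8",  "urine_control",  -20, -12,  15,
    "S8",  "urine_injured",  -30, -17,  22,
    "S12", "urine_control",  -10,  -5,   6,
    "S12", "urine_injured",  -14,  -7,   8
  )
  all_cls <- c("alcohol", "aldehyde", "ester", "urine_control",
               "urine_injured", "urine_severity", "water", "empty")
  full <- tidyr::expand_grid(element = element_ids(), class = all_cls) |>
    dplyr::left_join(m, by = c("element", "class")) |>
    dplyr::mutate(dplyr::across(c("dR", "dG", "dB"), ~ tidyr::replace_na(.x, 0)))
  trends <- tibble(
    element = element_ids(),
    chain_slope = c(0, 0, 0, 0, 0, 0.15, -0.08, -0.08, 0, 0, 0, 0),
    severity_slope = c(0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 0, 0)
  )
  out <- dplyr::left_join(full, trends, by = "element")
  class(out) <- c("response_profiles", class(out))
  out
}

#' Validate response profiles
#'
#' Checks the structural invariants the generator relies on: all 12
#' elements covered for every class used, channel means within
#' `[-255, 255]`, the documented selectivity pattern (S1/S3 alcohol,
#' S6/S7/S8 aldehyde, S4 ester, S12 all three), and the urine-mode
#' structure (S3/S7 silent in controls, severity-responsive in injured;
#' S4/S8 responding in both cohorts).
#'
#' @param profiles A profiles tibble as from [default_profiles()].
#' @return The profiles, invisibly, or an error.
#' @export
validate_profiles <- function(profiles) {
  need <- c("element", "class", "dR", "dG", "dB", "chain_slope", "severity_slope")
  if (!all(need %in% names(profiles))) {
    abort("profiles must have columns element, class, dR, dG, dB, chain_slope, severity_slope")
  }
  ch <- as.matrix(profiles[, c("dR", "dG", "dB")])
  if (any(abs(ch) > 255)) abort("profile channel means must lie in [-255, 255]")
  if (!all(element_ids() %in% profiles$element)) {
    abort("profiles must cover all 12 elements S1..S12")
  }
  nonzero <- function(el, cls) {
    row <- profiles[profiles$element == el & profiles$class == cls, c("dR", "dG", "dB")]
    nrow(row) > 0 && any(abs(as.numeric(row[1, ])) > 0)
  }
  sel_ok <- nonzero("S1", "alcohol") && nonzero("S3", "alcohol") &&
    nonzero("S6", "aldehyde") && nonzero("S7", "aldehyde") &&
    nonzero("S8", "aldehyde") && nonzero("S4", "ester") &&
    nonzero("S12", "alcohol") && nonzero("S12", "aldehyde") &&
    nonzero("S12", "ester")
  if (!sel_ok) abort("profiles violate the dye selectivity pattern")
  urine_ok <- !nonzero("S3", "urine_control") && !nonzero("S7", "urine_control") &&
    nonzero("S3", "urine_severity") && nonzero("S7", "urine_severity") &&
    nonzero("S4", "urine_control") && nonzero("S4", "urine_injured") &&
    nonzero("S8", "urine_control") && nonzero("S8", "urine_injured")
  if (!urine_ok) abort("profiles violate the urine-mode response structure")
  invisible(profiles)
}

# mean 36-vector (named, canonical order) for one element-class table,
# given per-element scale factors (chain/severity adjustments)
profile_mean_vector <- function(profiles, cls, scale = NULL) {
  rows <- profiles[profiles$class == cls, ]
  rows <- rows[match(element_ids(), rows$element), ]
  m <- as.matrix(rows[, c("dR", "dG", "dB")])
  if (!is.null(scale)) m <- m * scale
  m <- pmin(pmax(m, -255), 255)
  setNames(as.vector(t(m)), response_cols())
}

#' Default volatile-compound panel
#'
#' The nine pure compounds used to probe the array: three alcohols, three
#' aldehydes and three esters, with their carbon counts (the per-class
#' chain trend acts on `carbon_count` minus the class minimum).
#'
#' @return A tibble with columns `compound`, `class`, `carbon_count`.
#' @export
default_voc_panel <- function() {
  tibble::tribble(
    ~compound,        ~class,     ~carbon_count,
    "ethanol",        "alcohol",  2,
    "butanol",        "alcohol",  4,
    "hexanol",        "alcohol",  6,
    "acetaldehyde",   "aldehyde", 2,
    "butyraldehyde",  "aldehyde", 4,
    "hexanaldehyde",  "aldehyde", 6,
    "ethyl acetate",  "ester",    4,
    "ethyl butyrate", "ester",    6,
    "ethyl hexanoate","ester",    8
  )
}
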