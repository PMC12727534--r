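#' Scalar metabolic phenotype indices
#'
#' Vectorised formulas for the standard phenotype read-outs accompanying a
#' metabolic-programming study:
#'
#' * `homa_ir()` — insulin-resistance index: fasting insulin (uIU/ml) times
#'   fasting glucose (mmol/l) divided by 22.5.
#' * `odour_preference_index()` — difference in percentage of time spent in
#'   the two odour compartments (percentage points; positive favours the
#'   first odour).
#' * `percent_kcal_hfd()` — percentage of calories consumed from the
#'   high-fat diet in a two-diet choice test.
#' * `normalized_latency()` — latency to eat a test diet divided by the
#'   latency to eat the reference diet (unitless; 1 = equal attraction).
#' * `ee_lean_corrected()` — energy expenditure divided by lean mass
#'   (kcal/h per g lean), the ratio form of lean-mass correction for
#'   indirect calorimetry.
#'
#' @param insulin Fasting insulin in uIU/ml (> 0).
#' @param glucose Fasting glucose in mmol/l (> 0).
#' @return `homa_ir()`: the unitless HOMA-IR index.
#' @examples
#' homa_ir(10, 9)            # 4
#' odour_preference_index(70, 30)  # 40
#' percent_kcal_hfd(3, 1)    # 75
#' @export
homa_ir <- function(insulin, glucose) {
  if (any(!is.finite(insulin)) || any(!is.finite(glucose)) ||
      any(insulin <= 0) || any(glucose <= 0)) {
    abort_domain("`insulin` and `glucose` must be positive and finite.")
  }
  insulin * glucose / 22.5
}

#' @param pct_first,pct_second Percentage of session time spent in each
#'   odour compartment; non-negative, summing to at most 100.
#' @return `odour_preference_index()`: `pct_first - pct_second` in
#'   percentage points.
#' @rdname homa_ir
#' @export
odour_preference_index <- function(pct_first, pct_second) {
  if (any(pct_first < 0) || any(pct_second < 0)) {
    abort_domain("Compartment times must be non-negative percentages.")
  }
  if (any(pct_first + pct_second > 100 + 1e-9)) {
    abort_domain("Compartment percentages must sum to at most 100.")
  }
  pct_first - pct_second
}

#' @param kcal_hfd,kcal_other Calories consumed from the high-fat diet and
#'   the alternative diet (total > 0).
#' @return `percent_kcal_hfd()`: percentage of total calories from HFD.
#' @rdname homa_ir
#' @export
percent_kcal_hfd <- function(kcal_hfd, kcal_other) {
  if (any(kcal_hfd < 0) || any(kcal_other < 0)) {
    abort_domain("Caloric intakes must be non-negative.")
  }
  total <- kcal_hfd + kcal_other
  if (any(total <= 0)) abort_domain("Total intake must be > 0.")
  100 * kcal_hfd / total
}

#' @param latency_test,latency_ref Latencies to eat the test and reference
#'   diets, in seconds (`latency_ref > 0`).
#' @return `normalized_latency()`: the unitless ratio.
#' @rdname homa_ir
#' @export
normalized_latency <- function(latency_test, latency_ref) {
  if (any(latency_test < 0)) abort_domain("Latencies must be non-negative.")
  if (any(latency_ref <= 0)) abort_domain("`latency_ref` must be > 0.")
  latency_test / latency_ref
}

#' @param ee Energy expenditure in kcal/h (non-negative).
#' @param lean_mass Lean body mass in g (> 0).
#' @return `ee_lean_corrected()`: kcal/h per g lean mass.
#' @rdname homa_ir
#' @export
ee_lean_corrected <- function(ee, lean_mass) {
  if (any(ee < 0)) abort_domain("`ee` must be non-negative.")
  if (any(lean_mass <= 0)) abort_domain("`lean_mass` must be > 0.")
  ee / lean_mass
}

#' Add phenotype indices to a phenotype table
#'
#' Convenience wrapper mapping the scalar formulas over a per-animal
#' phenotype tibble. Only indices whose input columns are present are
#' added.
#'
#' @param data Tibble with any of the column pairs `insulin`/`glucose`
#'   (uIU/ml, mmol/l), `time_pct_aceto`/`time_pct_iso` (percent),
#'   `kcal_hfd`/`kcal_cd` (kcal), `latency_afd`/`latency_ncd` (s),
#'   `ee`/`lean_mass` (kcal/h, g).
#' @return `data` with columns `homa_ir`, `odour_pref`, `pct_kcal_hfd`,
#'   `latency_norm`, `ee_per_lean` appended where computable.
#' @export
add_phenotype_indices <- function(data) {
  stopifnot(is.data.frame(data))
  has <- function(...) all(c(...) %in% names(data))
  out <- as_tibble(data)
  if (has("insulin", "glucose")) {
    out <- dplyr::mutate(out, homa_ir = homa_ir(.data$insulin, .data$glucose))
  }
  if (has("time_pct_aceto", "time_pct_iso")) {
    out <- dplyr::mutate(out, odour_pref = odour_preference_index(
      .data$time_pct_aceto, .data$time_pct_iso))
  }
  if (has("kcal_hfd", "kcal_cd")) {
    out <- dplyr::mutate(out, pct_kcal_hfd = percent_kcal_hfd(
      .data$kcal_hfd, .data$kcal_cd))
  }
  if (has("latency_afd", "latency_ncd")) {
    out <- dplyr::mutate(out, latency_norm = normalized_latency(
      .data$latency_afd, .data$latency_ncd))
  }
  if (has("ee", "lean_mass")) {
    out <- dplyr::mutate(out, ee_per_lean = ee_lean_corrected(
      .data$ee, .data$lean_mass))
  }
  out
}
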