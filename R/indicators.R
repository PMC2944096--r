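#' Declare an indicator feeding one of the composite indices
#'
#' An indicator is a raw unit-level field (a column of the unit table) that
#' contributes to either the hazard-exposure index (H) or the
#' adaptive-capacity index (A). `polarity` states the direction of its effect:
#' `+1` when a higher raw value should raise the index, `-1` when it should
#' lower it (e.g. poverty rate lowers adaptive capacity). Weights are relative
#' within one index and are normalized to sum to one before combination.
#'
#' @param name column name of the raw indicator in the unit table.
#' @param index `"H"` (hazards/stressors exposure) or `"A"` (adaptive
#'   capacity / social character).
#' @param polarity `+1` or `-1`.
#' @param weight non-negative relative weight (default 1, i.e. equal weights).
#' @return a one-row data.frame with columns `name`, `index`, `polarity`,
#'   `weight`; rbind several to form an indicator set.
#' @seealso [default_indicators()]
#' @examples
#' rbind(
#'   indicator_spec("pop_density", "H", +1),
#'   indicator_spec("poverty_pct", "A", -1)
#' )
#' @export
indicator_spec <- function(name, index = c("H", "A"), polarity = 1, weight = 1) {
  index <- match.arg(index)
  if (!polarity %in% c(1, -1)) abort("polarity must be +1 or -1")
  if (!is.numeric(weight) || weight < 0) abort("weight must be non-negative")
  data.frame(
    name = as.character(name), index = index,
    polarity = as.numeric(polarity), weight = as.numeric(weight),
    stringsAsFactors = FALSE
  )
}

#' Default indicator set for the H and A indices
#'
#' The hazard index combines three density proxies (population, average daily
#' traffic, stationary pollution sources per unit area), all raising exposure.
#' The adaptive-capacity index combines five census-style social indicators:
#' percent of adults with high school as highest education (-), median
#' household income (+), percent of households in poverty (-), percent of
#' linguistically isolated households (-), and percent minority population
#' (-). All indicators carry equal weight by default, in the spirit of
#' equal-weight composite development indices; weights are fully configurable
#' via [indicator_spec()].
#'
#' Adaptive capacity should not be inferred from race or ethnicity in
#' isolation: `include_minority = FALSE` drops the minority indicator from the
#' A composite, in which case [compute_indices()] instead emits an
#' environmental-justice flag for units combining a high minority share with
#' very low capacity on the remaining indicators.
#'
#' @param include_minority keep the minority-share indicator inside the A
#'   composite (default `TRUE`).
#' @return data.frame of indicator specs (one row per indicator).
#' @export
default_indicators <- function(include_minority = TRUE) {
  specs <- rbind(
    indicator_spec("pop_density", "H", +1),
    indicator_spec("traffic_density", "H", +1),
    indicator_spec("pollution_density", "H", +1),
    indicator_spec("education_hs_pct", "A", -1),
    indicator_spec("median_income", "A", +1),
    indicator_spec("poverty_pct", "A", -1),
    indicator_spec("linguistic_isolation_pct", "A", -1),
    indicator_spec("minority_pct", "A", -1)
  )
  if (!include_minority) {
    specs <- specs[specs$name != "minority_pct", , drop = FALSE]
    rownames(specs) <- NULL
  }
  specs
}

# validate an indicator-spec data.frame; weights must sum > 0 within each index
check_indicator_specs <- function(specs) {
  need <- c("name", "index", "polarity", "weight")
  if (!is.data.frame(specs) || !all(need %in% names(specs))) {
    abort("indicator specs must be a data.frame with columns %s",
          paste(need, collapse = ", "))
  }
  if (anyDuplicated(specs$name)) abort("duplicate indicator name in specs")
  if (!all(specs$polarity %in% c(1, -1))) abort("polarity must be +1 or -1")
  if (any(specs$weight < 0)) abort("indicator weights must be non-negative")
  for (idx in unique(specs$index)) {
    if (sum(specs$weight[specs$index == idx]) <= 0) {
      abort("weights for index %s must sum to a positive value", idx)
    }
  }
  invisible(specs)
}
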