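# First-year soil N2O: IPCC tier-1 baseline and the biochar-induced credit.

#' Describe nitrogen inputs to the amended land
#'
#' @param area_ha Hectares receiving biochar above the eligibility
#'   threshold.
#' @param n_rate All direct nitrogen inputs, Mg N per hectare per year.
#' @param ef Tier-1 emission factor, fraction of N emitted as N2O-N
#'   (default 0.01, must lie in \[0, 0.1\]).
#' @param source_note Free-text provenance of the activity data.
#' @return Object of class `nitrogen_inputs`.
#' @export
nitrogen_inputs <- function(area_ha, n_rate, ef = bc_constants()$tier1_ef,
                            source_note = "") {
  stopifnot(is.numeric(area_ha), area_ha >= 0,
            is.numeric(n_rate), n_rate >= 0)
  if (ef < 0 || ef > 0.1) {
    stop("emission factor must lie in [0, 0.1]", call. = FALSE)
  }
  structure(
    list(area_ha = area_ha, n_rate = n_rate, ef = ef,
         source_note = source_note),
    class = "nitrogen_inputs"
  )
}

#' Baseline first-year N2O emission (tier 1)
#'
#' `area x n_rate x ef x 1.57`: direct N2O emitted annually from the land
#' receiving biochar, in Mg N2O per year, where 1.57 converts N2O-N to N2O
#' mass. Returned both raw and rounded to two significant figures — the
#' rounding convention used when quoting tier-1 results.
#'
#' @param inputs A [nitrogen_inputs()].
#' @return List with `raw` and `rounded` (2 significant figures), Mg N2O
#'   per year.
#' @export
#' @examples
#' baseline_n2o(nitrogen_inputs(1000, 0.15)) # raw 2.355, rounded 2.4
baseline_n2o <- function(inputs) {
  stopifnot(inherits(inputs, "nitrogen_inputs"))
  k <- bc_constants()
  raw <- inputs$area_ha * inputs$n_rate * inputs$ef * k$n2o_n_to_n2o
  list(raw = raw, rounded = signif(raw, 2))
}

#' N2O-credit eligibility
#'
#' The first-year N2O reduction applies only where the biochar application
#' rate exceeds 10 Mg of biochar carbon per hectare (strict inequality),
#' with the rate computed as `mass x F_C / area`.
#'
#' @param application_rate_c Mg biochar C per hectare.
#' @return `TRUE` iff the rate strictly exceeds the threshold.
#' @export
#' @examples
#' n2o_eligible(15 * 0.68) # 10.2 Mg C/ha -> TRUE
n2o_eligible <- function(application_rate_c) {
  stopifnot(application_rate_c >= 0)
  application_rate_c > bc_constants()$n2o_eligibility_threshold
}

#' First-year N2O credit in CO2-equivalents
#'
#' `co2e = baseline x reduction x gwp` when eligible, else 0. The credit
#' covers only the first year after amendment (longer-term persistence of
#' the effect is not demonstrated), and its inclusion in a GHG balance is
#' optional — it is typically small relative to the sequestration term.
#'
#' @param baseline Baseline annual N2O emission, Mg N2O.
#' @param eligible From [n2o_eligible()].
#' @param gwp 100-year global warming potential of N2O (273 current
#'   default; 298 for AR4-based comparisons).
#' @param reduction Fractional first-year reduction in N2O emissions
#'   (default 0.23; 95% CI 0.05-0.41 available in [bc_constants()]).
#' @return Object of class `n2o_credit`: `baseline_n2o`,
#'   `reduction_fraction`, `gwp_used`, `eligible`, `co2e` (Mg CO2e).
#' @export
#' @examples
#' n2o_credit(2.4, TRUE, gwp = 298)$co2e # 164.5
n2o_credit <- function(baseline, eligible,
                       gwp = bc_constants()$gwp_n2o_default,
                       reduction = bc_constants()$n2o_reduction) {
  stopifnot(baseline >= 0, is.logical(eligible),
            reduction >= 0, reduction <= 1)
  structure(
    list(
      baseline_n2o = baseline,
      reduction_fraction = reduction,
      gwp_used = gwp,
      eligible = eligible,
      co2e = if (eligible) baseline * reduction * gwp else 0
    ),
    class = "n2o_credit"
  )
}
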