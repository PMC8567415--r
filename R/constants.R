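# Physical constants, method defaults, and frozen regression coefficients.
# Every number here is a fixed method parameter; none may be altered at run
# time except the GWP choice, which is a config option (see bc_config()).

#' Method constants
#'
#' Returns the fixed physical constants and default emission-factor
#' parameters used throughout the package: the C-to-CO2e mass conversion
#' (44/12), the 100-year global warming potentials of N2O (273 current IPCC,
#' 298 AR4), the first-year N2O reduction effect size (23%, 95% CI 5-41%),
#' the eligibility threshold for the N2O credit (10 Mg C ha-1, strict), the
#' tier-1 N2O emission factor (0.01 Mg N2O-N per Mg N) and the N2O-N to N2O
#' mass conversion (1.57), the Q10 temperature-response coefficients
#' (Q10(T) = 1.1 + 12.0 exp(-0.19 T)), the mean annual soil temperatures of
#' global (14.9 degC) and US (10.9 degC) croplands, and the minimum
#' pyrolysis temperature covered by the method (350 degC).
#'
#' @return Named list of constants. Treat as immutable.
#' @export
#' @examples
#' bc_constants()$co2_per_c # 44/12
bc_constants <- function() {
  list(
    co2_per_c = 44 / 12,
    gwp_n2o_default = 273,
    gwp_n2o_ar4 = 298,
    n2o_reduction = 0.23,
    n2o_reduction_ci = c(lower = 0.05, upper = 0.41),
    n2o_eligibility_threshold = 10,    # Mg C ha-1, strict inequality
    tier1_ef = 0.01,                   # Mg N2O-N per Mg N input
    n2o_n_to_n2o = 1.57,               # approx 44/28
    q10_a = 1.1,
    q10_b = 12.0,
    q10_c = 0.19,
    global_cropland_temp = 14.9,       # degC
    us_cropland_temp = 10.9,           # degC
    min_pyrolysis_temp = 350,          # degC; lower-temperature chars excluded
    max_pyrolysis_temp = 900,          # degC; upper limit of regression domain
    hc_atypical_threshold = 0.7        # molar H/C_org above which char is atypical
  )
}

#' Coefficients of the continuous carbon-fraction regressions
#'
#' The continuous estimator expresses the dry-ash-free organic carbon
#' fraction of biochar as a saturating exponential of pyrolysis temperature,
#' `fc_daf(T) = a - b exp(-c T)`, and the dry-ash-free char yield as a linear
#' function of feedstock lignin content plus an exponential decline with
#' temperature, `y_bc(L, T) = a + m L + b exp(-k T)`. The coefficients below
#' were calibrated once, by least squares, against the packaged class-level
#' carbon-content table driven by the packaged feedstock composition table at
#' class-representative temperatures (400, 525, 700 degC), and are frozen;
#' a pinned-point test guards against silent drift. The source meta-analyses
#' report R2 = 0.65 for both regressions; that value is attached as metadata.
#'
#' @return Named list with elements `eq_fc_daf` (a, b, c), `eq_yield`
#'   (a, m_lignin, b, k), their `r2` metadata, and `rep_temps`, the
#'   representative temperature of each pyrolysis class.
#' @seealso [fc_daf()], [biochar_yield_daf()]
#' @export
fc_regression <- function() {
  list(
    eq_fc_daf = c(a = 0.850000, b = 0.717803, c = 0.004037),
    eq_fc_daf_r2 = 0.65,
    eq_yield = c(a = 0.173694, m_lignin = 0.205241, b = 0.918917, k = 0.002331),
    eq_yield_r2 = 0.65,
    rep_temps = c(low = 400, medium = 525, high = 700)
  )
}
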