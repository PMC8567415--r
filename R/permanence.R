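# F_perm: fraction of biochar organic carbon remaining after a chosen
# timeframe at a chosen soil temperature, via the pyrolysis-class
# parameterization, the H/C_org regression, or the conservative fallback.

.bc_perm_result <- function(fperm, se = NA_real_, method, warnings = character()) {
  structure(
    list(fperm = fperm, se = se, method = method, warnings = warnings),
    class = "permanence_result"
  )
}

#' @export
print.permanence_result <- function(x, ...) {
  cat("F_perm =", format(x$fperm, digits = 4),
      if (!is.na(x$se)) paste0("(SE ", format(x$se), ")"),
      "[", x$method, "]\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

# Domain guard shared by the permanence entry points. Returns a character
# vector of warnings (possibly empty); errors when out of domain and
# extrapolation was not requested.
.bc_perm_domain <- function(timeframe, soil_temp, extrapolate) {
  stopifnot(timeframe > 0)
  warnings <- character()
  out <- timeframe < 100 || timeframe > 1000 || soil_temp < 5 || soil_temp > 25
  if (out) {
    if (!extrapolate) {
      stop("(", soil_temp, " degC, ", timeframe, " y) is outside the ",
           "supported domain (soil temperature 5-25 degC, timeframe ",
           "100-1000 y); pass extrapolate = TRUE to evaluate the calibrated ",
           "surface outside it", call. = FALSE)
    }
    warnings <- paste0("extrapolated outside the supported domain (",
                       soil_temp, " degC, ", timeframe, " y)")
  }
  warnings
}

#' Permanence from the pyrolysis-temperature class
#'
#' Serves the printed grid cell verbatim (with its standard error) when the
#' query hits one of the 21 printed (soil temperature, timeframe) points, so
#' that inventory outputs are auditable against the published table.
#' Off-grid queries are evaluated from the two-pool surface calibrated to
#' the grid ([calibrate_class_pools()]).
#'
#' @param temp_class `"low"`, `"medium"` or `"high"`.
#' @param timeframe Accounting timeframe, years (default 100).
#' @param soil_temp Mean annual soil temperature, degC (default 14.9, the
#'   global cropland mean).
#' @param extrapolate Allow queries outside soil temperature 5-25 degC or
#'   timeframe 100-1000 y (refused by default); extrapolated results carry
#'   a warning in the result object.
#' @return A `permanence_result`: `fperm`, `se` (`NA` off-grid), `method`
#'   (`"exact_cell"` or `"calibrated_surface"`), `warnings`.
#' @export
#' @examples
#' fperm_from_class("medium", 100, 10) # 0.79, exact cell
fperm_from_class <- function(temp_class = c("low", "medium", "high"),
                             timeframe = 100,
                             soil_temp = bc_constants()$global_cropland_temp,
                             extrapolate = FALSE) {
  temp_class <- match.arg(temp_class)
  warnings <- .bc_perm_domain(timeframe, soil_temp, extrapolate)
  cell <- tryCatch(get_permanence_cell(soil_temp, timeframe),
                   error = function(e) NULL)
  if (!is.null(cell)) {
    return(.bc_perm_result(
      fperm = cell[[paste0("fperm_", temp_class)]],
      se = cell[[paste0("fperm_", temp_class, "_se")]],
      method = "exact_cell", warnings = warnings
    ))
  }
  pools <- calibrate_class_pools(temp_class)
  val <- fraction_remaining(pools, timeframe, soil_temp)
  .bc_perm_result(min(max(val, 0), 1), method = "calibrated_surface",
                  warnings = warnings)
}

# Bilinear interpolation of the H/C regression coefficients in
# (soil temperature, log10 timeframe) between printed cells; queries beyond
# the grid edge (reachable only with extrapolate = TRUE) clamp to the edge.
.bc_hc_coefs <- function(soil_temp, timeframe) {
  tab <- permanence_table()
  temps <- sort(unique(tab$soil_temp_c))
  times <- sort(unique(tab$timeframe_years))
  coef_at <- function(Tt, tf, what) {
    tab[[what]][abs(tab$soil_temp_c - Tt) < 1e-9 &
                  abs(tab$timeframe_years - tf) < 1e-9]
  }
  clamp <- function(x, lo, hi) min(max(x, lo), hi)
  Tq <- clamp(soil_temp, min(temps), max(temps))
  tq <- clamp(timeframe, min(times), max(times))
  iT <- findInterval(Tq, temps, rightmost.closed = TRUE)
  it <- findInterval(tq, times, rightmost.closed = TRUE)
  iT <- clamp(iT, 1, length(temps) - 1)
  it <- clamp(it, 1, length(times) - 1)
  T0 <- temps[iT]; T1 <- temps[iT + 1]
  t0 <- times[it]; t1 <- times[it + 1]
  wT <- if (T1 > T0) (Tq - T0) / (T1 - T0) else 0
  wt <- if (t1 > t0) (log10(tq) - log10(t0)) / (log10(t1) - log10(t0)) else 0
  interp <- function(what) {
    v00 <- coef_at(T0, t0, what); v10 <- coef_at(T1, t0, what)
    v01 <- coef_at(T0, t1, what); v11 <- coef_at(T1, t1, what)
    (1 - wt) * ((1 - wT) * v00 + wT * v10) + wt * ((1 - wT) * v01 + wT * v11)
  }
  list(c_hc = interp("c_hc"), m_hc = interp("m_hc"))
}

#' Permanence from the molar H/C_org ratio
#'
#' Evaluates the linear regression `F_perm = c_hc + m_hc * H/C_org` with
#' coefficients taken from the matching permanence-grid cell, or
#' interpolated bilinearly in (soil temperature, log10 timeframe) between
#' printed cells for off-grid queries. The raw regression value is clamped
#' to \[0, 1\] (the intercept exceeds 1 at low soil temperatures); clamping
#' is recorded as a warning in the result.
#'
#' @param hc Molar H/C_org ratio, in \[0, 1.5\]. Values above 0.7 are
#'   atypical of carbonized material and draw a warning.
#' @inheritParams fperm_from_class
#' @return A `permanence_result` with method `"hc_regression"`.
#' @export
#' @examples
#' fperm_from_hc(0.5, 100, 14.9) # 1.04 - 0.64 * 0.5 = 0.72
fperm_from_hc <- function(hc, timeframe = 100,
                          soil_temp = bc_constants()$global_cropland_temp,
                          extrapolate = FALSE) {
  k <- bc_constants()
  stopifnot(is.numeric(hc), length(hc) == 1)
  if (hc < 0 || hc > 1.5) stop("H/C_org must lie in [0, 1.5]", call. = FALSE)
  warnings <- .bc_perm_domain(timeframe, soil_temp, extrapolate)
  if (hc > k$hc_atypical_threshold) {
    warnings <- c(warnings, paste0(
      "H/C_org = ", hc, " exceeds ", k$hc_atypical_threshold,
      ", atypical of carbonized material"))
  }
  cf <- .bc_hc_coefs(soil_temp, timeframe)
  raw <- cf$c_hc + cf$m_hc * hc
  val <- min(max(raw, 0), 1)
  if (val != raw) {
    warnings <- c(warnings, paste0("regression value ", format(raw, digits = 4),
                                   " clamped to [0, 1]"))
  }
  .bc_perm_result(val, method = "hc_regression", warnings = warnings)
}

#' Conservative permanence estimate
#'
#' When neither H/C_org nor production conditions are reliably known, the
#' low-temperature-pyrolysis permanence is adopted as a conservative
#' estimate (low-temperature chars are the least persistent class).
#' Identical to `fperm_from_class("low", ...)` except that the result is
#' tagged `method = "conservative"`.
#'
#' @inheritParams fperm_from_class
#' @return A `permanence_result`.
#' @export
#' @examples
#' fperm_conservative(100, 14.9) # 0.63
fperm_conservative <- function(timeframe = 100,
                               soil_temp = bc_constants()$global_cropland_temp,
                               extrapolate = FALSE) {
  out <- fperm_from_class("low", timeframe, soil_temp, extrapolate)
  out$method <- "conservative"
  out
}

#' Choose the permanence parameterization for a biochar
#'
#' A measured H/C_org is the preferred basis (it correlates more closely
#' with persistence than pyrolysis temperature); failing that, the
#' pyrolysis-temperature class; failing both, the conservative fallback.
#'
#' @param spec A [biochar_spec()].
#' @return `"hc"`, `"class"` or `"conservative"`.
#' @export
choose_parameterization <- function(spec) {
  stopifnot(inherits(spec, "biochar_spec"))
  if (!is.null(spec$measured_hc)) return("hc")
  if (!is.null(spec$pyrolysis_temp) || !is.null(spec$temp_class)) return("class")
  "conservative"
}

#' Estimate permanence for a biochar
#'
#' Dispatches to [fperm_from_hc()], [fperm_from_class()] or
#' [fperm_conservative()] according to [choose_parameterization()].
#'
#' @param spec A [biochar_spec()].
#' @inheritParams fperm_from_class
#' @return A `permanence_result`.
#' @export
estimate_fperm <- function(spec, timeframe = 100,
                           soil_temp = bc_constants()$global_cropland_temp,
                           extrapolate = FALSE) {
  switch(choose_parameterization(spec),
    hc = fperm_from_hc(spec$measured_hc, timeframe, soil_temp, extrapolate),
    class = fperm_from_class(.bc_resolve_temp_class(spec), timeframe,
                             soil_temp, extrapolate),
    conservative = fperm_conservative(timeframe, soil_temp, extrapolate)
  )
}
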