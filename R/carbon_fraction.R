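# Carbon fraction of biochar on a dry-matter basis: continuous estimator
# (dry-ash-free carbon regression + char yield + ash mass balance) and
# class-table lookup, with measured-value passthrough.

#' Dry-ash-free organic carbon fraction of biochar
#'
#' Saturating exponential regression of the dry-ash-free organic carbon
#' fraction on highest pyrolysis temperature, valid for 350-900 degC.
#' Strictly increasing in temperature and bounded in (0, 1).
#'
#' @param pyrolysis_temp Highest treatment temperature, degC (vectorized).
#' @return Fraction of dry-ash-free matter.
#' @export
#' @examples
#' fc_daf(450)
fc_daf <- function(pyrolysis_temp) {
  k <- bc_constants()
  if (any(pyrolysis_temp < k$min_pyrolysis_temp)) {
    stop("pyrolysis temperature below ", k$min_pyrolysis_temp,
         " degC: chars produced below this temperature (torrefaction, ",
         "hydrothermal carbonization) are excluded from the method",
         call. = FALSE)
  }
  if (any(pyrolysis_temp > k$max_pyrolysis_temp)) {
    stop("pyrolysis temperature above ", k$max_pyrolysis_temp,
         " degC is outside the supported regression domain", call. = FALSE)
  }
  p <- fc_regression()$eq_fc_daf
  unname(p["a"] - p["b"] * exp(-p["c"] * pyrolysis_temp))
}

#' Dry-ash-free biochar yield
#'
#' Char yield per unit dry-ash-free feedstock as a function of feedstock
#' lignin content (fraction of dry matter) and pyrolysis temperature:
#' linear in lignin, declining exponentially with temperature.
#'
#' @param lignin Feedstock lignin content, fraction of dry matter.
#' @param pyrolysis_temp Highest treatment temperature, degC.
#' @return Yield fraction in (0, 1).
#' @export
biochar_yield_daf <- function(lignin, pyrolysis_temp) {
  k <- bc_constants()
  if (any(lignin < 0 | lignin > 1)) {
    stop("lignin content must be a fraction in [0, 1]", call. = FALSE)
  }
  if (any(pyrolysis_temp < k$min_pyrolysis_temp |
          pyrolysis_temp > k$max_pyrolysis_temp)) {
    stop("pyrolysis temperature outside supported range [",
         k$min_pyrolysis_temp, ", ", k$max_pyrolysis_temp, "] degC",
         call. = FALSE)
  }
  p <- fc_regression()$eq_yield
  unname(p["a"] + p["m_lignin"] * lignin + p["b"] * exp(-p["k"] * pyrolysis_temp))
}

#' Ash fraction of biochar by mass balance
#'
#' Ash is conserved during pyrolysis while the organic fraction shrinks by
#' the dry-ash-free yield, so the biochar ash fraction is
#' `ash_bm / (ash_bm + y_bc * (1 - ash_bm))`.
#'
#' @param ash_bm Feedstock ash content, fraction of dry matter, in \[0, 1).
#' @param y_bc Dry-ash-free char yield, in (0, 1\].
#' @return Biochar ash fraction, at least `ash_bm` and below 1.
#' @export
ash_fraction_biochar <- function(ash_bm, y_bc) {
  if (any(ash_bm < 0 | ash_bm >= 1)) {
    stop("feedstock ash fraction must lie in [0, 1)", call. = FALSE)
  }
  if (any(y_bc <= 0 | y_bc > 1)) {
    stop("dry-ash-free yield must lie in (0, 1]; a zero yield would leave ",
         "an all-ash residue with no organic carbon", call. = FALSE)
  }
  ash_bm / (ash_bm + y_bc * (1 - ash_bm))
}

#' Map a numeric pyrolysis temperature to its class
#'
#' Bin edges follow the class-table convention: low \[350, 450), medium
#' \[450, 600), high >= 600 degC.
#'
#' @param pyrolysis_temp degC.
#' @return `"low"`, `"medium"` or `"high"`.
#' @export
temp_class_of <- function(pyrolysis_temp) {
  k <- bc_constants()
  if (any(pyrolysis_temp < k$min_pyrolysis_temp)) {
    stop("pyrolysis temperature below ", k$min_pyrolysis_temp,
         " degC is excluded from the method", call. = FALSE)
  }
  out <- ifelse(pyrolysis_temp < 450, "low",
                ifelse(pyrolysis_temp < 600, "medium", "high"))
  unname(out)
}

#' Describe a biochar
#'
#' Bundles what is known about one biochar: feedstock class, production
#' process, pyrolysis temperature (numeric or as a class), and optional
#' measured organic carbon fraction and molar H/C_org ratio. At least one of
#' `measured_fc` or `feedstock` must be given. A measured H/C_org above 0.7
#' is atypical of carbonized material and is flagged with a warning.
#'
#' @param feedstock Feedstock class label (optional if `measured_fc` given).
#' @param process `"pyrolysis"` or `"gasification"`.
#' @param pyrolysis_temp Highest treatment temperature, degC (optional;
#'   must be >= 350).
#' @param temp_class `"low"`, `"medium"` or `"high"` (optional).
#' @param measured_fc Measured organic carbon fraction, dry-matter basis
#'   (optional).
#' @param measured_hc Measured molar H/C_org ratio (optional, in \[0, 1.5\]).
#' @return Object of class `biochar_spec`.
#' @export
#' @examples
#' biochar_spec("maize stover", pyrolysis_temp = 500)
biochar_spec <- function(feedstock = NULL,
                         process = c("pyrolysis", "gasification"),
                         pyrolysis_temp = NULL, temp_class = NULL,
                         measured_fc = NULL, measured_hc = NULL) {
  process <- match.arg(process)
  k <- bc_constants()
  if (is.null(feedstock) && is.null(measured_fc)) {
    stop("at least one of `feedstock` or `measured_fc` is required",
         call. = FALSE)
  }
  if (!is.null(feedstock)) feedstock <- normalize_feedstock(feedstock)
  if (!is.null(pyrolysis_temp)) {
    stopifnot(is.numeric(pyrolysis_temp), length(pyrolysis_temp) == 1)
    if (pyrolysis_temp < k$min_pyrolysis_temp) {
      stop("pyrolysis temperature below ", k$min_pyrolysis_temp,
           " degC is excluded from the method", call. = FALSE)
    }
  }
  if (!is.null(temp_class)) {
    temp_class <- match.arg(temp_class, c("low", "medium", "high"))
  }
  if (!is.null(measured_fc)) {
    stopifnot(is.numeric(measured_fc), length(measured_fc) == 1)
    if (measured_fc < 0 || measured_fc > 1) {
      stop("measured_fc must be a fraction in [0, 1]", call. = FALSE)
    }
  }
  if (!is.null(measured_hc)) {
    stopifnot(is.numeric(measured_hc), length(measured_hc) == 1)
    if (measured_hc < 0 || measured_hc > 1.5) {
      stop("measured_hc must lie in [0, 1.5]", call. = FALSE)
    }
    if (measured_hc > k$hc_atypical_threshold) {
      warning("H/C_org of ", measured_hc, " exceeds ",
              k$hc_atypical_threshold,
              ", atypical of carbonized material", call. = FALSE)
    }
  }
  structure(
    list(feedstock = feedstock, process = process,
         pyrolysis_temp = pyrolysis_temp, temp_class = temp_class,
         measured_fc = measured_fc, measured_hc = measured_hc),
    class = "biochar_spec"
  )
}

#' @export
print.biochar_spec <- function(x, ...) {
  cat("<biochar_spec>\n")
  for (f in names(x)) {
    if (!is.null(x[[f]])) cat(" ", f, ": ", format(x[[f]]), "\n", sep = "")
  }
  invisible(x)
}

# Resolve which temperature class a spec falls in; numeric temperature wins
# over a conflicting declared class (temperature-specific values are the more
# accurate parameterization), with a warning.
.bc_resolve_temp_class <- function(spec) {
  if (!is.null(spec$pyrolysis_temp)) {
    cls <- temp_class_of(spec$pyrolysis_temp)
    if (!is.null(spec$temp_class) && !identical(spec$temp_class, cls)) {
      warning("declared temp_class ", sQuote(spec$temp_class),
              " disagrees with pyrolysis_temp ", spec$pyrolysis_temp,
              " degC (class ", sQuote(cls), "); using the numeric temperature",
              call. = FALSE)
    }
    return(cls)
  }
  spec$temp_class
}

#' Estimate the biochar organic carbon fraction
#'
#' Dispatch order: a measured value is always used verbatim; otherwise the
#' class-level table is the default path, consistent with the method's
#' emission-factor philosophy (pyrolysis chars use the temperature-class
#' column, falling back to the pyrolysis mean when no temperature information
#' is available; gasification chars use the gasification column). The
#' continuous estimator (dry-ash-free carbon regression, lignin/temperature
#' yield regression, ash mass balance) is opt-in via `continuous = TRUE` and
#' requires a numeric pyrolysis temperature, a known feedstock, and the
#' pyrolysis process.
#'
#' Gasification residues whose ash has been partially removed are not
#' representable by either path; for those, supply `measured_fc`.
#'
#' @param spec A [biochar_spec()].
#' @param continuous Use the continuous estimator when its inputs are
#'   available (default `FALSE`).
#' @return Object of class `fc_estimate`: `fc`, `sd` (`NA` unless served
#'   from the class table), `source` (one of `"measured"`, `"class_table"`,
#'   `"continuous_equations"`), `condition` (class-table column used, if
#'   any), and `intermediates` (`fc_daf`, `y_bc`, `ash_bc` for the
#'   continuous path).
#' @export
#' @examples
#' estimate_fc(biochar_spec("maize stover", pyrolysis_temp = 500))$fc # 0.68
estimate_fc <- function(spec, continuous = FALSE) {
  stopifnot(inherits(spec, "biochar_spec"))
  if (!is.null(spec$measured_fc)) {
    return(structure(
      list(fc = spec$measured_fc, sd = NA_real_, source = "measured",
           condition = NULL, intermediates = NULL),
      class = "fc_estimate"
    ))
  }
  if (continuous && !is.null(spec$pyrolysis_temp) && !is.null(spec$feedstock) &&
      spec$process == "pyrolysis") {
    fs <- get_feedstock(spec$feedstock)
    fcd <- fc_daf(spec$pyrolysis_temp)
    y <- biochar_yield_daf(fs$lignin_mean, spec$pyrolysis_temp)
    ash_bc <- ash_fraction_biochar(fs$ash_mean, y)
    return(structure(
      list(fc = fcd * (1 - ash_bc), sd = NA_real_,
           source = "continuous_equations", condition = NULL,
           intermediates = list(fc_daf = fcd, y_bc = y, ash_bc = ash_bc)),
      class = "fc_estimate"
    ))
  }
  if (continuous && spec$process == "gasification") {
    warning("the continuous estimator covers pyrolysis only; ",
            "using the gasification class column", call. = FALSE)
  }
  condition <- if (spec$process == "gasification") {
    "gasification"
  } else {
    cls <- .bc_resolve_temp_class(spec)
    if (is.null(cls)) "mean" else cls
  }
  hit <- get_fc_class(spec$feedstock, condition)
  structure(
    list(fc = hit$value, sd = hit$sd, source = "class_table",
         condition = condition, intermediates = NULL),
    class = "fc_estimate"
  )
}

#' @export
print.fc_estimate <- function(x, ...) {
  cat("F_C =", format(x$fc, digits = 4),
      if (!is.na(x$sd)) paste0("(sd ", format(x$sd), ")"),
      "[", x$source, if (!is.null(x$condition)) paste0(": ", x$condition), "]\n")
  if (!is.null(x$intermediates)) {
    cat("  fc_daf =", format(x$intermediates$fc_daf, digits = 4),
        " y_bc =", format(x$intermediates$y_bc, digits = 4),
        " ash_bc =", format(x$intermediates$ash_bc, digits = 4), "\n")
  }
  invisible(x)
}
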