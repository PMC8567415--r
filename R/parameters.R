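# Parameter tables: feedstock composition, class-level biochar carbon
# content, and the permanence grid. The tables ship as plain-text CSV under
# inst/extdata so the transcription is auditable; loaders convert printed
# percentages to fractions and cache the result for the session.

.bc_cache <- new.env(parent = emptyenv())

.bc_extdata <- function(file) {
  path <- system.file("extdata", file, package = "biocharGHG")
  if (!nzchar(path)) {
    # during development (pkgload) fall back to the source tree
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) stop("packaged table not found: ", file, call. = FALSE)
  path
}

.bc_read_table <- function(file) {
  key <- paste0("table_", file)
  if (!is.null(.bc_cache[[key]])) return(.bc_cache[[key]])
  out <- utils::read.csv(.bc_extdata(file), comment.char = "#",
                         stringsAsFactors = FALSE, check.names = TRUE)
  .bc_cache[[key]] <- out
  out
}

#' Feedstock composition table
#'
#' Ash and lignin content (fraction of dry matter) and carbon content
#' (fraction of dry-ash-free matter) for the eleven supported biomass
#' feedstock classes, with standard deviations and sample counts, summarized
#' from the Phyllis2 database of biomass and waste. Percentages in the
#' shipped CSV are converted to fractions here; all mass quantities in the
#' package are fractions of dry matter unless stated otherwise.
#'
#' @return data.frame with one row per feedstock class: `feedstock`,
#'   `ash_mean`, `ash_sd`, `ash_n`, `c_daf_mean`, `c_daf_sd`, `c_n`,
#'   `lignin_mean`, `lignin_sd`, `lignin_n`.
#' @export
feedstock_table <- function() {
  raw <- .bc_read_table("table1_biomass.csv")
  data.frame(
    feedstock = raw$feedstock,
    ash_mean = raw$ash_pct / 100, ash_sd = raw$ash_sd_pct / 100, ash_n = raw$ash_n,
    c_daf_mean = raw$c_daf_pct / 100, c_daf_sd = raw$c_daf_sd_pct / 100, c_n = raw$c_n,
    lignin_mean = raw$lignin_pct / 100, lignin_sd = raw$lignin_sd_pct / 100,
    lignin_n = raw$lignin_n,
    stringsAsFactors = FALSE
  )
}

#' Class-level biochar carbon content table
#'
#' Organic carbon fraction of biochar on a dry-matter basis (with standard
#' deviations) by feedstock class and production condition: pyrolysis at
#' low (350-450 degC), medium (450-600 degC) or high (>= 600 degC)
#' temperature, the mean over the three pyrolysis ranges, and gasification.
#'
#' @return data.frame, one row per feedstock class.
#' @export
fc_class_table <- function() .bc_read_table("table2_fc_classes.csv")

#' Permanence grid
#'
#' Fraction of biochar organic carbon remaining (`F_perm`) by
#' pyrolysis-temperature class, for timeframes of 100, 500 and 1000 years
#' and mean annual soil temperatures of 5-25 degC in 5 degC steps plus the
#' US (10.9 degC) and global (14.9 degC) cropland means, with standard
#' errors; the right-hand columns hold the H/C_org linear-regression
#' coefficients (intercept `c_hc`, slope `m_hc`, and R2) for the same
#' (temperature, timeframe) cells.
#'
#' @return data.frame with 21 rows (7 soil temperatures x 3 timeframes).
#' @export
permanence_table <- function() .bc_read_table("table3_permanence.csv")

# Documented label aliases; activity data comes from heterogeneous sources.
.bc_feedstock_aliases <- c(
  "rice husk" = "rice residues",
  "rice husks" = "rice residues",
  "rice hull" = "rice residues",
  "rice hulls" = "rice residues",
  "rice straw" = "rice residues",
  "corn stover" = "maize stover",
  "biosolids" = "sewage sludge",
  "grass" = "herbaceous"
)

#' Normalize a feedstock label
#'
#' Case-insensitive matching against the eleven supported feedstock classes,
#' with documented aliases ("rice husk" -> "rice residues", "corn stover" ->
#' "maize stover", "biosolids" -> "sewage sludge", "grass" -> "herbaceous").
#'
#' @param label Character feedstock label.
#' @return Canonical class name.
#' @export
normalize_feedstock <- function(label) {
  stopifnot(is.character(label), length(label) == 1)
  classes <- feedstock_table()$feedstock
  lab <- tolower(trimws(label))
  if (lab %in% classes) return(lab)
  if (lab %in% names(.bc_feedstock_aliases)) return(unname(.bc_feedstock_aliases[lab]))
  stop(
    "unknown feedstock class ", sQuote(label), ". Valid classes: ",
    paste(classes, collapse = ", "),
    ". For feedstocks outside these classes (e.g. food waste, which is too ",
    "variable in composition), the biochar carbon content must be measured ",
    "directly and supplied as `measured_fc`.",
    call. = FALSE
  )
}

#' Look up feedstock composition
#'
#' @param feedstock_class Feedstock label (case-insensitive; aliases accepted).
#' @return List with the class's ash, carbon (dry-ash-free) and lignin means,
#'   standard deviations and sample counts, all mass quantities as fractions,
#'   plus a `source` provenance note.
#' @export
#' @examples
#' get_feedstock("wood")$ash_mean # 0.022
get_feedstock <- function(feedstock_class) {
  cls <- normalize_feedstock(feedstock_class)
  tab <- feedstock_table()
  row <- tab[tab$feedstock == cls, , drop = FALSE]
  out <- as.list(row)
  out$feedstock_class <- cls
  out$feedstock <- NULL
  out$source <- "packaged feedstock composition table (Phyllis2 summary)"
  out
}

#' Look up class-level biochar carbon content
#'
#' @param feedstock_class Feedstock label (case-insensitive; aliases accepted).
#' @param condition One of `"low"`, `"medium"`, `"high"`, `"mean"`,
#'   `"gasification"`.
#' @return List with `value`, `sd`, the resolved `feedstock_class` and
#'   `condition`, and a `source` provenance note.
#' @export
#' @examples
#' get_fc_class("maize stover", "medium")$value # 0.68
get_fc_class <- function(feedstock_class,
                         condition = c("low", "medium", "high", "mean", "gasification")) {
  cls <- normalize_feedstock(feedstock_class)
  condition <- match.arg(condition)
  tab <- fc_class_table()
  row <- tab[tab$feedstock == cls, , drop = FALSE]
  list(
    value = row[[paste0("fc_", condition)]],
    sd = row[[paste0("fc_", condition, "_sd")]],
    feedstock_class = cls,
    condition = condition,
    source = "packaged class-level biochar carbon content table"
  )
}

#' Look up a printed permanence-grid cell
#'
#' Serves only the 21 printed (soil temperature, timeframe) grid points.
#' Off-grid queries are the permanence module's job ([fperm_from_class()],
#' [fperm_from_hc()]), which interpolates or evaluates a calibrated decay
#' surface; this accessor refuses them so table lookups stay auditable.
#'
#' @param soil_temp Mean annual soil temperature, degC.
#' @param timeframe Accounting timeframe, years.
#' @return List with `soil_temp`, `timeframe`, `fperm_low/medium/high` and
#'   their `_se`, `c_hc`, `m_hc`, `r2`, and a `source` note.
#' @export
#' @examples
#' get_permanence_cell(10, 100)$fperm_medium # 0.79
get_permanence_cell <- function(soil_temp, timeframe) {
  tab <- permanence_table()
  hit <- abs(tab$soil_temp_c - soil_temp) < 1e-9 &
    abs(tab$timeframe_years - timeframe) < 1e-9
  if (!any(hit)) {
    stop(
      "(", soil_temp, " degC, ", timeframe, " y) is not a printed grid point. ",
      "Printed soil temperatures: ", paste(unique(tab$soil_temp_c), collapse = ", "),
      "; timeframes: ", paste(unique(tab$timeframe_years), collapse = ", "),
      ". For other (temperature, timeframe) combinations use fperm_from_class() ",
      "or fperm_from_hc(), which evaluate the calibrated decay surface.",
      call. = FALSE
    )
  }
  row <- tab[hit, , drop = FALSE]
  list(
    soil_temp = row$soil_temp_c, timeframe = row$timeframe_years,
    fperm_low = row$fperm_low, fperm_low_se = row$fperm_low_se,
    fperm_medium = row$fperm_medium, fperm_medium_se = row$fperm_medium_se,
    fperm_high = row$fperm_high, fperm_high_se = row$fperm_high_se,
    c_hc = row$c_hc, m_hc = row$m_hc, r2 = row$r2,
    source = "packaged permanence grid"
  )
}

#' List supported feedstock classes with provenance
#'
#' Combines the composition and carbon-content tables into one data.frame,
#' as dumped by the command-line `list-feedstocks` subcommand.
#'
#' @return data.frame with one row per feedstock class.
#' @export
list_feedstocks <- function() {
  merge(feedstock_table(), fc_class_table(), by = "feedstock")
}
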