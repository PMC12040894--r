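# Domain vocabulary and tidy table I/O with validation.

WHEAT_LEVELS <- c("RT", "DT")
MAIZE_LEVELS <- c("NT", "SBR", "SIR")

MEASURE_COLS <- c(
  "bd_g_cm3", "soc_g_kg", "loc_g_kg", "doc_mg_kg", "mbc_mg_kg",
  "invertase", "urease", "phosphatase"
)
PROFILE_COLS <- c(
  "year", "wheat_tillage", "maize_tillage", "replicate",
  "top_cm", "bottom_cm", MEASURE_COLS
)
YIELD_COLS <- c("year", "wheat_tillage", "maize_tillage", "replicate",
                "yield_kg_ha")

#' The six tillage treatment combinations
#'
#' The trial crosses a wheat-season main-plot factor (rotary tillage `RT` or
#' deep tillage `DT`) with a maize-season sub-plot factor (no-tillage `NT`,
#' subsoiling between rows `SBR`, or subsoiling within rows `SIR`), giving
#' six treatments labelled `"<wheat>-<maize>"`, e.g. `"RT-NT"`.
#'
#' @return A tibble with columns `wheat_tillage`, `maize_tillage` and the
#'   rendered `treatment` label, in canonical order (`RT-NT` ... `DT-SIR`).
#' @export
#' @examples
#' all_treatments()
all_treatments <- function() {
  grid <- expand.grid(maize_tillage = MAIZE_LEVELS,
                      wheat_tillage = WHEAT_LEVELS,
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  tibble(
    wheat_tillage = grid$wheat_tillage,
    maize_tillage = grid$maize_tillage,
    treatment = treatment_label(grid$wheat_tillage, grid$maize_tillage)
  )
}

#' @rdname all_treatments
#' @param wheat_tillage,maize_tillage character vectors of factor levels.
#' @export
treatment_label <- function(wheat_tillage, maize_tillage) {
  if (length(wheat_tillage) == 0) return(character(0))
  paste0(wheat_tillage, "-", maize_tillage)
}

treatment_levels <- function() all_treatments()$treatment

#' Default depth layering: five 10 cm layers from 0 to 50 cm
#'
#' Layers are half-open integer intervals `[top_cm, bottom_cm)` so that
#' cumulative sums over depth are unambiguous.
#'
#' @param max_depth_cm profile bottom in cm (multiple of `step_cm`).
#' @param step_cm layer thickness in cm.
#' @return tibble with columns `top_cm`, `bottom_cm`.
#' @export
default_layers <- function(max_depth_cm = 50, step_cm = 10) {
  tops <- seq(0L, max_depth_cm - step_cm, by = step_cm)
  tibble(top_cm = as.integer(tops), bottom_cm = as.integer(tops + step_cm))
}

# Canonical row order used everywhere: year, treatment (canonical level
# order), replicate, top_cm.
arrange_profiles <- function(profiles) {
  ord <- order(
    profiles$year,
    match(treatment_label(profiles$wheat_tillage, profiles$maize_tillage),
          treatment_levels()),
    profiles$replicate,
    profiles$top_cm
  )
  profiles[ord, PROFILE_COLS]
}

arrange_yields <- function(yields) {
  ord <- order(
    yields$year,
    match(treatment_label(yields$wheat_tillage, yields$maize_tillage),
          treatment_levels()),
    yields$replicate
  )
  yields[ord, YIELD_COLS]
}

empty_report <- function() {
  tibble(table = character(), row_number = integer(),
         rule = character(), message = character())
}

validate_profile_rows <- function(profiles) {
  report <- empty_report()
  reject <- rep(FALSE, nrow(profiles))
  flag <- function(bad, rule, msg) {
    bad[is.na(bad)] <- TRUE
    if (any(bad)) {
      report <<- bind_rows(report, tibble(
        table = "profiles", row_number = which(bad),
        rule = rule, message = msg
      ))
      reject <<- reject | bad
    }
  }
  for (col in MEASURE_COLS) {
    flag(profiles[[col]] <= 0, "positive",
         paste0(col, " must be strictly positive"))
  }
  flag(profiles$bd_g_cm3 <= 0.5 | profiles$bd_g_cm3 >= 2.2, "bd_range",
       "bd_g_cm3 outside physically plausible (0.5, 2.2)")
  flag(profiles$loc_g_kg > profiles$soc_g_kg, "loc_le_soc",
       "loc ≤ soc violated")
  flag(profiles$bottom_cm <= profiles$top_cm | profiles$top_cm < 0,
       "layer_interval", "depth layer must satisfy 0 ≤ top_cm < bottom_cm")
  flag(!(profiles$wheat_tillage %in% WHEAT_LEVELS) |
         !(profiles$maize_tillage %in% MAIZE_LEVELS), "treatment_code",
       "unknown tillage code")
  list(accepted = profiles[!reject, , drop = FALSE], report = report)
}

validate_yield_rows <- function(yields) {
  report <- empty_report()
  bad <- yields$yield_kg_ha <= 0
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    report <- tibble(table = "yields", row_number = which(bad),
                     rule = "positive", message = "yield_kg_ha must be > 0")
  }
  list(accepted = yields[!bad, , drop = FALSE], report = report)
}

# Balance over year x treatment x replicate x layer, against the cells
# implied by the observed margins. Missing cells are reported, never imputed.
balance_report <- function(profiles) {
  if (nrow(profiles) == 0) return(empty_report())
  expected <- expand.grid(
    year = sort(unique(profiles$year)),
    treatment = unique(treatment_label(profiles$wheat_tillage,
                                       profiles$maize_tillage)),
    replicate = sort(unique(profiles$replicate)),
    top_cm = sort(unique(profiles$top_cm)),
    stringsAsFactors = FALSE
  )
  observed <- paste(profiles$year,
                    treatment_label(profiles$wheat_tillage,
                                    profiles$maize_tillage),
                    profiles$replicate, profiles$top_cm)
  missing <- expected[!(paste(expected$year, expected$treatment,
                              expected$replicate, expected$top_cm)
                        %in% observed), , drop = FALSE]
  if (nrow(missing) == 0) return(empty_report())
  tibble(
    table = "profiles", row_number = NA_integer_, rule = "balance",
    message = paste0("missing cell: year=", missing$year, " treatment=",
                     missing$treatment, " replicate=", missing$replicate,
                     " top_cm=", missing$top_cm)
  )
}

#' Assemble a validated trial dataset
#'
#' Bundles plot-level soil-profile measurements and (optionally) wheat
#' yields into a single validated object. Row-level rule violations
#' (non-positive measurements, bulk density outside (0.5, 2.2) g cm^-3,
#' `loc > soc`, malformed layers, unknown tillage codes) lead to the row
#' being rejected and recorded in the validation report; imbalance over
#' year x treatment x replicate x layer is reported but never "fixed".
#' Validation never mutates values.
#'
#' @param profiles data frame with columns `r paste(PROFILE_COLS, collapse=", ")`.
#' @param yields optional data frame with columns
#'   `year, wheat_tillage, maize_tillage, replicate, yield_kg_ha`.
#' @param provenance free-text origin note (the synthetic generator records
#'   its seed here).
#' @return An object of class `soil_dataset`: a list with elements
#'   `profiles`, `yields`, `provenance` and `validation` (a tibble of
#'   `table`, `row_number`, `rule`, `message`).
#' @export
soil_dataset <- function(profiles, yields = NULL, provenance = "user-supplied") {
  profiles <- as_tibble(profiles)
  missing_cols <- setdiff(PROFILE_COLS, names(profiles))
  if (length(missing_cols) > 0) {
    stop("profiles is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  vp <- validate_profile_rows(profiles)
  report <- bind_rows(vp$report, balance_report(vp$accepted))
  if (!is.null(yields)) {
    yields <- as_tibble(yields)
    missing_cols <- setdiff(YIELD_COLS, names(yields))
    if (length(missing_cols) > 0) {
      stop("yields is missing mandatory column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    vy <- validate_yield_rows(yields)
    report <- bind_rows(report, vy$report)
    yields <- arrange_yields(vy$accepted)
  }
  structure(
    list(profiles = arrange_profiles(vp$accepted), yields = yields,
         provenance = provenance, validation = report),
    class = "soil_dataset"
  )
}

#' @export
print.soil_dataset <- function(x, ...) {
  cat("<soil_dataset> ", nrow(x$profiles), " profile rows",
      if (!is.null(x$yields)) paste0(", ", nrow(x$yields), " yield rows"),
      "\n", sep = "")
  cat("  years: ", paste(sort(unique(x$profiles$year)), collapse = ", "),
      "; treatments: ",
      length(unique(treatment_label(x$profiles$wheat_tillage,
                                    x$profiles$maize_tillage))),
      "; layers: ", length(unique(x$profiles$top_cm)), "\n", sep = "")
  cat("  provenance: ", x$provenance, "\n", sep = "")
  n_issues <- nrow(x$validation)
  cat("  validation: ", n_issues, " issue(s)\n", sep = "")
  invisible(x)
}

#' Read a trial dataset from CSV
#'
#' Expects the plain UTF-8 CSV schema written by [write_dataset()]: one
#' profiles file with header `year, wheat_tillage, maize_tillage,
#' replicate, top_cm, bottom_cm, bd_g_cm3, soc_g_kg, loc_g_kg, doc_mg_kg,
#' mbc_mg_kg, invertase, urease, phosphatase` and optionally a yields file
#' with `year, wheat_tillage, maize_tillage, replicate, yield_kg_ha`.
#' A missing mandatory column is a hard error; a non-numeric measurement
#' or a rule violation rejects that row into the validation report.
#'
#' @param profiles_path path to the profiles CSV.
#' @param yields_path optional path to the yields CSV.
#' @param schema_version declared schema version (currently only `"1"`).
#' @return a [soil_dataset()].
#' @export
read_dataset <- function(profiles_path, yields_path = NULL,
                         schema_version = "1") {
  if (!identical(schema_version, "1")) {
    stop("unsupported schema_version: ", schema_version)
  }
  raw <- readr::read_csv(profiles_path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  missing_cols <- setdiff(PROFILE_COLS, names(raw))
  if (length(missing_cols) > 0) {
    stop("profiles CSV is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  num_cols <- setdiff(PROFILE_COLS, c("wheat_tillage", "maize_tillage"))
  parsed <- raw
  for (col in num_cols) {
    parsed[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  bad <- rowSums(is.na(parsed[num_cols])) > 0
  read_report <- empty_report()
  if (any(bad)) {
    read_report <- tibble(table = "profiles", row_number = which(bad),
                          rule = "non-numeric",
                          message = "non-numeric measurement value")
  }
  parsed$year <- as.integer(parsed$year)
  parsed$replicate <- as.integer(parsed$replicate)
  parsed$top_cm <- as.integer(parsed$top_cm)
  parsed$bottom_cm <- as.integer(parsed$bottom_cm)
  yields <- NULL
  yield_report <- empty_report()
  if (!is.null(yields_path)) {
    yraw <- readr::read_csv(yields_path, col_types = readr::cols(
      .default = readr::col_character()
    ), progress = FALSE)
    missing_cols <- setdiff(YIELD_COLS, names(yraw))
    if (length(missing_cols) > 0) {
      stop("yields CSV is missing mandatory column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    yraw$year <- suppressWarnings(as.integer(yraw$year))
    yraw$replicate <- suppressWarnings(as.integer(yraw$replicate))
    yraw$yield_kg_ha <- suppressWarnings(as.numeric(yraw$yield_kg_ha))
    ybad <- is.na(yraw$year) | is.na(yraw$replicate) | is.na(yraw$yield_kg_ha)
    if (any(ybad)) {
      yield_report <- tibble(table = "yields", row_number = which(ybad),
                             rule = "non-numeric",
                             message = "non-numeric yield value")
    }
    yields <- yraw[!ybad, , drop = FALSE]
  }
  ds <- soil_dataset(parsed[!bad, , drop = FALSE], yields = yields,
                     provenance = paste0("read from ", profiles_path))
  ds$validation <- bind_rows(read_report, yield_report, ds$validation)
  ds
}

#' Write a trial dataset to CSV
#'
#' Columns are written in the fixed schema order and rows in the canonical
#' sort (year, treatment, replicate, top_cm), so writing the same dataset
#' twice yields byte-identical files and `read_dataset(write_dataset(d))`
#' is the identity on valid data.
#'
#' @param d a [soil_dataset()].
#' @param profiles_path output path for the profiles CSV.
#' @param yields_path optional output path for the yields CSV (required if
#'   `d` carries yields).
#' @return `d`, invisibly.
#' @export
write_dataset <- function(d, profiles_path, yields_path = NULL) {
  stopifnot(inherits(d, "soil_dataset"))
  readr::write_csv(arrange_profiles(d$profiles), profiles_path,
                   progress = FALSE)
  if (!is.null(yields_path)) {
    yields <- d$yields
    if (is.null(yields)) {
      yields <- tibble(year = integer(), wheat_tillage = character(),
                       maize_tillage = character(), replicate = integer(),
                       yield_kg_ha = double())
    }
    readr::write_csv(arrange_yields(yields), yields_path, progress = FALSE)
  }
  invisible(d)
}

#' Non-labile organic carbon
#'
#' NLOC is defined as total minus labile organic carbon, `soc - loc`
#' (g kg^-1). It is always derived on demand, never stored, so it can
#' never drift out of step with its parents.
#'
#' @param soc,loc numeric vectors, g kg^-1, with `loc <= soc` elementwise.
#' @return `soc - loc` (g kg^-1), always `>= 0`.
#' @export
#' @examples
#' derive_nloc(10, 3)       # 7
#' derive_nloc(9.53, 3.23)  # 6.30
derive_nloc <- function(soc, loc) {
  if (any(loc > soc)) stop("loc ≤ soc violated; cannot derive NLOC")
  soc - loc
}

# Sample-level table used by the indices and stats modules: profiles plus
# derived treatment label and NLOC.
sample_table <- function(d) {
  p <- d$profiles
  p$treatment <- treatment_label(p$wheat_tillage, p$maize_tillage)
  p$nloc_g_kg <- derive_nloc(p$soc_g_kg, p$loc_g_kg)
  p
}
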