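#' Parse free-text questionnaire durations into minutes
#'
#' Implements the measurement-cleaning rules for parent-reported
#' durations: numeric answers with a unit are converted to minutes
#' (hours x 60); ranges such as `"10–30 min"` are replaced by their
#' midpoint; verbal answers ("a couple of minutes", "a few minutes")
#' become 2 minutes; empty cells are missing. Bare numbers are read as
#' minutes, except that unit-ambiguous entries are excluded with a
#' provenance flag: under the default rule (`"lt1"`) a bare positive
#' value below 1 (which could plausibly be hours) and any negative value
#' are excluded; under `"lt0"` only negative values are. Every input
#' maps to a row — nothing errors.
#'
#' @param raw character vector of questionnaire cells.
#' @param ambiguous_rule `"lt1"` (default) or `"lt0"`; see Details.
#' @return A data frame with columns `minutes` (numeric, `NA` when
#'   excluded or missing) and `provenance` (one of `"numeric"`,
#'   `"range_mean"`, `"verbal"`, `"excluded_ambiguous"`, `"missing"`).
#' @examples
#' parse_duration(c("10–30 min", "a couple of minutes", "45", "1.5 h",
#'                  "0.5", ""))
#' @export
parse_duration <- function(raw, ambiguous_rule = c("lt1", "lt0")) {
  ambiguous_rule <- match.arg(ambiguous_rule)
  raw <- as.character(raw)
  n <- length(raw)
  minutes <- rep(NA_real_, n)
  prov <- rep("missing", n)

  num <- "[0-9]+(?:[.,][0-9]+)?"
  unit <- "(min|mins|minutes?|m|h|hr|hrs|hours?)"
  re_range <- paste0("^(", num, ")\\s*[-–—]\\s*(", num, ")\\s*",
                     unit, "?\\.?$")
  re_unit <- paste0("^(-?", num, ")\\s*", unit, "\\.?$")
  re_bare <- paste0("^(-?", num, ")$")
  to_num <- function(x) as.numeric(gsub(",", ".", x))
  unit_factor <- function(u) ifelse(grepl("^h", u), 60, 1)

  x <- tolower(trimws(raw))
  for (i in seq_len(n)) {
    xi <- x[i]
    if (is.na(xi) || xi == "") next
    if (grepl("couple|few", xi)) {
      minutes[i] <- 2; prov[i] <- "verbal"; next
    }
    m <- regmatches(xi, regexec(re_range, xi))[[1]]
    if (length(m)) {
      f <- if (m[4] == "") 1 else unit_factor(m[4])
      minutes[i] <- f * (to_num(m[2]) + to_num(m[3])) / 2
      prov[i] <- "range_mean"; next
    }
    m <- regmatches(xi, regexec(re_unit, xi))[[1]]
    if (length(m)) {
      v <- to_num(m[2])
      if (v < 0) { prov[i] <- "excluded_ambiguous"; next }
      minutes[i] <- unit_factor(m[3]) * v
      prov[i] <- "numeric"; next
    }
    m <- regmatches(xi, regexec(re_bare, xi))[[1]]
    if (length(m)) {
      v <- to_num(m[2])
      ambiguous <- v < 0 || (ambiguous_rule == "lt1" && v > 0 && v < 1)
      if (ambiguous) { prov[i] <- "excluded_ambiguous" }
      else { minutes[i] <- v; prov[i] <- "numeric" }
      next
    }
    prov[i] <- "excluded_ambiguous"  # non-empty but unintelligible
  }
  data.frame(minutes = minutes, provenance = prov,
             stringsAsFactors = FALSE)
}

#' Corrected age for prematurity
#'
#' Chronological age minus the number of days between a full-term
#' pregnancy (39 weeks) and the actual gestational age, i.e.
#' `chronological_days - 7 * (39 - gestational_weeks)`.
#'
#' @param chronological_days chronological age in days.
#' @param gestational_weeks gestational age at birth in weeks; values
#'   above 45 or at/below 0 are invalid. The study floor is 34 weeks
#'   (very premature births excluded); lower values warn.
#' @return Corrected age in days.
#' @examples
#' corrected_age(80, 36)  # 59
#' @export
corrected_age <- function(chronological_days, gestational_weeks) {
  if (any(!is.na(gestational_weeks) &
          (gestational_weeks > 45 | gestational_weeks <= 0)))
    stop("invalid input: gestational_weeks must be in (0, 45]")
  if (any(!is.na(gestational_weeks) & gestational_weeks < 34))
    warning("gestational age below the 34-week study inclusion floor")
  chronological_days - 7 * (39 - gestational_weeks)
}

#' Exclusion report
#'
#' Tallies of individuals retained and excluded (by reason) by a
#' sample-definition filter; the categories partition the input.
#' @param input_n number of individuals seen.
#' @param counts named integer vector of category counts, including
#'   `retained`.
#' @return An `exclusion_report` object.
#' @export
exclusion_report <- function(input_n, counts) {
  if (sum(counts) != input_n)
    stop("exclusion counts must partition the input")
  structure(list(input_n = input_n, retained = counts[["retained"]],
                 counts = counts), class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("Exclusion report: %d of %d individuals retained\n",
              x$retained, x$input_n))
  for (nm in setdiff(names(x$counts), "retained"))
    if (x$counts[[nm]] > 0) cat(sprintf("  %s: %d\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Exclude individuals outside the corrected-age assessment window
#'
#' Retains individuals whose corrected age lies within
#' `target_days +/- tolerance` (boundaries inclusive); others have their
#' phenotype cells at the filtered timepoint set to missing, so a pair
#' with one valid twin keeps that twin's data (the model fitters handle
#' the incomplete pair by full-information likelihood). Individuals with
#' missing corrected age are tallied separately, not excluded by age.
#'
#' @param cohort a [twin_cohort()] with a per-individual corrected-age
#'   column.
#' @param target_days target assessment age in days (60 for the 2-month,
#'   150 for the 5-month assessment).
#' @param tolerance half-width of the window in days, default 40.
#' @param age_col name of the corrected-age column, default `"age"`.
#' @param timepoint which timepoint's phenotype cells to blank for
#'   excluded individuals, default the cohort's first.
#' @return A list with elements `cohort` (filtered) and `report`
#'   (an [exclusion_report()]).
#' @export
filter_age_window <- function(cohort, target_days, tolerance = 40,
                              age_col = "age",
                              timepoint = cohort_timepoints(cohort)[1]) {
  if (!age_col %in% names(cohort))
    stop("age column '", age_col, "' not found")
  ages <- cohort[[age_col]]
  status <- ifelse(is.na(ages), "missing_age",
            ifelse(ages < target_days - tolerance, "too_young",
            ifelse(ages > target_days + tolerance, "too_old", "retained")))
  counts <- c(retained = sum(status == "retained"),
              too_young = sum(status == "too_young"),
              too_old = sum(status == "too_old"),
              missing_age = sum(status == "missing_age"))
  report <- exclusion_report(length(ages), counts)
  out <- as.data.frame(cohort)
  pheno_cols <- grep(paste0("_", timepoint, "$"), names(out), value = TRUE)
  drop_cells <- status %in% c("too_young", "too_old")
  for (col in pheno_cols) out[[col]][drop_cells] <- NA
  all_pheno <- grep("_t[0-9]+$", names(out), value = TRUE)
  has_data <- rowSums(!is.na(out[, all_pheno, drop = FALSE])) > 0
  out <- out[has_data, , drop = FALSE]
  list(cohort = twin_cohort(out, phenotypes = cohort_phenotypes(cohort),
                            timepoints = cohort_timepoints(cohort),
                            provenance = cohort_provenance(cohort)),
       report = report)
}

#' Day length from latitude and day of year
#'
#' Geometric sunrise-to-sunset duration using the standard sunrise
#' equation with the conventional -0.833 degree solar altitude
#' (refraction plus solar radius) and a Fourier-series solar
#' declination. Clamps to 1440 minutes under polar day and 0 under
#' polar night.
#'
#' @param latitude_deg latitude in degrees, in [-90, 90].
#' @param day_of_year day of the year, 1-365.
#' @return Day length in minutes, in [0, 1440]. Vectorized.
#' @examples
#' day_length_minutes(59.33, 166)  # Stockholm in mid-June, ~ 18.5 h
#' @export
day_length_minutes <- function(latitude_deg, day_of_year) {
  stopifnot(all(abs(latitude_deg) <= 90))
  g <- 2 * pi / 365 * (day_of_year - 1)
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  phi <- latitude_deg * pi / 180
  zenith <- 90.833 * pi / 180
  cos_ha <- (cos(zenith) - sin(phi) * sin(decl)) / (cos(phi) * cos(decl))
  cos_ha <- pmin(1, pmax(-1, cos_ha))
  ha <- acos(cos_ha)
  8 * ha * 180 / pi  # 2*ha degrees of rotation at 15 deg/h, in minutes
}

#' Default postal-region to latitude mapping
#'
#' Sweden's postal codes start with a digit 1-9; the study design groups
#' them into four large areas and evaluates daylight at a reference city
#' in the middle of each. The paper names neither the cities nor the
#' grouping, so this mapping is an explicit, overridable configuration:
#' south 55.60 N (Malmo), mid 59.33 N (Stockholm), mid-north 62.39 N
#' (Sundsvall), north 67.86 N (Kiruna); digits 2-4 south, 1 and 5-6 mid,
#' 7-8 mid-north, 9 north.
#'
#' @return A list with `latitudes` (named numeric) and `digits` (named
#'   character mapping digit to region).
#' @export
default_region_map <- function() {
  list(latitudes = c(south = 55.60, mid = 59.33,
                     mid_north = 62.39, north = 67.86),
       digits = c("1" = "mid", "2" = "south", "3" = "south",
                  "4" = "south", "5" = "mid", "6" = "mid",
                  "7" = "mid_north", "8" = "mid_north", "9" = "north"))
}

#' Daylight exposure from postal region and assessment month
#'
#' Maps the first digit of the postal code to one of four reference
#' latitudes and evaluates [day_length_minutes()] on the 15th of the
#' assessment month, so all families in a region share one value per
#' month.
#'
#' @param postal_first_digit integer vector, digits 1-9.
#' @param assessment_month integer vector, months 1-12.
#' @param region_map a mapping as returned by [default_region_map()].
#' @return Daylight minutes, vectorized over inputs.
#' @export
assign_region_daylight <- function(postal_first_digit, assessment_month,
                                   region_map = default_region_map()) {
  digit <- as.character(postal_first_digit)
  if (!all(digit %in% names(region_map$digits)))
    stop("configuration error: unmapped postal digit")
  stopifnot(all(assessment_month %in% 1:12))
  region <- region_map$digits[digit]
  lat <- region_map$latitudes[region]
  if (any(is.na(lat)))
    stop("configuration error: region without a latitude")
  month_start <- c(0, 31, 59, 90, 120, 151, 181, 212, 243, 273, 304, 334)
  doy <- month_start[assessment_month] + 15
  unname(day_length_minutes(lat, doy))
}

#' Parse a rendered questionnaire table back into a numeric cohort
#'
#' Applies [parse_duration()] to every phenotype column of a raw
#' response table (as produced by [render_questionnaire()] or read from
#' a questionnaire CSV) and returns a numeric [twin_cohort()] together
#' with per-column provenance tallies.
#'
#' @param raw data frame with twin identifier columns and character
#'   phenotype columns `<phenotype>_<timepoint>`.
#' @param phenotypes phenotype base names; default: inferred from
#'   column names.
#' @param ambiguous_rule passed to [parse_duration()].
#' @return A list with `cohort` (numeric [twin_cohort()]) and
#'   `parse_report` (provenance counts per column).
#' @export
parse_questionnaire <- function(raw, phenotypes = NULL,
                                ambiguous_rule = "lt1") {
  pheno_cols <- grep("_t[0-9]+$", names(raw), value = TRUE)
  if (is.null(phenotypes))
    phenotypes <- unique(sub("_t[0-9]+$", "", pheno_cols))
  tps <- sort(unique(sub("^.*_(t[0-9]+)$", "\\1", pheno_cols)))
  out <- as.data.frame(raw)
  report <- list()
  for (col in pheno_cols) {
    parsed <- parse_duration(out[[col]], ambiguous_rule = ambiguous_rule)
    out[[col]] <- parsed$minutes
    report[[col]] <- table(factor(parsed$provenance,
                                  levels = c("numeric", "range_mean",
                                             "verbal", "excluded_ambiguous",
                                             "missing")))
  }
  list(cohort = twin_cohort(out, phenotypes = phenotypes, timepoints = tps),
       parse_report = report)
}
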