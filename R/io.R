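#' Outcome columns recognised by default
#'
#' The daily-record outcomes the pipeline reports on: total energy
#' expenditure (TEE), physical activity energy expenditure (PAEE), physical
#' activity level (PAL = TEE/RMR), minutes in each activity-intensity band,
#' total energy intake and macronutrient percentages of intake.
#'
#' @return Character vector of outcome column names.
#' @export
default_outcomes <- function() {
  c(
    "tee_kcal", "paee_kcal", "pal",
    "sedentary_min", "light_min", "mvpa_min",
    "intake_kcal", "protein_pct", "fat_pct", "carb_pct", "alcohol_pct"
  )
}

.day_levels <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")

.required_daily_cols <- c("subject_id", "order_index", "day_of_week", "wear_minutes")

#' Read a daily-record table
#'
#' Reads a delimited text file with one row per subject-day. Required
#' columns: `subject_id`, `order_index` (1-based day of entry),
#' `day_of_week` (three-letter English abbreviation), `wear_minutes`.
#' Any further columns named in `schema` are parsed as numeric outcomes;
#' unknown extra columns are kept under their header names. Missing outcome
#' cells are allowed and stay `NA` (absent, not zero).
#'
#' @param path Path to a CSV/TSV file with a header row (delimiter guessed
#'   from the extension; `.tsv` means tab).
#' @param schema Character vector of outcome column names expected in the
#'   file. Defaults to the intersection of [default_outcomes()] with the
#'   header, so arbitrary subsets are fine; name a column explicitly to make
#'   its absence an error.
#' @return A tibble of validated daily records, ordered as in the file.
#' @export
read_daily_table <- function(path, schema = NULL) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing_req <- setdiff(.required_daily_cols, names(raw))
  if (length(missing_req) > 0) {
    abort(sprintf(
      "Daily table is missing required column(s): %s",
      paste(missing_req, collapse = ", ")
    ), class = "ebvar_schema_error")
  }
  if (is.null(schema)) {
    schema <- intersect(default_outcomes(), names(raw))
  } else {
    missing_out <- setdiff(schema, names(raw))
    if (length(missing_out) > 0) {
      abort(sprintf(
        "Daily table is missing outcome column(s): %s",
        paste(missing_out, collapse = ", ")
      ), class = "ebvar_schema_error")
    }
  }
  numeric_cols <- union(c("order_index", "wear_minutes"), schema)
  extra <- setdiff(names(raw), c(.required_daily_cols, schema))
  numeric_cols <- union(numeric_cols, extra[vapply(raw[extra], .looks_numeric, logical(1))])
  out <- raw
  for (col in numeric_cols) {
    vals <- .parse_numeric(raw[[col]], col)
    out[[col]] <- vals
  }
  out$order_index <- as.integer(out$order_index)
  out <- dplyr::relocate(out, dplyr::all_of(.required_daily_cols))
  validate_daily_records(out)
  out
}

.looks_numeric <- function(x) {
  nz <- x[!is.na(x) & x != ""]
  length(nz) > 0 && !anyNA(suppressWarnings(as.numeric(nz)))
}

.parse_numeric <- function(x, col) {
  vals <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(vals) & !is.na(x) & x != "" & toupper(x) != "NA")
  if (length(bad) > 0) {
    abort(sprintf(
      "Non-numeric value '%s' in column '%s' at data row %d",
      x[bad[1]], col, bad[1]
    ), class = "ebvar_parse_error")
  }
  vals
}

#' Validate daily records
#'
#' Checks the structural invariants of a daily-record table: wear minutes in
#' \[0, 1440\], unique (subject, order) pairs, recognised day-of-week labels,
#' intensity-band minutes not exceeding wear minutes (1-minute rounding
#' slack), and macronutrient percentages summing to 100 (0.5 slack) whenever
#' all four are present.
#'
#' @param records Daily-record tibble.
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_daily_records <- function(records) {
  stopifnot(is.data.frame(records))
  missing_req <- setdiff(.required_daily_cols, names(records))
  if (length(missing_req) > 0) {
    abort(sprintf("Missing required column(s): %s", paste(missing_req, collapse = ", ")),
          class = "ebvar_schema_error")
  }
  dup <- duplicated(records[c("subject_id", "order_index")])
  if (any(dup)) {
    d <- records[dup, c("subject_id", "order_index")][1, ]
    abort(sprintf(
      "Duplicate (subject_id, order_index) pair: (%s, %s)",
      d$subject_id, d$order_index
    ), class = "ebvar_integrity_error")
  }
  bad_day <- setdiff(unique(records$day_of_week), .day_levels)
  if (length(bad_day) > 0) {
    abort(sprintf("Unrecognised day_of_week label(s): %s", paste(bad_day, collapse = ", ")),
          class = "ebvar_parse_error")
  }
  w <- records$wear_minutes
  if (any(!is.na(w) & (w < 0 | w > 1440))) {
    abort("wear_minutes must lie in [0, 1440]", class = "ebvar_integrity_error")
  }
  bands <- c("sedentary_min", "light_min", "mvpa_min")
  if (all(bands %in% names(records))) {
    tot <- rowSums(records[bands])
    over <- !is.na(tot) & !is.na(w) & tot > w + 1
    if (any(over)) {
      abort(sprintf(
        "Intensity-band minutes exceed wear minutes for subject %s, order %d",
        records$subject_id[which(over)[1]], records$order_index[which(over)[1]]
      ), class = "ebvar_integrity_error")
    }
  }
  macro <- c("protein_pct", "fat_pct", "carb_pct", "alcohol_pct")
  if (all(macro %in% names(records))) {
    s <- rowSums(records[macro])
    off <- !is.na(s) & abs(s - 100) > 0.5
    if (any(off)) {
      abort(sprintf(
        "Macronutrient percentages sum to %.2f (not 100) for subject %s, order %d",
        s[which(off)[1]], records$subject_id[which(off)[1]],
        records$order_index[which(off)[1]]
      ), class = "ebvar_integrity_error")
    }
  }
  invisible(records)
}

#' Write a daily-record table
#'
#' Inverse of [read_daily_table()]: full-precision CSV so that a
#' write-then-read round trip reproduces the records.
#'
#' @param records Daily-record tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_daily_table <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' Read a subject table
#'
#' Columns: `subject_id`, `age` (years), `sex` (`male`/`female`),
#' `injury_level` (vertebral label such as `"T7"`, converted to an ordinal
#' `injury_level_code` via the coding table), `rmr_kcal` (measured resting
#' metabolic rate, kcal/day).
#'
#' @param path CSV path.
#' @param coding Injury-level coding table (see [injury_level_codes()]).
#' @return Tibble with an added integer `injury_level_code` column.
#' @export
read_subject_table <- function(path, coding = injury_level_codes()) {
  subj <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      age = readr::col_double(),
      sex = readr::col_character(),
      injury_level = readr::col_character(),
      rmr_kcal = readr::col_double()
    ),
    progress = FALSE
  )
  validate_subjects(dplyr::mutate(
    subj,
    injury_level_code = parse_injury_level(.data$injury_level, coding)
  ))
}

#' Validate a subject table
#'
#' @param subjects Subject tibble with `subject_id`, `age`, `sex`,
#'   `injury_level_code`, `rmr_kcal`.
#' @return The input (invisibly returned visible for piping) if valid.
#' @export
validate_subjects <- function(subjects) {
  need <- c("subject_id", "age", "sex", "injury_level_code", "rmr_kcal")
  missing_req <- setdiff(need, names(subjects))
  if (length(missing_req) > 0) {
    abort(sprintf("Subject table missing column(s): %s", paste(missing_req, collapse = ", ")),
          class = "ebvar_schema_error")
  }
  if (anyDuplicated(subjects$subject_id)) {
    abort("subject_id must be unique", class = "ebvar_integrity_error")
  }
  if (any(subjects$rmr_kcal <= 0, na.rm = TRUE) || any(subjects$age <= 0, na.rm = TRUE)) {
    abort("age and rmr_kcal must be positive", class = "ebvar_integrity_error")
  }
  bad_sex <- setdiff(unique(subjects$sex), c("male", "female"))
  if (length(bad_sex) > 0) {
    abort(sprintf("sex must be 'male' or 'female', got: %s", paste(bad_sex, collapse = ", ")),
          class = "ebvar_parse_error")
  }
  subjects
}

#' Read a minute-epoch file
#'
#' Columns: `subject_id`, `timestamp` (ISO 8601 date-time), `met`
#' (metabolic equivalents, non-negative), `worn` (0/1).
#'
#' @param path CSV path.
#' @return Tibble of minute epochs.
#' @export
read_epoch_table <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      timestamp = readr::col_datetime(),
      met = readr::col_double(),
      worn = readr::col_integer()
    ),
    progress = FALSE
  ) |>
    dplyr::mutate(worn = as.logical(.data$worn))
}

#' Filter daily records to valid wear days
#'
#' A day is valid when the monitor was worn for strictly more than
#' `cutoff_fraction` of the day: with the defaults, strictly more than
#' 0.80 x 1440 = 1152 minutes, so a day at exactly 1152 minutes is
#' excluded. Input order is preserved and the result carries a per-subject
#' valid-day count in the `"valid_day_counts"` attribute (also available via
#' [valid_day_counts()]).
#'
#' @param records Daily-record tibble.
#' @param cutoff_fraction Fraction of the day in (0, 1\]; default 0.80.
#' @param day_minutes Minutes in a full day; default 1440.
#' @return The retained records (possibly zero rows).
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   subject_id = "S01", order_index = 1:3, day_of_week = c("Mon", "Tue", "Wed"),
#'   wear_minutes = c(1440, 1152, 1200)
#' )
#' filter_valid_days(rec) # keeps 1440 and 1200; 1152 exactly is dropped
filter_valid_days <- function(records, cutoff_fraction = 0.80, day_minutes = 1440L) {
  if (!is.numeric(cutoff_fraction) || length(cutoff_fraction) != 1 ||
      cutoff_fraction <= 0 || cutoff_fraction > 1) {
    abort("cutoff_fraction must be a single value in (0, 1]",
          class = "ebvar_validation_error")
  }
  threshold <- cutoff_fraction * day_minutes
  attr(records, "valid_day_counts") <- NULL
  keep <- !is.na(records$wear_minutes) & records$wear_minutes > threshold
  out <- records[keep, , drop = FALSE]
  counts <- dplyr::count(tibble::as_tibble(out), .data$subject_id,
                         name = "n_valid_days")
  attr(counts, "valid_day_counts") <- NULL
  attr(out, "valid_day_counts") <- counts
  out
}

#' Per-subject valid-day counts from a filtered table
#'
#' @param records Output of [filter_valid_days()] (falls back to counting
#'   rows per subject if the attribute is absent).
#' @return Tibble with `subject_id` and `n_valid_days`.
#' @export
valid_day_counts <- function(records) {
  counts <- attr(records, "valid_day_counts")
  if (is.null(counts)) {
    counts <- dplyr::count(records, .data$subject_id, name = "n_valid_days")
  }
  counts
}

#' Activity-intensity MET bands
#'
#' Default band boundaries: sedentary behaviour below 1.5 METs,
#' light-intensity activity from 1.5 up to (but excluding) 3.0 METs, and
#' moderate-to-vigorous physical activity (MVPA) at 3.0 METs or above.
#'
#' @param light_min Lower bound of the light band (inclusive).
#' @param mvpa_min Lower bound of the MVPA band (inclusive).
#' @return Named list with the two boundaries.
#' @export
met_bands <- function(light_min = 1.5, mvpa_min = 3.0) {
  stopifnot(light_min > 0, mvpa_min > light_min)
  list(light_min = light_min, mvpa_min = mvpa_min)
}

#' Aggregate minute epochs into per-day intensity summaries
#'
#' Collapses a one-minute MET epoch stream into one row per subject-day:
#' wear minutes (count of worn epochs) and minutes per intensity band,
#' counted over worn epochs only — non-worn minutes are missing data, not
#' sedentary time. Band minutes therefore partition wear minutes exactly.
#'
#' @param epochs Tibble with `subject_id`, `timestamp`, `met`, `worn`.
#' @param bands Band boundaries from [met_bands()].
#' @return Tibble with `subject_id`, `date`, `wear_minutes`,
#'   `sedentary_min`, `light_min`, `mvpa_min`.
#' @export
aggregate_epochs <- function(epochs, bands = met_bands()) {
  stopifnot(all(c("subject_id", "timestamp", "met", "worn") %in% names(epochs)))
  epochs <- dplyr::arrange(epochs, .data$subject_id, .data$timestamp)
  epochs$date <- as.Date(epochs$timestamp)
  check_day <- function(ts, subject, date) {
    mins <- as.numeric(difftime(ts[-1], ts[-length(ts)], units = "mins"))
    if (anyDuplicated(ts)) {
      abort(sprintf("Duplicate timestamp for subject %s on %s", subject, date),
            class = "ebvar_integrity_error")
    }
    if (length(mins) > 0 && any(abs(mins - 1) > 1e-9)) {
      abort(sprintf("Gap in epoch stream for subject %s on %s", subject, date),
            class = "ebvar_integrity_error")
    }
  }
  epochs |>
    dplyr::group_by(.data$subject_id, .data$date) |>
    dplyr::group_modify(function(d, key) {
      check_day(d$timestamp, key$subject_id, key$date)
      worn <- d[d$worn, , drop = FALSE]
      tibble::tibble(
        wear_minutes = nrow(worn),
        sedentary_min = sum(worn$met < bands$light_min),
        light_min = sum(worn$met >= bands$light_min & worn$met < bands$mvpa_min),
        mvpa_min = sum(worn$met >= bands$mvpa_min)
      )
    }) |>
    dplyr::ungroup()
}
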