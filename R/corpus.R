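#' @importFrom tibble tibble as_tibble
NULL

# Canonical corpus column schema: name -> readr column type code.
.corpus_cols <- c(
  study_id               = "c",
  experiment_id          = "c",
  setting                = "c",
  variable               = "c",
  stage                  = "c",
  method_tag             = "c",
  control_salinity_value = "d",
  control_salinity_unit  = "c",
  stress_salinity_value  = "d",
  stress_salinity_unit   = "c",
  control_value          = "d",
  stress_value           = "d",
  stress_duration_days   = "d",
  concentration_basis    = "c",
  n_genotypes            = "d",
  year_label             = "c"
)

#' Corpus column schema
#'
#' Names of the columns of the delimited observation-corpus format: one row
#' per (study, experiment, setting, variable, salinity level) with control
#' and stress means, the salinity of both treatments as value/unit pairs,
#' and optional stress duration, concentration basis, genotype count and
#' year metadata.
#'
#' @return Character vector of column names.
#' @export
corpus_columns <- function() names(.corpus_cols)

# Per-row validation. Returns a character vector of violation messages
# (empty if the row set is clean) alongside a logical keep mask.
.validate_rows <- function(df) {
  n <- nrow(df)
  reasons <- vector("list", n)
  add <- function(idx, msg) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], msg)
  }

  add(is.na(df$study_id) | df$study_id == "", "missing study_id")
  add(!df$setting %in% setting_levels(),
      "unknown setting label")
  add(!df$variable %in% variable_levels(), "unknown variable name")

  stage <- ifelse(is.na(df$stage) | df$stage == "", "none", df$stage)
  growth <- df$variable %in% growth_variables()
  add(!stage %in% c("vegetative", "reproductive", "none"), "unknown stage label")
  add(!growth & stage %in% c("vegetative", "reproductive"),
      "stage label only admissible for growth variables")

  for (side in c("control", "stress")) {
    v <- df[[paste0(side, "_salinity_value")]]
    u <- df[[paste0(side, "_salinity_unit")]]
    add(is.na(v) | v < 0, paste0(side, " salinity value missing or negative"))
    add(is.na(u) | !u %in% salinity_units(),
        paste0(side, " salinity unit missing or unknown"))
  }

  add(is.na(df$control_value) | df$control_value <= 0,
      "control_value must be positive")
  add(is.na(df$stress_value) | df$stress_value < 0,
      "stress_value must be non-negative")
  add(!is.na(df$stress_duration_days) & df$stress_duration_days <= 0,
      "stress_duration_days must be positive when present")
  add(!is.na(df$concentration_basis) &
        !df$concentration_basis %in% c("dry_weight", "fresh_weight"),
      "unknown concentration_basis")

  # Added-salinity rule: the stress treatment must exceed the control in EC.
  ok_sal <- !is.na(df$control_salinity_value) & df$control_salinity_value >= 0 &
    !is.na(df$stress_salinity_value) & df$stress_salinity_value >= 0 &
    df$control_salinity_unit %in% salinity_units() &
    df$stress_salinity_unit %in% salinity_units()
  if (any(ok_sal)) {
    ec_c <- ec_from_unit(ifelse(ok_sal, df$control_salinity_value, 0),
                         ifelse(ok_sal, df$control_salinity_unit, "dS_per_m"))
    ec_s <- ec_from_unit(ifelse(ok_sal, df$stress_salinity_value, 0),
                         ifelse(ok_sal, df$stress_salinity_unit, "dS_per_m"))
    add(ok_sal & ec_s <= ec_c, "stress EC must exceed control EC")
  }
  reasons
}

# Normalize optional text columns and compute the fresh-weight exclusion
# flag. Fresh-weight metabolite rows are kept but flagged excluded.
.finalize_records <- function(df) {
  df$stage <- ifelse(is.na(df$stage) | df$stage == "", "none", df$stage)
  df$experiment_id <- ifelse(is.na(df$experiment_id) | df$experiment_id == "",
                             "E1", df$experiment_id)
  df$excluded_fresh_weight <- df$variable %in% metabolite_variables() &
    !is.na(df$concentration_basis) & df$concentration_basis == "fresh_weight"
  as_tibble(df)
}

#' Validate observation records
#'
#' Checks a data frame of observation rows against the corpus invariants:
#' admissible setting / variable / stage / unit labels, positive control
#' values, non-negative stress values, and stress EC strictly greater than
#' control EC. Fresh-weight metabolite rows are retained but flagged
#' `excluded_fresh_weight` (they are dropped from analysis, not from the
#' corpus).
#'
#' @param df Data frame with the columns of [corpus_columns()] (missing
#'   optional columns are added as `NA`).
#' @return A list with `records` (tibble of valid rows, with the
#'   `excluded_fresh_weight` flag) and `rejections` (tibble with `row` and
#'   `reason` for each invalid input row).
#' @export
validate_corpus <- function(df) {
  missing_mandatory <- setdiff(
    c("study_id", "setting", "variable",
      "control_salinity_value", "control_salinity_unit",
      "stress_salinity_value", "stress_salinity_unit",
      "control_value", "stress_value"),
    names(df))
  if (length(missing_mandatory)) {
    stop("corpus is missing mandatory column(s): ",
         paste(missing_mandatory, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(corpus_columns(), names(df))) {
    df[[col]] <- if (.corpus_cols[[col]] == "d") NA_real_ else NA_character_
  }
  df <- df[corpus_columns()]

  reasons <- .validate_rows(df)
  bad <- !vapply(reasons, is.null, logical(1))
  rejections <- tibble(
    row = which(bad),
    reason = vapply(reasons[bad], paste, character(1), collapse = "; ")
  )
  list(records = .finalize_records(df[!bad, , drop = FALSE]),
       rejections = rejections)
}

#' Read an observation corpus from delimited text
#'
#' Reads a UTF-8 comma-delimited corpus file (one header row, columns as in
#' [corpus_columns()]), validates every row, and returns the valid records
#' together with a rejection report. Malformed rows are never silently
#' dropped: `nrow(records) + nrow(rejections)` equals the number of input
#' rows.
#'
#' @param path Path to the corpus file.
#' @param col_map Optional column mapping for ingesting third-party tables:
#'   either a named character vector (`c(ours = "theirs")`) or the path to a
#'   `key = value` text file with the same content.
#' @return A list with `records` and `rejections` tibbles, as in
#'   [validate_corpus()].
#' @export
read_corpus <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  if (!is.null(col_map)) {
    if (is.character(col_map) && is.null(names(col_map)) &&
        length(col_map) == 1 && file.exists(col_map)) {
      col_map <- .read_key_value(col_map)
    }
    for (ours in names(col_map)) {
      theirs <- col_map[[ours]]
      if (theirs %in% names(raw)) names(raw)[names(raw) == theirs] <- ours
    }
  }
  if (nrow(raw) == 0) {
    warning("empty corpus file: ", path, call. = FALSE)
    res <- validate_corpus(raw[corpus_columns()[corpus_columns() %in% names(raw)]][0, , drop = FALSE])
    return(res)
  }
  # Coerce numeric columns; unparseable cells become NA and are caught by
  # row validation with a named reason.
  for (col in names(.corpus_cols)[.corpus_cols == "d"]) {
    if (col %in% names(raw)) suppressWarnings(raw[[col]] <- as.numeric(raw[[col]]))
  }
  validate_corpus(raw)
}

.read_key_value <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "=", fixed = TRUE)
  vals <- vapply(parts, function(p) trimws(paste(p[-1], collapse = "=")), character(1))
  names(vals) <- vapply(parts, function(p) trimws(p[[1]]), character(1))
  vals
}

#' Write an observation corpus to delimited text
#'
#' Writes records in the canonical comma-delimited corpus format. Reading
#' the file back with [read_corpus()] reproduces the records field for
#' field; absent optional fields round-trip as empty cells.
#'
#' @param records Tibble of observation records (as produced by
#'   [validate_corpus()] or [generate_corpus()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(records, path) {
  out <- records[intersect(corpus_columns(), names(records))]
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
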