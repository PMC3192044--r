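#' Morphometric records
#'
#' The package's tabular data container: one row per animal with columns
#' `animal_id` (opaque label), `sex` (`"M"`, `"F"`, or `"I"` for the
#' indifferent pouch-young stage), `age_months` (may be `NA` for animals of
#' unknown age), `measure` (`"pes"`, `"head"` or `"tail"`) and `value_mm`
#' (positive measurement in mm).  `morph_records()` validates and coerces a
#' data frame to this layout.
#'
#' @param data A data frame with the columns above.
#' @return The validated data frame (class `c("morph_records",
#'   "data.frame")`).
#' @export
morph_records <- function(data) {
  if (inherits(data, "morph_records")) return(data)
  if (!is.data.frame(data)) gs_stop("data must be a data frame", "gs_data_error")
  needed <- c("animal_id", "sex", "age_months", "measure", "value_mm")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    gs_stop(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
            "gs_data_error")
  }
  data <- as.data.frame(data)[needed]
  data$animal_id <- as.character(data$animal_id)
  data$sex <- as.character(data$sex)
  data$measure <- as.character(data$measure)
  data$age_months <- as.numeric(data$age_months)
  data$value_mm <- as.numeric(data$value_mm)
  if (!all(data$sex %in% c("M", "F", "I"))) {
    gs_stop("sex must be one of M, F, I", "gs_data_error")
  }
  if (!all(data$measure %in% c("pes", "head", "tail"))) {
    gs_stop("measure must be one of pes, head, tail", "gs_data_error")
  }
  if (any(!is.finite(data$value_mm) | data$value_mm <= 0)) {
    gs_stop("value_mm must be positive and finite", "gs_data_error")
  }
  if (any(data$age_months < 0, na.rm = TRUE)) {
    gs_stop("age_months must be non-negative", "gs_data_error")
  }
  class(data) <- c("morph_records", "data.frame")
  data
}

#' Read a morphometric CSV file
#'
#' Expected header: `animal_id, sex, age_value, age_unit, measure, value_mm`
#' (comma-separated UTF-8, decimal point).  `sex` is `M`/`F`/`I`; `age_unit`
#' is `days` or `months` and is an explicit column, never inferred from the
#' magnitude of the age; ages are normalised to months (days / 28).
#' `age_value` may be empty for animals of unknown age.  Malformed rows are
#' dropped, each with a recorded reason — never silently.
#'
#' @param path Path to the CSV file.
#' @return A dataset: list with `records` (a [morph_records()] frame of the
#'   kept rows) and `provenance` (source path, `rows_read`, `rows_kept`,
#'   `rows_dropped`, and a data frame `dropped` with one row per dropped
#'   input row and its reason).
#' @export
read_morph_csv <- function(path) {
  if (!file.exists(path)) {
    gs_stop(paste0("file not found: ", path), "gs_format_error")
  }
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) gs_stop(paste0("cannot parse CSV: ", conditionMessage(e)),
                                "gs_format_error")
  )
  needed <- c("animal_id", "sex", "age_value", "age_unit", "measure", "value_mm")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    gs_stop(paste0("missing mandatory column(s): ",
                   paste(missing_cols, collapse = ", ")), "gs_format_error")
  }
  if (nrow(raw) == 0) gs_stop("empty file: no data rows", "gs_format_error")

  drop_row <- function(i, reason) data.frame(row = i, reason = reason)
  dropped <- list()
  keep <- logical(nrow(raw))
  age_months <- rep(NA_real_, nrow(raw))
  value <- suppressWarnings(as.numeric(raw$value_mm))
  age_raw <- trimws(raw$age_value)
  age_num <- suppressWarnings(as.numeric(age_raw))

  for (i in seq_len(nrow(raw))) {
    if (!raw$sex[i] %in% c("M", "F", "I")) {
      dropped[[length(dropped) + 1L]] <- drop_row(i, "unknown sex code")
    } else if (!raw$measure[i] %in% c("pes", "head", "tail")) {
      dropped[[length(dropped) + 1L]] <- drop_row(i, "unknown measure")
    } else if (is.na(value[i]) || value[i] <= 0) {
      dropped[[length(dropped) + 1L]] <- drop_row(i, "non-positive measurement")
    } else if (nzchar(age_raw[i]) && is.na(age_num[i])) {
      dropped[[length(dropped) + 1L]] <- drop_row(i, "unparseable age")
    } else if (nzchar(age_raw[i]) && age_num[i] < 0) {
      dropped[[length(dropped) + 1L]] <- drop_row(i, "negative age")
    } else if (nzchar(age_raw[i]) && !raw$age_unit[i] %in% c("days", "months")) {
      dropped[[length(dropped) + 1L]] <- drop_row(i, "unknown age unit")
    } else {
      keep[i] <- TRUE
      if (nzchar(age_raw[i])) {
        age_months[i] <- if (raw$age_unit[i] == "days")
          days_to_months(age_num[i]) else age_num[i]
      }
    }
  }
  if (!any(keep)) gs_stop("no valid rows in file", "gs_format_error")

  records <- morph_records(data.frame(
    animal_id = raw$animal_id[keep], sex = raw$sex[keep],
    age_months = age_months[keep], measure = raw$measure[keep],
    value_mm = value[keep], stringsAsFactors = FALSE
  ))
  dropped_df <- if (length(dropped)) do.call(rbind, dropped)
                else data.frame(row = integer(), reason = character())
  list(
    records = records,
    provenance = list(
      source = path, rows_read = nrow(raw), rows_kept = sum(keep),
      rows_dropped = nrow(dropped_df), dropped = dropped_df
    )
  )
}

#' Write morphometric records as CSV
#'
#' Inverse of [read_morph_csv()]: writes the standard six-column layout with
#' ages in months.
#'
#' @param records A [morph_records()] frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_morph_csv <- function(records, path) {
  records <- morph_records(records)
  out <- data.frame(
    animal_id = records$animal_id, sex = records$sex,
    age_value = ifelse(is.na(records$age_months), "", records$age_months),
    age_unit = ifelse(is.na(records$age_months), "", "months"),
    measure = records$measure, value_mm = records$value_mm
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
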