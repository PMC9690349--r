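#' Construct a temperature series
#'
#' A validated per-subject, per-setting sensor record: a vector of skin (or
#' personal air) temperatures at nominally 1-minute spacing. Timestamps are
#' normalised to integer minutes from the series start; deviations from the
#' nominal spacing are recorded in a gap summary, never repaired.
#'
#' @param values numeric temperatures in degrees Celsius; finite, length >= 1.
#' @param time integer minute stamps, strictly increasing. Defaults to
#'   `0:(length(values)-1)`.
#' @param subject_id opaque subject identifier.
#' @param setting `"urban"` or `"mountainous"`.
#' @return an object of class `temperature_series`: list with `values`,
#'   `time` (minutes from start), `subject_id`, `setting`, and `gaps`, a data
#'   frame of positions where the spacing deviates from 1 minute.
#' @export
temperature_series <- function(values, time = seq_along(values) - 1,
                               subject_id = NA_character_,
                               setting = NA_character_) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("series must have length >= 1")
  if (anyNA(values) || any(!is.finite(values)))
    stop(sprintf("non-finite or missing temperature at row %d",
                 which(!is.finite(values))[1]))
  time <- as.numeric(time)
  if (length(time) != length(values)) stop("time and values differ in length")
  if (anyNA(time)) stop("missing timestamps")
  if (length(time) > 1L) {
    d <- diff(time)
    bad <- which(d <= 0)
    if (length(bad))
      stop(sprintf("timestamps not strictly increasing at row %d", bad[1] + 1L))
  }
  if (!is.na(setting) && !setting %in% c("urban", "mountainous"))
    stop("setting must be 'urban' or 'mountainous'")
  time <- time - time[1]
  gaps <- if (length(time) > 1L) {
    d <- diff(time)
    idx <- which(d != 1)
    data.frame(after_row = idx, delta_minutes = d[idx])
  } else {
    data.frame(after_row = integer(0), delta_minutes = numeric(0))
  }
  structure(list(values = values, time = time,
                 subject_id = as.character(subject_id),
                 setting = as.character(setting), gaps = gaps),
            class = "temperature_series")
}

#' @export
print.temperature_series <- function(x, ...) {
  cat(sprintf("Temperature series: %d points at 1-min nominal spacing", length(x$values)))
  if (!is.na(x$subject_id)) cat(sprintf(" (subject %s, %s)", x$subject_id, x$setting))
  cat(sprintf("\n  range %.2f-%.2f degC; %d spacing irregularities\n",
              min(x$values), max(x$values), nrow(x$gaps)))
  invisible(x)
}

#' @export
length.temperature_series <- function(x) length(x$values)

# ISO-8601 or bare-number timestamps -> minutes (numeric)
.parse_timestamps <- function(raw) {
  num <- suppressWarnings(as.numeric(raw))
  if (!anyNA(num)) return(num)
  t <- as.POSIXct(raw, tz = "UTC", tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                                  "%Y-%m-%d %H:%M:%OS",
                                                  "%Y-%m-%d %H:%M"))
  if (anyNA(t))
    stop(sprintf("unparseable timestamp at row %d", which(is.na(t))[1]))
  as.numeric(difftime(t, t[1], units = "mins"))
}

#' Read a sensor time series from delimited text
#'
#' @param path CSV file with a header row.
#' @param dialect named list mapping the roles `time` and `temp` to the
#'   column names used in the file. Default `list(time = "t", temp = "temp")`.
#' @param subject_id,setting metadata attached to the returned series.
#' @return a [temperature_series]. Irregular spacing is preserved and
#'   reported in the `gaps` element, never interpolated.
#' @export
read_temperature_series <- function(path, dialect = list(time = "t", temp = "temp"),
                                    subject_id = NA_character_,
                                    setting = NA_character_) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c(dialect$time, dialect$temp), names(df))
  if (length(miss))
    stop(sprintf("format error: missing column(s) %s in %s",
                 paste(miss, collapse = ", "), path))
  tm <- .parse_timestamps(df[[dialect$time]])
  vals <- df[[dialect$temp]]
  if (anyNA(vals))
    stop(sprintf("missing temperature value at row %d of %s",
                 which(is.na(vals))[1], path))
  temperature_series(vals, time = tm, subject_id = subject_id, setting = setting)
}

#' Write a temperature series as CSV
#'
#' Columns `t` (integer minutes from start) and `temp`. Numbers are written
#' with enough digits to round-trip doubles exactly, so
#' `read_temperature_series(write_temperature_series(x))` reproduces `x`.
#'
#' @param x a [temperature_series].
#' @param path output file.
#' @export
write_temperature_series <- function(x, path) {
  stopifnot(inherits(x, "temperature_series"))
  df <- data.frame(t = .fmt_num(x$time), temp = .fmt_num(x$values),
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# shortest-exact decimal for doubles (%.17g round-trips IEEE doubles;
# try fewer digits first so quantized sensor values stay readable)
.fmt_num <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    v <- x[i]
    if (is.na(v)) { out[i] <- "NA"; next }
    s <- sprintf("%.15g", v)
    if (as.numeric(s) != v) s <- sprintf("%.17g", v)
    out[i] <- s
  }
  out
}

#' Write a tabular result as CSV
#'
#' Generic writer for metric tables, filter reports, line histograms and
#' model-result tables. Numeric columns are written with round-trip
#' precision; [read_result_table()] restores them to full float precision.
#'
#' @param x non-empty data frame.
#' @param path output file.
#' @export
write_result_table <- function(x, path) {
  if (!is.data.frame(x) || nrow(x) == 0L)
    stop("refusing to write an empty table")
  out <- x
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- .fmt_num(out[[j]])
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read back a tabular result written by [write_result_table()]
#'
#' @param path CSV file.
#' @return data frame with numeric columns restored.
#' @export
read_result_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read a cohort manifest
#'
#' Expected columns: `subject_id`, `group` (`first_urban` or
#' `first_mountainous`), `age`, `sex`, and per-setting file columns
#' `urban_file`, `mountainous_file` (paths relative to the manifest).
#'
#' @param path manifest CSV.
#' @return data frame, validated: one row per subject, positive ages, known
#'   group labels.
#' @export
read_cohort_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "age", "sex")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop(sprintf("format error: manifest missing column(s) %s",
                 paste(miss, collapse = ", ")))
  if (anyDuplicated(m$subject_id))
    stop("duplicated subject_id in manifest")
  if (any(!m$group %in% c("first_urban", "first_mountainous")))
    stop("unknown group label in manifest")
  if (any(!is.finite(m$age) | m$age <= 0)) stop("ages must be positive")
  m
}

#' Read a hormone measurement table
#'
#' Expected columns: `subject_id`, `setting`, `sample_type` (`first_morning`
#' or `night`), analyte concentrations (`leptin`, `adiponectin`, `cortisol`),
#' `creatinine`, and per-analyte `<analyte>_below_lod` flags and
#' `<analyte>_lod` values.
#'
#' @param path hormone CSV.
#' @param analytes analyte column names expected.
#' @return validated data frame.
#' @export
read_hormone_table <- function(path,
                               analytes = c("leptin", "adiponectin", "cortisol")) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  h <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "setting", "sample_type", analytes, "creatinine")
  miss <- setdiff(need, names(h))
  if (length(miss))
    stop(sprintf("format error: hormone table missing column(s) %s",
                 paste(miss, collapse = ", ")))
  if (any(!h$sample_type %in% c("first_morning", "night")))
    stop("sample_type must be 'first_morning' or 'night'")
  for (a in analytes) {
    if (any(h[[a]] < 0, na.rm = TRUE))
      stop(sprintf("negative concentration in %s", a))
    flag <- paste0(a, "_below_lod")
    lodc <- paste0(a, "_lod")
    if (flag %in% names(h) && lodc %in% names(h)) {
      bad <- which(h[[flag]] & h[[a]] > h[[lodc]])
      if (length(bad))
        stop(sprintf("row %d: %s flagged below LOD but exceeds it", bad[1], a))
    }
  }
  h
}
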